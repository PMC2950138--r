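# Small builders shared across test files.

# peak table with a constant control sum of `csum` and given target heights
toy_peaks <- function(target_heights, probe = "FCGR3B_2", csum = 100,
                      batch = "b1") {
  n <- length(target_heights)
  ids <- sprintf("s%02d", seq_len(n))
  ctrl <- mlpa_control_genes()
  peak_table(
    sample_id = c(rep(ids, each = length(ctrl)), ids),
    probe_id = c(rep(ctrl, n), rep(probe, n)),
    peak_height = c(rep(csum / length(ctrl), n * length(ctrl)), target_heights),
    batch = batch
  )
}

# WT and MT (-256A>TG) promoter alleles
wt_allele <- function() synthetic_promoter()
mt_allele <- function() apply_variant(synthetic_promoter(), fcgr3b_indel_variant())

# base at a promoter coordinate
substr_at <- function(ps, coord) {
  i <- coord - ps$start + 1L - as.integer(ps$start < 0 & coord > 0)
  substr(ps$seq, i, i)
}

# allele sequences for an individual's per-copy WT/MT tags
alleles_for <- function(tags, wt = wt_allele(), mt = mt_allele()) {
  lapply(tags, function(t) if (t == "WT") wt else mt)
}
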