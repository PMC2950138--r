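#' FCGR3B promoter half-probe sequences
#'
#' The three promoter half-probe pairs used for FCGR3B copy-number typing,
#' in target-matching sense, with the junction coordinates used by the
#' bundled synthetic promoter. Probe 1's ligation site sits at promoter
#' position -256, where the -256A>TG indel falls; probe 2 and probe 3
#' junctions are far from it.
#'
#' @return data.frame `probe_id`, `upstream_seq`, `downstream_seq`,
#'   `junction_pos`.
#' @export
fcgr3b_probe_sequences <- function() {
  data.frame(
    probe_id = c("FCGR3B_1", "FCGR3B_2", "FCGR3B_3"),
    upstream_seq = c(
      "CGTGGAGATAATATTGAGGCAGAGACACTGCTAGTGGTCA",
      "CCGACGTACGTATCTAAATCCAGGAGATGGGGGCAAGCATCCTGGGAA",
      "CCCCACCTTGCCTCCAGGCTCTTTCCTTCCTA"
    ),
    downstream_seq = c(
      "AAGATTTGAAAGGACAACTTTCTGTGTGCAGGCAGGGC",
      "AGCTGAGGGCACACTCTGGCAGATTCTGTGTG",
      "TTCCTGTTCTATGGTGGGGCTCCATTGCGAGA"
    ),
    junction_pos = c(-256L, -390L, -149L),
    stringsAsFactors = FALSE
  )
}

#' @rdname fcgr3b_probe_sequences
#' @export
mlpa_control_genes <- function() c("CREBBP", "EXT1", "EP300")

#' The -256A>TG promoter indel
#'
#' Deletion of the adenine 256 bases upstream of the transcription start
#' followed by a TG insertion (net +1 base). It falls exactly at the
#' ligation site of probe FCGR3B_1, abolishing that probe's signal on
#' carrier copies.
#'
#' @return A [variant()].
#' @export
fcgr3b_indel_variant <- function() variant(-256L, "A", "TG", "-256A>TG")

#' Synthetic FCGR3B promoter reference
#'
#' A synthetic stand-in for the FCGR3B promoter: the published half-probe
#' sequences are placed adjacently at their declared junction coordinates
#' (so every probe ligates on this reference by construction) and the
#' remaining bases are deterministic filler. Spans promoter coordinates
#' -600..+100 (no position 0). The real promoter sequence is not
#' redistributed here; only the probe-binding sites are faithful.
#'
#' @return A [promoter_sequence()] with id `"FCGR3B_promoter_synthetic"`.
#' @export
synthetic_promoter <- function() {
  start <- -600L; end <- 100L
  len <- end - start + 1L - 1L                  # no position 0
  state <- 104729
  bases <- character(len)
  for (i in seq_len(len)) {
    state <- (state * 69069 + 1) %% 4294967296
    bases[i] <- c("A", "C", "G", "T")[state %% 4 + 1]
  }
  idx <- function(coord) coord - start + 1L - as.integer(coord > 0)
  pr <- fcgr3b_probe_sequences()
  for (i in seq_len(nrow(pr))) {
    target <- strsplit(paste0(pr$upstream_seq[i], pr$downstream_seq[i]), "")[[1]]
    from <- idx(pr$junction_pos[i]) - nchar(pr$upstream_seq[i]) + 1L
    bases[seq(from, length.out = length(target))] <- target
  }
  promoter_sequence(paste(bases, collapse = ""), start,
                    id = "FCGR3B_promoter_synthetic")
}

#' Default FCGR3B ligation probes
#'
#' @param w junction window (bases each side of the nick), default 10.
#' @return named list of [half_probe_pair()] objects.
#' @export
default_probes <- function(w = 10L) {
  pr <- fcgr3b_probe_sequences()
  probes <- lapply(seq_len(nrow(pr)), function(i) {
    half_probe_pair(pr$probe_id[i], pr$upstream_seq[i], pr$downstream_seq[i],
                    pr$junction_pos[i], w = w)
  })
  names(probes) <- pr$probe_id
  probes
}

#' Simulation parameters for a synthetic case-control cohort
#'
#' Defaults emulate the Dutch cohort the assay was developed on: 518 cases
#' and 304 controls; a control copy-number distribution with 6.7% one-copy,
#' 83.9% two-copy and 9.4% high copy number (split 8%/1%/0.4% across 3/4/5
#' copies); a mutant-indel frequency of 0.407 per gene copy, independent
#' across copies; multiplicative MLPA peak noise with CV 0.07; and Ct
#' replicate noise of 0.15 cycles. Case copy-number distributions are
#' derived from the control distribution through per-class odds ratios
#' (odds-rescale then renormalize), so null and alternative simulations
#' share one code path.
#'
#' @param n_cases,n_controls cohort sizes.
#' @param cn_probs named numeric: control probability of each total copy
#'   number (names are the copy numbers); must sum to 1.
#' @param class_or per-class case:control odds ratios (recycled; default
#'   all 1 = null).
#' @param mt_freq per-copy probability of carrying the -256A>TG indel.
#' @param mlpa_cv lognormal sigma of multiplicative peak noise.
#' @param control_scale total control-probe fluorescence per sample
#'   (arbitrary units).
#' @param ct_target_baseline,ct_reference_baseline Ct of a two-copy target
#'   and of the reference assay (cycles).
#' @param ct_sd replicate Ct noise SD (cycles).
#' @param n_replicates qPCR replicates per sample x assay.
#' @param probe_behavior named character map probe -> one of `counts_all`,
#'   `counts_wt_only`, `no_cnv`.
#' @param seed integer master seed; every random draw of the simulator
#'   derives from it.
#' @return list of class `"sim_params"`.
#' @export
sim_params <- function(n_cases = 518L, n_controls = 304L,
                       cn_probs = c("1" = 0.067, "2" = 0.839,
                                    "3" = 0.080, "4" = 0.010, "5" = 0.004),
                       class_or = 1,
                       mt_freq = 0.407,
                       mlpa_cv = 0.07,
                       control_scale = 3000,
                       ct_target_baseline = 26,
                       ct_reference_baseline = 25,
                       ct_sd = 0.15,
                       n_replicates = 3L,
                       probe_behavior = c(FCGR3B_1 = "counts_wt_only",
                                          FCGR3B_2 = "counts_all",
                                          FCGR3B_3 = "no_cnv"),
                       seed = 1L) {
  stopifnot(n_cases > 0, n_controls > 0,
            abs(sum(cn_probs) - 1) < 1e-8, all(cn_probs >= 0),
            mt_freq >= 0, mt_freq <= 1, mlpa_cv >= 0, ct_sd >= 0,
            n_replicates >= 2L,
            all(probe_behavior %in% c("counts_all", "counts_wt_only", "no_cnv")))
  class_or <- rep_len(class_or, length(cn_probs))
  stopifnot(all(class_or > 0))
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 cn_probs = cn_probs, class_or = class_or,
                 mt_freq = mt_freq, mlpa_cv = mlpa_cv,
                 control_scale = control_scale,
                 ct_target_baseline = ct_target_baseline,
                 ct_reference_baseline = ct_reference_baseline,
                 ct_sd = ct_sd, n_replicates = as.integer(n_replicates),
                 probe_behavior = probe_behavior,
                 seed = as.integer(seed)),
            class = "sim_params")
}

# case-class probabilities from control probabilities + per-class ORs
case_cn_probs <- function(p, or) {
  odds <- p / (1 - p) * or
  q <- ifelse(p >= 1, 1, odds / (1 + odds))
  if (any(!is.finite(q)) || any(q < 0) || any(q > 1)) {
    stop("odds-ratio adjustment drove a class probability out of [0, 1]")
  }
  q / sum(q)
}

#' Simulate a case-control cohort with per-copy indel status
#'
#' Samples each individual's total copy number from the group-specific
#' class distribution, then marks each gene copy independently as mutant
#' with probability `mt_freq`. True per-probe signals follow the probe
#' behavior map: `counts_all` reads the total copies, `counts_wt_only` the
#' wild-type copies, `no_cnv` always reads 2 (phenomenological: the
#' behavior of a probe whose ratios show no copy-number structure).
#' Deterministic under `params$seed`.
#'
#' @param params a [sim_params()].
#' @return data.frame of class `"synthetic_cohort"`: `sample_id`, `status`
#'   (`case`/`control`), `cn`, `wt`, `mt`, one `signal_<probe>` column per
#'   probe, and a `copies` list-column of per-copy `"WT"`/`"MT"` tags.
#'   `params` attached as an attribute.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_cases + params$n_controls
  status <- rep(c("case", "control"), c(params$n_cases, params$n_controls))
  cn_values <- as.integer(names(params$cn_probs))
  p_ctrl <- params$cn_probs
  p_case <- case_cn_probs(p_ctrl, params$class_or)
  cn <- integer(n)
  cn[status == "case"] <-
    cn_values[sample.int(length(cn_values), params$n_cases, TRUE, p_case)]
  cn[status == "control"] <-
    cn_values[sample.int(length(cn_values), params$n_controls, TRUE, p_ctrl)]
  mt <- stats::rbinom(n, cn, params$mt_freq)
  wt <- cn - mt
  copies <- lapply(seq_len(n), function(i)
    c(rep("WT", wt[i]), rep("MT", mt[i])))
  truth <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    status = status, cn = cn, wt = wt, mt = mt,
    stringsAsFactors = FALSE
  )
  for (pb in names(params$probe_behavior)) {
    truth[[paste0("signal_", pb)]] <- switch(
      params$probe_behavior[[pb]],
      counts_all = cn, counts_wt_only = wt, no_cnv = rep(2L, n)
    )
  }
  truth$copies <- I(copies)
  attr(truth, "params") <- params
  class(truth) <- c("synthetic_cohort", "data.frame")
  truth
}

#' Render a synthetic cohort as MLPA peak heights
#'
#' Control-probe heights are drawn around `control_scale / 3` each with
#' multiplicative lognormal noise (sigma = `mlpa_cv`); each target-probe
#' height is its true signal times the sample's control sum times
#' lognormal noise, so the raw dosage ratio is centred on the true copy
#' signal. Zero-signal copies leave a small half-normal background peak
#' whose scale is proportional to the noise level (exactly zero in the
#' noiseless limit). Deterministic under `params$seed`.
#'
#' @param truth a [simulate_cohort()] result.
#' @param params the matching [sim_params()]; defaults to the params
#'   attached to `truth`.
#' @return A [peak_table()] with target and control probes, single batch.
#' @export
render_mlpa <- function(truth, params = attr(truth, "params")) {
  stopifnot(inherits(truth, "synthetic_cohort"), inherits(params, "sim_params"))
  set.seed(params$seed + 1L)
  n <- nrow(truth)
  ctrl <- mlpa_control_genes()
  sig <- params$mlpa_cv
  ch <- matrix(params$control_scale / length(ctrl) *
                 exp(stats::rnorm(n * length(ctrl), 0, sig)),
               n, length(ctrl), dimnames = list(truth$sample_id, ctrl))
  csum <- rowSums(ch)
  targets <- names(params$probe_behavior)
  th <- matrix(0, n, length(targets),
               dimnames = list(truth$sample_id, targets))
  for (p in targets) {
    s <- truth[[paste0("signal_", p)]]
    pos <- s > 0
    th[pos, p] <- s[pos] * csum[pos] * exp(stats::rnorm(sum(pos), 0, sig))
    th[!pos, p] <- csum[!pos] * abs(stats::rnorm(sum(!pos), 0, 0.3 * sig))
  }
  H <- cbind(th, ch)
  peak_table(
    sample_id = rep(rownames(H), ncol(H)),
    probe_id = rep(colnames(H), each = nrow(H)),
    peak_height = as.vector(H),
    batch = "sim"
  )
}

#' Render a synthetic cohort as qPCR Ct replicates
#'
#' Target replicate Ct = baseline - log2(max(copies, 0.5) / 2) + noise;
#' reference replicate Ct = reference baseline + noise (the reference gene
#' has no CNV). The 0.5 floor keeps zero-copy samples finite (background
#' amplification late in the run). Deterministic under `params$seed`.
#'
#' @inheritParams render_mlpa
#' @return long data.frame `sample_id`, `assay` (`target`/`reference`),
#'   `replicate`, `ct`.
#' @export
render_qpcr <- function(truth, params = attr(truth, "params")) {
  stopifnot(inherits(truth, "synthetic_cohort"), inherits(params, "sim_params"))
  set.seed(params$seed + 2L)
  n <- nrow(truth)
  reps <- params$n_replicates
  tgt_mu <- params$ct_target_baseline - log2(pmax(truth$cn, 0.5) / 2)
  out <- rbind(
    data.frame(sample_id = rep(truth$sample_id, each = reps),
               assay = "target", replicate = rep(seq_len(reps), n),
               ct = rep(tgt_mu, each = reps) +
                 stats::rnorm(n * reps, 0, params$ct_sd),
               stringsAsFactors = FALSE),
    data.frame(sample_id = rep(truth$sample_id, each = reps),
               assay = "reference", replicate = rep(seq_len(reps), n),
               ct = params$ct_reference_baseline +
                 stats::rnorm(n * reps, 0, params$ct_sd),
               stringsAsFactors = FALSE)
  )
  out
}

#' Compare calls against the generating truth
#'
#' Tabulates a confusion matrix of true versus called copy number,
#' overall accuracy and per-class recall; when the calls carry `wt`/`mt`
#' columns (genotypes), also the absolute error between the estimated
#' mutant-allele frequency and the frequency realized in the truth.
#'
#' @param truth a [simulate_cohort()] result.
#' @param calls data.frame with `sample_id`, `cn` and optionally
#'   `wt`, `mt`, `valid`.
#' @param signal which truth column the calls measure: `"cn"` (default),
#'   `"wt"`, or any `signal_<probe>` column name.
#' @return list `confusion`, `accuracy`, `recall` (per true class),
#'   `mt_freq_error` (or `NA`).
#' @export
truth_metrics <- function(truth, calls, signal = "cn") {
  stopifnot(inherits(truth, "synthetic_cohort"),
            all(c("sample_id", "cn") %in% names(calls)))
  m <- match(calls$sample_id, truth$sample_id)
  if (anyNA(m)) stop("sample id(s) in calls not present in truth")
  tr <- truth[[signal]][m]
  cf <- table(truth = tr, called = calls$cn)
  acc <- mean(tr == calls$cn)
  recall <- vapply(sort(unique(tr)), function(k)
    mean(calls$cn[tr == k] == k), numeric(1))
  names(recall) <- sort(unique(tr))
  mt_err <- NA_real_
  if (all(c("wt", "mt") %in% names(calls))) {
    ok <- if ("valid" %in% names(calls)) calls$valid else rep(TRUE, nrow(calls))
    ok <- ok & !is.na(calls$wt) & !is.na(calls$mt)
    est <- sum(calls$mt[ok]) / sum(calls$wt[ok] + calls$mt[ok])
    gen <- sum(truth$mt) / sum(truth$cn)
    mt_err <- abs(est - gen)
  }
  list(confusion = cf, accuracy = acc, recall = recall,
       mt_freq_error = mt_err)
}
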