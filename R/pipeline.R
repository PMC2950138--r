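#' End-to-end MLPA copy-number and indel pipeline
#'
#' Runs the full analysis on a raw peak table: sample-to-control ratios,
#' per-batch median-to-2 normalization, a per-probe copy-number mixture
#' ([fit_cn_model()]), integer calls, and — given a WT-only probe and a
#' total-copy probe — per-copy indel genotypes with the discordance
#' exclusion.
#'
#' @param peaks a [peak_table()].
#' @param control_probes control probe ids (default the three control
#'   genes of the FCGR3B assay).
#' @param wt_probe,total_probe probe ids of the WT-only and total-copy
#'   probes; set either to `NULL` to skip genotyping.
#' @param max_cn,seed,posterior_threshold passed to [fit_cn_model()].
#' @return list of class `"mlpa_pipeline"`: `ratios` (normalized
#'   `"ratio_matrix"`), `models` (per-probe `"cn_mixture"`), `calls`
#'   (long data.frame `sample_id`, `probe_id`, `ratio`, `cn`, `posterior`,
#'   `low_conf`, `no_cnv`), and, when both probes are given, `genotypes`
#'   (an `"indel_genotypes"` data.frame) and `exclusions`
#'   (an [exclusion_report()]).
#' @export
mlpa_pipeline <- function(peaks, control_probes = mlpa_control_genes(),
                          wt_probe = "FCGR3B_1", total_probe = "FCGR3B_2",
                          max_cn = 6, seed = 1L, posterior_threshold = 0.9) {
  rr <- compute_ratios(peaks, control_probes)
  nr <- normalize_ratios(rr)
  probes <- colnames(nr$ratios)
  models <- list(); calls <- NULL
  for (p in probes) {
    x <- nr$ratios[!nr$failed, p]
    m <- fit_cn_model(x, max_cn = max_cn, seed = seed,
                      posterior_threshold = posterior_threshold)
    models[[p]] <- m
    pr <- predict(m, nr$ratios[, p])
    calls <- rbind(calls, data.frame(
      sample_id = rownames(nr$ratios), probe_id = p,
      ratio = pr$ratio, cn = pr$cn, posterior = pr$posterior,
      low_conf = pr$low_conf, no_cnv = is_no_cnv(m),
      stringsAsFactors = FALSE
    ))
  }
  out <- list(ratios = nr, models = models, calls = calls)
  if (!is.null(wt_probe) && !is.null(total_probe) &&
      all(c(wt_probe, total_probe) %in% probes)) {
    wide <- data.frame(
      sample_id = rownames(nr$ratios),
      cn_wt = calls$cn[calls$probe_id == wt_probe],
      cn_total = calls$cn[calls$probe_id == total_probe],
      stringsAsFactors = FALSE
    )
    out$exclusions <- exclusion_report(wide)
    out$genotypes <- suppressWarnings(derive_genotypes(wide))
  }
  class(out) <- "mlpa_pipeline"
  out
}

#' @export
print.mlpa_pipeline <- function(x, ...) {
  cat("MLPA pipeline:", nrow(x$ratios$ratios), "samples,",
      length(x$models), "target probe(s)\n")
  for (p in names(x$models)) {
    m <- x$models[[p]]
    cat(sprintf("  %s: K = %d, CN labels %s%s\n", p, m$K,
                paste(m$labels, collapse = "/"),
                if (m$no_cnv) " [no CNV]" else ""))
  }
  if (!is.null(x$exclusions)) {
    cat(sprintf("  genotypes: %d typed, %d excluded (%.2f%%)\n",
                x$exclusions$n_typed, x$exclusions$n_excluded,
                100 * x$exclusions$rate))
  }
  invisible(x)
}

#' Reference cohort counts for the FCGR3B assay
#'
#' The published Dutch rheumatoid-arthritis case-control counts the
#' package's statistics are validated against: per-probe copy-number class
#' counts (three promoter probes), the indel genotype-class counts and the
#' WT/MT allele totals. Rows are `RA` and `Control` throughout.
#'
#' @return list with matrices `probe1` (columns `0`,`1`,`2`,`3` copies),
#'   `probe2` and `probe3` (columns `low`, `2`, `high`), `genotype`
#'   (columns `WT>MT`, `WT=MT`, `WT<MT`) and `alleles` (columns `MT`,
#'   `WT`).
#' @examples
#' cc <- fcgr3b_cohort_counts()
#' odds_ratio(collapse_to_2x2(cc$probe2, "low"))
#' @export
fcgr3b_cohort_counts <- function() {
  g <- c("RA", "Control")
  list(
    probe1 = matrix(c(54, 175, 179, 10,
                      43, 113, 98, 1), 2, 4, byrow = TRUE,
                    dimnames = list(g, c("0", "1", "2", "3"))),
    probe2 = matrix(c(25, 344, 49,
                      17, 213, 24), 2, 3, byrow = TRUE,
                    dimnames = list(g, c("low", "2", "high"))),
    probe3 = matrix(c(3, 416, 0,
                      0, 252, 3), 2, 3, byrow = TRUE,
                    dimnames = list(g, c("low", "2", "high"))),
    genotype = matrix(c(197, 150, 63,
                        102, 97, 51), 2, 3, byrow = TRUE,
                      dimnames = list(g, genotype_classes())),
    alleles = matrix(c(306, 546,
                       207, 302), 2, 2, byrow = TRUE,
                     dimnames = list(g, c("MT", "WT")))
  )
}
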