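#' Aggregate replicate Ct values
#'
#' Arithmetic mean of the replicate Ct values of one sample x assay, with a
#' QC flag when the replicate standard deviation exceeds `sd_threshold`
#' cycles (default 0.5). Fewer than two finite replicates is an error at
#' this level; pipeline callers exclude such samples with a warning.
#'
#' @param replicates numeric Ct values (cycles), typically a triplicate.
#' @param sd_threshold QC threshold on the replicate SD, in cycles.
#' @return list with `mean`, `sd`, `n`, `qc_pass`.
#' @examples
#' aggregate_ct(c(20.0, 20.2, 19.8))
#' @export
aggregate_ct <- function(replicates, sd_threshold = 0.5) {
  r <- as.numeric(replicates)
  r <- r[is.finite(r)]
  if (length(r) < 2L) stop("need at least 2 finite Ct replicates")
  if (any(r <= 0 | r >= 45)) warning("Ct value outside (0, 45)")
  s <- stats::sd(r)
  list(mean = mean(r), sd = s, n = length(r), qc_pass = s <= sd_threshold)
}

#' Copy number from delta-delta Ct
#'
#' Relative quantities Q = 2^(-dCt) are anchored so that the cohort mean
#' copy number is exactly 2 (CN_i = 2 * Q_i / mean(Q)); alternatively a
#' calibrator sample can be the anchor (textbook delta-delta Ct, the
#' calibrator being assigned CN 2). Amplification efficiency is fixed at
#' perfect doubling. Adding a constant to every dCt leaves all estimates
#' unchanged.
#'
#' @param delta_ct per-sample mean target-minus-reference Ct (cycles).
#' @param calibrator optional index (or name) of the calibrator sample; if
#'   `NULL` (default) the cohort mean anchors at 2.
#' @return numeric vector of continuous copy-number estimates.
#' @examples
#' ddct_copy_number(c(5, 5, 5, 4))  # 1.6 1.6 1.6 3.2
#' @export
ddct_copy_number <- function(delta_ct, calibrator = NULL) {
  dct <- as.numeric(delta_ct)
  if (!any(is.finite(dct))) stop("no finite delta-Ct values")
  q <- 2^(-dct)
  anchor <- if (is.null(calibrator)) {
    mean(q[is.finite(q)])
  } else {
    qc <- q[calibrator]
    if (length(qc) != 1L || !is.finite(qc)) stop("invalid calibrator sample")
    qc
  }
  cn <- 2 * q / anchor
  names(cn) <- names(delta_ct)
  cn
}

#' qPCR copy-number estimation from a long Ct table
#'
#' Full ddCt pipeline: replicates of the target and reference assays are
#' aggregated per sample ([aggregate_ct()]), delta-Ct = mean target Ct minus
#' mean reference Ct, and copy number is anchored at cohort mean 2
#' ([ddct_copy_number()]). Samples with fewer than two finite replicates in
#' either assay are excluded with a warning; a replicate-SD QC flag is
#' carried through but flagged samples are retained.
#'
#' @param ct data.frame with columns `sample_id`, `assay`, `ct` (long; one
#'   row per replicate).
#' @param target,reference assay labels (defaults `"target"`, `"reference"`).
#' @param sd_threshold replicate-SD QC threshold in cycles.
#' @param calibrator optional calibrator `sample_id` (see
#'   [ddct_copy_number()]).
#' @return data.frame `sample_id`, `delta_ct`, `q`, `cn_estimate`, `qc_flag`.
#' @export
qpcr_copy_number <- function(ct, target = "target", reference = "reference",
                             sd_threshold = 0.5, calibrator = NULL) {
  stopifnot(all(c("sample_id", "assay", "ct") %in% names(ct)))
  if (!all(c(target, reference) %in% ct$assay)) {
    stop("target/reference assay labels not found in Ct table")
  }
  ids <- unique(ct$sample_id)
  agg <- lapply(ids, function(s) {
    res <- lapply(c(target, reference), function(a) {
      r <- ct$ct[ct$sample_id == s & ct$assay == a]
      tryCatch(aggregate_ct(r, sd_threshold), error = function(e) NULL)
    })
    if (any(vapply(res, is.null, logical(1)))) {
      warning("sample '", s, "' excluded: <2 finite replicates in an assay")
      return(NULL)
    }
    data.frame(sample_id = s,
               delta_ct = res[[1]]$mean - res[[2]]$mean,
               qc_flag = !(res[[1]]$qc_pass && res[[2]]$qc_pass),
               stringsAsFactors = FALSE)
  })
  agg <- do.call(rbind, agg[!vapply(agg, is.null, logical(1))])
  if (is.null(agg) || nrow(agg) == 0L) stop("all samples failed qPCR QC")
  cal <- if (is.null(calibrator)) NULL else match(calibrator, agg$sample_id)
  agg$q <- 2^(-agg$delta_ct)
  agg$cn_estimate <- ddct_copy_number(agg$delta_ct, calibrator = cal)
  agg[, c("sample_id", "delta_ct", "q", "cn_estimate", "qc_flag")]
}

#' Correlate qPCR and MLPA copy-number estimates
#'
#' Pearson product-moment correlation with its two-sided t-based p-value,
#' used to validate one platform against the other.
#'
#' @param qpcr_cn,mlpa_cn numeric vectors of equal length (>= 3).
#' @return list with `r`, `p_value`, `n`.
#' @export
correlate_platforms <- function(qpcr_cn, mlpa_cn) {
  x <- as.numeric(qpcr_cn); y <- as.numeric(mlpa_cn)
  stopifnot(length(x) == length(y), length(x) >= 3L,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in one platform")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Read a Ct table from TSV (long or wide)
#'
#' Long format: columns `sample_id`, `assay`, `replicate`, `ct`. Wide
#' format: `sample_id`, `assay`, `ct_rep1`..`ct_repN`, which is melted to
#' long.
#'
#' @param path file path.
#' @return long-format data.frame `sample_id`, `assay`, `replicate`, `ct`.
#' @export
read_ct_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if ("ct" %in% names(df)) {
    stopifnot(all(c("sample_id", "assay") %in% names(df)))
    if (!"replicate" %in% names(df)) df$replicate <- NA_integer_
    return(df[, c("sample_id", "assay", "replicate", "ct")])
  }
  reps <- grep("^ct_rep", names(df), value = TRUE)
  if (!length(reps)) stop("Ct TSV needs a 'ct' column or ct_rep1..N columns")
  long <- do.call(rbind, lapply(seq_along(reps), function(i) {
    data.frame(sample_id = df$sample_id, assay = df$assay,
               replicate = i, ct = df[[reps[i]]], stringsAsFactors = FALSE)
  }))
  long[order(long$sample_id, long$assay, long$replicate), ]
}
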