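#' Construct an MLPA peak table
#'
#' A peak table holds raw fluorescence peak heights in long format: one row
#' per sample x probe, with an assay-batch label per sample. Heights are in
#' arbitrary fluorescence units and must be nonnegative; an explicit 0 is a
#' biological zero (candidate homozygous deletion), not missing data.
#'
#' @param sample_id character vector of sample identifiers.
#' @param probe_id character vector of probe identifiers.
#' @param peak_height numeric vector of nonnegative peak heights.
#' @param batch batch label per row; a sample must belong to one batch only.
#'   Defaults to a single batch.
#' @return A data.frame of class `"peak_table"` with columns `sample_id`,
#'   `probe_id`, `peak_height`, `batch`.
#' @examples
#' pt <- peak_table(
#'   sample_id = rep(c("s1", "s2"), each = 2),
#'   probe_id = rep(c("FCGR3B_2", "CREBBP"), 2),
#'   peak_height = c(200, 100, 150, 110)
#' )
#' @export
peak_table <- function(sample_id, probe_id, peak_height, batch = "batch1") {
  n <- length(sample_id)
  stopifnot(length(probe_id) == n, length(peak_height) == n)
  if (length(batch) == 1L) batch <- rep(batch, n)
  stopifnot(length(batch) == n)
  peak_height <- as.numeric(peak_height)
  if (any(is.finite(peak_height) & peak_height < 0)) {
    stop("peak heights must be nonnegative")
  }
  df <- data.frame(
    sample_id = as.character(sample_id),
    probe_id = as.character(probe_id),
    peak_height = peak_height,
    batch = as.character(batch),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df[, c("sample_id", "probe_id")])) {
    stop("duplicate sample_id x probe_id entries in peak table")
  }
  sb <- unique(df[, c("sample_id", "batch")])
  if (anyDuplicated(sb$sample_id)) {
    stop("a sample may not belong to more than one batch")
  }
  class(df) <- c("peak_table", "data.frame")
  df
}

#' Read an MLPA peak table from TSV
#'
#' Expects a header with columns `sample_id`, `probe_id`, `peak_height` and
#' optionally `batch` (absent batch = one batch). UTF-8, '.' decimal
#' separator.
#'
#' @param path file path.
#' @return A [peak_table()].
#' @export
read_peaks_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("sample_id", "probe_id", "peak_height")
  if (!all(need %in% names(df))) {
    stop("peaks TSV must have columns: ", paste(need, collapse = ", "))
  }
  batch <- if ("batch" %in% names(df)) df$batch else "batch1"
  peak_table(df$sample_id, df$probe_id, df$peak_height, batch)
}

#' Compute raw sample-to-control dosage ratios
#'
#' Each target-probe peak height is divided by the sum of the control-probe
#' heights of the same sample. Samples whose control sum is not strictly
#' positive fail QC: they are retained in the output with `failed = TRUE`
#' and `NA` ratios so that downstream counts stay auditable, but they are
#' excluded from normalization and statistics.
#'
#' @param peaks a [peak_table()].
#' @param control_probes character vector of control probe ids (>= 1, all
#'   present in `peaks`).
#' @return An object of class `"ratio_matrix"`: a list with elements
#'   `ratios` (sample x target-probe matrix), `batch` (named by sample),
#'   `failed` (logical, named by sample), `control_probes`, `normalized`
#'   (FALSE), `norm_factors` (NULL until [normalize_ratios()]).
#' @export
compute_ratios <- function(peaks, control_probes) {
  stopifnot(inherits(peaks, "peak_table"), length(control_probes) >= 1L)
  probes <- unique(peaks$probe_id)
  missing_ctrl <- setdiff(control_probes, probes)
  if (length(missing_ctrl)) {
    stop("unknown control probe id(s): ", paste(missing_ctrl, collapse = ", "))
  }
  samples <- unique(peaks$sample_id)
  targets <- setdiff(probes, control_probes)
  H <- matrix(NA_real_, length(samples), length(probes),
              dimnames = list(samples, probes))
  H[cbind(peaks$sample_id, peaks$probe_id)] <- peaks$peak_height
  if (anyNA(H[, control_probes, drop = FALSE])) {
    stop("every sample needs a height for every control probe")
  }
  csum <- rowSums(H[, control_probes, drop = FALSE])
  failed <- !(is.finite(csum) & csum > 0)
  if (any(failed)) {
    warning(sum(failed), " sample(s) failed control-sum QC")
  }
  ratios <- H[, targets, drop = FALSE] / csum
  ratios[failed, ] <- NA_real_
  batch <- vapply(samples, function(s) peaks$batch[peaks$sample_id == s][1L],
                  character(1))
  structure(
    list(ratios = ratios, batch = batch, failed = failed,
         control_probes = control_probes, normalized = FALSE,
         norm_factors = NULL),
    class = "ratio_matrix"
  )
}

#' Median-anchor dosage ratios at two copies
#'
#' For each probe within each batch, ratios of passing samples are rescaled
#' so that their median equals `target_level` (default 2, the diploid
#' anchor). Even sample counts use the midpoint of the two central values.
#' Normalizing an already-normalized matrix is the identity.
#'
#' @param raw a `"ratio_matrix"` from [compute_ratios()] (or an already
#'   normalized one, in which case the call is idempotent).
#' @param target_level the ratio assigned to the batch median (default 2.0).
#' @return A `"ratio_matrix"` with `normalized = TRUE` and `norm_factors`,
#'   a batch -> probe matrix of multiplicative factors applied.
#' @export
normalize_ratios <- function(raw, target_level = 2.0) {
  stopifnot(inherits(raw, "ratio_matrix"), target_level > 0)
  batches <- unique(raw$batch)
  out <- raw$ratios
  nf <- matrix(NA_real_, length(batches), ncol(out),
               dimnames = list(batches, colnames(out)))
  for (b in batches) {
    sel <- raw$batch == b & !raw$failed
    if (!any(sel)) stop("batch '", b, "' has no passing samples")
    for (p in colnames(out)) {
      med <- stats::median(raw$ratios[sel, p], na.rm = TRUE)
      if (!is.finite(med) || med <= 0) {
        warning("probe '", p, "' in batch '", b,
                "' has nonpositive median ratio; probe failed for batch")
        out[raw$batch == b, p] <- NA_real_
        next
      }
      f <- target_level / med
      nf[b, p] <- f
      out[raw$batch == b, p] <- raw$ratios[raw$batch == b, p] * f
    }
  }
  res <- raw
  res$ratios <- out
  res$normalized <- TRUE
  res$norm_factors <- nf
  res
}

#' @export
print.ratio_matrix <- function(x, ...) {
  cat(sprintf(
    "MLPA %s dosage ratios: %d samples x %d target probes (%d batch(es), %d QC-failed)\n",
    if (x$normalized) "normalized" else "raw",
    nrow(x$ratios), ncol(x$ratios), length(unique(x$batch)), sum(x$failed)
  ))
  invisible(x)
}

#' Export a ratio matrix as a long TSV
#'
#' Columns: sample_id, probe_id, ratio, qc_flag ("pass"/"fail").
#'
#' @param x a `"ratio_matrix"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ratios_tsv <- function(x, path) {
  stopifnot(inherits(x, "ratio_matrix"))
  long <- data.frame(
    sample_id = rep(rownames(x$ratios), ncol(x$ratios)),
    probe_id = rep(colnames(x$ratios), each = nrow(x$ratios)),
    ratio = as.vector(x$ratios),
    qc_flag = rep(ifelse(x$failed, "fail", "pass"), ncol(x$ratios)),
    stringsAsFactors = FALSE
  )
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
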