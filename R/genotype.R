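#' Derive per-copy indel genotypes from two probes
#'
#' Combines integer copy-number calls from a total-copy probe (counts every
#' gene copy) and a WT-only probe (whose ligation site the indel disrupts,
#' so it counts only wild-type copies): mutant copies = total - WT. A
#' sample whose WT-only call exceeds its total call is physically
#' impossible and is marked invalid — it is reported but excluded from
#' association tables, never "repaired". Samples missing either call are
#' skipped with a warning (distinct from invalid).
#'
#' @param pairs data.frame with columns `sample_id`, `cn_wt` (WT-only
#'   probe call), `cn_total` (total-copy probe call).
#' @return data.frame of class `"indel_genotypes"` with columns
#'   `sample_id`, `wt`, `mt`, `class` (factor `WT>MT`/`WT=MT`/`WT<MT`),
#'   `valid`.
#' @examples
#' derive_genotypes(data.frame(sample_id = c("a", "b", "c"),
#'                             cn_wt = c(2, 1, 3), cn_total = c(2, 2, 2)))
#' @export
derive_genotypes <- function(pairs) {
  stopifnot(all(c("sample_id", "cn_wt", "cn_total") %in% names(pairs)))
  miss <- !is.finite(pairs$cn_wt) | !is.finite(pairs$cn_total)
  if (any(miss)) {
    warning(sum(miss), " sample(s) skipped: missing a copy-number call")
  }
  p <- pairs[!miss, , drop = FALSE]
  stopifnot(all(p$cn_wt >= 0), all(p$cn_total >= 0),
            all(p$cn_wt == round(p$cn_wt)), all(p$cn_total == round(p$cn_total)))
  valid <- p$cn_wt <= p$cn_total
  out <- data.frame(
    sample_id = p$sample_id,
    wt = ifelse(valid, as.integer(p$cn_wt), NA_integer_),
    mt = ifelse(valid, as.integer(p$cn_total - p$cn_wt), NA_integer_),
    valid = valid,
    stringsAsFactors = FALSE
  )
  out$class <- factor(rep(NA_character_, nrow(out)), levels = genotype_classes())
  out$class[valid] <- classify_genotype(out$wt[valid], out$mt[valid])
  out <- out[, c("sample_id", "wt", "mt", "class", "valid")]
  class(out) <- c("indel_genotypes", "data.frame")
  out
}

#' @rdname derive_genotypes
#' @export
genotype_classes <- function() c("WT>MT", "WT=MT", "WT<MT")

#' Classify a WT/MT copy-count pair
#'
#' @param wt,mt nonnegative integer copy counts (vectorized).
#' @return factor with levels `WT>MT`, `WT=MT`, `WT<MT`.
#' @export
classify_genotype <- function(wt, mt) {
  stopifnot(all(wt >= 0), all(mt >= 0))
  factor(ifelse(wt > mt, "WT>MT", ifelse(wt == mt, "WT=MT", "WT<MT")),
         levels = genotype_classes())
}

#' Per-group allele totals and genotype-class counts
#'
#' Allele totals are sums of per-individual WT and MT copy counts — not
#' twice the number of individuals, since copy-number variation makes the
#' total allele count differ from 2n. Invalid genotypes are excluded.
#'
#' @param genotypes an `"indel_genotypes"` data.frame.
#' @param phenotypes data.frame with `sample_id` and `status` (e.g.
#'   `"case"`/`"control"`).
#' @return list of class `"cohort_alleles"`: per group, `wt`, `mt` allele
#'   totals, `mt_freq`, and `classes` (named counts); plus matrices
#'   `allele_table` (group x WT/MT) and `class_table` (group x class)
#'   ready for the association tests.
#' @export
cohort_allele_table <- function(genotypes, phenotypes) {
  stopifnot(inherits(genotypes, "indel_genotypes"),
            all(c("sample_id", "status") %in% names(phenotypes)))
  g <- genotypes[genotypes$valid, , drop = FALSE]
  g$status <- phenotypes$status[match(g$sample_id, phenotypes$sample_id)]
  if (anyNA(g$status)) stop("genotyped sample(s) missing from phenotype table")
  groups <- unique(phenotypes$status)
  per <- lapply(groups, function(gr) {
    gg <- g[g$status == gr, , drop = FALSE]
    if (!nrow(gg)) stop("group '", gr, "' has no valid genotypes")
    list(wt = sum(gg$wt), mt = sum(gg$mt),
         mt_freq = sum(gg$mt) / (sum(gg$wt) + sum(gg$mt)),
         n = nrow(gg),
         classes = table(gg$class))
  })
  names(per) <- groups
  allele_table <- t(vapply(per, function(p) c(MT = p$mt, WT = p$wt), numeric(2)))
  class_table <- t(vapply(per, function(p) as.numeric(p$classes),
                          numeric(length(genotype_classes()))))
  colnames(class_table) <- genotype_classes()
  structure(list(groups = per, allele_table = allele_table,
                 class_table = class_table),
            class = "cohort_alleles")
}

#' @export
print.cohort_alleles <- function(x, ...) {
  for (gr in names(x$groups)) {
    p <- x$groups[[gr]]
    cat(sprintf("%s: n = %d, WT %d (%.1f%%), MT %d (%.1f%%) | %s\n",
                gr, p$n, p$wt, 100 * (1 - p$mt_freq), p$mt, 100 * p$mt_freq,
                paste(sprintf("%s %d", names(p$classes), p$classes),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Exclusion accounting for discordant probe pairs
#'
#' Counts samples whose WT-only call exceeds the total-copy call (a
#' technical impossibility) and reports their fraction of all typed pairs —
#' the assay's technical error rate. A rate of 1 raises a data-integrity
#' alarm.
#'
#' @param pairs data.frame as for [derive_genotypes()].
#' @return list `n_typed`, `n_excluded`, `rate`, `alarm`.
#' @export
exclusion_report <- function(pairs) {
  ok <- is.finite(pairs$cn_wt) & is.finite(pairs$cn_total)
  n <- sum(ok)
  excl <- sum(pairs$cn_wt[ok] > pairs$cn_total[ok])
  rate <- if (n > 0) excl / n else 0
  if (n > 0 && excl == n) warning("every typed pair is discordant: data-integrity alarm")
  list(n_typed = n, n_excluded = excl, rate = rate,
       alarm = n > 0 && excl == n)
}

#' Cohort summary as JSON
#'
#' Serializes a [cohort_allele_table()] result (per-group allele totals,
#' frequencies and genotype-class counts) to a JSON string or file.
#'
#' @param x a `"cohort_alleles"` object.
#' @param path optional output path; if `NULL`, the JSON string is
#'   returned.
#' @return JSON string (invisibly, when written to `path`).
#' @export
cohort_summary_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "cohort_alleles"))
  obj <- lapply(x$groups, function(p) {
    list(n = p$n, wt_alleles = p$wt, mt_alleles = p$mt,
         mt_freq = p$mt_freq, classes = as.list(p$classes))
  })
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
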