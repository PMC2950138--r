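#' Collapse a group x class contingency table to 2x2
#'
#' Sums the "exposed" columns against the rest, per row — e.g. low copy
#' number versus everything else.
#'
#' @param counts matrix of nonnegative integer counts, rows = phenotype
#'   groups, columns = classes.
#' @param exposed character vector of exposed column labels (a strict,
#'   nonempty subset of the columns).
#' @return 2-column matrix with columns `exposed`, `rest`.
#' @examples
#' tab <- rbind(RA = c(low = 25, two = 344, high = 49),
#'              Control = c(17, 213, 24))
#' collapse_to_2x2(tab, "low")
#' @export
collapse_to_2x2 <- function(counts, exposed) {
  stopifnot(is.matrix(counts), all(counts >= 0),
            all(exposed %in% colnames(counts)))
  rest <- setdiff(colnames(counts), exposed)
  if (!length(rest)) stop("exposing every column leaves a degenerate table")
  cbind(exposed = rowSums(counts[, exposed, drop = FALSE]),
        rest = rowSums(counts[, rest, drop = FALSE]))
}

new_assoc_result <- function(method, or = NA_real_, ci = c(NA_real_, NA_real_),
                             statistic = NA_real_, df = NA_integer_,
                             p_value = NA_real_, table = NULL, note = NULL) {
  structure(list(method = method, or = or, ci_low = ci[1], ci_high = ci[2],
                 statistic = statistic, df = df, p_value = p_value,
                 table = table, note = note),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat("Association test [", x$method, "]\n", sep = "")
  if (is.finite(x$or)) {
    cat(sprintf("  OR = %.4f (95%% CI %.4f-%.4f)\n", x$or, x$ci_low, x$ci_high))
  }
  if (is.finite(x$statistic)) {
    cat(sprintf("  chi-square = %.4f, df = %d, p = %.4g\n",
                x$statistic, x$df, x$p_value))
  }
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Odds ratio with Woolf confidence interval
#'
#' OR = (a d)/(b c) for a 2x2 table (rows = groups, columns = exposed/rest,
#' row 1 x column 1 being the exposed cases cell a). The 95% CI is Woolf's
#' log-normal interval `exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' Any zero cell triggers the Haldane-Anscombe correction (0.5 added to
#' every cell) and is tagged in the result; an all-zero row or column is an
#' error.
#'
#' @param tab 2x2 matrix of nonnegative counts.
#' @param conf_level confidence level (default 0.95).
#' @return An `"assoc_result"` with `or`, `ci_low`, `ci_high`.
#' @examples
#' odds_ratio(rbind(c(25, 393), c(17, 237)))  # OR 0.89
#' @export
odds_ratio <- function(tab, conf_level = 0.95) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("odds ratio undefined: a margin of the 2x2 table is zero")
  }
  note <- NULL
  method <- "woolf_ci"
  t2 <- tab
  if (any(tab == 0)) {
    t2 <- tab + 0.5
    method <- "haldane_corrected"
    note <- "zero cell: Haldane-Anscombe 0.5 added to all cells"
  }
  a <- t2[1, 1]; b <- t2[1, 2]; c <- t2[2, 1]; d <- t2[2, 2]
  or <- (a * d) / (b * c)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  new_assoc_result(method, or = or,
                   ci = exp(log(or) + c(-1, 1) * z * se),
                   table = tab, note = note)
}

#' Pearson chi-square test of association
#'
#' Classic sum of (O - E)^2 / E over an r x c table with
#' (r - 1)(c - 1) degrees of freedom and an upper-tail chi-square p-value.
#' No continuity correction is applied. Any zero expected count is an
#' error.
#'
#' @param tab matrix of nonnegative counts, at least 2x2.
#' @return An `"assoc_result"` with `statistic`, `df`, `p_value`.
#' @export
pearson_chi2 <- function(tab) {
  stopifnot(is.matrix(tab), nrow(tab) >= 2, ncol(tab) >= 2, all(tab >= 0))
  n <- sum(tab)
  if (n <= 0) stop("empty table")
  E <- outer(rowSums(tab), colSums(tab)) / n
  if (any(E == 0)) stop("zero expected count")
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  new_assoc_result("pearson", statistic = stat, df = df,
                   p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                   table = tab)
}

#' Cochran-Mantel-Haenszel test over 2x2 strata
#'
#' Continuity-uncorrected CMH chi-square with the Mantel-Haenszel common
#' odds ratio. For a single stratum the statistic reduces to
#' (N - 1)/N times the Pearson chi-square of that table. Strata with a
#' degenerate margin contribute nothing; if all are degenerate it is an
#' error.
#'
#' @param strata a single 2x2 matrix or a list of them.
#' @param conf_level confidence level for the common-OR interval
#'   (Robins-Breslow-Greenland variance).
#' @return An `"assoc_result"` with `statistic` (df 1), `p_value` and the
#'   common `or` with CI.
#' @examples
#' mantel_haenszel(rbind(c(25, 393), c(17, 237)))  # p = 0.71
#' @export
mantel_haenszel <- function(strata, conf_level = 0.95) {
  if (is.matrix(strata)) strata <- list(strata)
  stopifnot(length(strata) >= 1L)
  num <- 0; V <- 0; R <- 0; S <- 0
  PR <- 0; PSQR <- 0; QS <- 0
  used <- 0L
  for (t in strata) {
    stopifnot(is.matrix(t), all(dim(t) == c(2, 2)), all(t >= 0))
    n <- sum(t)
    r1 <- sum(t[1, ]); r2 <- sum(t[2, ]); c1 <- sum(t[, 1]); c2 <- sum(t[, 2])
    if (n < 2 || r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) next
    used <- used + 1L
    a <- t[1, 1]; b <- t[1, 2]; cc <- t[2, 1]; d <- t[2, 2]
    num <- num + (a - r1 * c1 / n)
    V <- V + r1 * r2 * c1 * c2 / (n^2 * (n - 1))
    R <- R + a * d / n
    S <- S + b * cc / n
    # Robins-Breslow-Greenland variance pieces for the common OR
    P <- (a + d) / n; Q <- (b + cc) / n
    PR <- PR + P * (a * d / n)
    PSQR <- PSQR + P * (b * cc / n) + Q * (a * d / n)
    QS <- QS + Q * (b * cc / n)
  }
  if (used == 0L || V <= 0) stop("all strata degenerate")
  stat <- num^2 / V
  or <- if (S > 0) R / S else NA_real_
  ci <- c(NA_real_, NA_real_)
  if (is.finite(or) && or > 0 && R > 0 && S > 0) {
    se <- sqrt(PR / (2 * R^2) + PSQR / (2 * R * S) + QS / (2 * S^2))
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- exp(log(or) + c(-1, 1) * z * se)
  }
  new_assoc_result("mantel_haenszel", or = or, ci = ci, statistic = stat,
                   df = 1L, p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
                   table = strata)
}

#' Allelic association test on WT/MT allele totals
#'
#' Each gene copy is counted once (allele totals per group), and the 2x2
#' allele table is tested with [odds_ratio()] (Woolf CI) and
#' [pearson_chi2()].
#'
#' @param tab 2x2 matrix: rows = groups, columns = alleles (exposed allele
#'   first).
#' @param conf_level confidence level for the Woolf CI.
#' @return An `"assoc_result"` combining OR, CI, chi-square and p-value.
#' @examples
#' allelic_test(rbind(RA = c(MT = 306, WT = 546), Control = c(207, 302)))
#' @export
allelic_test <- function(tab, conf_level = 0.95) {
  o <- odds_ratio(tab, conf_level)
  p <- pearson_chi2(tab)
  new_assoc_result(paste0("allelic(", o$method, ")"),
                   or = o$or, ci = c(o$ci_low, o$ci_high),
                   statistic = p$statistic, df = p$df, p_value = p$p_value,
                   table = tab, note = o$note)
}
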