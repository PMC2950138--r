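#' Fit a one-dimensional Gaussian mixture to dosage ratios
#'
#' Formalizes by-eye cluster assignment of normalized MLPA ratios as a
#' reproducible model: for each candidate number of components K = 1..
#' `max_cn + 1`, a univariate Gaussian mixture is fitted by EM (k-means++
#' initialization, variance floor), and K is chosen by BIC, resolving ties
#' of less than 2 units toward the smaller K. Components are then labeled
#' with integer copy numbers (see Details) and the fitted object supports
#' `print`, `summary`, `coef`, `predict`, `plot`, `simulate` and `logLik`.
#'
#' @details
#' Copy-number labels: the highest-weight (modal) component is anchored at
#' CN 2 — median-to-2 normalization presupposes the modal individual is
#' diploid — giving a provisional unit spacing u = modal mean / 2; each
#' component gets label round(mean/u), components with mean below `0.3 * u`
#' are labeled CN 0, and components whose labels collide are merged
#' (moment-matched) with a warning. When the resulting nonzero labels share
#' a common integer factor (e.g. labels 0/2/4/6), copy-number states are
#' assumed adjacent and the labels are divided through: this resolves the
#' harmonic ambiguity that arises for probes that count only a subset of
#' gene copies, for which the modal individual carries one countable copy
#' rather than two. A model that collapses to a single component is flagged
#' `no_cnv` and calls a constant CN 2.
#'
#' @param x numeric vector of (normalized) dosage ratios; `NA` dropped.
#' @param max_cn largest copy number entertained (default 6; K ranges over
#'   1..max_cn+1 but is also capped at `floor(n/2)` and at the number of
#'   distinct values).
#' @param seed integer seed controlling the k-means++ initialization.
#' @param var_floor lower bound on component variances; default
#'   `(1e-3 * sd(x))^2`, which keeps the likelihood finite on noiseless
#'   (degenerate) clusters.
#' @param posterior_threshold calls with maximum posterior below this are
#'   flagged low-confidence (default 0.9).
#' @return An object of class `"cn_mixture"`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(60, 1, 0.07), rnorm(480, 2, 0.07), rnorm(60, 3, 0.07))
#' m <- fit_cn_model(x, seed = 1)
#' summary(m)
#' head(predict(m, c(0.02, 1.1, 2.0, 2.9)))
#' @export
fit_cn_model <- function(x, max_cn = 6, seed = 1L, var_floor = NULL,
                         posterior_threshold = 0.9) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 10L) stop("need at least 10 passing samples to fit a mixture")
  if (any(x < 0)) stop("dosage ratios must be >= 0")
  sx <- stats::sd(x)
  if (is.null(var_floor)) var_floor <- (1e-3 * max(sx, 1e-6))^2
  n_distinct <- length(unique(round(x / max(sx, 1e-12), 8)))
  k_max <- min(max_cn + 1L, floor(n / 2), max(n_distinct, 1L))
  if (k_max < max_cn + 1L) {
    warning("candidate components capped at K = ", k_max,
            " by sample count / distinct values")
  }
  fits <- vector("list", k_max)
  bic_tab <- data.frame(K = seq_len(k_max), loglik = NA_real_, bic = NA_real_)
  for (K in seq_len(k_max)) {
    f <- tryCatch(em_1d(x, K, seed = seed, var_floor = var_floor),
                  error = function(e) NULL)
    if (is.null(f)) next
    fits[[K]] <- f
    bic_tab$loglik[K] <- f$loglik
    bic_tab$bic[K] <- -2 * f$loglik + (3 * K - 1) * log(n)
  }
  ok <- which(is.finite(bic_tab$bic))
  if (!length(ok)) stop("no mixture candidate could be fitted")
  best <- min(bic_tab$bic[ok])
  K_sel <- min(bic_tab$K[ok][bic_tab$bic[ok] < best + 2])  # ties -> smaller K
  f <- fits[[K_sel]]
  lab <- label_components(f$means, f$vars, f$weights)
  model <- structure(
    list(K = length(lab$means), means = lab$means, vars = lab$vars,
         weights = lab$weights, labels = lab$labels, unit = lab$unit,
         no_cnv = length(lab$means) == 1L,
         merged = lab$merged, boundaries = NULL,
         posterior_threshold = posterior_threshold,
         loglik = f$loglik, n = n, bic_table = bic_tab,
         data = x, seed = seed, var_floor = var_floor),
    class = "cn_mixture"
  )
  model$boundaries <- component_boundaries(model)
  model
}

# k-means++ center selection (1-D), deterministic under the supplied seed
kmeanspp_centers <- function(x, K, seed) {
  centers <- numeric(K)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  centers[1] <- x[sample.int(length(x), 1L)]
  if (K > 1L) {
    for (k in 2:K) {
      d2 <- vapply(x, function(v) min((v - centers[1:(k - 1)])^2), numeric(1))
      if (sum(d2) <= 0) stop("fewer distinct values than components")
      centers[k] <- x[sample.int(length(x), 1L, prob = d2)]
    }
  }
  sort(centers)
}

# EM for a univariate Gaussian mixture with a variance floor
em_1d <- function(x, K, seed, var_floor, max_iter = 500L, tol = 1e-8) {
  n <- length(x)
  if (K == 1L) {
    mu <- mean(x); v <- max(stats::var(x) * (n - 1) / n, var_floor)
    ll <- sum(stats::dnorm(x, mu, sqrt(v), log = TRUE))
    return(list(means = mu, vars = v, weights = 1, loglik = ll))
  }
  centers <- kmeanspp_centers(x, K, seed)
  km <- suppressWarnings(stats::kmeans(x, centers = matrix(centers, ncol = 1)))
  mu <- as.numeric(km$centers)
  w <- tabulate(km$cluster, K) / n
  v <- vapply(seq_len(K), function(k) {
    xs <- x[km$cluster == k]
    if (length(xs) < 2L) var_floor else max(stats::var(xs), var_floor)
  }, numeric(1))
  w <- pmax(w, 1e-10); w <- w / sum(w)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(K), function(k)
      log(w[k]) + stats::dnorm(x, mu[k], sqrt(v[k]), log = TRUE),
      numeric(n))
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    r <- exp(logd - lse)                     # n x K responsibilities
    nk <- pmax(colSums(r), 1e-10)
    w <- nk / n
    mu <- colSums(r * x) / nk
    v <- pmax(colSums(r * (outer(x, mu, "-")^2)) / nk, var_floor)
    # guard against spurious one-point spikes: no component may be more
    # than 20x tighter (in variance) than the mixture's weighted average
    v <- pmax(v, 0.05 * sum(w * v))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  o <- order(mu)
  list(means = mu[o], vars = v[o], weights = w[o], loglik = ll)
}

# Integer copy-number labelling of mixture components (see fit_cn_model)
label_components <- function(means, vars, weights) {
  merged <- FALSE
  repeat {
    K <- length(means)
    modal <- which.max(weights)
    u <- means[modal] / 2
    if (!is.finite(u) || u <= 0) u <- max(means) / 2
    if (u <= 0) u <- 1  # all-zero degenerate probe
    # refine the ratio-per-copy unit from the spacing of adjacent non-zero
    # components: robust to a modal component that is not diploid (WT-only
    # probes) and to drift of high-copy component means; spacings far from
    # the anchor scale (sub-clusters, skipped states) are not trusted
    nzm <- means[means >= 0.3 * u]
    if (length(nzm) >= 2L) {
      d <- stats::median(diff(nzm))
      if (d >= 0.6 * u && d <= 2.5 * u) u <- d
    }
    labels <- as.integer(round(means / u))
    labels[means < 0.3 * u] <- 0L
    if (anyDuplicated(labels) && K > 1L) {
      # merge the first colliding pair (moment-matched), then relabel
      d <- which(duplicated(labels))[1L]
      i <- which(labels == labels[d])[1:2]
      wsum <- sum(weights[i])
      m <- sum(weights[i] * means[i]) / wsum
      v <- sum(weights[i] * (vars[i] + means[i]^2)) / wsum - m^2
      means <- c(means[-i], m); vars <- c(vars[-i], v)
      weights <- c(weights[-i], wsum)
      o <- order(means)
      means <- means[o]; vars <- vars[o]; weights <- weights[o]
      merged <- TRUE
      warning("merged mixture components with duplicate copy-number labels")
      next
    }
    break
  }
  nz <- labels[labels > 0L]
  if (length(nz) >= 1L && length(labels) >= 2L) {
    g <- Reduce(gcd2, nz)
    if (g >= 2L) {       # harmonic ambiguity: assume adjacent CN states
      labels <- labels %/% g
      u <- u * g
    }
  }
  list(means = means, vars = vars, weights = weights,
       labels = labels, unit = u, merged = merged)
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

# Decision boundaries between adjacent components: the ratio where the two
# weighted densities cross (guarantees calls monotone in ratio).
component_boundaries <- function(model) {
  K <- model$K
  if (K == 1L) return(numeric(0))
  b <- numeric(K - 1)
  for (k in seq_len(K - 1)) {
    f <- function(t) {
      log(model$weights[k]) +
        stats::dnorm(t, model$means[k], sqrt(model$vars[k]), log = TRUE) -
        log(model$weights[k + 1]) -
        stats::dnorm(t, model$means[k + 1], sqrt(model$vars[k + 1]), log = TRUE)
    }
    lo <- model$means[k]; hi <- model$means[k + 1]
    if (f(lo) > 0 && f(hi) < 0) {
      b[k] <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
    } else {
      b[k] <- (lo + hi) / 2  # pathological weights: fall back to midpoint
    }
  }
  b
}

#' Assign integer copy numbers from a fitted mixture
#'
#' Ratios are assigned by the decision boundaries between adjacent
#' components (where the weighted component densities cross), which makes
#' calls non-decreasing in the ratio; the posterior probability of the
#' assigned component is recorded and calls below the model's posterior
#' threshold are flagged low-confidence. A `no_cnv` model calls a constant
#' CN 2.
#'
#' @param object a `"cn_mixture"` from [fit_cn_model()].
#' @param newdata numeric ratios to call; defaults to the training data.
#' @param ... unused.
#' @return data.frame with columns `ratio`, `cn`, `posterior`, `low_conf`.
#' @export
predict.cn_mixture <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data else as.numeric(newdata)
  out <- data.frame(ratio = x, cn = NA_integer_,
                    posterior = NA_real_, low_conf = NA)
  fin <- is.finite(x)
  if (object$K == 1L) {
    out$cn[fin] <- object$labels[1L]
    out$posterior[fin] <- 1
    out$low_conf[fin] <- FALSE
    return(out)
  }
  comp <- findInterval(x[fin], object$boundaries) + 1L
  logd <- vapply(seq_len(object$K), function(k)
    log(object$weights[k]) +
      stats::dnorm(x[fin], object$means[k], sqrt(object$vars[k]), log = TRUE),
    numeric(sum(fin)))
  logd <- matrix(logd, nrow = sum(fin))
  m <- apply(logd, 1, max)
  post <- exp(logd - (m + log(rowSums(exp(logd - m)))))
  out$cn[fin] <- object$labels[comp]
  out$posterior[fin] <- post[cbind(seq_len(sum(fin)), comp)]
  out$low_conf[fin] <- out$posterior[fin] < object$posterior_threshold
  out
}

#' Does a fitted ratio mixture show no copy-number variation?
#'
#' TRUE iff the model has a single component (possibly after label merging),
#' the situation of a probe whose ratios form one unimodal cloud; such
#' probes yield constant CN 2 calls.
#'
#' @param model a `"cn_mixture"`.
#' @return logical.
#' @export
is_no_cnv <- function(model) {
  stopifnot(inherits(model, "cn_mixture"))
  isTRUE(model$no_cnv)
}

#' @export
print.cn_mixture <- function(x, ...) {
  cat(sprintf("Copy-number mixture: K = %d component(s), n = %d, unit = %.3f%s\n",
              x$K, x$n, x$unit, if (x$no_cnv) " [no CNV]" else ""))
  cat("  CN labels:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' @method summary cn_mixture
#' @export
summary.cn_mixture <- function(object, ...) {
  tab <- data.frame(cn = object$labels, mean = object$means,
                    sd = sqrt(object$vars), weight = object$weights)
  res <- list(components = tab, K = object$K, n = object$n,
              unit = object$unit, no_cnv = object$no_cnv,
              loglik = object$loglik, bic_table = object$bic_table)
  class(res) <- "summary.cn_mixture"
  res
}

#' @export
print.summary.cn_mixture <- function(x, ...) {
  cat(sprintf("Copy-number mixture (n = %d, K = %d, unit spacing %.3f%s)\n",
              x$n, x$K, x$unit, if (x$no_cnv) ", no CNV" else ""))
  print(x$components, row.names = FALSE, digits = 4)
  cat("BIC by candidate K:\n")
  print(x$bic_table, row.names = FALSE, digits = 6)
  invisible(x)
}

#' @method coef cn_mixture
#' @export
coef.cn_mixture <- function(object, ...) {
  data.frame(cn = object$labels, mean = object$means,
             var = object$vars, weight = object$weights)
}

#' @method logLik cn_mixture
#' @export
logLik.cn_mixture <- function(object, ...) {
  structure(object$loglik, df = 3 * object$K - 1, nobs = object$n,
            class = "logLik")
}

#' @method plot cn_mixture
#' @export
plot.cn_mixture <- function(x, breaks = 50, ...) {
  h <- graphics::hist(x$data, breaks = breaks, freq = FALSE,
                      main = "Dosage-ratio mixture", xlab = "normalized ratio",
                      col = "grey90", border = "grey70", ...)
  xs <- seq(min(x$data), max(x$data), length.out = 512)
  for (k in seq_len(x$K)) {
    graphics::lines(xs, x$weights[k] * stats::dnorm(xs, x$means[k], sqrt(x$vars[k])),
                    col = k + 1, lwd = 2)
    graphics::text(x$means[k], max(h$density) * 0.95, labels = x$labels[k],
                   col = k + 1)
  }
  invisible(x)
}

#' @export
simulate.cn_mixture <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(object$K, nsim, replace = TRUE, prob = object$weights)
  stats::rnorm(nsim, object$means[comp], sqrt(object$vars[comp]))
}

#' Construct a copy-number mixture from explicit parameters
#'
#' Builds a `"cn_mixture"` directly from component means, variances, weights
#' and integer labels, bypassing fitting — useful for simulation studies and
#' for calling against a reference model.
#'
#' @param means,vars,weights,labels parallel numeric/integer vectors;
#'   means must be strictly increasing, weights sum to 1.
#' @param posterior_threshold low-confidence flag threshold (default 0.9).
#' @return A `"cn_mixture"`.
#' @export
cn_mixture_model <- function(means, vars, weights, labels,
                             posterior_threshold = 0.9) {
  K <- length(means)
  stopifnot(length(vars) == K, length(weights) == K, length(labels) == K,
            all(diff(means) > 0), all(vars > 0),
            abs(sum(weights) - 1) < 1e-8, all(labels >= 0))
  m <- structure(
    list(K = K, means = means, vars = vars, weights = weights / sum(weights),
         labels = as.integer(labels),
         unit = if (K > 1) stats::median(diff(means)) else means[1] / 2,
         no_cnv = K == 1L, merged = FALSE, boundaries = NULL,
         posterior_threshold = posterior_threshold,
         loglik = NA_real_, n = 0L,
         bic_table = NULL, data = numeric(0), seed = NA_integer_,
         var_floor = NA_real_),
    class = "cn_mixture"
  )
  m$boundaries <- component_boundaries(m)
  m
}
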