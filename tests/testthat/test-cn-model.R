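test_that("a single tight cluster fits one component labeled CN 2", {
  set.seed(1)
  m <- fit_cn_model(rnorm(200, 2, 0.02), seed = 1)
  expect_equal(m$K, 1L)
  expect_equal(m$labels, 0:0 + 2L)
  expect_true(is_no_cnv(m))
  pr <- predict(m, c(1.9, 2.0, 2.1))
  expect_equal(pr$cn, rep(2L, 3))
})

test_that("three well-separated clusters are recovered with correct labels", {
  set.seed(17)
  x <- c(rnorm(60, 1, 0.07), rnorm(480, 2, 0.07), rnorm(60, 3, 0.07))
  m <- fit_cn_model(x, seed = 17)
  expect_equal(m$K, 3L)
  expect_equal(m$labels, 1:3)
  expect_true(all(abs(m$means - 1:3) < 0.05))
  expect_equal(sum(m$weights), 1, tolerance = 1e-9)
})

test_that("unstructured unimodal data selects K = 1 and flags no CNV", {
  set.seed(5)
  # candidate components inside the uniform blob merge under one label
  m <- suppressWarnings(fit_cn_model(runif(400, 1.7, 2.3), seed = 5))
  expect_equal(m$K, 1L)
  expect_true(is_no_cnv(m))
})

test_that("near-zero cluster is labeled CN 0 and calls ratio 0.02 as CN 0", {
  set.seed(9)
  x <- c(abs(rnorm(60, 0, 0.015)), rnorm(300, 1, 0.06), rnorm(240, 2, 0.06))
  m <- fit_cn_model(x, seed = 9)
  expect_equal(m$labels, c(0L, 1L, 2L))
  expect_equal(predict(m, 0.02)$cn, 0L)
})

test_that("labels sharing a common factor are rescaled to adjacent states", {
  # a probe counting only a subset of copies: clusters at 0 / 2 / 4 after
  # median-to-2 anchoring must mean 0 / 1 / 2 countable copies
  set.seed(21)
  x <- c(abs(rnorm(50, 0, 0.01)), rnorm(300, 2, 0.05), rnorm(120, 4, 0.08))
  m <- fit_cn_model(x, seed = 21)
  expect_equal(m$labels, c(0L, 1L, 2L))
  expect_equal(m$unit, 2, tolerance = 0.05)
  expect_equal(predict(m, c(0.01, 2.1, 3.9))$cn, c(0L, 1L, 2L))
})

test_that("components rounding to the same label merge into no-CNV", {
  set.seed(3)
  x <- c(rnorm(100, 1.98, 0.004), rnorm(100, 2.02, 0.004))
  expect_warning(m <- fit_cn_model(x, seed = 3), "merged")
  expect_equal(m$K, 1L)
  expect_true(is_no_cnv(m))
})

test_that("calls are non-decreasing in the ratio for any fitted model", {
  set.seed(33)
  for (rep in 1:5) {
    K <- sample(2:4, 1)
    mu <- sort(sample(1:5, K))
    x <- unlist(lapply(mu, function(m) rnorm(80, m, runif(1, 0.04, 0.12))))
    m <- suppressWarnings(fit_cn_model(x, seed = rep))
    grid <- seq(min(x) - 0.2, max(x) + 0.2, length.out = 400)
    cn <- predict(m, grid)$cn
    expect_true(all(diff(cn) >= 0))
  }
})

test_that("a ratio midway between two equal components has posterior 0.5", {
  m <- cn_mixture_model(means = c(1, 2), vars = c(0.01, 0.01),
                        weights = c(0.5, 0.5), labels = c(1L, 2L))
  pr <- predict(m, 1.5)
  expect_equal(pr$posterior, 0.5, tolerance = 1e-9)
  expect_true(pr$low_conf)
  # at the modal component mean the call is the anchor with high posterior
  expect_equal(predict(m, 2)$cn, 2L)
  expect_gte(predict(m, 2)$posterior, 0.5)
})

test_that("fitting is deterministic under identical seed and data", {
  set.seed(8)
  x <- c(rnorm(100, 1, 0.07), rnorm(300, 2, 0.07))
  m1 <- fit_cn_model(x, seed = 99)
  m2 <- fit_cn_model(x, seed = 99)
  expect_identical(m1[c("means", "vars", "weights", "labels")],
                   m2[c("means", "vars", "weights", "labels")])
  expect_identical(predict(m1), predict(m2))
})

test_that("candidate K is capped by sample count with a warning", {
  set.seed(2)
  expect_warning(m <- fit_cn_model(rnorm(11, 2, 0.1), seed = 2), "capped")
  expect_lte(m$K, 5L)
})

test_that("noiseless integer ratios are fitted exactly", {
  x <- rep(c(0, 1, 2, 3), c(20, 50, 100, 15))
  m <- suppressWarnings(fit_cn_model(x, seed = 1))
  expect_equal(m$labels, 0:3)
  expect_equal(m$means, 0:3, tolerance = 1e-6)
  expect_equal(predict(m, x)$cn, as.integer(x))
})

test_that("mixture means agree with an independent EM implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(17)
  x <- c(rnorm(60, 1, 0.07), rnorm(480, 2, 0.07), rnorm(60, 3, 0.07))
  m <- fit_cn_model(x, seed = 17)
  ref <- Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
  expect_equal(sort(m$means), sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.02)
  expect_equal(ref$G, m$K)
})

test_that("simulate() draws reproduce the fitted mixture's moments", {
  m <- cn_mixture_model(means = c(1, 2, 3), vars = rep(0.07^2, 3),
                        weights = c(0.1, 0.8, 0.1), labels = 1:3)
  y <- simulate(m, nsim = 20000, seed = 12)
  expect_equal(mean(y), sum(m$weights * m$means), tolerance = 0.02)
  frac <- as.numeric(prop.table(table(predict(m, y)$cn)))
  expect_equal(frac, m$weights, tolerance = 0.02)
})
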