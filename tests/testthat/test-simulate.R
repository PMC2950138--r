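test_that("identical parameters give byte-identical cohorts and renders", {
  p <- sim_params(n_cases = 40, n_controls = 30, seed = 77)
  t1 <- simulate_cohort(p); t2 <- simulate_cohort(p)
  expect_identical(t1, t2)
  expect_identical(render_mlpa(t1), render_mlpa(t2))
  expect_identical(render_qpcr(t1), render_qpcr(t2))
  # a different seed changes the draw
  t3 <- simulate_cohort(sim_params(n_cases = 40, n_controls = 30, seed = 78))
  expect_false(identical(t1$cn, t3$cn))
})

test_that("degenerate parameters give an all-(WT,WT) diploid cohort", {
  p <- sim_params(n_cases = 15, n_controls = 15, cn_probs = c("2" = 1),
                  mt_freq = 0, seed = 3)
  tr <- simulate_cohort(p)
  expect_true(all(tr$cn == 2))
  expect_true(all(tr$mt == 0))
  expect_true(all(vapply(tr$copies, function(cp)
    identical(cp, c("WT", "WT")), logical(1))))
  expect_equal(tr$signal_FCGR3B_1, tr$signal_FCGR3B_2)
})

test_that("large-cohort class and allele fractions match the generator", {
  p <- sim_params(n_cases = 5000, n_controls = 5000, seed = 41)
  tr <- simulate_cohort(p)
  n <- nrow(tr)
  # MT allele fraction within 3 binomial SE of 0.407
  alleles <- sum(tr$cn)
  se_mt <- sqrt(0.407 * 0.593 / alleles)
  expect_lt(abs(sum(tr$mt) / alleles - 0.407), 3 * se_mt)
  # low (1 copy) and high (>=3 copies) class fractions near 0.067 / 0.094
  expect_lt(abs(mean(tr$cn == 1) - 0.067), 3 * sqrt(0.067 * 0.933 / n))
  expect_lt(abs(mean(tr$cn >= 3) - 0.094), 3 * sqrt(0.094 * 0.906 / n))
})

test_that("per-class odds ratios reshape the case distribution correctly", {
  p <- sim_params(class_or = c(2, 1, 1, 1, 1), seed = 1)
  tr <- simulate_cohort(sim_params(n_cases = 20000, n_controls = 100,
                                   class_or = c(2, 1, 1, 1, 1), seed = 1))
  p0 <- p$cn_probs
  odds <- p0 / (1 - p0) * c(2, 1, 1, 1, 1)
  expected <- (odds / (1 + odds)) / sum(odds / (1 + odds))
  frac_low <- mean(tr$cn[tr$status == "case"] == 1)
  expect_equal(frac_low, unname(expected["1"]), tolerance = 0.01)
  expect_error(sim_params(class_or = -1), "class_or")
})

test_that("probe behavior map drives true signals", {
  p <- sim_params(n_cases = 30, n_controls = 20, seed = 9)
  tr <- simulate_cohort(p)
  expect_equal(tr$signal_FCGR3B_2, tr$cn)
  expect_equal(tr$signal_FCGR3B_1, tr$wt)
  expect_true(all(tr$signal_FCGR3B_3 == 2))
})

test_that("noiseless MLPA render reproduces exact integer ratios", {
  p <- sim_params(n_cases = 60, n_controls = 40, mlpa_cv = 0, seed = 13)
  tr <- simulate_cohort(p)
  nr <- normalize_ratios(compute_ratios(render_mlpa(tr), mlpa_control_genes()))
  # WT-only probe: median individual has 1 countable copy, anchored to 2
  med_wt <- median(tr$wt)
  expect_equal(unname(nr$ratios[, "FCGR3B_1"]), 2 * tr$wt / med_wt,
               tolerance = 1e-12)
  expect_equal(unname(nr$ratios[, "FCGR3B_2"]), tr$cn, tolerance = 1e-12)
  expect_true(all(nr$ratios[, "FCGR3B_3"] == 2))
})

test_that("the no-CNV probe is flagged regardless of the cohort's truth", {
  p <- sim_params(n_cases = 120, n_controls = 80, seed = 25)
  pl <- suppressWarnings(mlpa_pipeline(render_mlpa(simulate_cohort(p)), seed = 2))
  expect_true(is_no_cnv(pl$models$FCGR3B_3))
  expect_false(is_no_cnv(pl$models$FCGR3B_2))
  expect_true(all(pl$calls$cn[pl$calls$probe_id == "FCGR3B_3"] == 2))
})

test_that("noiseless qPCR gives exact ddCt copy numbers and cycle shifts", {
  p <- sim_params(n_cases = 6, n_controls = 6, cn_probs = c("2" = 1),
                  ct_sd = 0, seed = 2)
  tr <- simulate_cohort(p)
  q <- qpcr_copy_number(render_qpcr(tr))
  expect_equal(q$cn_estimate, rep(2, 12), tolerance = 1e-12)

  p2 <- sim_params(n_cases = 4, n_controls = 4,
                   cn_probs = c("2" = 0.5, "4" = 0.5), ct_sd = 0, seed = 6)
  tr2 <- simulate_cohort(p2)
  ct2 <- render_qpcr(tr2)
  mean_ct <- tapply(ct2$ct[ct2$assay == "target"],
                    ct2$sample_id[ct2$assay == "target"], mean)
  mean_ct <- mean_ct[tr2$sample_id]
  # four copies amplify one full cycle earlier than two copies
  expect_equal(as.numeric(mean_ct[tr2$cn == 2] - mean_ct[tr2$cn == 4][1]),
               rep(1, sum(tr2$cn == 2)), tolerance = 1e-12)
  q2 <- qpcr_copy_number(ct2)
  r <- q2$cn_estimate[match(tr2$sample_id, q2$sample_id)]
  expect_equal(unname(r[tr2$cn == 4] / r[tr2$cn == 2][1]),
               rep(2, sum(tr2$cn == 4)), tolerance = 1e-12)
})

test_that("qPCR at realistic noise correlates strongly with true CN", {
  p <- sim_params(n_cases = 12, n_controls = 12,
                  cn_probs = c("1" = 0.3, "2" = 0.4, "3" = 0.3),
                  ct_sd = 0.15, seed = 31)
  tr <- simulate_cohort(p)
  q <- qpcr_copy_number(render_qpcr(tr))
  cp <- correlate_platforms(q$cn_estimate,
                            tr$cn[match(q$sample_id, tr$sample_id)])
  expect_gte(cp$r, 0.9)
  expect_equal(cp$n, 24L)
})

test_that("truth metrics tabulate accuracy, recall and MT-frequency error", {
  p <- sim_params(n_cases = 60, n_controls = 40,
                  cn_probs = c("1" = 0.1, "2" = 0.9), seed = 55)
  tr <- simulate_cohort(p)
  perfect <- data.frame(sample_id = tr$sample_id, cn = tr$cn,
                        wt = tr$wt, mt = tr$mt)
  m <- truth_metrics(tr, perfect)
  expect_equal(m$accuracy, 1)
  expect_equal(m$mt_freq_error, 0)

  all2 <- data.frame(sample_id = tr$sample_id, cn = 2L)
  m2 <- truth_metrics(tr, all2)
  expect_equal(m2$accuracy, mean(tr$cn == 2))
  expect_equal(unname(m2$recall["1"]), 0)
  expect_error(truth_metrics(tr, data.frame(sample_id = "nope", cn = 2)),
               "not present")
})

test_that("a simulated low-CN effect of OR 2 is recovered by the pipeline", {
  set.seed(61)
  seeds <- sample.int(2^31 - 2, 200)
  ors <- vapply(seeds, function(s) {
    tr <- simulate_cohort(sim_params(class_or = c(2, 1, 1, 1, 1), seed = s))
    tab <- rbind(case = c(sum(tr$cn[tr$status == "case"] == 1),
                          sum(tr$cn[tr$status == "case"] > 1)),
                 control = c(sum(tr$cn[tr$status == "control"] == 1),
                             sum(tr$cn[tr$status == "control"] > 1)))
    odds_ratio(tab)$or
  }, numeric(1))
  expect_gte(median(ors), 1.6)
  expect_lte(median(ors), 2.5)
})
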