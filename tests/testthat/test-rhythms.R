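test_that("the g-test flags a pure cosine and ignores scale and offset", {
  t <- seq(0, 44, by = 4)
  x <- cos(2 * pi * t / 24)
  res <- gtest_periodicity(x, t)
  expect_lt(res$p_value, 1e-3)
  expect_equal(res$k, 2) # second Fourier frequency of a 48 h span is 24 h
  noisy <- x + rnorm(length(t), 0, 0.1)
  expect_equal(gtest_periodicity(3 + 10 * noisy, t)$p_value,
               gtest_periodicity(noisy, t)$p_value, tolerance = 1e-9)

  const <- gtest_periodicity(rep(2, 12), t)
  expect_equal(const$p_value, 1)
  expect_true(const$degenerate)

  expect_error(gtest_periodicity(x[1:6], t[1:6]), "at least 8")
  expect_error(gtest_periodicity(x, c(t[-12], 100)), "evenly spaced")
})

test_that("dual-condition selection is strict on both cutoffs", {
  expect_true(select_circadian(0.2, 0.25))
  expect_false(select_circadian(0.2, 0.5))
  expect_false(select_circadian(0.3, 0.1)) # boundary is excluded
  expect_equal(select_circadian(c(0.1, 0.4), c(0.1, 0.1)), c(TRUE, FALSE))
})

test_that("under the null the dual selection passes at about cutoff squared", {
  sim <- simulate_timeseries(n_features = 4000, fraction_rhythmic = 0,
                             noise_sd = 1, seed = 12)
  calls <- detect_rhythms(sim$expr, sim$samples, cutoff = 0.3)
  expect_gt(mean(calls$is_circadian), 0.075)
  expect_lt(mean(calls$is_circadian), 0.105)
})

test_that("permutation FDR is seeded, near 1 on noise and floored by signal", {
  null_sim <- simulate_timeseries(n_features = 300, fraction_rhythmic = 0,
                                  noise_sd = 1, seed = 13)
  f1 <- permutation_fdr(null_sim$expr, null_sim$samples, n_perm = 50,
                        seed = 5)
  f2 <- permutation_fdr(null_sim$expr, null_sim$samples, n_perm = 50,
                        seed = 5)
  expect_equal(f1, f2) # determinism under a fixed seed
  expect_gt(f1$fdr, 0.5) # pure noise: estimated FDR near its cap of 1

  strong <- simulate_timeseries(n_features = 300, fraction_rhythmic = 1,
                                amplitude = 10, noise_sd = 1, seed = 14)
  fs <- permutation_fdr(strong$expr, strong$samples, n_perm = 50, seed = 5)
  expect_equal(fs$n_observed, 300)
  # the estimate drops to its permutation floor (~ cutoff^2), far below null
  expect_lt(fs$fdr, 0.2)
  expect_lt(fs$fdr, f1$fdr / 3)

  # a degenerate matrix passes nothing: FDR 1 with a warning
  flat <- null_sim
  flat$expr[, -1] <- 1
  expect_warning(f0 <- permutation_fdr(flat$expr, flat$samples, n_perm = 10,
                                       seed = 1), "no feature")
  expect_equal(f0$fdr, 1)
})

test_that("cosinor fitting recovers a noiseless rhythm exactly", {
  t <- seq(0, 44, by = 4)
  fit <- fit_cosine(t, 3 + 2 * cos(2 * pi * (t - 7) / 24))
  expect_equal(fit$period, 24)
  expect_equal(fit$acrophase, 7, tolerance = 1e-6)
  expect_equal(fit$amplitude, 2, tolerance = 1e-6)
  expect_equal(fit$mesor, 3, tolerance = 1e-6)
  expect_lt(fit$p_value, 0.01)

  flat <- fit_cosine(t, rep(5, length(t)) + 1e-9 * seq_along(t))
  expect_lt(flat$amplitude, 1e-6)

  expect_error(fit_cosine(1:3, 1:3), "at least 4")
  expect_error(fit_cosine(1:5, c(1, 2, NA, 4, 5)), "finite")
})

test_that("cosinor p-values on flat series are only mildly anti-conservative", {
  # the F-test is evaluated at the best period of the 20-28 h grid, so the
  # null retention rate sits below the nominal 95% (selection effect)
  retained <- withr::with_seed(202, {
    mean(vapply(seq_len(400), function(i) {
      t <- seq(0, 24, by = 6)
      fit_cosine(t, 5 + rnorm(length(t), 0, 0.01))$p_value > 0.05
    }, logical(1)))
  })
  expect_gte(retained, 0.8)
})

test_that("one-way ANOVA across timepoints is calibrated and powered", {
  p_null <- withr::with_seed(33, {
    vapply(seq_len(300), function(i) {
      anova_timepoints(rnorm(15), rep(c(0, 6, 12, 18, 24), each = 3))
    }, numeric(1))
  })
  expect_gt(stats::ks.test(p_null, "punif")$p.value, 0.01)

  y <- withr::with_seed(34, rnorm(15))
  y[1:3] <- y[1:3] + 5 # one timepoint group shifted by 5 sigma
  expect_lt(anova_timepoints(y, rep(c(0, 6, 12, 18, 24), each = 3)), 0.01)

  expect_error(anova_timepoints(rnorm(5), c(0, 6, 12, 18, 24)),
               "at least 2 replicates")
  expect_error(anova_timepoints(rep(1, 12), rep(c(0, 6), each = 6)),
               "variance")
})

test_that("the metabolite circadian call needs both tests below alpha", {
  expect_true(classify_circadian_metabolite(0.01, 0.03))
  expect_false(classify_circadian_metabolite(0.01, 0.2))
  expect_false(classify_circadian_metabolite(0.05, 0.01)) # strict boundary
  expect_equal(classify_circadian_metabolite(c(0.04, 0.06), c(0.04, 0.04)),
               c(TRUE, FALSE))
})

test_that("total-intensity scaling normalises rows and is idempotent", {
  m <- rbind(c(2, 3, 5), c(1, 1, 2))
  s <- scale_total_intensity(m)
  expect_equal(s[1, ], c(0.2, 0.3, 0.5))
  expect_equal(rowSums(s), c(1, 1))
  expect_equal(scale_total_intensity(s), s)
  expect_error(scale_total_intensity(rbind(c(1, 2), c(0, 0))), "positive")
  df <- as.data.frame(m)
  expect_s3_class(scale_total_intensity(df), "data.frame")
})

test_that("the differential filter applies abundance then fold-change rules", {
  expect_equal(filter_differential(c(0.5, 0.5), c(0.4, 0.3)), "excluded")
  expect_equal(filter_differential(40, 5), "significant") # |log2 8| = 3
  expect_equal(filter_differential(6, 2), "not_significant") # |log2 3| < 2
  # zero control mean: pseudocount policy
  expect_equal(filter_differential(10, 0), "significant")
  expect_equal(filter_differential(10, 0, use_pseudocount = FALSE),
               "significant")
  expect_error(filter_differential(c(1, -2), 3), "nonnegative")
})
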