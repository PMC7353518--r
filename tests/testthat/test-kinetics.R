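test_that("zero-order fit is exact on noiseless lines", {
  f <- fit_zero_order(noiseless_df(4.17, 0.013, c(0, 30, 60, 90)))
  expect_equal(f$k, 0.013, tolerance = 1e-12)
  expect_equal(f$intercept, 4.17, tolerance = 1e-12)
  expect_equal(f$r2, 1)

  f2 <- fit_zero_order(data.frame(time_days = c(0, 10, 20),
                                  intensity_mean = c(4, 4.5, 5)))
  expect_equal(f2$k, 0.05, tolerance = 1e-12)
  expect_equal(f2$intercept, 4, tolerance = 1e-12)
})

test_that("zero-order OLS equals the brute-force grid-search oracle", {
  t <- c(0, 14, 28, 42, 56)
  y <- c(4.21, 4.48, 4.90, 5.12, 5.55)
  f <- fit_zero_order(data.frame(time_days = t, intensity_mean = y))
  oracle <- grid_ols(t, y)
  expect_equal(f$k, oracle$slope, tolerance = 1e-4)
  expect_equal(f$intercept, oracle$intercept, tolerance = 1e-4)
})

test_that("slope is invariant to intensity offsets and time shifts", {
  t <- c(0, 10, 25, 40, 60)
  y <- c(4.1, 4.4, 4.8, 5.3, 5.6)
  base <- fit_zero_order(data.frame(time_days = t, intensity_mean = y))
  shifted_y <- fit_zero_order(data.frame(time_days = t, intensity_mean = y + 0.7))
  expect_equal(shifted_y$k, base$k)
  expect_equal(shifted_y$intercept, base$intercept + 0.7)
  shifted_t <- fit_zero_order(data.frame(time_days = t + 30, intensity_mean = y))
  expect_equal(shifted_t$k, base$k)
})

test_that("estimator is unbiased across simulated panel studies", {
  # continuous (unrounded) mechanism: rounding to the 7-point grid adds a
  # known oscillatory quantization bias that is not an estimator property.
  # The design keeps the trajectory > 3 SD below the scale ceiling, as a
  # real study would, so clamping cannot bias the panel means.
  true_k <- 0.03
  p <- kinetic_params(I0 = 4.3, Ea = 0, kref = true_k, sigma_panel = 0.3)
  k_hat <- vapply(seq_len(1000), function(i) {
    d <- sampling_design(temperatures_C = 20, times_days = seq(0, 50, by = 10),
                         n_panelists = 1, seed = i)
    fit_zero_order(simulate_sensory_trajectory(p, d, 20, round_scores = FALSE))$k
  }, 0)
  mc_se <- sd(k_hat) / sqrt(length(k_hat))
  expect_lt(abs(mean(k_hat) - true_k), 3 * mc_se)
})

test_that("slope standard error shrinks as 1/sqrt(n) under replication", {
  p <- kinetic_params(I0 = 4.3, Ea = 0, kref = 0.05, sigma_panel = 0.3)
  times4 <- rep(c(0, 15, 30, 45), each = 4)
  times16 <- rep(c(0, 15, 30, 45), each = 16)
  ratio <- vapply(seq_len(200), function(i) {
    d4 <- sampling_design(temperatures_C = 20, times_days = times4,
                          n_panelists = 1, seed = i)
    d16 <- sampling_design(temperatures_C = 20, times_days = times16,
                           n_panelists = 1, seed = i + 5000)
    f4 <- fit_zero_order(simulate_sensory_trajectory(p, d4, 20, round_scores = FALSE))
    f16 <- fit_zero_order(simulate_sensory_trajectory(p, d16, 20, round_scores = FALSE))
    f4$se_k / f16$se_k
  }, 0)
  # quadrupling replication should halve se_k
  expect_equal(mean(ratio), 2, tolerance = 0.1)
})

test_that("censored observations are excluded by default", {
  df <- noiseless_df(4, 0.1, seq(0, 50, by = 10))
  df$censored <- df$time_days > 30
  df$intensity_mean[df$censored] <- 7  # pinned at the scale ceiling
  f <- fit_zero_order(df)
  expect_equal(f$k, 0.1, tolerance = 1e-12)
  expect_equal(f$n_censored_excluded, 2L)
  f_all <- fit_zero_order(df, exclude_censored = FALSE)
  expect_lt(f_all$k, 0.1)  # ceiling flattens the apparent rate
})

test_that("degenerate designs error and constant response warns", {
  expect_error(fit_zero_order(data.frame(time_days = c(5, 5),
                                         intensity_mean = c(4, 5))),
               "degenerate")
  expect_warning(f <- fit_zero_order(data.frame(time_days = c(0, 10, 20),
                                                intensity_mean = c(4, 4, 4))),
                 "identical")
  expect_equal(f$k, 0)
  expect_equal(f$r2, 0)
})

test_that("kinetics table fits every batch-temperature cell", {
  p1 <- kinetic_params(I0 = 4.2, Ea = 5e4, kref = 0.05, sigma_panel = 0,
                       batch_label = "low", oil_pv = 5)
  p2 <- kinetic_params(I0 = 4.2, Ea = 6e4, kref = 0.15, sigma_panel = 0,
                       batch_label = "high", oil_pv = 25)
  df <- trajectories_to_df(simulate_study(list(p1, p2),
                                          sampling_design(seed = 1),
                                          round_scores = FALSE))
  tab <- fit_kinetics_table(df)
  expect_equal(nrow(tab), 6L)
  expect_setequal(tab$batch_label, c("low", "high"))
  k_low_40 <- tab$k[tab$batch_label == "low" & tab$temperature_C == 40]
  expect_equal(k_low_40, 0.05, tolerance = 1e-10)
})

test_that("inverse-SEM weighting is available and agrees on homoskedastic data", {
  p <- kinetic_params(I0 = 4.3, Ea = 0, kref = 0.05, sigma_panel = 0.4)
  d <- sampling_design(temperatures_C = 20, times_days = seq(0, 60, by = 10),
                       n_panelists = 30, seed = 2)
  tr <- simulate_sensory_trajectory(p, d, 20, round_scores = FALSE)
  f_u <- fit_zero_order(tr)
  f_w <- fit_zero_order(tr, weights = "inv_sem2")
  expect_equal(f_w$k, f_u$k, tolerance = 0.15)
})
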