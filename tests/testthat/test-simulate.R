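test_that("noiseless simulated means lie exactly on the zero-order line", {
  # Ea = 0 makes the rate 0.05/day at every temperature
  p <- kinetic_params(I0 = 4, Ea = 0, kref = 0.05, sigma_panel = 0)
  d <- sampling_design(times_days = c(0, 10, 20), n_panelists = 5, seed = 1)
  tr <- simulate_sensory_trajectory(p, d, 40, round_scores = FALSE)
  expect_equal(tr$observations$intensity_mean, c(4, 4.5, 5))
  expect_equal(tr$observations$intensity_sd, c(0, 0, 0))

  # general Arrhenius-distributed rate: simulated means follow I0 + k(T) t
  p2 <- kinetic_params(I0 = 4.33, Ea = 50820, kref = 0.040, sigma_panel = 0)
  tr2 <- simulate_sensory_trajectory(p2, sampling_design(seed = 1), 20,
                                     round_scores = FALSE)
  k20 <- 0.040 * exp(-(50820 / 8.314) * (1 / 293.15 - 1 / 313.15))
  expect_equal(tr2$observations$intensity_mean,
               4.33 + k20 * tr2$observations$time_days)
  # the reparametrized law itself: a rate of 0.040/day at 40 C with
  # Ea ~ 51 kJ/mol slows to about a quarter of that at 20 C
  expect_equal(true_rate(p2, 20), k20)
  expect_equal(true_rate(p2, 40), 0.040)
})

test_that("panel noise SD is reproduced at large panel size", {
  p <- kinetic_params(I0 = 4, Ea = 0, kref = 0.01, sigma_panel = 0.5)
  d <- sampling_design(times_days = c(0, 1), n_panelists = 10000, seed = 7)
  tr <- simulate_sensory_trajectory(p, d, 20, round_scores = FALSE)
  expect_true(all(abs(tr$observations$intensity_sd - 0.5) / 0.5 < 0.02))
})

test_that("scores respect scale bounds and censoring is monotone in time", {
  p <- kinetic_params(I0 = 4.5, Ea = 40000, kref = 0.5, sigma_panel = 1.2)
  d <- sampling_design(times_days = seq(0, 40, by = 4), n_panelists = 20, seed = 11)
  for (tc in c(20, 40, 60)) {
    tr <- simulate_sensory_trajectory(p, d, tc)
    obs <- tr$observations
    expect_true(all(obs$intensity_mean >= 1 & obs$intensity_mean <= 7))
    # once the noiseless mean crosses the ceiling it stays there (k > 0)
    expect_true(all(diff(as.integer(obs$censored)) >= 0))
  }
})

test_that("simulation is seed-deterministic and order-independent", {
  p <- kinetic_params(I0 = 4.2, Ea = 50000, kref = 0.05, sigma_panel = 0.8,
                      batch_label = "low", oil_pv = 5)
  d1 <- sampling_design(seed = 99)
  d2 <- sampling_design(seed = 99)
  t1 <- simulate_sensory_trajectory(p, d1, 40)
  t2 <- simulate_sensory_trajectory(p, d2, 40)
  expect_identical(t1, t2)

  d3 <- sampling_design(seed = 100)
  t3 <- simulate_sensory_trajectory(p, d3, 40)
  expect_false(identical(t1$observations$intensity_mean,
                         t3$observations$intensity_mean))

  # each (batch, temperature) has its own stream: simulating the whole
  # study or just one trajectory gives the same draws
  study <- simulate_study(list(p), d1)
  at40 <- Filter(function(x) x$temperature_C == 40, study)[[1]]
  expect_identical(at40, t1)
})

test_that("simulator rejects unknown temperatures and bad parameters", {
  p <- kinetic_params(I0 = 4, Ea = 5e4, kref = 0.05)
  d <- sampling_design(temperatures_C = c(20, 40), times_days = c(0, 10), seed = 1)
  expect_error(simulate_sensory_trajectory(p, d, 60), "not part of the design")
  expect_error(kinetic_params(I0 = 4, Ea = 5e4, kref = -1), "kref")
  expect_error(kinetic_params(I0 = 8, Ea = 5e4, kref = 0.1), "I0")
  expect_error(kinetic_params(I0 = 4, Ea = 5e4, kref = 0.1, sigma_panel = -0.1),
               "sigma_panel")
  expect_error(sampling_design(times_days = c(5, 5), seed = 1), "distinct")
  expect_error(sampling_design(times_days = c(-1, 5), seed = 1), "non-negative")
})

test_that("standard-curve simulator is exact at zero noise and consistent with its fit", {
  pts <- simulate_standard_curve(0.05, 0.01, c(0, 2, 4, 6, 8, 10), noise_sd = 0)
  expect_equal(pts$absorbance, 0.01 + 0.05 * pts$iron_micrograms)
  expect_equal(pts$absorbance[pts$iron_micrograms == 10], 0.51)
  cv <- fit_standard_curve(pts)
  expect_equal(cv$slope_m, 0.05, tolerance = 1e-12)
  expect_equal(cv$intercept_Ic, 0.01, tolerance = 1e-12)

  # round trip at 50 points: residual SD within 20% of the injected noise
  pts50 <- simulate_standard_curve(0.05, 0.01, seq(0, 49), noise_sd = 0.005,
                                   seed = 123)
  cv50 <- fit_standard_curve(pts50)
  resid_sd <- sd(pts50$absorbance -
                   (cv50$intercept_Ic + cv50$slope_m * pts50$iron_micrograms))
  expect_lt(abs(resid_sd - 0.005) / 0.005, 0.20)

  expect_error(simulate_standard_curve(0.05, 0.01, c(0, 10), noise_sd = -1),
               "noise_sd")
  expect_error(simulate_standard_curve(-0.05, 0.01, c(0, 10)), "slope_m")
})

test_that("tidy flattening and CSV round trip preserve the trajectory schema", {
  p <- kinetic_params(I0 = 4.2, Ea = 5e4, kref = 0.05, sigma_panel = 0.5,
                      batch_label = "low", oil_pv = 5.06)
  study <- simulate_study(list(p), sampling_design(seed = 5))
  df <- trajectories_to_df(study)
  expect_named(df, c("batch_label", "oil_pv", "temperature_C", "time_days",
                     "intensity_mean", "intensity_sd", "n", "censored"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectories_csv(study, path)
  back <- read_trajectories_csv(path)
  expect_equal(back$intensity_mean, df$intensity_mean)
  expect_identical(back$censored, df$censored)
})
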