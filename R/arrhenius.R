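#' Reparametrized Arrhenius fit from per-temperature rate constants
#'
#' Two-step pathway: given the zero-order rate constants estimated at each
#' storage temperature, fits `ln k = ln kref - (Ea/R) * (1/T - 1/Tref)` by
#' least squares with T in kelvin. Anchoring the model at a reference
#' temperature in the middle of the experimental range decorrelates the
#' slope and intercept and stabilizes the estimate of the activation
#' energy. The frequency factor is recovered as
#' `k0 = exp(ln kref + Ea / (R * Tref))`.
#'
#' @param rates data frame with columns `temperature_C` and `k`, or a
#'   numeric vector of temperatures (degree C) when `k` is supplied.
#' @param k optional rate-constant vector matching `rates`.
#' @param Tref_C reference temperature, degree C (default 40).
#' @param gas_constant gas constant, J/(mol K); default 8.314, settable to
#'   8.31 (changes Ea by under 0.05%).
#' @return an object of class `arrhenius_fit`: `Ea` and `se_Ea` (kJ/mol),
#'   `kref` (rate at `Tref_C`, intensity/day), `Tref_C`, `Tref_K`, `k0`
#'   (intensity/day), `r2` and `p_slope` from the ln-scale regression
#'   (two-sided t-test, n - 2 df), `n_temperatures`, `gas_constant_used`.
#' @export
fit_arrhenius_from_rates <- function(rates, k = NULL, Tref_C = 40,
                                     gas_constant = .GAS_CONSTANT_DEFAULT) {
  if (is.data.frame(rates)) {
    temperature_C <- rates$temperature_C
    k <- rates$k
  } else {
    temperature_C <- rates
  }
  stopifnot(length(temperature_C) == length(k))
  if (any(k <= 0)) stop("all rate constants must be positive", call. = FALSE)
  if (length(unique(temperature_C)) < 2L) {
    stop("degenerate design: need at least 2 distinct temperatures", call. = FALSE)
  }

  T_K <- celsius_to_kelvin(temperature_C)
  Tref_K <- celsius_to_kelvin(Tref_C)
  x <- 1 / T_K - 1 / Tref_K
  fit <- stats::lm(log(k) ~ x)
  cf <- summary(fit)$coefficients

  Ea_J <- -unname(cf["x", "Estimate"]) * gas_constant
  se_Ea_J <- unname(cf["x", "Std. Error"]) * gas_constant
  kref <- exp(unname(cf["(Intercept)", "Estimate"]))
  n <- length(k)
  r2 <- summary(fit)$r.squared
  # flat-rate limit: identical ks give slope 0 and an undefined r2
  if (length(unique(k)) == 1L) r2 <- 0
  p_slope <- if (n > 2L) unname(cf["x", "Pr(>|t|)"]) else NA_real_

  new_arrhenius_fit(Ea_J, se_Ea_J, kref, Tref_C, Tref_K, r2, p_slope,
                    n, gas_constant)
}

new_arrhenius_fit <- function(Ea_J, se_Ea_J, kref, Tref_C, Tref_K, r2,
                              p_slope, n_temperatures, gas_constant) {
  k0 <- exp(log(kref) + Ea_J / (gas_constant * Tref_K))
  structure(
    list(Ea = Ea_J / 1000, se_Ea = se_Ea_J / 1000, Ea_J = Ea_J,
         kref = kref, Tref_C = Tref_C, Tref_K = Tref_K, k0 = k0,
         r2 = r2, p_slope = p_slope, n_temperatures = n_temperatures,
         gas_constant_used = gas_constant),
    class = "arrhenius_fit"
  )
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf(
    "<arrhenius_fit> Ea = %.2f +/- %.2f kJ/mol, kref(%g C) = %.4g /day, k0 = %.3g /day\n",
    x$Ea, x$se_Ea, x$Tref_C, x$kref, x$k0))
  cat(sprintf("  ln-scale r2 = %.3f, p = %s, n = %d temperatures, R = %g J/(mol K)\n",
              x$r2, format(x$p_slope, digits = 3), x$n_temperatures,
              x$gas_constant_used))
  invisible(x)
}

#' One-step pooled Arrhenius fit from raw trajectories
#'
#' Nonlinear least squares of all observations jointly over temperatures:
#' `I(t, T) = I0 + kref * exp(-(Ea/R) * (1/T - 1/Tref)) * t`,
#' sharing a single initial intensity `I0` across temperatures. Initialized
#' from the two-step result ([fit_zero_order()] per temperature followed by
#' [fit_arrhenius_from_rates()]). Compared with the two-step pathway this
#' uses every data point at once instead of compressing each temperature
#' into one rate constant first.
#'
#' @param trajectories list of `sensory_trajectory` objects (at least two
#'   distinct temperatures, each with at least two time points), or a tidy
#'   trajectory data frame.
#' @param Tref_C,gas_constant as in [fit_arrhenius_from_rates()].
#' @param exclude_censored drop censored observations (default TRUE).
#' @return list with elements `fit` (an `arrhenius_fit`; its `r2` is the
#'   squared correlation of observed and fitted intensities and `p_slope`
#'   the Wald test on Ea) and `I0` (shared initial-intensity estimate).
#'   Non-convergence raises an error of class `shelfkin_nonconvergence`
#'   whose `fallback` field carries the two-step fit.
#' @export
fit_arrhenius_one_step <- function(trajectories, Tref_C = 40,
                                   gas_constant = .GAS_CONSTANT_DEFAULT,
                                   exclude_censored = TRUE) {
  df <- if (is.data.frame(trajectories)) trajectories else trajectories_to_df(trajectories)
  if (exclude_censored && "censored" %in% names(df)) {
    df <- df[!df$censored, , drop = FALSE]
  }
  temps <- unique(df$temperature_C)
  if (length(temps) < 2L) {
    stop("degenerate design: need at least 2 distinct temperatures", call. = FALSE)
  }

  # two-step initialization
  per_temp <- lapply(temps, function(tc) {
    fit_zero_order(df[df$temperature_C == tc, , drop = FALSE],
                   exclude_censored = FALSE)
  })
  two_step <- fit_arrhenius_from_rates(
    data.frame(temperature_C = temps, k = vapply(per_temp, `[[`, 0, "k")),
    Tref_C = Tref_C, gas_constant = gas_constant
  )
  I0_init <- mean(vapply(per_temp, `[[`, 0, "intercept"))

  Tref_K <- celsius_to_kelvin(Tref_C)
  dat <- data.frame(y = df$intensity_mean, t = df$time_days,
                    invT = 1 / celsius_to_kelvin(df$temperature_C))
  R <- gas_constant

  nls_fit <- tryCatch(
    stats::nls(
      y ~ I0 + kref * exp(-(Ea / R) * (invT - 1 / Tref_K)) * t,
      data = dat,
      start = list(I0 = I0_init, kref = two_step$kref, Ea = two_step$Ea_J),
      control = stats::nls.control(maxiter = 200, warnOnly = FALSE),
      algorithm = "port",
      lower = c(I0 = -Inf, kref = 1e-12, Ea = -Inf)
    ),
    error = function(e) e
  )
  if (inherits(nls_fit, "error")) {
    cond <- structure(
      class = c("shelfkin_nonconvergence", "error", "condition"),
      list(message = paste0("one-step Arrhenius regression did not converge: ",
                            conditionMessage(nls_fit)),
           call = sys.call(-1), fallback = two_step)
    )
    stop(cond)
  }

  est <- stats::coef(nls_fit)
  se <- sqrt(diag(stats::vcov(nls_fit)))
  fitted_y <- stats::fitted(nls_fit)
  r2 <- stats::cor(dat$y, fitted_y)^2
  z <- est["Ea"] / se["Ea"]
  dfree <- nrow(dat) - 3L
  p_Ea <- if (dfree > 0) 2 * stats::pt(-abs(z), df = dfree) else NA_real_

  fit <- new_arrhenius_fit(unname(est["Ea"]), unname(se["Ea"]),
                           unname(est["kref"]), Tref_C, Tref_K,
                           r2, unname(p_Ea), length(temps), gas_constant)
  list(fit = fit, I0 = unname(est["I0"]))
}

#' Predict the rate constant at a storage temperature
#'
#' Evaluates the fitted reparametrized Arrhenius law
#' `k(T) = kref * exp(-(Ea/R) * (1/T - 1/Tref))`.
#'
#' @param fit an `arrhenius_fit`.
#' @param temperature_C storage temperature(s), degree C.
#' @return predicted rate constant(s), intensity/day.
#' @export
predict_rate <- function(fit, temperature_C) {
  stopifnot(inherits(fit, "arrhenius_fit"))
  T_K <- celsius_to_kelvin(temperature_C)
  fit$kref * exp(-(fit$Ea_J / fit$gas_constant_used) * (1 / T_K - 1 / fit$Tref_K))
}

#' Arrhenius fits for every batch in a rate-constant table
#'
#' @param rate_table data frame as produced by [fit_kinetics_table()]
#'   (columns `batch_label`, `oil_pv`, `temperature_C`, `k`).
#' @param Tref_C,gas_constant as in [fit_arrhenius_from_rates()].
#' @return data frame, one row per batch: `batch_label`, `oil_pv`, `k0`,
#'   `Ea_kJ_mol`, `se_Ea_kJ_mol`, `kref`, `Tref_C`, `r2`, `p_slope`.
#' @export
fit_arrhenius_table <- function(rate_table, Tref_C = 40,
                                gas_constant = .GAS_CONSTANT_DEFAULT) {
  batches <- unique(rate_table$batch_label)
  rows <- lapply(batches, function(b) {
    sub <- rate_table[rate_table$batch_label == b, , drop = FALSE]
    f <- fit_arrhenius_from_rates(sub, Tref_C = Tref_C, gas_constant = gas_constant)
    data.frame(batch_label = b,
               oil_pv = if ("oil_pv" %in% names(sub)) sub$oil_pv[1L] else NA_real_,
               k0 = f$k0, Ea_kJ_mol = f$Ea, se_Ea_kJ_mol = f$se_Ea,
               kref = f$kref, Tref_C = f$Tref_C, r2 = f$r2, p_slope = f$p_slope)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
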