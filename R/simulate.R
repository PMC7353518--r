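#' Ground-truth kinetic parameters for the sensory simulator
#'
#' Bundles the true zero-order/Arrhenius parameters used to generate a
#' simulated accelerated shelf-life study. The rate at any storage
#' temperature follows the reparametrized Arrhenius law
#' `k(T) = kref * exp(-(Ea/R) * (1/T - 1/Tref))`.
#'
#' @param I0 initial rancid-odor intensity on the sensory scale (the fresh
#'   control anchors at 4 on the 7-point scale).
#' @param Ea activation energy, J/mol.
#' @param kref rate constant at the reference temperature, intensity/day.
#' @param Tref_C reference temperature, degree C (default 40, the middle of
#'   the usual 20/40/60 storage design).
#' @param sigma_panel additive panel noise SD, intensity units. The default
#'   1.0 matches the between-panelist spread typically reported for a
#'   30-member quantitative descriptive panel scoring fresh crackers.
#' @param scale_min,scale_max sensory scale bounds (default 1 and 7).
#' @param batch_label,oil_pv optional batch identity carried into simulated
#'   trajectories; `oil_pv` is the peroxide value of the ingredient oil,
#'   mEq O2/kg oil.
#' @param gas_constant gas constant, J/(mol K).
#' @return an object of class `kinetic_params`.
#' @export
kinetic_params <- function(I0 = 4.33, Ea, kref, Tref_C = 40,
                           sigma_panel = 1.0, scale_min = 1, scale_max = 7,
                           batch_label = "batch", oil_pv = NA_real_,
                           gas_constant = .GAS_CONSTANT_DEFAULT) {
  stopifnot(is.numeric(Ea), length(Ea) == 1L, is.finite(Ea))
  if (kref <= 0) stop("kref must be positive", call. = FALSE)
  if (sigma_panel < 0) stop("sigma_panel must be non-negative", call. = FALSE)
  if (scale_min >= scale_max) stop("scale_min must be below scale_max", call. = FALSE)
  if (I0 <= scale_min || I0 >= scale_max) {
    stop("I0 must lie strictly inside [scale_min, scale_max]", call. = FALSE)
  }
  Tref_K <- celsius_to_kelvin(Tref_C)
  structure(
    list(I0 = I0, Ea = Ea, kref = kref, Tref_C = Tref_C, Tref_K = Tref_K,
         sigma_panel = sigma_panel, scale_min = scale_min, scale_max = scale_max,
         batch_label = batch_label, oil_pv = oil_pv, gas_constant = gas_constant),
    class = "kinetic_params"
  )
}

#' True rate constant at a storage temperature
#'
#' Evaluates the ground-truth Arrhenius law of a [kinetic_params] object.
#'
#' @param params a [kinetic_params] object.
#' @param temperature_C storage temperature, degree C.
#' @return rate constant, intensity/day.
#' @export
true_rate <- function(params, temperature_C) {
  stopifnot(inherits(params, "kinetic_params"))
  T_K <- celsius_to_kelvin(temperature_C)
  params$kref *
    exp(-(params$Ea / params$gas_constant) * (1 / T_K - 1 / params$Tref_K))
}

#' Sampling design of an accelerated shelf-life study
#'
#' @param temperatures_C storage temperatures, degree C (default 20/40/60,
#'   the market temperature plus two abuse temperatures).
#' @param times_days sampling times in days: either one numeric vector used
#'   at every temperature, or a list with one vector per temperature. Each
#'   schedule needs at least two distinct non-negative times. The defaults
#'   are denser early at the abuse temperatures, where rancid odor can hit
#'   the scale ceiling within days for heavily oxidized oil.
#' @param n_panelists panel size per tasting session (default 30).
#' @param seed integer RNG seed for the whole study.
#' @return an object of class `sampling_design`.
#' @export
sampling_design <- function(temperatures_C = c(20, 40, 60),
                            times_days = list(
                              `20` = c(0, 15, 30, 60, 90, 120, 150, 180),
                              `40` = c(0, 2, 5, 10, 15, 20, 30, 45, 60),
                              `60` = c(0, 1, 2, 3, 5, 7, 10, 14, 18)
                            ),
                            n_panelists = 30, seed = 1L) {
  if (!is.list(times_days)) {
    times_days <- stats::setNames(
      rep(list(as.numeric(times_days)), length(temperatures_C)),
      as.character(temperatures_C)
    )
  }
  if (is.null(names(times_days))) names(times_days) <- as.character(temperatures_C)
  for (tc in temperatures_C) {
    tt <- times_days[[as.character(tc)]]
    if (is.null(tt)) stop("no sampling times for temperature ", tc, " C", call. = FALSE)
    if (any(tt < 0)) stop("sampling times must be non-negative", call. = FALSE)
    if (length(unique(tt)) < 2L) {
      stop("need at least 2 distinct sampling times per temperature", call. = FALSE)
    }
  }
  if (n_panelists < 1L) stop("n_panelists must be at least 1", call. = FALSE)
  structure(
    list(temperatures_C = temperatures_C,
         times_days = lapply(times_days, function(x) sort(as.numeric(x))),
         n_panelists = as.integer(n_panelists), seed = as.integer(seed)),
    class = "sampling_design"
  )
}

#' Simulate one sensory trajectory at one storage temperature
#'
#' Generates panel data following the zero-order model
#' `I(t) = I0 + k(T) * t` with `k(T)` from the Arrhenius law in `params`.
#' Each panelist's score is the noiseless intensity plus Normal panel noise,
#' optionally rounded to the nearest scale integer, then clamped to the
#' scale bounds. An observation is flagged censored once the noiseless mean
#' exceeds the scale maximum; censored points are excluded from kinetic
#' fits by default because the bounded scale no longer tracks the reaction.
#'
#' @param params a [kinetic_params] object (ground truth).
#' @param design a [sampling_design] object; `temperature_C` must be one of
#'   its temperatures.
#' @param temperature_C storage temperature, degree C.
#' @param round_scores round each panelist score to the nearest integer on
#'   the scale (the mechanics of a 7-point category scale). Set `FALSE` for
#'   estimator property checks on the continuous mechanism.
#' @return an object of class `sensory_trajectory`: batch label, oil PV,
#'   temperature, and an `observations` data frame with columns
#'   `time_days`, `intensity_mean`, `intensity_sd`, `n`, `censored`.
#' @export
simulate_sensory_trajectory <- function(params, design, temperature_C,
                                        round_scores = TRUE) {
  stopifnot(inherits(params, "kinetic_params"), inherits(design, "sampling_design"))
  if (!temperature_C %in% design$temperatures_C) {
    stop("temperature ", temperature_C, " C is not part of the design", call. = FALSE)
  }
  times <- design$times_days[[as.character(temperature_C)]]
  if (length(times) == 0L) stop("empty time list", call. = FALSE)

  k <- true_rate(params, temperature_C)
  traj_seed <- derive_seed(design$seed, params$batch_label, temperature_C)

  obs <- with_local_seed(traj_seed, {
    do.call(rbind, lapply(times, function(t) {
      noiseless <- params$I0 + k * t
      scores <- noiseless + stats::rnorm(design$n_panelists, 0, params$sigma_panel)
      if (round_scores) scores <- round(scores)
      scores <- pmin(pmax(scores, params$scale_min), params$scale_max)
      data.frame(
        time_days = t,
        intensity_mean = mean(scores),
        intensity_sd = if (design$n_panelists > 1L) stats::sd(scores) else NA_real_,
        n = design$n_panelists,
        censored = noiseless > params$scale_max
      )
    }))
  })

  structure(
    list(batch_label = params$batch_label, oil_pv = params$oil_pv,
         temperature_C = temperature_C, observations = obs),
    class = "sensory_trajectory"
  )
}

#' Simulate a full multi-batch, multi-temperature storage study
#'
#' @param batch_params list of [kinetic_params], one per oil batch (each
#'   carrying its `batch_label` and `oil_pv`).
#' @param design a [sampling_design].
#' @param round_scores see [simulate_sensory_trajectory()].
#' @return list of `sensory_trajectory` objects, one per
#'   (batch, temperature).
#' @export
simulate_study <- function(batch_params, design, round_scores = TRUE) {
  stopifnot(is.list(batch_params), length(batch_params) >= 1L)
  out <- list()
  for (p in batch_params) {
    for (tc in design$temperatures_C) {
      out[[length(out) + 1L]] <-
        simulate_sensory_trajectory(p, design, tc, round_scores = round_scores)
    }
  }
  out
}

#' Simulate a ferric-thiocyanate iron standard curve
#'
#' Absorbance at 510 nm is linear in the amount of iron:
#' `A = intercept_Ic + slope_m * micrograms Fe + Normal(0, noise_sd)`.
#'
#' @param slope_m absorbance per microgram iron (must be positive).
#' @param intercept_Ic blank absorbance.
#' @param iron_micrograms iron amounts, micrograms (non-negative).
#' @param noise_sd photometric noise SD, absorbance units.
#' @param seed integer RNG seed.
#' @return data frame with columns `iron_micrograms`, `absorbance`.
#' @export
simulate_standard_curve <- function(slope_m, intercept_Ic, iron_micrograms,
                                    noise_sd = 0, seed = 1L) {
  if (slope_m <= 0) stop("slope_m must be positive", call. = FALSE)
  if (any(iron_micrograms < 0)) stop("iron amounts must be non-negative", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  absorbance <- with_local_seed(seed, {
    intercept_Ic + slope_m * iron_micrograms +
      stats::rnorm(length(iron_micrograms), 0, noise_sd)
  })
  data.frame(iron_micrograms = iron_micrograms, absorbance = absorbance)
}

#' @export
print.sensory_trajectory <- function(x, ...) {
  cat(sprintf("<sensory_trajectory> batch %s (oil PV %s) at %g C, %d observations\n",
              x$batch_label, format(x$oil_pv), x$temperature_C, nrow(x$observations)))
  print(x$observations, row.names = FALSE)
  invisible(x)
}

#' Flatten sensory trajectories to the tidy CSV schema
#'
#' @param x a `sensory_trajectory` object.
#' @param row.names,optional,... passed through for S3 compatibility.
#' @return data frame with columns `batch_label`, `oil_pv`, `temperature_C`,
#'   `time_days`, `intensity_mean`, `intensity_sd`, `n`, `censored`.
#' @export
as.data.frame.sensory_trajectory <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  cbind(
    data.frame(batch_label = x$batch_label, oil_pv = x$oil_pv,
               temperature_C = x$temperature_C),
    x$observations
  )
}

#' Bind a list of trajectories into one tidy data frame
#'
#' @param trajectories list of `sensory_trajectory` objects.
#' @return tidy data frame in the trajectory CSV schema.
#' @export
trajectories_to_df <- function(trajectories) {
  if (inherits(trajectories, "sensory_trajectory")) trajectories <- list(trajectories)
  do.call(rbind, lapply(trajectories, as.data.frame))
}
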