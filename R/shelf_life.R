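#' Linear model of the oxidation rate on ingredient-oil peroxide value
#'
#' OLS of the zero-order rancid-odor rate constant (at one fixed storage
#' temperature, normally 20 degree C) on the peroxide value of the
#' ingredient oil: `k = slope * PV + intercept`. The validity range is set
#' to the span of the fitted PVs; predictions outside it warn.
#'
#' @param pairs data frame with columns `oil_pv` and `k`, or a numeric
#'   vector of oil PVs when `k` is supplied.
#' @param k optional rate-constant vector matching `pairs`.
#' @param temperature_C storage temperature at which the rates were
#'   measured (default 20). Recorded on the model; shelf-life predictions
#'   are only valid at this temperature.
#' @return an object of class `rate_pv_model`: `slope`
#'   ((intensity/day) per (mEq O2/kg oil)), `intercept` (intensity/day),
#'   `r2`, `p_slope`, `pv_valid_range`, `temperature_C`, `n`.
#' @export
fit_rate_vs_pv <- function(pairs, k = NULL, temperature_C = 20) {
  if (is.data.frame(pairs)) {
    oil_pv <- pairs$oil_pv
    k <- pairs$k
  } else {
    oil_pv <- pairs
  }
  stopifnot(length(oil_pv) == length(k))
  if (any(k <= 0)) stop("all rate constants must be positive", call. = FALSE)
  if (length(unique(oil_pv)) < 2L) {
    stop("degenerate design: need at least 2 distinct oil PVs", call. = FALSE)
  }
  fit <- stats::lm(k ~ oil_pv)
  cf <- summary(fit)$coefficients
  n <- length(k)
  new_rate_pv_model(
    slope = unname(cf["oil_pv", "Estimate"]),
    intercept = unname(cf["(Intercept)", "Estimate"]),
    r2 = summary(fit)$r.squared,
    p_slope = if (n > 2L) unname(cf["oil_pv", "Pr(>|t|)"]) else NA_real_,
    pv_valid_range = range(oil_pv),
    temperature_C = temperature_C, n = n
  )
}

#' Construct a rate-versus-PV model from known coefficients
#'
#' @param slope,intercept line coefficients (intensity/day per mEq O2/kg
#'   oil, and intensity/day).
#' @param r2,p_slope optional diagnostics.
#' @param pv_valid_range PV range over which the line was established,
#'   mEq O2/kg oil.
#' @param temperature_C storage temperature of the rates.
#' @param n number of points behind the fit (NA if unknown).
#' @return a `rate_pv_model`.
#' @export
new_rate_pv_model <- function(slope, intercept, r2 = NA_real_,
                              p_slope = NA_real_, pv_valid_range = c(5, 25),
                              temperature_C = 20, n = NA_integer_) {
  if (slope <= 0) stop("slope must be positive for an oxidation rate model",
                       call. = FALSE)
  if (pv_valid_range[1L] >= pv_valid_range[2L]) {
    stop("pv_valid_range must be an increasing interval", call. = FALSE)
  }
  structure(
    list(slope = slope, intercept = intercept, r2 = r2, p_slope = p_slope,
         pv_valid_range = pv_valid_range, temperature_C = temperature_C, n = n),
    class = "rate_pv_model"
  )
}

#' @export
print.rate_pv_model <- function(x, ...) {
  cat(sprintf("<rate_pv_model> k(%g C) = %.4g * PV + %.4g  (r2 = %s, PV in [%g, %g])\n",
              x$temperature_C, x$slope, x$intercept, format(x$r2, digits = 3),
              x$pv_valid_range[1L], x$pv_valid_range[2L]))
  invisible(x)
}

#' Primary shelf life from the zero-order model
#'
#' Time for the quality indicator to travel from its initial value to the
#' acceptability limit at constant rate: `SL = (I_lim - I0) / k`.
#'
#' @param I0 initial indicator value (intensity of the just-made product).
#' @param I_lim acceptability limit, same units (must be >= I0).
#' @param k zero-order rate constant, indicator units/day (must be > 0).
#' @return shelf life, days.
#' @export
compute_shelf_life <- function(I0, I_lim, k) {
  if (any(k <= 0)) stop("rate constant k must be positive", call. = FALSE)
  if (any(I_lim < I0)) {
    stop("acceptability limit I_lim below initial value I0", call. = FALSE)
  }
  (I_lim - I0) / k
}

#' Predict cracker shelf life from ingredient-oil peroxide value
#'
#' Combines the rate-versus-PV line with the shelf-life equation:
#' `SL = (I_lim - I0) / (slope * PV + intercept)`. PVs outside the model's
#' validity range are evaluated with an extrapolation warning.
#'
#' @param model a `rate_pv_model`.
#' @param oil_pv peroxide value(s) of the ingredient oil, mEq O2/kg oil.
#' @param I_lim sensory acceptability limit chosen by the producer
#'   (default 6 on the 7-point scale).
#' @param I0 initial rancid-odor intensity (default 4.33, the mean score of
#'   just-baked crackers).
#' @param temperature_C storage temperature of the prediction; must equal
#'   the temperature the model was fitted at (no rate-versus-PV line exists
#'   at other temperatures).
#' @param days_per_month divisor for the months conversion (default 30.44,
#'   the mean Gregorian month).
#' @return data frame of class `shelf_life_result` with columns `oil_pv`,
#'   `I_lim`, `I0`, `k_used` (intensity/day), `sl_days`, `sl_months`.
#' @export
predict_shelf_life_from_pv <- function(model, oil_pv, I_lim = 6, I0 = 4.33,
                                       temperature_C = model$temperature_C,
                                       days_per_month = .DAYS_PER_MONTH_DEFAULT) {
  stopifnot(inherits(model, "rate_pv_model"))
  if (!isTRUE(all.equal(temperature_C, model$temperature_C))) {
    stop("rate-vs-PV model was fitted at ", model$temperature_C,
         " C; no predictions available at ", temperature_C, " C", call. = FALSE)
  }
  if (any(I_lim <= I0)) {
    stop("acceptability limit I_lim must exceed the initial intensity I0",
         call. = FALSE)
  }
  out_of_range <- oil_pv < model$pv_valid_range[1L] | oil_pv > model$pv_valid_range[2L]
  if (any(out_of_range)) {
    warning(sum(out_of_range), " PV value(s) outside the model validity range [",
            model$pv_valid_range[1L], ", ", model$pv_valid_range[2L],
            "] mEq O2/kg oil: extrapolating", call. = FALSE)
  }
  k_used <- model$slope * oil_pv + model$intercept
  sl_days <- compute_shelf_life(I0, I_lim, k_used)
  res <- data.frame(oil_pv = oil_pv, I_lim = I_lim, I0 = I0,
                    k_used = k_used, sl_days = sl_days,
                    sl_months = sl_days / days_per_month)
  class(res) <- c("shelf_life_result", class(res))
  res
}

#' Maximum admissible oil peroxide value for a target shelf life
#'
#' Inverts the shelf-life predictor: the largest ingredient-oil PV still
#' compatible with reaching `target_sl_days` before the acceptability limit
#' is crossed: `PV = ((I_lim - I0)/target - intercept) / slope`.
#'
#' @param model a `rate_pv_model`.
#' @param target_sl_days required shelf life, days (positive).
#' @param I_lim,I0 as in [predict_shelf_life_from_pv()].
#' @return maximum admissible oil PV, mEq O2/kg oil. Values outside the
#'   model validity range are returned with a warning. If even a perfectly
#'   fresh oil (PV = 0) could not reach the target (required rate at or
#'   below the line's intercept), an unreachable-target error is raised.
#' @export
max_admissible_pv <- function(model, target_sl_days, I_lim = 6, I0 = 4.33) {
  stopifnot(inherits(model, "rate_pv_model"))
  if (any(target_sl_days <= 0)) stop("target_sl_days must be positive", call. = FALSE)
  if (any(I_lim <= I0)) {
    stop("acceptability limit I_lim must exceed the initial intensity I0",
         call. = FALSE)
  }
  k_required <- (I_lim - I0) / target_sl_days
  if (any(k_required <= model$intercept)) {
    stop("unreachable target: required rate ", format(min(k_required)),
         " /day does not exceed the model intercept ", format(model$intercept),
         " /day even at PV = 0", call. = FALSE)
  }
  pv <- (k_required - model$intercept) / model$slope
  out_of_range <- pv < model$pv_valid_range[1L] | pv > model$pv_valid_range[2L]
  if (any(out_of_range)) {
    warning("admissible PV outside the model validity range [",
            model$pv_valid_range[1L], ", ", model$pv_valid_range[2L],
            "] mEq O2/kg oil", call. = FALSE)
  }
  pv
}

#' Shelf-life surface over oil PV and acceptability limit
#'
#' Dense evaluation of [predict_shelf_life_from_pv()] over a PV grid for
#' each acceptability limit, the numerical counterpart of the usual
#' shelf-life contour figure.
#'
#' @param model a `rate_pv_model`.
#' @param pv_grid oil PVs, mEq O2/kg oil (default 5..25 in unit steps).
#' @param ilim_set acceptability limits (default 5.5, 6.0, 6.5).
#' @param I0,days_per_month as in [predict_shelf_life_from_pv()].
#' @return data frame ordered by (`I_lim`, `oil_pv`) with columns `oil_pv`,
#'   `I_lim`, `I0`, `k_used`, `sl_days`, `sl_months`.
#' @export
shelf_life_surface <- function(model, pv_grid = seq(5, 25, by = 1),
                               ilim_set = c(5.5, 6.0, 6.5), I0 = 4.33,
                               days_per_month = .DAYS_PER_MONTH_DEFAULT) {
  stopifnot(length(pv_grid) >= 1L, length(ilim_set) >= 1L)
  rows <- lapply(sort(ilim_set), function(il) {
    predict_shelf_life_from_pv(model, sort(pv_grid), I_lim = il, I0 = I0,
                               days_per_month = days_per_month)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}
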