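#' Fit the iron standard curve of the ferric-thiocyanate assay
#'
#' Ordinary least-squares line of absorbance (510 nm) on micrograms of
#' iron, used to convert sample absorbances to peroxide values.
#'
#' @param points data frame with columns `iron_micrograms` and `absorbance`,
#'   or a numeric vector of iron amounts when `absorbance` is supplied.
#' @param absorbance optional absorbance vector matching `points`.
#' @return an object of class `standard_curve` with `slope_m` (absorbance
#'   per microgram Fe), `intercept_Ic` (blank absorbance), `r2` and `n`.
#' @export
fit_standard_curve <- function(points, absorbance = NULL) {
  if (is.data.frame(points)) {
    iron <- points$iron_micrograms
    abs_ <- points$absorbance
  } else {
    iron <- points
    abs_ <- absorbance
  }
  stopifnot(length(iron) == length(abs_), length(iron) >= 2L)
  if (length(unique(iron)) < 2L) {
    stop("degenerate design: all iron amounts identical", call. = FALSE)
  }
  fit <- stats::lm(abs_ ~ iron)
  s <- summary(fit)
  structure(
    list(slope_m = unname(stats::coef(fit)[2L]),
         intercept_Ic = unname(stats::coef(fit)[1L]),
         r2 = s$r.squared, n = length(iron)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> A = %.5f + %.5f * ugFe  (r2 = %.4f, n = %d)\n",
              x$intercept_Ic, x$slope_m, x$r2, x$n))
  invisible(x)
}

#' Peroxide value from ferric-thiocyanate absorbance
#'
#' Converts a background-corrected sample absorbance to micrograms of iron
#' through the standard curve, then to milliequivalents of active oxygen
#' per kilogram of oil:
#' `PV = ((As - Ac) - Ic) / m / (55.84 * 2 * Ws)`,
#' with `Ws` the oil sample mass in grams, 55.84 the atomic weight of iron
#' and 2 the oxygen equivalence factor. Because micrograms per gram equal
#' milligrams per kilogram, the result comes out per kg of oil.
#'
#' @param curve a `standard_curve`.
#' @param As sample absorbance at 510 nm.
#' @param Ac control (reagent blank) absorbance.
#' @param Ws oil sample mass, grams (positive).
#' @return peroxide value(s), mEq O2/kg oil. A blank exceeding the sample
#'   (negative implied iron) returns 0 with a warning.
#' @export
compute_pv <- function(curve, As, Ac, Ws) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(Ws <= 0)) stop("sample mass Ws must be positive", call. = FALSE)
  iron_ug <- ((As - Ac) - curve$intercept_Ic) / curve$slope_m
  pv <- iron_ug / (.IRON_ATOMIC_WEIGHT * 2 * Ws)
  if (any(iron_ug < 0)) {
    warning("blank absorbance exceeds sample for ", sum(iron_ug < 0),
            " measurement(s); PV reported as 0", call. = FALSE)
    pv[iron_ug < 0] <- 0
  }
  pv
}

#' Absorbance expected for a given peroxide value (assay inverse)
#'
#' Inverse of [compute_pv()]: the background-corrected absorbance a sample
#' of mass `Ws` with peroxide value `pv` would produce. Useful for
#' simulating assay readings and for round-trip checks.
#'
#' @param curve a `standard_curve`.
#' @param pv peroxide value, mEq O2/kg oil.
#' @param Ws oil sample mass, grams.
#' @param Ac control absorbance added back (default 0 returns As - Ac).
#' @return absorbance value(s).
#' @export
pv_to_absorbance <- function(curve, pv, Ws, Ac = 0) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(Ws <= 0)) stop("sample mass Ws must be positive", call. = FALSE)
  iron_ug <- pv * (.IRON_ATOMIC_WEIGHT * 2 * Ws)
  Ac + curve$intercept_Ic + curve$slope_m * iron_ug
}
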