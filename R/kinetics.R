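#' Fit the zero-order kinetic model to one trajectory
#'
#' Ordinary least squares of mean rancid-odor intensity (or peroxide value)
#' on storage time: `I(t) = intercept + k * t`. The slope is the apparent
#' zero-order rate constant at that storage temperature. Fitting is on
#' panel means, unweighted by default; censored observations (scale ceiling
#' reached) are excluded by default because the bounded scale stops
#' tracking the underlying reaction there.
#'
#' @param trajectory a `sensory_trajectory`, or a data frame with columns
#'   `time_days` and `intensity_mean` (optionally `censored`,
#'   `intensity_sd`, `n`).
#' @param exclude_censored drop observations flagged censored (default TRUE).
#' @param weights `"none"` (default) for unweighted OLS on panel means, or
#'   `"inv_sem2"` to weight each mean by the inverse of its squared
#'   standard error (`n / sd^2`).
#' @return an object of class `zero_order_fit`: `k`, `se_k`, `intercept`,
#'   `se_intercept`, `r2`, `p_slope` (two-sided t-test, n - 2 df),
#'   `n_points`, `n_censored_excluded`.
#' @export
fit_zero_order <- function(trajectory, exclude_censored = TRUE,
                           weights = c("none", "inv_sem2")) {
  weights <- match.arg(weights)
  df <- if (inherits(trajectory, "sensory_trajectory")) {
    as.data.frame(trajectory)
  } else {
    as.data.frame(trajectory)
  }
  stopifnot(all(c("time_days", "intensity_mean") %in% names(df)))

  n_censored_excluded <- 0L
  if (exclude_censored && "censored" %in% names(df)) {
    n_censored_excluded <- sum(df$censored, na.rm = TRUE)
    df <- df[!df$censored, , drop = FALSE]
  }
  if (length(unique(df$time_days)) < 2L) {
    stop("degenerate design: fewer than 2 distinct time points", call. = FALSE)
  }

  w <- NULL
  if (weights == "inv_sem2") {
    if (!all(c("intensity_sd", "n") %in% names(df)) ||
        any(!is.finite(df$intensity_sd)) || any(df$intensity_sd <= 0)) {
      stop("inv_sem2 weighting needs positive intensity_sd and n columns",
           call. = FALSE)
    }
    w <- df$n / df$intensity_sd^2
  }

  y <- df$intensity_mean
  constant_y <- length(unique(y)) == 1L
  fit <- stats::lm(intensity_mean ~ time_days, data = df, weights = w)
  cf <- summary(fit)$coefficients

  r2 <- summary(fit)$r.squared
  if (constant_y) {
    warning("all intensities identical: k = 0 and r2 reported as 0", call. = FALSE)
    r2 <- 0
  }

  structure(
    list(k = unname(cf["time_days", "Estimate"]),
         se_k = unname(cf["time_days", "Std. Error"]),
         intercept = unname(cf["(Intercept)", "Estimate"]),
         se_intercept = unname(cf["(Intercept)", "Std. Error"]),
         r2 = r2,
         p_slope = if (constant_y) NA_real_ else unname(cf["time_days", "Pr(>|t|)"]),
         n_points = nrow(df),
         n_censored_excluded = n_censored_excluded),
    class = "zero_order_fit"
  )
}

#' @export
print.zero_order_fit <- function(x, ...) {
  cat(sprintf(
    "<zero_order_fit> k = %.4g +/- %.2g /day, intercept = %.4g, r2 = %.3f, p = %.3g (n = %d%s)\n",
    x$k, x$se_k, x$intercept, x$r2, x$p_slope, x$n_points,
    if (x$n_censored_excluded > 0)
      sprintf(", %d censored excluded", x$n_censored_excluded) else ""))
  invisible(x)
}

#' Zero-order fits for every (batch, temperature) in a tidy table
#'
#' Applies [fit_zero_order()] to each batch-temperature combination of a
#' tidy trajectory table, producing a rate-constant table (one row per
#' combination) in the shape conventionally reported for storage studies.
#'
#' @param data tidy data frame in the trajectory CSV schema (see
#'   [trajectories_to_df()]).
#' @param exclude_censored,weights passed to [fit_zero_order()].
#' @return data frame with columns `batch_label`, `oil_pv`,
#'   `temperature_C`, `k`, `se_k`, `intercept`, `se_intercept`, `r2`,
#'   `p_slope`, `n_points`, `n_censored_excluded`.
#' @export
fit_kinetics_table <- function(data, exclude_censored = TRUE,
                               weights = c("none", "inv_sem2")) {
  weights <- match.arg(weights)
  stopifnot(all(c("batch_label", "temperature_C") %in% names(data)))
  keys <- unique(data[, c("batch_label", "temperature_C")])
  keys <- keys[order(keys$batch_label, keys$temperature_C), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- data[data$batch_label == keys$batch_label[i] &
                  data$temperature_C == keys$temperature_C[i], , drop = FALSE]
    f <- fit_zero_order(sub, exclude_censored = exclude_censored, weights = weights)
    data.frame(batch_label = keys$batch_label[i],
               oil_pv = if ("oil_pv" %in% names(sub)) sub$oil_pv[1L] else NA_real_,
               temperature_C = keys$temperature_C[i],
               k = f$k, se_k = f$se_k,
               intercept = f$intercept, se_intercept = f$se_intercept,
               r2 = f$r2, p_slope = f$p_slope, n_points = f$n_points,
               n_censored_excluded = f$n_censored_excluded)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
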