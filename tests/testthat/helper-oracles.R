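# Brute-force 2-D grid search minimizing the sum of squared errors of a
# straight line. Independent oracle for the OLS-based fits: no call to lm().
# Searches in mean-centered coordinates (y = a + b (x - xbar)) where the SSE
# surface is axis-aligned, so the grid refinement converges.
grid_ols <- function(x, y, rounds = 12L, grid_n = 41L) {
  xbar <- mean(x)
  xc <- x - xbar
  n <- length(x)
  slope <- (y[n] - y[1L]) / (x[n] - x[1L])
  level <- mean(y)
  slope_half <- abs(slope) + 1
  level_half <- stats::sd(y) + 1
  for (r in seq_len(rounds)) {
    ss <- seq(slope - slope_half, slope + slope_half, length.out = grid_n)
    ls <- seq(level - level_half, level + level_half, length.out = grid_n)
    sse <- outer(ss, ls, Vectorize(function(b, a) sum((y - (a + b * xc))^2)))
    best <- arrayInd(which.min(sse), dim(sse))
    slope <- ss[best[1L]]
    level <- ls[best[2L]]
    slope_half <- slope_half / 4
    level_half <- level_half / 4
  }
  list(slope = slope, intercept = level - slope * xbar)
}

# Noiseless trajectory data frame on an exact zero-order line.
noiseless_df <- function(I0, k, times, temperature_C = 20,
                         batch_label = "b", oil_pv = NA_real_) {
  data.frame(batch_label = batch_label, oil_pv = oil_pv,
             temperature_C = temperature_C, time_days = times,
             intensity_mean = I0 + k * times,
             intensity_sd = 0, n = 30, censored = FALSE)
}

# Closed-form two-point activation energy, J/mol.
two_point_ea <- function(T1_C, k1, T2_C, k2, R = 8.314) {
  T1 <- T1_C + 273.15
  T2 <- T2_C + 273.15
  R * log(k2 / k1) / (1 / T1 - 1 / T2)
}
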