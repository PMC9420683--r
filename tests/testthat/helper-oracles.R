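# Independent numerical oracles used across the suite.

# Central finite-difference derivative of the enhancement curve; stays
# independent of gv_slope().
fd_slope <- function(params, times, h = 1e-5) {
  (gv_enhancement(params, times + h) - gv_enhancement(params, pmax(times - h, 0))) /
    (times + h - pmax(times - h, 0))
}

# Brute-force maximum slope: dense grid over the upslope refined by
# optimize() on the finite-difference derivative.
numeric_max_slope <- function(params) {
  grid <- seq(1e-6, params$t_max, length.out = 4001)
  d <- fd_slope(params, grid)
  i <- which.max(d)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  stats::optimize(function(t) fd_slope(params, t), c(lo, hi), maximum = TRUE,
                  tol = 1e-10)$objective
}

# Noiseless sampled curve for a given parameter set.
sampled_curve <- function(params, baseline = 0, n_frames = 40, interval = 1.5) {
  tt <- (seq_len(n_frames) - 1) * interval
  te_curve(tt, baseline + gv_enhancement(params, tt))
}
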