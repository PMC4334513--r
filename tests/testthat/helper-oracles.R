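# Closed-form autocovariance of unit-variance fractional Gaussian noise.
fgn_cov_theory <- function(alpha, k) {
  0.5 * (abs(k + 1)^alpha - 2 * abs(k)^alpha + abs(k - 1)^alpha)
}

# Exact power-law TAMSD curve value(n) = D * n^alpha.
powerlaw_curve <- function(alpha, D = 1, max_lag = 50, L = 1000) {
  new_tamsd_curve(seq_len(max_lag), D * seq_len(max_lag)^alpha, L)
}

# Sample standard deviation of a trajectory's increments with the package's
# normalization convention (denominator = number of increments, L - 1).
increment_sd <- function(traj) {
  d <- diff(traj$positions)
  sqrt(sum((d - mean(d))^2) / length(d))
}

# Hand-build a precision_map object for tests of selection/tie-break logic.
fake_map <- function(grid, alpha = 0.7, sigma = 0.5) {
  structure(list(alpha = alpha, sigma = sigma, halfwidth = 0.1,
                 n_reps = 100L, seed = 1L, grid = grid),
            class = "precision_map")
}
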