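#' Construct a TAMSD curve object
#'
#' @param lags integer lags 1..max_lag in units of the sampling interval.
#' @param values TAMSD values, squared length units.
#' @param source_length length L of the underlying trajectory.
#' @param corrected_offset noise offset already subtracted (0 if none).
#' @return an object of class `tamsd_curve`.
#' @export
new_tamsd_curve <- function(lags, values, source_length,
                            corrected_offset = 0) {
  stopifnot(length(lags) == length(values), all(diff(lags) > 0))
  structure(
    list(lags = as.integer(lags), values = as.numeric(values),
         source_length = as.integer(source_length),
         corrected_offset = as.numeric(corrected_offset)),
    class = "tamsd_curve")
}

#' @export
print.tamsd_curve <- function(x, ...) {
  cat(sprintf("<tamsd_curve> lags 1..%d from a trajectory of L = %d%s\n",
              max(x$lags), x$source_length,
              if (x$corrected_offset > 0)
                sprintf(", noise offset %g subtracted", x$corrected_offset)
              else ""))
  invisible(x)
}

#' @export
as.data.frame.tamsd_curve <- function(x, ...) {
  data.frame(lag = x$lags, tamsd = x$values)
}

# Direct evaluation of the overlapping-window TAMSD definition:
# value(n) = mean over m of (x(m+n) - x(m))^2, denominator L - n.
# O(L * max_lag); kept as the independent oracle for the FFT path.
tamsd_naive <- function(x, max_lag) {
  L <- length(x)
  vapply(seq_len(max_lag), function(n)
    mean((x[(1L + n):L] - x[1:(L - n)])^2), numeric(1))
}

# FFT-accelerated TAMSD on a bare numeric vector. Uses the standard
# decomposition sum (x_{m+n} - x_m)^2 = S1(n) - 2 * sum_m x_m x_{m+n},
# with the autocorrelation term computed by one zero-padded FFT and
# S1(n) by cumulative sums. O(L log L) for all lags at once.
tamsd_fft <- function(x, max_lag) {
  L <- length(x)
  nfft <- stats::nextn(2L * L, 2)
  fx <- stats::fft(c(x, numeric(nfft - L)))
  ac <- Re(stats::fft(fx * Conj(fx), inverse = TRUE)) / nfft
  q <- x * x
  csq <- cumsum(q)
  tot <- csq[L]
  n <- seq_len(max_lag)
  s1 <- tot - csq[n] + csq[L - n]
  (s1 - 2 * ac[n + 1L]) / (L - n)
}

#' Time-averaged mean square displacement
#'
#' Computes, for every integer lag `n` in `1..max_lag`, the average squared
#' displacement over all overlapping windows of the trajectory:
#' `TAMSD(n) = (1/(L-n)) * sum_{m=1..L-n} (x(m+n) - x(m))^2`.
#' The computation is FFT-accelerated, identical to the direct double sum
#' to rounding error.
#'
#' @param traj an `spt_trajectory`.
#' @param max_lag largest lag, between 1 and `L - 1`. Defaults to
#'   `floor(L/2)`, the largest lag the sweep machinery ever fits.
#' @return a `tamsd_curve` with `corrected_offset = 0`.
#' @examples
#' tr <- new_trajectory(c(0, 1, -1, 2))
#' compute_tamsd(tr, max_lag = 2)$values  # c(14/3, 1)
#' @export
compute_tamsd <- function(traj, max_lag = floor(length(traj$positions) / 2)) {
  stopifnot(inherits(traj, "spt_trajectory"))
  L <- length(traj$positions)
  max_lag <- as.integer(max_lag)
  if (is.na(max_lag) || max_lag < 1L || max_lag > L - 1L)
    stop("max_lag must satisfy 1 <= max_lag <= L - 1", call. = FALSE)
  new_tamsd_curve(seq_len(max_lag), tamsd_fft(traj$positions, max_lag), L)
}

#' Subtract the localization-noise offset from a TAMSD curve
#'
#' I.i.d. localization noise of standard deviation `sigma` inflates the
#' expected TAMSD by a constant: each displacement picks up two independent
#' error terms, so the offset is `2 * sigma^2` (the `"double"` convention,
#' default). A `"single"` convention subtracting `sigma^2` is provided for
#' compatibility with analyses that fold the factor of two into their noise
#' estimate. Corrected values can become non-positive at small lags; they
#' are retained in the curve and excluded lag-wise at fit time.
#'
#' @param curve an uncorrected `tamsd_curve`.
#' @param sigma known noise standard deviation, >= 0.
#' @param convention `"double"` (subtract `2 sigma^2`) or `"single"`
#'   (subtract `sigma^2`).
#' @return the corrected `tamsd_curve` with `corrected_offset` recorded.
#' @export
correct_noise <- function(curve, sigma, convention = c("double", "single")) {
  stopifnot(inherits(curve, "tamsd_curve"))
  convention <- match.arg(convention)
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop("sigma must be a single number >= 0", call. = FALSE)
  if (curve$corrected_offset > 0)
    stop("curve has already been noise-corrected", call. = FALSE)
  offset <- if (convention == "double") 2 * sigma^2 else sigma^2
  new_tamsd_curve(curve$lags, curve$values - offset, curve$source_length,
                  corrected_offset = offset)
}

#' Fit a power law to a TAMSD curve on log-log axes
#'
#' Ordinary unweighted least squares of `log(TAMSD)` on `log(lag)` over the
#' integer lags `1..tau_max`; the slope estimates the anomalous exponent
#' and the intercept the log generalized diffusion coefficient. Lags whose
#' value is non-positive (possible after noise correction) are excluded
#' from the regression; fewer than two usable lags is an error, never a
#' silent NA.
#'
#' @param curve a `tamsd_curve` covering lags `1..tau_max`.
#' @param tau_max maximal lag entering the fit, >= 2.
#' @return a list of class `tamsd_fit` with `alpha_hat`, `log_D_hat`
#'   (natural log), `tau_max_used` and `n_lags_used`.
#' @examples
#' cv <- new_tamsd_curve(1:20, 5 * (1:20)^1.3, 100)
#' fit_powerlaw(cv, 20)$alpha_hat  # 1.3
#' @export
fit_powerlaw <- function(curve, tau_max) {
  stopifnot(inherits(curve, "tamsd_curve"))
  tau_max <- as.integer(tau_max)
  if (is.na(tau_max) || tau_max < 2L)
    stop("tau_max must be an integer >= 2", call. = FALSE)
  if (max(curve$lags) < tau_max || !all(seq_len(tau_max) %in% curve$lags))
    stop("curve does not cover lags 1..tau_max", call. = FALSE)
  keep <- curve$lags <= tau_max & curve$values > 0
  if (sum(keep) < 2L)
    stop(sprintf(paste0("power-law fit needs >= 2 positive TAMSD values in ",
                        "lags 1..%d (found %d)"), tau_max, sum(keep)),
         call. = FALSE)
  lx <- log(curve$lags[keep])
  ly <- log(curve$values[keep])
  mx <- mean(lx); my <- mean(ly)
  slope <- sum((lx - mx) * (ly - my)) / sum((lx - mx)^2)
  structure(
    list(alpha_hat = slope, log_D_hat = my - slope * mx,
         tau_max_used = tau_max, n_lags_used = sum(keep)),
    class = "tamsd_fit")
}

#' @export
print.tamsd_fit <- function(x, ...) {
  cat(sprintf(
    "<tamsd_fit> alpha_hat = %.4f, log D = %.4f (tau_M = %d, %d lags)\n",
    x$alpha_hat, x$log_D_hat, x$tau_max_used, x$n_lags_used))
  invisible(x)
}

# Slopes of the log-log OLS fit for every tau_M at once, via cumulative
# sums: O(max lag) per curve instead of O(max lag^2). Requires all values
# positive (always true for an uncorrected TAMSD of a non-constant
# trajectory); falls back to per-tau fits with lag-wise exclusion
# otherwise. Returns a vector indexed by tau_grid, NA where a fit fails.
fit_powerlaw_all <- function(values, tau_grid) {
  k_max <- max(tau_grid)
  if (any(values[seq_len(k_max)] <= 0)) {
    cv <- new_tamsd_curve(seq_len(k_max), values[seq_len(k_max)], k_max + 1L)
    return(vapply(tau_grid, function(tm)
      tryCatch(fit_powerlaw(cv, tm)$alpha_hat, error = function(e) NA_real_),
      numeric(1)))
  }
  lx <- log(seq_len(k_max))
  ly <- log(values[seq_len(k_max)])
  k <- seq_len(k_max)
  sx <- cumsum(lx); sy <- cumsum(ly)
  sxy <- cumsum(lx * ly); sxx <- cumsum(lx * lx)
  slope <- (k * sxy - sx * sy) / (k * sxx - sx * sx)
  slope[tau_grid]
}
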