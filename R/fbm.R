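#' Derive a reproducible sub-seed from a master seed and a counter
#'
#' Lehmer-style hash on the Mersenne prime 2^31 - 1. Every Monte-Carlo
#' routine in the package draws one counter value per independent random
#' stream (one per trajectory for the path, one for its noise), so any
#' single trajectory can be regenerated in isolation.
#'
#' @param seed master integer seed.
#' @param counter non-negative integer stream index.
#' @return an integer seed in [0, 2^31 - 1), distinct for distinct counters.
#' @keywords internal
derive_seed <- function(seed, counter) {
  p <- 2147483647
  x <- (abs(as.double(seed)) %% (p - 1)) + 1
  x <- (x * 16807) %% p
  x <- (x + as.double(counter)) %% p
  x <- (x * 16807) %% p
  x <- (x * 16807) %% p
  as.integer(x)
}

#' Construct a trajectory object
#'
#' A 1-D position series sampled at unit time intervals. Positions are in
#' arbitrary length units; when produced by [simulate_fbm()] the increments
#' are normalized so their per-trajectory standard deviation is exactly 1
#' (generalized diffusion coefficient 1).
#'
#' @param positions numeric vector of length >= 2.
#' @param true_alpha optional anomalous exponent used in generation.
#' @param true_sigma optional localization-noise standard deviation added.
#' @param is_noisy logical, whether localization noise has been added.
#' @param stride sub-sampling stride applied so far (1 = none).
#' @return an object of class `spt_trajectory`.
#' @export
new_trajectory <- function(positions, true_alpha = NA_real_,
                           true_sigma = NA_real_, is_noisy = FALSE,
                           stride = 1L) {
  if (!is.numeric(positions) || length(positions) < 2L)
    stop("a trajectory needs at least 2 numeric positions", call. = FALSE)
  if (anyNA(positions))
    stop("positions must not contain NA", call. = FALSE)
  structure(
    list(positions = as.numeric(positions),
         true_alpha = true_alpha, true_sigma = true_sigma,
         is_noisy = isTRUE(is_noisy), stride = as.integer(stride)),
    class = "spt_trajectory")
}

#' @export
print.spt_trajectory <- function(x, ...) {
  cat(sprintf("<spt_trajectory> L = %d point%s%s%s%s\n",
              length(x$positions),
              if (length(x$positions) == 1L) "" else "s",
              if (!is.na(x$true_alpha))
                sprintf(", true alpha = %g", x$true_alpha) else "",
              if (x$is_noisy)
                sprintf(", noise sigma = %g", x$true_sigma) else " (noise-free)",
              if (x$stride > 1L)
                sprintf(", sub-sampled stride %d", x$stride) else ""))
  invisible(x)
}

#' @export
length.spt_trajectory <- function(x) length(x$positions)

# Autocovariance of fractional Gaussian noise with unit variance:
# gamma(k) = 0.5 * (|k+1|^a - 2|k|^a + |k-1|^a), where a = 2H is the
# TAMSD exponent. gamma(0) = 1.
fgn_autocov <- function(alpha, k) {
  0.5 * (abs(k + 1)^alpha - 2 * abs(k)^alpha + abs(k - 1)^alpha)
}

# Exact fractional-Gaussian-noise sampler by circulant embedding
# (Davies-Harte / Wood-Chan). The covariance row is embedded in a
# circulant of power-of-two size m >= 2n so every FFT is fast; the
# embedding eigenvalues are checked for non-negativity.
# Returns n_inc unit-variance fGn values. Assumes the RNG seed is set
# by the caller.
fgn_davies_harte <- function(alpha, n_inc) {
  m <- stats::nextn(2L * n_inc, 2)
  repeat {
    half <- m %/% 2L
    g <- fgn_autocov(alpha, 0:half)
    row <- c(g, rev(g[2:half]))           # length m, circulant first row
    lam <- Re(stats::fft(row))
    if (min(lam) > -1e-8 * max(lam)) break
    m <- m * 2L
    if (m > 2^26) return(NULL)            # give up; caller falls back
  }
  lam[lam < 0] <- 0
  half <- m %/% 2L
  z1 <- stats::rnorm(half + 1L)
  z2 <- stats::rnorm(half + 1L)
  v <- complex(length.out = m)
  v[1L] <- sqrt(lam[1L]) * z1[1L]
  v[half + 1L] <- sqrt(lam[half + 1L]) * z1[half + 1L]
  j <- 2:half
  v[j] <- sqrt(lam[j] / 2) * complex(real = z1[j], imaginary = z2[j])
  v[m + 2L - j] <- Conj(v[j])
  x <- Re(stats::fft(v)) / sqrt(m)
  x[seq_len(n_inc)]
}

# Hosking's recursive method: exact but O(n^2). Fallback for the rare
# case the circulant embedding is not non-negative definite.
fgn_hosking <- function(alpha, n_inc) {
  g <- fgn_autocov(alpha, 0:(n_inc - 1L))
  x <- numeric(n_inc)
  phi <- numeric(n_inc)
  v <- 1
  x[1L] <- stats::rnorm(1L)
  if (n_inc == 1L) return(x)
  for (k in 1:(n_inc - 1L)) {
    if (k == 1L) {
      phi[1L] <- g[2L]
    } else {
      prev <- phi[1:(k - 1L)]
      a <- (g[k + 1L] - sum(prev * g[k:2])) / v
      phi[1:(k - 1L)] <- prev - a * rev(prev)
      phi[k] <- a
    }
    v <- v * (1 - phi[k]^2)
    mu <- sum(phi[1:k] * x[k:1])
    x[k + 1L] <- mu + sqrt(v) * stats::rnorm(1L)
  }
  x
}

#' Simulate a fractional Brownian motion trajectory
#'
#' Generates a noise-free FBM sample path whose TAMSD exponent is `alpha`
#' (Hurst index `alpha/2`). Increments are stationary Gaussian with
#' autocovariance `0.5 * (|k+1|^alpha - 2|k|^alpha + |k-1|^alpha)` at lag
#' `k`, and are rescaled so the per-trajectory sample standard deviation of
#' the `length - 1` increments is exactly 1, which fixes the generalized
#' diffusion coefficient to 1. The sampler is the exact circulant-embedding
#' (Davies-Harte) construction, with Hosking's recursion as a fallback.
#'
#' @param alpha anomalous exponent, in (0, 2). `alpha < 1` is subdiffusion,
#'   `alpha = 1` ordinary Brownian motion, `alpha > 1` superdiffusion.
#' @param length number of time points `L` (>= 2); sampling interval is 1.
#' @param seed integer seed; identical `(alpha, length, seed)` give
#'   bit-identical trajectories.
#' @return an [new_trajectory()] object with `true_alpha` recorded.
#' @examples
#' tr <- simulate_fbm(alpha = 0.7, length = 128, seed = 1)
#' sd_inc <- sqrt(sum((diff(tr$positions) - mean(diff(tr$positions)))^2) / 127)
#' stopifnot(abs(sd_inc - 1) < 1e-12)
#' @export
simulate_fbm <- function(alpha, length, seed) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 2)
    stop("alpha must lie strictly inside (0, 2)", call. = FALSE)
  length <- as.integer(length)
  if (is.na(length) || length < 2L)
    stop("length must be an integer >= 2", call. = FALSE)
  n_inc <- length - 1L
  set.seed(as.integer(seed))
  d <- fgn_davies_harte(alpha, n_inc)
  if (is.null(d)) d <- fgn_hosking(alpha, n_inc)
  # normalize increment sd to one: denominator = number of increments
  s <- sqrt(sum((d - mean(d))^2) / n_inc)
  if (s == 0) stop("degenerate increment sample", call. = FALSE)
  d <- d / s
  new_trajectory(c(0, cumsum(d)), true_alpha = alpha, true_sigma = 0,
                 is_noisy = FALSE)
}

#' Add Gaussian localization noise to a trajectory
#'
#' Adds i.i.d. Normal(0, `sigma^2`) measurement errors to every position,
#' emulating static localization error in single-particle tracking. The
#' trajectory is not re-normalized, so `sigma` is the noise standard
#' deviation relative to the (unit) increment standard deviation.
#'
#' @param traj an `spt_trajectory`.
#' @param sigma noise standard deviation, >= 0.
#' @param seed integer seed; the noise stream is independent of the path.
#' @return a noisy `spt_trajectory` with `is_noisy = TRUE`.
#' @export
add_noise <- function(traj, sigma, seed) {
  stopifnot(inherits(traj, "spt_trajectory"))
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop("sigma must be a single number >= 0", call. = FALSE)
  pos <- traj$positions
  if (sigma > 0) {
    set.seed(as.integer(seed))
    pos <- pos + stats::rnorm(length(pos), mean = 0, sd = sigma)
  }
  new_trajectory(pos, true_alpha = traj$true_alpha, true_sigma = sigma,
                 is_noisy = TRUE, stride = traj$stride)
}

#' Sub-sample a trajectory
#'
#' Keeps every `stride`-th position starting from the first, so the kept
#' length is `floor((L - 1) / stride) + 1`. Sub-sampling enlarges the
#' typical step relative to a fixed localization noise, lowering the
#' effective relative noise level (see [effective_relative_sigma()]) at the
#' cost of trajectory length. True generation parameters are carried over
#' unchanged.
#'
#' @param traj an `spt_trajectory`.
#' @param stride integer >= 1.
#' @return the sub-sampled `spt_trajectory`.
#' @export
subsample <- function(traj, stride) {
  stopifnot(inherits(traj, "spt_trajectory"))
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L)
    stop("stride must be an integer >= 1", call. = FALSE)
  L <- length(traj$positions)
  idx <- seq.int(1L, L, by = stride)
  if (length(idx) < 2L)
    stop("stride too large: fewer than 2 points would remain", call. = FALSE)
  new_trajectory(traj$positions[idx], true_alpha = traj$true_alpha,
                 true_sigma = traj$true_sigma, is_noisy = traj$is_noisy,
                 stride = traj$stride * stride)
}

#' Effective relative noise level after sub-sampling
#'
#' With unit-normalized increments the step standard deviation at lag `k`
#' is `k^(alpha/2)`, so keeping every `stride`-th point rescales the noise
#' standard deviation relative to the new unit step by
#' `sigma / stride^(alpha/2)`.
#'
#' @param sigma noise standard deviation relative to the original step.
#' @param alpha anomalous exponent of the underlying motion.
#' @param stride sub-sampling stride, >= 1.
#' @return the noise standard deviation relative to the sub-sampled step.
#' @examples
#' effective_relative_sigma(1, 0.7, 7)  # ~0.506: sigma = 1 behaves like 0.5
#' @export
effective_relative_sigma <- function(sigma, alpha, stride) {
  if (!is.numeric(sigma) || sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L)
    stop("stride must be an integer >= 1", call. = FALSE)
  sigma / stride^(alpha / 2)
}
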