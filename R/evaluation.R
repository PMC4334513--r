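#' Precision of an exponent estimate set
#'
#' The precision statistic is the fraction of single-trajectory exponent
#' estimates falling within `halfwidth` of the true exponent, endpoints
#' inclusive. Failed fits (NA) are excluded from the denominator.
#'
#' @param estimates numeric vector of fitted exponents; NA marks a failed
#'   fit.
#' @param true_alpha the exponent the trajectories were generated with.
#' @param halfwidth acceptance half-width, > 0; default 0.1, i.e. the
#'   window `[alpha - 0.1, alpha + 0.1]`. Endpoints are inclusive (up to
#'   binary representation error of decimal window edges).
#' @return the precision, a number in `[0, 1]`.
#' @examples
#' compute_phi(c(0.55, 0.65, 0.75, 0.85, 0.95), 0.7)  # 0.6
#' @export
compute_phi <- function(estimates, true_alpha, halfwidth = 0.1) {
  est <- estimates[!is.na(estimates)]
  if (length(est) == 0L)
    stop("no successful estimates to evaluate", call. = FALSE)
  if (!is.numeric(halfwidth) || halfwidth <= 0)
    stop("halfwidth must be > 0", call. = FALSE)
  mean(abs(est - true_alpha) <= halfwidth + 1e-12)
}

#' Bias of an exponent estimate set
#'
#' Mean fitted exponent minus the true exponent: the accuracy of the
#' estimator when many realizations of the same process are averaged.
#'
#' @inheritParams compute_phi
#' @return the bias (signed).
#' @export
compute_bias <- function(estimates, true_alpha) {
  est <- estimates[!is.na(estimates)]
  if (length(est) == 0L)
    stop("no successful estimates to evaluate", call. = FALSE)
  mean(est) - true_alpha
}

# Simulate n_reps noisy FBM trajectories of length L and fit the TAMSD of
# each at every maximal lag in tau_grid. Returns an n_reps x |tau_grid|
# matrix of fitted exponents (NA = failed fit). counter_base offsets the
# per-trajectory seed streams so different L values draw independently.
estimate_alpha_matrix <- function(alpha, sigma, L, tau_grid, n_reps, seed,
                                  counter_base = 0) {
  max_lag <- max(tau_grid)
  out <- matrix(NA_real_, nrow = n_reps, ncol = length(tau_grid))
  for (i in seq_len(n_reps)) {
    tr <- simulate_fbm(alpha, L, derive_seed(seed, counter_base + 2 * i))
    if (sigma > 0)
      tr <- add_noise(tr, sigma, derive_seed(seed, counter_base + 2 * i + 1))
    vals <- tamsd_fft(tr$positions, max_lag)
    out[i, ] <- fit_powerlaw_all(vals, tau_grid)
  }
  out
}

#' Monte-Carlo map of estimation precision and bias
#'
#' For each trajectory length in `L_grid`, simulates `n_reps` independent
#' unit-normalized FBM trajectories with additive Gaussian localization
#' noise, computes each trajectory's TAMSD once up to lag `floor(L/2)`,
#' fits the power law at every maximal lag `tau_M` in `2..floor(L/2)`
#' (re-using the same trajectories across `tau_M`), and records per
#' `(L, tau_M)` cell the precision `phi` (fraction of fits within
#' `halfwidth` of `alpha`) and the bias (mean fitted exponent minus
#' `alpha`). Trajectories are drawn independently across `L` values.
#'
#' @param alpha true anomalous exponent, in (0, 2).
#' @param sigma localization-noise standard deviation, >= 0.
#' @param L_grid integer vector of trajectory lengths, each >= 10.
#' @param n_reps trajectories per length; 1000 matches the reference
#'   benchmark protocol, smaller values give scaled-down maps.
#' @param seed master integer seed; the map is fully reproducible from it.
#' @param halfwidth precision acceptance half-width (default 0.1).
#' @return an object of class `precision_map`: a list with the condition
#'   (`alpha`, `sigma`, `halfwidth`, `n_reps`, `seed`) and `grid`, a
#'   data.frame with columns `L`, `tau_M`, `phi`, `bias`, `n_effective`.
#' @export
sweep_precision <- function(alpha, sigma, L_grid, n_reps = 1000, seed,
                            halfwidth = 0.1) {
  L_grid <- sort(unique(as.integer(L_grid)))
  if (length(L_grid) == 0L || any(is.na(L_grid)) || any(L_grid < 10L))
    stop("L_grid must contain integers >= 10", call. = FALSE)
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L)
    stop("n_reps must be >= 1", call. = FALSE)
  rows <- vector("list", length(L_grid))
  for (j in seq_along(L_grid)) {
    L <- L_grid[j]
    tau_grid <- 2:(L %/% 2L)
    am <- estimate_alpha_matrix(alpha, sigma, L, tau_grid, n_reps, seed,
                                counter_base = (j - 1) * 2^21)
    ok <- !is.na(am)
    n_eff <- colSums(ok)
    hit <- abs(am - alpha) <= halfwidth + 1e-12
    phi <- colSums(hit, na.rm = TRUE) / pmax(n_eff, 1L)
    bias <- colMeans(am, na.rm = TRUE) - alpha
    phi[n_eff == 0L] <- NA_real_
    bias[!is.finite(bias)] <- NA_real_
    rows[[j]] <- data.frame(L = L, tau_M = tau_grid, phi = phi, bias = bias,
                            n_effective = n_eff)
  }
  structure(
    list(alpha = alpha, sigma = sigma, halfwidth = halfwidth,
         n_reps = n_reps, seed = as.integer(seed),
         grid = do.call(rbind, rows)),
    class = "precision_map")
}

#' @export
print.precision_map <- function(x, ...) {
  cat(sprintf(paste0("<precision_map> alpha = %g, sigma = %g, L in {%s}, ",
                     "%d reps, halfwidth %g\n"),
              x$alpha, x$sigma, paste(unique(x$grid$L), collapse = ", "),
              x$n_reps, x$halfwidth))
  invisible(x)
}

#' @export
as.data.frame.precision_map <- function(x, ...) {
  cbind(alpha = x$alpha, sigma = x$sigma, x$grid, seed = x$seed)
}

#' Optimal maximal lag at a given trajectory length
#'
#' Picks, among the `tau_M` cells of a precision map at length `L`, the one
#' with maximal precision `phi`; ties are broken by smaller absolute bias,
#' then by smaller `tau_M`.
#'
#' @param map a `precision_map`.
#' @param L a trajectory length present in the map.
#' @return a list with `tau_M`, `phi` and `bias` of the selected cell.
#' @export
optimal_tau <- function(map, L) {
  stopifnot(inherits(map, "precision_map"))
  g <- map$grid[map$grid$L == L & !is.na(map$grid$phi), , drop = FALSE]
  if (nrow(g) == 0L)
    stop(sprintf("length L = %d is not present in the map", L), call. = FALSE)
  ord <- order(-g$phi, abs(g$bias), g$tau_M)
  best <- g[ord[1L], ]
  list(tau_M = best$tau_M, phi = best$phi, bias = best$bias)
}

#' Compare sub-sampled and direct fitting on the same trajectories
#'
#' Under large relative noise it can be better to sub-sample a long
#' trajectory — trading length for a larger step relative to the fixed
#' localization error — than to fit it directly. This routine simulates
#' `n_reps` noisy FBM trajectories and evaluates both strategies on the
#' same realizations: (a) keep every `stride`-th point, truncate to
#' `floor(L / stride)` points, and fit with maximal lag `tau_sub`;
#' (b) fit the unmodified trajectory at every `tau_M` up to `floor(L/2)`
#' and take the best achievable precision.
#'
#' @param alpha true anomalous exponent.
#' @param sigma noise standard deviation.
#' @param L trajectory length before sub-sampling.
#' @param stride sub-sampling stride.
#' @param tau_sub maximal lag used on the sub-sampled trajectories.
#' @param n_reps number of trajectories.
#' @param seed master integer seed.
#' @param halfwidth precision acceptance half-width (default 0.1).
#' @return a list with `phi_subsampled`, `phi_original_optimal`,
#'   `tau_original` (the maximizing lag of branch b), `effective_length`
#'   and `effective_sigma` of the sub-sampled branch.
#' @export
compare_subsampling <- function(alpha, sigma, L, stride, tau_sub, n_reps,
                                seed, halfwidth = 0.1) {
  L <- as.integer(L); stride <- as.integer(stride)
  tau_sub <- as.integer(tau_sub); n_reps <- as.integer(n_reps)
  L_eff <- L %/% stride
  if (L_eff < tau_sub + 1L)
    stop("tau_sub too large for the sub-sampled length", call. = FALSE)
  tau_grid <- 2:(L %/% 2L)
  a_sub <- numeric(n_reps)
  a_full <- matrix(NA_real_, n_reps, length(tau_grid))
  for (i in seq_len(n_reps)) {
    tr <- simulate_fbm(alpha, L, derive_seed(seed, 2 * i))
    if (sigma > 0) tr <- add_noise(tr, sigma, derive_seed(seed, 2 * i + 1))
    sub <- subsample(tr, stride)
    sub$positions <- sub$positions[seq_len(L_eff)]
    a_sub[i] <- fit_powerlaw_all(tamsd_fft(sub$positions, tau_sub),
                                 seq(2L, tau_sub))[tau_sub - 1L]
    a_full[i, ] <- fit_powerlaw_all(tamsd_fft(tr$positions, max(tau_grid)),
                                    tau_grid)
  }
  phi_full <- colMeans(abs(a_full - alpha) <= halfwidth + 1e-12,
                       na.rm = TRUE)
  best <- which.max(phi_full)
  list(phi_subsampled = compute_phi(a_sub, alpha, halfwidth),
       phi_original_optimal = phi_full[best],
       tau_original = tau_grid[best],
       effective_length = L_eff,
       effective_sigma = effective_relative_sigma(sigma, alpha, stride))
}

#' Heat map of a precision map
#'
#' Renders precision as a filled tile map over trajectory length and
#' maximal lag (both on log axes) with bias contours overlaid at
#' `0, +/-0.05, +/-0.1, +/-0.2, +/-0.3`.
#'
#' @param x a `precision_map` (with at least two `L` values for a useful
#'   picture).
#' @param ... ignored.
#' @return a ggplot object.
#' @export
plot.precision_map <- function(x, ...) {
  g <- x$grid[!is.na(x$grid$phi), ]
  ggplot2::ggplot(g, ggplot2::aes(x = .data$L, y = .data$tau_M)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$phi)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$bias),
                          breaks = c(-0.3, -0.2, -0.1, -0.05, 0, 0.05,
                                     0.1, 0.2, 0.3),
                          colour = "black", linewidth = 0.3) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "precision") +
    ggplot2::labs(
      x = "trajectory length L", y = "maximal fitted lag",
      title = sprintf("TAMSD exponent estimation, alpha = %g, sigma = %g",
                      x$alpha, x$sigma),
      subtitle = sprintf("%d trajectories per L; contours: bias", x$n_reps)) +
    ggplot2::theme_minimal()
}
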