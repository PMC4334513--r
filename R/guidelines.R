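#' Reference table of recommended maximal lags
#'
#' The quick look-up table of near-optimal maximal fitting lags `tau_M`
#' extracted from Monte-Carlo precision/bias maps of noisy FBM: one entry
#' per simulated exponent regime (`alpha` in 0.3, 0.7, 1.3, 1.7), noise
#' level (`sigma` in 0.1, 0.5, 1) and trajectory length (`L` 100 or 1000).
#' [benchmark_tau_table()] re-derives these optima by re-simulation.
#'
#' @return a data.frame with columns `alpha`, `sigma`, `L`, `tau_M`.
#' @export
tau_table <- function() {
  data.frame(
    alpha = rep(c(0.3, 0.7, 1.3, 1.7), each = 6),
    sigma = rep(rep(c(0.1, 0.5, 1), each = 2), times = 4),
    L     = rep(c(100L, 1000L), times = 12),
    tau_M = c(15L,  20L, 10L,  10L, 20L, 200L,   # alpha = 0.3
              10L,  10L, 10L,  40L, 40L, 400L,   # alpha = 0.7
              10L,  10L, 10L,  45L, 40L, 150L,   # alpha = 1.3
              10L,  10L, 20L,  75L, 50L, 150L))  # alpha = 1.7
}

snap_to_grid <- function(x, grid, what) {
  s <- grid[which.min(abs(grid - x))]
  if (abs(s - x) > 1e-9)
    warning(sprintf("%s = %g is off the simulated grid; snapping to %g",
                    what, x, s), call. = FALSE)
  s
}

#' Look up a recommended maximal lag
#'
#' Snaps `alpha_regime` and `sigma` to the nearest simulated grid values
#' (0.3/0.7/1.3/1.7 and 0.1/0.5/1, with a warning when off-grid), then
#' reads the reference table. For `L` strictly between the two tabulated
#' anchors (100 and 1000) the recommendation is interpolated linearly in
#' `log L` and rounded; beyond 1000 it is extrapolated flat, and below 100
#' the 100-point entry is used. The result is always clamped to
#' `floor(L / 2)` (and to at least 2).
#'
#' @param alpha_regime expected anomalous exponent.
#' @param sigma noise standard deviation relative to the unit step.
#' @param L trajectory length, >= 10.
#' @return the recommended maximal lag `tau_M` (integer).
#' @examples
#' lookup_tau(0.7, 0.5, 1000)  # 40
#' @export
lookup_tau <- function(alpha_regime, sigma, L) {
  L <- as.integer(L)
  if (is.na(L) || L < 10L) stop("L must be >= 10", call. = FALSE)
  a <- snap_to_grid(alpha_regime, c(0.3, 0.7, 1.3, 1.7), "alpha_regime")
  s <- snap_to_grid(sigma, c(0.1, 0.5, 1), "sigma")
  tab <- tau_table()
  row <- tab[tab$alpha == a & tab$sigma == s, ]
  t100 <- row$tau_M[row$L == 100L]
  t1000 <- row$tau_M[row$L == 1000L]
  tau <- if (L <= 100L) {
    t100
  } else if (L >= 1000L) {
    t1000
  } else {
    w <- (log(L) - log(100)) / (log(1000) - log(100))
    round(t100 + w * (t1000 - t100))
  }
  max(2L, min(as.integer(tau), L %/% 2L))
}

# Stride for which the effective relative noise after sub-sampling is
# about `target`; from sigma / stride^(alpha/2) = target.
propose_stride <- function(sigma, alpha, target = 0.5) {
  if (sigma <= target) return(1L)
  max(1L, as.integer(round((sigma / target)^(2 / alpha))))
}

new_recommendation <- function(case_label, tau_M, apply_correction = FALSE,
                               correction_offset = 0, subsample_stride = 1L,
                               tau_sub = NA_integer_, expected_phi = NA_real_,
                               expected_bias = NA_real_, refuse = FALSE,
                               rationale = character()) {
  structure(
    list(case_label = case_label, tau_M = tau_M,
         apply_correction = apply_correction,
         correction_offset = correction_offset,
         subsample_stride = as.integer(subsample_stride),
         tau_sub = as.integer(tau_sub),
         expected_phi = expected_phi, expected_bias = expected_bias,
         refuse = isTRUE(refuse), rationale = rationale),
    class = "fit_recommendation")
}

#' @export
print.fit_recommendation <- function(x, ...) {
  if (x$refuse) {
    cat(sprintf("<fit_recommendation> REFUSE (case %s)\n", x$case_label))
  } else {
    cat(sprintf("<fit_recommendation> case %s: tau_M = %d%s%s\n",
                x$case_label, x$tau_M,
                if (x$apply_correction)
                  sprintf(", subtract offset %g from the TAMSD",
                          x$correction_offset) else "",
                if (x$subsample_stride > 1L)
                  sprintf("; or sub-sample stride %d and fit to tau_M = %d",
                          x$subsample_stride, x$tau_sub) else ""))
  }
  for (r in x$rationale) cat("  - ", r, "\n", sep = "")
  invisible(x)
}

#' Recommend a TAMSD fitting protocol
#'
#' Encodes the decision rules for choosing the maximal fitting lag given
#' what is known about the localization noise:
#'
#' * **known sigma** (`sigma_quality = "exact"`): subtract the noise offset
#'   `2 sigma^2` from the TAMSD and fit with `tau_M = 10`; a somewhat
#'   larger lag (20) when the motion is expected to be strongly
#'   subdiffusive (`alpha_regime <= 0.3`). Under large noise
#'   (`sigma >= 0.75`) on long trajectories a sub-sampling stride bringing
#'   the effective relative noise to about 0.5 is additionally proposed.
#' * **approximate sigma** (`"approximate"`): correct with the nominal
#'   `sigma`, then pick `tau_M` from the reference table at the residual
#'   noise regime (residual below 0.25 is treated as low noise, 0.25-0.75
#'   as medium, above as large). The residual defaults to half the nominal
#'   `sigma` unless `sigma_residual` is given.
#' * **unknown sigma** (`"unknown"`): estimation is refused for short
#'   trajectories (`L <= 300`) unless the motion is expected to be strongly
#'   subdiffusive, and refused for `L < 1000` in general unless
#'   `sigma_bound` supplies an upper bound on the noise; for `L >= 1000`
#'   a recommendation is issued with a strong warning, assuming the
#'   worst simulated noise level.
#'
#' The recommended lag never exceeds `floor(L / 2)`.
#'
#' @param L trajectory length, >= 10.
#' @param sigma_known the (exact or approximate) noise standard deviation;
#'   required unless `sigma_quality = "unknown"`.
#' @param sigma_quality one of `"exact"`, `"approximate"`, `"unknown"`.
#' @param alpha_regime optional expected exponent regime.
#' @param sigma_residual for approximate sigma: expected residual noise sd
#'   after correction (default `sigma_known / 2`).
#' @param sigma_bound for unknown sigma: an upper bound on the noise sd, if
#'   one exists; enables a warning-level recommendation for
#'   `300 < L < 1000`.
#' @param map optional `precision_map` matching the condition; when given,
#'   `expected_phi` / `expected_bias` are read from it.
#' @return a `fit_recommendation`; `refuse = TRUE` with `tau_M = NA` when
#'   estimation is not advised.
#' @export
recommend_fit <- function(L, sigma_known = NULL,
                          sigma_quality = c("exact", "approximate",
                                            "unknown"),
                          alpha_regime = NULL, sigma_residual = NULL,
                          sigma_bound = NULL, map = NULL) {
  L <- as.integer(L)
  if (is.na(L) || L < 10L) stop("L must be >= 10", call. = FALSE)
  sigma_quality <- match.arg(sigma_quality)
  if (sigma_quality != "unknown" && is.null(sigma_known))
    stop(sprintf("sigma_quality = \"%s\" requires sigma_known",
                 sigma_quality), call. = FALSE)
  clamp <- function(tau) max(2L, min(as.integer(tau), L %/% 2L))
  strong_sub <- !is.null(alpha_regime) && alpha_regime <= 0.3
  a_lookup <- if (is.null(alpha_regime)) 0.7 else alpha_regime

  rec <- switch(
    sigma_quality,
    exact = {
      tau <- clamp(if (strong_sub) 20L else 10L)
      notes <- c(paste0("exact noise level: subtract 2*sigma^2 = ",
                        format(2 * sigma_known^2),
                        " from the TAMSD, then fit the first lags"),
                 if (strong_sub)
                   "strongly subdiffusive regime: slightly larger tau_M")
      r <- new_recommendation("known_sigma", tau, apply_correction = TRUE,
                              correction_offset = 2 * sigma_known^2,
                              rationale = notes)
      if (sigma_known >= 0.75 && !is.null(alpha_regime)) {
        stride <- propose_stride(sigma_known, alpha_regime)
        L_eff <- L %/% stride
        if (stride > 1L && L_eff >= 20L) {
          r$subsample_stride <- stride
          # medium residual noise on a short effective trajectory: fit
          # ~12% of its length (inside the 10-20% short-trajectory band)
          r$tau_sub <- max(2L, min(as.integer(round(0.12 * L_eff)),
                                   L_eff %/% 2L))
          r$rationale <- c(r$rationale, sprintf(
            paste0("large relative noise: alternatively sub-sample every ",
                   "%d points (effective L = %d, effective sigma = %.2f) ",
                   "and fit to tau_M = %d"),
            stride, L_eff,
            effective_relative_sigma(sigma_known, alpha_regime, stride),
            r$tau_sub))
        }
      }
      r
    },
    approximate = {
      resid <- if (is.null(sigma_residual)) sigma_known / 2
               else sigma_residual
      regime <- if (resid < 0.25) 0.1 else if (resid < 0.75) 0.5 else 1
      tau <- clamp(suppressWarnings(lookup_tau(a_lookup, regime, L)))
      r <- new_recommendation(
        "approximate_sigma", tau, apply_correction = TRUE,
        correction_offset = 2 * sigma_known^2,
        rationale = c(
          sprintf(paste0("approximate noise level: correct with the nominal ",
                         "sigma, residual ~%.2g treated as the sigma = %g ",
                         "regime"), resid, regime),
          if (is.null(alpha_regime))
            "no exponent prior: weak-subdiffusion table column assumed"))
      if (regime >= 1 && !is.null(alpha_regime)) {
        stride <- propose_stride(resid, alpha_regime)
        L_eff <- L %/% stride
        if (stride > 1L && L_eff >= 20L) {
          r$subsample_stride <- stride
          r$tau_sub <- max(2L, min(as.integer(round(0.12 * L_eff)),
                                   L_eff %/% 2L))
          r$rationale <- c(r$rationale, sprintf(
            "large residual noise: consider sub-sampling every %d points",
            stride))
        }
      }
      r
    },
    unknown = {
      if (L >= 1000L) {
        tau <- clamp(suppressWarnings(lookup_tau(a_lookup, 1, L)))
        new_recommendation(
          "unknown_sigma", tau,
          rationale = c(
            paste0("noise level unknown: worst simulated regime (sigma = 1) ",
                   "assumed; expect low precision and a negative bias"),
            "report that the localization error was not characterized"))
      } else if (L <= 300L && strong_sub) {
        tau <- clamp(as.integer(round(0.2 * L)))
        new_recommendation(
          "unknown_sigma", tau,
          rationale = paste0("strong-subdiffusion exemption: tau_M at 20% ",
                             "of L tolerates an uncharacterized noise level"))
      } else if (L > 300L && !is.null(sigma_bound)) {
        regime <- if (sigma_bound < 0.25) 0.1
                  else if (sigma_bound < 0.75) 0.5 else 1
        tau <- clamp(suppressWarnings(lookup_tau(a_lookup, regime, L)))
        new_recommendation(
          "unknown_sigma", tau,
          rationale = sprintf(
            paste0("sigma unknown but bounded by %g: warning-level ",
                   "recommendation for an intermediate-length trajectory"),
            sigma_bound))
      } else {
        new_recommendation(
          "unknown_sigma", NA_integer_, refuse = TRUE,
          rationale = paste0(
            "noise level unknown and L ", if (L <= 300L) "<= 300" else "< 1000",
            ": the possibility sigma >= 1 makes the exponent unassessable; ",
            "characterize the measurement error first"))
      }
    })

  if (!rec$refuse && !is.null(map) && inherits(map, "precision_map")) {
    cell <- map$grid[map$grid$L == L & map$grid$tau_M == rec$tau_M, ]
    if (nrow(cell) == 1L) {
      rec$expected_phi <- cell$phi
      rec$expected_bias <- cell$bias
    }
  }
  rec
}

#' Bias-correct an ensemble-averaged exponent estimate
#'
#' When many realizations of the same process are available, the mean
#' fitted exponent converges to `alpha + B(L, tau_M)` rather than `alpha`;
#' subtracting the mapped bias recovers the true exponent.
#'
#' @param mean_alpha_hat mean of single-trajectory fitted exponents.
#' @param map a `precision_map` for the matching `(alpha, sigma)` regime.
#' @param L trajectory length of the realizations.
#' @param tau_M maximal lag used in the fits.
#' @return the bias-corrected ensemble exponent.
#' @export
debias_mean_alpha <- function(mean_alpha_hat, map, L, tau_M) {
  stopifnot(inherits(map, "precision_map"))
  cell <- map$grid[map$grid$L == L & map$grid$tau_M == tau_M, ]
  if (nrow(cell) != 1L || is.na(cell$bias))
    stop(sprintf("cell (L = %d, tau_M = %d) is not in the map", L, tau_M),
         call. = FALSE)
  mean_alpha_hat - cell$bias
}
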