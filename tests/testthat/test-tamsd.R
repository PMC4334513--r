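test_that("the TAMSD matches hand enumeration and closed forms", {
  # hand enumeration of the overlapping-window definition
  cv <- compute_tamsd(new_trajectory(c(0, 1, -1, 2)), max_lag = 2)
  expect_equal(cv$values, c(14 / 3, 1))
  expect_equal(cv$corrected_offset, 0)

  # constant trajectory: no displacement at any lag
  expect_equal(compute_tamsd(new_trajectory(rep(2.5, 20)), 10)$values,
               rep(0, 10))

  # ballistic trajectory x(t) = t: TAMSD(n) = n^2 exactly
  expect_equal(compute_tamsd(new_trajectory(0:49), 25)$values,
               (1:25)^2, tolerance = 1e-12)

  expect_error(compute_tamsd(new_trajectory(0:9), 10), "max_lag")
})

test_that("FFT-accelerated TAMSD equals the direct double sum", {
  set.seed(101)
  for (i in 1:100) {
    L <- sample(8:256, 1)
    x <- cumsum(stats::rnorm(L)) + stats::rnorm(L, sd = 0.3)
    max_lag <- sample(2:(L - 1), 1)
    fast <- compute_tamsd(new_trajectory(x), max_lag)$values
    slow <- tamsdfit:::tamsd_naive(x, max_lag)
    expect_lt(max(abs(fast - slow) / pmax(slow, .Machine$double.eps)), 1e-10)
  }
})

test_that("ensemble TAMSD follows tau^alpha + 2 sigma^2", {
  n_traj <- 1000
  alpha <- 0.7; sigma <- 0.5; L <- 128
  vals <- matrix(NA_real_, n_traj, 10)
  corr <- matrix(NA_real_, n_traj, 10)
  for (i in seq_len(n_traj)) {
    tr <- add_noise(simulate_fbm(alpha, L, seed = 2 * i), sigma,
                    seed = 2 * i + 1)
    cv <- compute_tamsd(tr, 10)
    vals[i, ] <- cv$values
    corr[i, ] <- correct_noise(cv, sigma)$values
  }
  theory <- (1:10)^alpha + 2 * sigma^2
  se <- apply(vals, 2, stats::sd) / sqrt(n_traj)
  expect_true(all(abs(colMeans(vals) - theory) < 3 * se))
  # corrected curve recovers the pure power law
  expect_true(all(abs(colMeans(corr) - (1:10)^alpha) < 3 * se))
})

test_that("noise correction subtracts a constant offset once", {
  cv <- new_tamsd_curve(1:2, c(3.0, 3.5), 100)
  fixed <- correct_noise(cv, 1)
  expect_equal(fixed$values, c(1.0, 1.5))
  expect_equal(fixed$corrected_offset, 2)
  expect_error(correct_noise(fixed, 1), "already")

  # zero sigma is the identity
  expect_equal(correct_noise(cv, 0)$values, cv$values)

  # the single-sigma^2 convention
  expect_equal(correct_noise(cv, 1, convention = "single")$values,
               c(2.0, 2.5))
})

test_that("power-law fitting inverts exact curves to machine precision", {
  for (alpha in c(0.05, 0.3, 0.7, 1.0, 1.3, 1.7, 1.95)) {
    for (D in c(0.2, 1, 5)) {
      fit <- fit_powerlaw(powerlaw_curve(alpha, D), tau_max = 50)
      expect_equal(fit$alpha_hat, alpha, tolerance = 1e-12)
      expect_equal(fit$log_D_hat, log(D), tolerance = 1e-12)
      expect_identical(fit$n_lags_used, 50L)
    }
  }
})

test_that("the log-log fit agrees with an independent regression", {
  cv <- new_tamsd_curve(1:3, c(1.0, 3.0, 5.0), 100)
  fit <- fit_powerlaw(cv, 3)
  oracle <- stats::lm(log(c(1.0, 3.0, 5.0)) ~ log(1:3))
  expect_equal(fit$alpha_hat, unname(stats::coef(oracle)[2]),
               tolerance = 1e-12)
  expect_equal(fit$log_D_hat, unname(stats::coef(oracle)[1]),
               tolerance = 1e-12)
})

test_that("non-positive corrected values are excluded, and too few is an error", {
  cv <- new_tamsd_curve(1:4, c(-0.5, 0.8, 2.0, 3.1), 100,
                        corrected_offset = 2)
  fit <- fit_powerlaw(cv, 4)
  expect_identical(fit$n_lags_used, 3L)
  oracle <- stats::lm(log(c(0.8, 2.0, 3.1)) ~ log(2:4))
  expect_equal(fit$alpha_hat, unname(stats::coef(oracle)[2]), tolerance = 1e-12)

  bad <- new_tamsd_curve(1:3, c(-1, -2, 3), 100, corrected_offset = 2)
  expect_error(fit_powerlaw(bad, 3), ">= 2 positive")
  expect_error(fit_powerlaw(powerlaw_curve(0.7, max_lag = 5), 10),
               "cover")
  expect_error(fit_powerlaw(powerlaw_curve(0.7), 1), "tau_max")
})

test_that("the all-tau fast path matches per-tau fits", {
  set.seed(55)
  x <- cumsum(stats::rnorm(300))
  vals <- compute_tamsd(new_trajectory(x), 150)$values
  fast <- tamsdfit:::fit_powerlaw_all(vals, 2:150)
  cv <- new_tamsd_curve(1:150, vals, 300)
  slow <- vapply(2:150, function(tm) fit_powerlaw(cv, tm)$alpha_hat,
                 numeric(1))
  expect_equal(fast, slow, tolerance = 1e-10)
})

test_that("noise correction with the true sigma improves accuracy", {
  alpha <- 0.7; sigma <- 1; L <- 1000; tau_M <- 10
  n <- 500
  err_raw <- err_fix <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tr <- add_noise(simulate_fbm(alpha, L, seed = 7000 + 2 * i), sigma,
                    seed = 7000 + 2 * i + 1)
    cv <- compute_tamsd(tr, tau_M)
    err_raw[i] <- abs(fit_powerlaw(cv, tau_M)$alpha_hat - alpha)
    err_fix[i] <- tryCatch(
      abs(fit_powerlaw(correct_noise(cv, sigma), tau_M)$alpha_hat - alpha),
      error = function(e) NA_real_)
  }
  both <- !is.na(err_fix)
  expect_gt(mean(both), 0.9)  # corrected fits rarely fail here
  expect_lt(mean(err_fix[both]), mean(err_raw[both]))
})
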