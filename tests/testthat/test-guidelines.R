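test_that("the reference lag table has the expected cells", {
  tab <- tau_table()
  expect_equal(nrow(tab), 24L)
  expect_equal(lookup_tau(0.7, 0.5, 1000), 40L)
  expect_equal(lookup_tau(1.7, 1, 100), 50L)
  expect_equal(lookup_tau(0.3, 0.5, 100), 10L)
  expect_equal(lookup_tau(0.3, 0.5, 1000), 10L)
  expect_equal(lookup_tau(0.3, 1, 1000), 200L)
  expect_equal(lookup_tau(0.7, 1, 1000), 400L)
})

test_that("lookups interpolate in log L, snap off-grid inputs, and clamp", {
  # interpolation stays between the anchors and hits them exactly
  t100 <- lookup_tau(0.7, 0.5, 100)
  t1000 <- lookup_tau(0.7, 0.5, 1000)
  mids <- vapply(c(150, 300, 500, 800), function(L) lookup_tau(0.7, 0.5, L),
                 integer(1))
  expect_true(all(mids >= t100 & mids <= t1000))
  expect_true(all(diff(c(t100, mids, t1000)) >= 0))
  # geometric midpoint of (10, 40) rounds to 25
  expect_equal(lookup_tau(0.7, 0.5, as.integer(round(sqrt(100 * 1000)))), 25L)

  # flat extrapolation beyond the anchors
  expect_equal(lookup_tau(0.7, 0.5, 2000), t1000)
  expect_equal(lookup_tau(0.7, 0.5, 50), min(t100, 25L))

  # off-grid regimes snap with a warning
  expect_warning(v <- lookup_tau(0.65, 0.5, 1000), "snapping")
  expect_equal(v, 40L)
  expect_warning(lookup_tau(0.7, 0.4, 1000), "snapping")

  # the lag cap tau_M <= L/2 always wins
  expect_lte(lookup_tau(0.3, 1, 500), 250L)
  expect_lte(lookup_tau(1.7, 1, 100), 50L)
})

test_that("exact-sigma advice corrects the offset and fits the first lags", {
  rec <- recommend_fit(1000, sigma_known = 0.5, sigma_quality = "exact")
  expect_false(rec$refuse)
  expect_equal(rec$case_label, "known_sigma")
  expect_true(rec$apply_correction)
  expect_equal(rec$correction_offset, 2 * 0.25)
  expect_equal(rec$tau_M, 10L)

  strong <- recommend_fit(1000, sigma_known = 0.5, sigma_quality = "exact",
                          alpha_regime = 0.3)
  expect_equal(strong$tau_M, 20L)
})

test_that("large known noise on a long trajectory proposes sub-sampling", {
  rec <- recommend_fit(2000, sigma_known = 1, sigma_quality = "exact",
                       alpha_regime = 0.7)
  expect_equal(rec$subsample_stride, 7L)
  expect_equal(rec$tau_sub, 34L)
  expect_equal(effective_relative_sigma(1, 0.7, rec$subsample_stride), 0.5,
               tolerance = 0.02)
})

test_that("approximate-sigma advice reads the residual-noise regime", {
  rec <- recommend_fit(1000, sigma_known = 0.5,
                       sigma_quality = "approximate", alpha_regime = 0.7)
  expect_false(rec$refuse)
  expect_equal(rec$case_label, "approximate_sigma")
  expect_equal(rec$tau_M, 40L)  # residual 0.25 -> medium-noise column
  expect_true(rec$apply_correction)

  low <- recommend_fit(1000, sigma_known = 0.2, sigma_quality = "approximate",
                       alpha_regime = 0.7, sigma_residual = 0.1)
  expect_equal(low$tau_M, 10L)
})

test_that("unknown sigma refuses short trajectories except strong subdiffusion", {
  expect_true(recommend_fit(200, sigma_quality = "unknown")$refuse)
  expect_true(recommend_fit(200, sigma_quality = "unknown",
                            alpha_regime = 0.7)$refuse)
  expect_true(recommend_fit(500, sigma_quality = "unknown")$refuse)

  exempt <- recommend_fit(200, sigma_quality = "unknown", alpha_regime = 0.3)
  expect_false(exempt$refuse)
  expect_equal(exempt$tau_M, 40L)  # 20% of L

  bounded <- recommend_fit(500, sigma_quality = "unknown",
                           alpha_regime = 0.7, sigma_bound = 0.4)
  expect_false(bounded$refuse)

  long <- recommend_fit(1000, sigma_quality = "unknown", alpha_regime = 0.7)
  expect_false(long$refuse)
  expect_equal(long$tau_M, 400L)  # worst simulated noise level assumed
})

test_that("contradictory or invalid recommender inputs error", {
  expect_error(recommend_fit(1000, sigma_quality = "exact"), "requires")
  expect_error(recommend_fit(5, sigma_quality = "unknown"), "L must be")
})

test_that("recommended lags never exceed half the trajectory length", {
  set.seed(44)
  for (i in 1:50) {
    L <- sample(10:2000, 1)
    rec <- recommend_fit(
      L,
      sigma_known = stats::runif(1, 0, 1.5),
      sigma_quality = sample(c("exact", "approximate"), 1),
      alpha_regime = stats::runif(1, 0.1, 1.9))
    expect_lte(rec$tau_M, L %/% 2)
    expect_gte(rec$tau_M, 2L)
    if (rec$subsample_stride > 1L)
      expect_lte(rec$tau_sub, (L %/% rec$subsample_stride) %/% 2L)
  }
})

test_that("ensemble bias correction is the map's own inverse", {
  g <- data.frame(L = 100L, tau_M = c(10L, 20L), phi = c(0.4, 0.5),
                  bias = c(-0.15, 0), n_effective = 100L)
  mp <- fake_map(g)
  expect_equal(debias_mean_alpha(0.55, mp, 100, 10), 0.70)
  expect_equal(debias_mean_alpha(0.55, mp, 100, 20), 0.55)
  expect_error(debias_mean_alpha(0.55, mp, 100, 15), "not in the map")

  # self-consistency on a simulated map: mean(alpha_hat) - bias == alpha
  sim <- sweep_precision(0.7, 0.5, 60, n_reps = 200, seed = 61)
  cell_bias <- sim$grid$bias[sim$grid$tau_M == 10]
  expect_equal(debias_mean_alpha(0.7 + cell_bias, sim, 60, 10), 0.7)
})
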