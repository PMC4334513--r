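# tamsdfit

Tools for the question every single-particle-tracking analysis has to
answer: **up to which lag should the time-averaged MSD be fitted?**

Single-particle trajectories are routinely summarized by the
time-averaged mean square displacement over all overlapping windows,

    TAMSD(τ) = (1/(L−n)) Σ_{m=1..L−n} (x(m+n) − x(m))²,   τ = n·δ,

and classified by the anomalous exponent α of the power law
`TAMSD(τ) = D_α τ^α`, fitted by least squares on log–log axes over lags
`τ = 1..τ_M`. The estimate is fragile: the TAMSD's variance grows with τ,
while i.i.d. localization noise of standard deviation σ adds a constant
offset `2σ²` that flattens the curve at small τ. The best maximal lag
`τ_M` balances the two and depends on trajectory length `L`, the relative
noise level σ and α itself.

`tamsdfit` quantifies this trade-off by Monte Carlo and turns the result
into a fitting protocol. It provides:

* an exact fractional-Brownian-motion simulator (circulant embedding,
  Hosking fallback) with per-trajectory unit-normalized increments
  (`D_α = 1`) and additive Gaussian localization noise — the benchmark
  model for ergodic anomalous diffusion (`simulate_fbm()`, `add_noise()`);
* FFT-accelerated TAMSD computation, log–log power-law fitting, and the
  known-σ offset correction (`compute_tamsd()`, `fit_powerlaw()`,
  `correct_noise()`);
* Monte-Carlo maps of the estimator's **precision** Φ (fraction of
  single-trajectory estimates within ±0.1 of the truth) and **bias** B
  (mean estimate minus truth) over `(L, τ_M)` grids, with optimal-lag
  extraction (`sweep_precision()`, `optimal_tau()`, `plot()`);
* the encoded fitting guidelines: a quick look-up table of recommended
  `τ_M` (`tau_table()`, `lookup_tau()`), a recommender covering known,
  approximate and unknown noise — including principled refusals when the
  exponent is unassessable — (`recommend_fit()`), sub-sampling for large
  relative noise (`subsample()`, `compare_subsampling()`), and ensemble
  bias correction (`debias_mean_alpha()`).

## Worked example

Simulate a weakly subdiffusive trajectory at medium noise, fit it, and
ask the recommender what it would have advised:

```r
library(tamsdfit)

tr <- simulate_fbm(alpha = 0.7, length = 1000, seed = 2)
tr <- add_noise(tr, sigma = 0.5, seed = 3)
tr
#> <spt_trajectory> L = 1000 points, true alpha = 0.7, noise sigma = 0.5

curve <- compute_tamsd(tr, max_lag = 50)
fit_powerlaw(curve, tau_max = 50)
#> <tamsd_fit> alpha_hat = 0.7296, log D = 0.1264 (tau_M = 50, 50 lags)

# with the noise level known exactly, subtract the 2*sigma^2 offset and
# fit only the first lags:
fit_powerlaw(correct_noise(curve, sigma = 0.5), tau_max = 10)
#> <tamsd_fit> alpha_hat = 0.7508, log D = -0.0767 (tau_M = 10, 10 lags)

recommend_fit(L = 1000, sigma_known = 0.5, sigma_quality = "approximate",
              alpha_regime = 0.7)
#> <fit_recommendation> case approximate_sigma: tau_M = 40, subtract offset 0.5 from the TAMSD
#>   - approximate noise level: correct with the nominal sigma, residual
#>     ~0.25 treated as the sigma = 0.5 regime
```

Both fits land within ±0.1 of the true α = 0.7 — this trajectory is one
of the ~63% that do at this condition. That fraction is exactly what the
sweep machinery measures:

```r
mp <- sweep_precision(alpha = 0.7, sigma = 0.5, L_grid = 1000,
                      n_reps = 300, seed = 4)
optimal_tau(mp, 1000)
#> $tau_M
#> [1] 63
#>
#> $phi
#> [1] 0.6333333
#>
#> $bias
#> [1] -0.07603321
```

So at `L = 1000`, `σ = 0.5`, the best maximal lag sits in the few-dozen
range and even the optimal protocol leaves a third of single-trajectory
estimates outside ±0.1 — the central caveat when comparing exponents
across experiments. The Φ ridge is flat near its optimum, so the argmax
(here 63) wobbles between seeds while its precision does not; `plot(mp)`
renders the full map with bias contours when `L_grid` has several
lengths.

The same operations are scriptable from a shell via `exec/tamsdfit`
(subcommands `simulate`, `tamsd`, `fit`, `sweep`, `optimal`, `recommend`,
`subsample-compare`, `benchmark-table`, `heatmap`; refusals from
`recommend` exit with status 3).

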