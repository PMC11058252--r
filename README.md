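# colimfit

Growth of phytoplankton is rarely limited by a single resource. In
gradient microhabitat arrays — 8×8 grids of nanoliter culture chambers
where rows carry a diffusive nitrogen gradient and columns an optical
light gradient — a single device exposes algal cells to 64 combinations
of nitrogen concentration and light intensity at once. `colimfit` is an R
package for analysing such experiments (and for simulating them, so the
analysis can be validated end to end): it turns per-habitat fluorescence
time series into maximum specific growth rates, fits Monod-type
colimitation models to the resulting growth-rate matrix by
weighted-bootstrap nonlinear least squares, compares rival model forms,
and predicts growth over arbitrary resource combinations.

## The model

The core model is multiplicative Monod colimitation,

```
mu(L, N) = mu_max * (L + L0)/(K_L + L + L0) * (N + N0)/(K_N + N + N0)
```

with `mu_max` the rate ceiling (day⁻¹), `K_L`, `K_N` half-saturation
constants (µmol·m⁻²·s⁻¹ PAR and µM), and storage offsets `L0` (acetate-
derived, light-independent energy) and `N0` (internal nitrogen
reserves). A generalized product form extends this to any number of
independent, non-substitutable factors, and a law-of-minimum (Liebig)
form `mu_max * min(f_L, f_N)` over the same saturating factors serves as
the natural rival. Default fitting protocol: `mu_max` fixed at 2.4 day⁻¹,
`N0` fixed at 0 µM (nitrogen-starved inocula), `L0`, `K_L`, `K_N` free —
with `L0` fixed at 0 for acetate-free media.

Growth rates are extracted from `ln(N/N0)` curves (background-subtracted
fluorescence as a cell-number proxy) by 9-point sliding-window linear
fits, taking the maximum slope among windows centered after day 1.3.
Uncertainty comes from a replicate-resampling bootstrap: each of B = 1000
runs picks, per condition, one replicate's rate with probability
proportional to 1/SE², refits, and the estimates are the bootstrap means.

## Worked example

Simulate the default experiment (3 replicates, 7 days at 4-h imaging,
multiplicative truth `L0 = 50.8`, `K_L = 57.2`, `K_N = 2.8`), extract
rates, and fit:

```r
library(colimfit)

env  <- environment_grid(row_nitrogen_profile(), col_light_profile())
cfg  <- simulation_config(env = env, seed = 1)
ts   <- simulate_array(cfg)
rates <- extract_growth_rates(ts, env)
boot  <- bootstrap_fit(rates$matrix, model_spec(), B = 200, seed = 2)
boot
#> colim_boot [multiplicative_storage], B = 200, seed = 2
#>   L0     = 52.52 (sd 1.18)
#>   K_L    = 52.18 (sd 1.05)
#>   K_N    = 2.568 (sd 0.0463)
#>   mean SSE = 0.02524, mean R2 = 0.9818
```

The bootstrap means recover the generating parameters (the residual bias
reflects the fluorescence noise and random seeding of the simulated
arrays); `param_significance(boot, "L0")` reports p = 0 under both the
Wald and tail-fraction readings, i.e. the dark-growth storage term is
clearly nonzero when acetate is present. Prediction maps evaluate the
fitted surface anywhere:

```r
p <- monod_params(mu_max = 2.4, L0 = boot$means[["L0"]],
                  K_L = boot$means[["K_L"]], N0 = 0,
                  K_N = boot$means[["K_N"]])
round(predict_map(p, L_grid = c(10, 45, 100), N_grid = c(5, 17, 93)), 2)
#>      10   45  100
#> 5  0.86 1.03 1.18
#> 17 1.14 1.36 1.55
#> 93 1.27 1.52 1.74
```

Rows are nitrogen (µM), columns light (PAR), entries predicted growth
rates in day⁻¹: a bright, moderately nitrogen-poor site (100 PAR, 17 µM
→ 1.55 day⁻¹) out-grows a dim nitrogen-rich one (10 PAR, 93 µM → 1.27
day⁻¹).

The `analysis/` directory holds the same workflow as numbered driver
scripts (`01_simulate.R` … `05_predict.R`), each writing its tables under
`results/`; see `vignettes/colimitation-methods.Rmd` for the methodological
choices and their rationale.

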