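# selfthin

Self-thinning boundary lines for mixed forest stands.

As a crowded stand grows, competition kills the weakest stems, and on log
scales the cloud of (mean tree size, stems per hectare) observations has a
stable upper boundary — the maximum size-density relationship that density
management diagrams and stocking guides are built on. `selfthin` estimates
that boundary from plot-level inventory tables for mixed (multi-species,
multi-layered) stands, where the classical diameter-only rule is too rigid.

Two boundary models:

* **Reineke's model (RM)**: `ln N = k + α ln Dg`
* **variable density model (VDM)**: `ln N = k + α ln Dg + β ln Hd`

with `Dg` the quadratic mean diameter (cm) and `Hd` the dominant height (m).
In mixed stands a taller dominant canopy supports more canopy layers, so
`β > 0` raises the carrying capacity while `α` keeps its meaning as the
self-thinning rate.

Two boundary estimators, both implemented in the package:

* **upper-quantile regression** — exact minimization of the asymmetric check
  loss at τ = 0.90-0.99 (majorize-minimize iteration plus vertex polish,
  verified against brute-force and linear-programming oracles), with
  percentile-bootstrap confidence intervals;
* **stochastic frontier maximum likelihood** — `ln N = x'b + v − u` with
  symmetric noise `v` and one-sided inefficiency `u` from half-normal,
  exponential, or truncated-normal laws (closed-form densities), compared
  across nested models by AIC and likelihood-ratio test, with
  profile-likelihood-calibrated standard errors and Jondrow-type
  `E[u | ε]` predictions.

Around the estimators: stand density index projection to a reference size
(16 cm / 12 m), relative density, mortality-vs-crowding regression,
traditional boundary-point selection (equal-width interval, mortality
threshold, relative density, upper convex hull), Shannon/Simpson/CV/Hd-D
structure covariates with an SDI covariate model, a calibrated synthetic
mixed-oak stand generator, and an end-to-end pipeline.

## Worked example

Simulate a 265-plot mixed-oak inventory surveyed twice, split it 70/30, fit
both boundary models by quantile regression and all three frontier laws,
and report the diagnostics:

```r
library(selfthin)

cfg <- synthetic_config(n_plots = 265, seed = 3)   # defaults documented in the vignette
run <- run_full_analysis(cfg, seed = 3)
run
```

```
Self-thinning analysis run (seed 3): 265 plots -> 185 modeling / 80 validation

Stochastic frontier comparison:
   model intercept slope_d slope_hd sigma_v2 sigma_u2   aic lrt_p
1  NH-RM     8.987 -0.7332       NA   0.3827   0.1790 384.3 1e-04
2 NH-VDM     8.648 -1.1101   0.5741   0.2988   0.3083 369.8    NA
3  NE-RM     8.815 -0.7370       NA   0.4231   0.0247 384.3 1e-04
4 NE-VDM     8.493 -1.1239   0.5777   0.3421   0.0694 370.0    NA
5  NT-RM     9.037 -0.7322       NA   0.3734   0.1586 386.3 1e-04
6 NT-VDM     8.605 -1.1136   0.5762   0.3075   0.3927 371.8    NA

Best frontier by AIC: NH-VDM
Mortality ~ relative density: slope 0.361 (p = 2.62e-105, R2 0.836)
Holdout SDI t-test: t = -0.083, p = 0.934
Covariate model relative error: 67.6%
```

Reading the output: for every error law the variable density model beats
Reineke's diameter-only model (ΔAIC ≈ −15, LRT p ≈ 1e-4), the diameter
slope is near −1.1 and the height slope near +0.58 against generating
values of −0.996 and 0.621, and the best boundary translates to a maximum
stocking at the 16 cm / 12 m reference size of about 1100 stems/ha
(`exp(frontier_log_density(run$best_spec, 16, 12))`). The mortality
regression confirms the fitted boundary orders stands by crowding
(strongly positive slope), and the holdout t-test shows the projected
density index transfers to the 80 validation plots (p = 0.93). Estimates
move noticeably between seeds — at 185 modeling plots the diameter slope
carries a standard error of roughly 0.2, which is what the reported
confidence measures say.

Individual pieces are plain functions on data frames:

```r
plots <- read_plot_table("plots_2004.csv")
X <- design_matrix(plots, "VDM")
fit_quantile(X, log_density(plots), tau = 0.95)
fit_sfa(X, log_density(plots), dist = "NT", seed = 1)
```

A thin command-line front end ships in `inst/scripts/selfthin`
(subcommands `simulate`, `fit-qr`, `fit-sfa`, `select`, `covariates`,
`run-all`, `validate`).

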