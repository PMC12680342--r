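# mcident

Identification of dynamic models of microbial communities: a three-phase
workflow for fitting nonlinear ODE community models to time-series
abundance data without falling into the four classic traps —
non-identifiability (structural or practical), finite-time blow-up during
estimation, underfitting (local optima), and overfitting (fitting noise).

The core model family is the generalized Lotka-Volterra (gLV) system

```
dx_i/dt = x_i ( mu_i + sum_j beta_ij x_j ),   i = 1..N
```

with growth rates `mu_i` and a dense pairwise interaction matrix
`beta` (`n_theta = N + N^2` parameters: 6, 12 and 156 for the built-in
2-, 3- and 12-species benchmarks). Arbitrary ODE models plug in through
the same interface. Calibration minimizes the weighted least-squares
objective

```
J(theta) = sum_e sum_o sum_s [ (ym - y(theta, t_s)) / sigma ]^2
```

subject to the dynamics and box bounds, with every objective evaluation
protected by an event-based blow-up guard that converts solver explosions
into finite, ordered penalty values.

**Phase 1** — `local_sia_rank()`: a numeric local structural-identifiability
screen (sensitivity-rank test with null-space reporting) per observation
scheme (fully observed, species subsets, total biomass).
**Phase 2** — `multistart_local()` and `ess_optimize()` (an enhanced
scatter-search metaheuristic with periodic Levenberg-Marquardt
refinement); OF/GF/LO fit classification against the nominal objective;
`compute_fim()` / `cramer_rao_intervals()` for practical identifiability
(eigen-spectrum, confidence intervals, parameter correlations);
`find_equilibria()` / `stability_screen()` for equilibrium classification
and long-horizon stability.
**Phase 3** — `residual_diagnostics()` (including a Q-Q overfitting
indicator), `cross_validate()` on held-out experiments (RMSE/NRMSE), and
`plausibility_check()` for mechanistic rules.

Everything is tidyverse-shaped: datasets and reports are tibbles, fitted
objects have `tidy()`/`glance()` methods, result types have `autoplot()`
methods, and `run_workflow()` drives all three phases from one seeded
configuration. A thin CLI lives at `inst/scripts/mcid.R`.

## Worked example

```r
library(mcident)

res <- run_workflow(list(
  fixture   = "glv2_coexistence", seed = 10,
  synthesis = list(noise_level = 0.05),
  optimizer = list(method = "ess", max_evals = 1200)
), out_dir = "glv2_run")

res$verdict
#> SIA (full observation): locally_identifiable;
#> fit: status=converged, J=32.67, class=GF;
#> PIA: 0 practically non-identifiable parameter(s);
#> stability: plausible;
#> cross-validation mean NRMSE: 0.2015
```

Reading the verdict: the fully observed two-species scheme passes the
local rank screen (all 6 parameters locally distinguishable); scatter
search converged to a good fit — the objective `J = 32.67` over 48
records is statistically consistent with the nominal parameters' own
objective, i.e. the fit explains the signal without absorbing the noise;
no Cramer-Rao interval or correlation crosses the practical-identifiability
reporting thresholds; the fitted dynamics remain bounded well beyond the
data window; and a model refit on one experiment predicts the held-out
experiment (different initial abundances) with a range-normalized error
of about 20% — the effect of 5% measurement noise on a 6-parameter fit
from a single experiment. `glv2_run/` holds the per-phase JSON reports,
the correlation-matrix CSV and a consolidated `report.md`.

The same machinery at benchmark scale, on the 3-species community with
10% noise:

```r
fx <- glv3_fixture()
ds <- generate_dataset(fx$model, fx$theta_nominal, fx$designs[1],
                       noise_model("proportional", 0.1), seed = 1)
pr <- estimation_problem(fx$model, fx$designs[1], ds)
glance(multistart_local(pr, n_starts = 200, seed = 1))
#> # A tibble: 1 × 9
#>   n_runs converged blowup solver_failure    OF    GF    LO delta J_nominal
#> 1    200     0.255  0.745              0     0 0.16  0.095  0.25      25.0
```

Three quarters of the local-optimizer runs abort in blow-up regions of
the bounded parameter box; `ess_optimize()` on the same problem returns a
usable calibration from every seed. `autoplot()` on the ensemble draws
the log10 objective-ratio histogram with the OF/GF/LO bands.

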