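# laminpop

Laminar population analysis of extracellular potentials: joint decomposition
of multi-unit activity (MUA) and local field potential / current source
density (LFP/CSD) from laminar probe recordings into per-population
contributions.

## Who this is for

Electrophysiologists and computational neuroscientists working with laminar
(linear multi-contact) recordings who want to know *which* populations —
cortical layers, feedforward thalamic input, cortical feedback, diffuse
background — generated the sinks and sources they see in a CSD plot. Instead
of statistical decompositions (PCA's orthogonality, ICA's independence), the
method uses physiological constraints: populations are contiguous bands of
depth, and the field each population generates follows its firing rate
through a causal synaptic kernel.

## The model

The MUA is decomposed into non-overlapping trapezoidal depth profiles and
firing-rate time courses,

```
phi_M(z_i, t_j) = sum_n M_n(z_i) r_n(t_j),
```

with `r = (M^T)^+ phi_M` the least-squares rates for candidate profiles and
the trapezoid parameters `{z_n, a_n, b_n}` fitted by seeded differential
evolution to minimize `e_M = sum(phi_M - phi_est)^2 / sum(phi_M)^2`. Each
population's rate (plus the rates of any external structures, simply appended
as extra rows) is convolved with a causal exponential kernel
`h(t) = (1/tau) exp(-(t - Delta)/tau) Theta(t - Delta)`, the spatial profile
of its field contribution is `L = phi R^+`, and the per-population
contribution is the rank-1 product of the matched column of `L` and row of
`R = h (*) r`. The kernel parameters `(tau_n, Delta_n)` are fitted the same
way, with an optional penalty `lambda * mean_t |sum_z C_est| / max |C_est|`
that discourages violations of charge balance in the CSD estimate. CSD comes
from the LFP via the delta inverse-CSD method (thin current discs of radius
R, forward matrix `F_ji = (sqrt(R^2 + dz^2) - |dz|) / (2 sigma)`) or the
traditional second-derivative estimator.

A forward-model synthetic generator (`synth_config()`, `make_recordings()`)
produces laminar recordings with known populations, kernels, field profiles
and controllable inter-population rate synchrony, and is the package's
validation testbed: every headline claim is scored against stored ground
truth by parameter recovery.

## Worked example

```r
library(laminpop)

truth <- make_recordings(synth_config(seed = 3))   # 26 ch x 750 ms, 5 layers
cfg <- analysis_config(n_populations = 5, rng_seed = 7,
                       optimizer = list(maxiter = 150))
mua_fit <- fit_mua(truth$mua, truth$geometry, cfg)
tidy(mua_fit)
#> # A tibble: 5 x 7
#>   population  z_um  a_um  b_um support_lo_um support_hi_um layer
#>   <chr>      <dbl> <dbl> <dbl>         <dbl>         <dbl> <chr>
#> 1 pop_1       32.9  61.1  16.7         -14.4          80.2 L1
#> 2 pop_2      200.  134.   52.9          80.2         320.  L2/3
#> 3 pop_3      420.  105.   43.9         324.          516.  L4
#> 4 pop_4      640.  138.   49.2         522.          758.  L5
#> 5 pop_5      900.  168.   57.4         758.         1042.  L6
```

Five trapezoids, one per layer: `z_um` is each population's centre depth and
the supports tile the probe without overlap. `e_M` (from `glance(mua_fit)`)
was `6.2e-15` on this noise-free fixture — the MUA is reconstructed
essentially exactly. Channel-layer classification against the geometry's true
boundaries is perfect:

```r
pred <- predict_channel_layers(mua_fit$populations, truth$geometry)
layer_scores(confusion_matrix(pred$predicted_layer,
                              channel_layers(truth$geometry)))
#> # A tibble: 5 x 4
#>   layer precision recall    f1
#>   <chr>     <dbl>  <dbl> <dbl>
#> 1 L1            1      1     1
#> 2 L2/3          1      1     1
#> 3 L4            1      1     1
#> 4 L5            1      1     1
#> 5 L6            1      1     1
```

The kernel fit then recovers the planted synaptic kernels and per-population
CSD contributions (here the five laminar populations plus three external
structures):

```r
cfg8 <- analysis_config(8, rng_seed = 7, optimizer = list(maxiter = 200))
csd_fit <- fit_csd(truth$csd, truth$rates, cfg8)
glance(csd_fit)
#> # A tibble: 1 x 7
#>        e_c   rel_mse penalty_term lambda correlation iterations converged
#>      <dbl>     <dbl>        <dbl>  <dbl>       <dbl>      <int> <lgl>
#> 1  1.17e-10  1.17e-10     3.69e-15      0        1.00        200 TRUE

match_contributions(csd_fit$contributions, truth$contributions)
# per-population correlation vs truth: >= 0.9999 for all 8 populations;
# fitted tau within 0.5% and Delta within 9.5% of the planted kernels
```

`autoplot()` methods draw the signal heatmaps, spatial profiles and
per-population contribution maps; `run_pipeline()` chains all four steps from
a raw ECP ensemble; `inst/cli/lpa` exposes `synth`, `csd`, `fit-mua`,
`fit-csd`, `baselines` and `report` subcommands for shell use.

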