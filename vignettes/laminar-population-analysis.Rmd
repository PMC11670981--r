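---
title: "Decomposing laminar extracellular potentials into population contributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing laminar extracellular potentials into population contributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(laminpop)
```

## The problem

A laminar probe inserted through cortex records the extracellular potential at
a column of contacts. Its high-frequency band (above ~300 Hz), the multi-unit
activity (MUA), mostly reflects spiking of neurons near each contact; the
low-frequency band, the local field potential (LFP), and the current source
density (CSD) derived from it reflect the synaptic currents that inputs to the
local populations evoke. Many presynaptic pathways superimpose in the same
LFP/CSD, which makes the raw signal hard to interpret. Statistical
decompositions (PCA, ICA) separate components by orthogonality or statistical
independence — assumptions the underlying physiology need not satisfy.

`laminpop` implements a physiologically constrained alternative. It decomposes
the MUA and the LFP/CSD jointly, in four steps:

1. **MUA decomposition.** The MUA is modelled as
   $\phi_M(z_i, t_j) = \sum_n M_n(z_i)\, r_n(t_j)$, where each laminar
   population $n$ has a trapezoidal depth profile $M_n$ (position $z$,
   plateau width $a$, ramp width $b$, height fixed at 1) and a firing-rate
   time course $r_n$. Profiles are constrained to be non-overlapping, so each
   population is a contiguous, localized band of depths. Given candidate
   profiles, the rates are the least-squares solution via the pseudoinverse;
   the trapezoid parameters are optimized globally (differential evolution) to
   minimize the relative mean square error
   $e_M = \sum (\phi_M - \phi_{M,est})^2 / \sum \phi_M^2$.
2. **Postsynaptic kernels.** Each population's rate is convolved with a causal
   exponential kernel $h_i(t) = \tau_i^{-1} e^{-(t - \Delta_i)/\tau_i}
   \Theta(t - \Delta_i)$ — delay $\Delta_i$, time constant $\tau_i$, one pair
   per presynaptic population — yielding the temporal profile of the field
   each population generates, $R = h \circledast r$.
3. **Field decomposition.** The spatial profile of each population's field
   contribution is the least-squares solution $L = \phi\, R^{+}$ against the
   recorded LFP or CSD.
4. **Contributions.** The per-population field contribution is the rank-1
   product of column $n$ of $L$ with row $n$ of $R$; the contributions sum to
   the total reconstruction (bit-exactly, by construction), which is compared
   to the recording.

Steps 2–4 are iterated by a seeded differential-evolution search over all
$(\tau_i, \Delta_i)$.

Two extensions matter in awake recordings. First, structures outside the
probed area (feedforward thalamic input, cortical feedback, diffuse
background) also generate local synaptic currents: their firing rates are
simply appended as extra rows of the rate matrix before step 2
(`append_external_rates()`), exempt from the MUA spatial model. Second, the
delta inverse-CSD estimator does not enforce charge balance across channels,
so the decomposition cost can include a penalty
$\lambda \cdot \frac{1}{B}\sum_j |\sum_i C_{est}(z_i, t_j)| / \max |C_{est}|$
on the channel-summed CSD (`csd_cost()`, `select_lambda()`).

## CSD estimation

Two estimators are provided. The **traditional** estimator is the negative
conductivity times the discrete second spatial derivative of the LFP; it
requires uniform spacing, drops the two boundary channels, and forces the
channel sum to zero by construction. The **delta inverse-CSD** models sources
as thin current discs of radius $R$ at each contact; the forward matrix
$F_{ji} = \frac{1}{2\sigma}\left(\sqrt{R^2 + (z_j - z_i)^2} - |z_j -
z_i|\right)$ maps planar disc densities to potentials and is inverted per time
bin. The two are exact mutual inverses with the generator's forward model,
which the tests exploit as a machine-precision identity. CSD values are
reported as planar source density (current per disc area); the decomposition
only uses them up to a consistent scaling. Conductivity defaults to
$\sigma = 0.3$ S/m, a conventional cortical value, and the disc radius to
400 µm; both are configurable per probe.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_populations` | — | laminar populations assumed a priori |
| `cutoff_hz`, `filter_order` | 300 Hz, 5 | Butterworth band split (zero-phase, forward–backward) |
| `smooth_ms` | 2 ms | Gaussian sd of the MUA envelope smoother |
| `tau_bounds_ms` | [1, 100] | kernel time-constant search range |
| `delta_bounds_ms` | [0, 50] | kernel delay search range |
| `lambda_penalty` | 0 | weight of the zero-sum CSD penalty |
| `optimizer$np`, `$maxiter` | 10×dim, 250 | differential-evolution population and budget |
| `rng_seed` | 1 | seed controlling the whole stochastic search |

The kernel bounds are deliberately wide: postsynaptic current time constants
of a few ms up to tens of ms and conduction/synaptic delays below ~50 ms cover
the physiological range; they are reported in every result object.

## Numerical choices

* **Pseudoinverses** use the SVD with a relative singular-value cutoff of
  1e-10. The spatial-field step warns when the condition number of the
  postsynaptic temporal profiles exceeds 1e6, naming the most correlated pair
  of populations, and `fit_csd()` warns upfront when the presynaptic rates
  themselves are near-collinear — no kernel can separate populations that
  fire in lockstep.
* **MUA envelope.** The band-split filter leaves a zero-mean high-band signal;
  the decomposition needs a non-negative, slowly varying amplitude. The
  envelope is the absolute value smoothed with a 2-ms-sd Gaussian
  (reflect padding, so trial edges do not produce roll-on artifacts). This
  rectify-and-smooth step is this package's documented choice; band power
  over the same window is a reasonable alternative, and the cost surface is
  insensitive to the distinction at the smoothing scales used. Fits run on
  the trial-averaged envelope.
* **Kernel discretization.** Convolution uses the bin-averaged exponential
  kernel (the integral of the kernel over each bin divided by the bin width)
  rather than point samples. The two agree as `dt -> 0`, but the integrated
  form has exactly unit mass and varies continuously with the delay, so the
  kernel-fit cost surface has no bin-edge discontinuities; the convolution
  itself is evaluated with an O(B) recursion that the exponential obeys and
  is verified against a naive O(B²) loop in the tests.
* **Non-overlap enforcement.** Rather than rejecting infeasible candidates,
  the trapezoid search runs in a reparameterized space — N+1 inter-support
  gaps, N plateau and N ramp widths, rescaled to tile the probe span exactly —
  in which *every* point is a feasible, depth-ordered, non-overlapping layout.
  The span is padded by one inter-channel spacing so edge channels can lie on
  a plateau. The plateau/ramp bounds of the configuration act as a feasibility
  check before the search (can `n` populations of minimal width fit at all?)
  rather than as hard per-parameter box constraints inside the rescaled space.
* **Optimization.** Both fits use differential evolution (seeded, population
  `np`, budget `maxiter`) followed by a staged local refinement
  (box-constrained quasi-Newton with shrinking finite-difference steps). The
  staged refinement matters: near the optimum the cost basin is narrow and
  anisotropic (the $\tau$–$\Delta$ trade-off is sloppy), and coarse numeric
  gradients stall well before the minimum. A run is flagged non-converged
  only when the budget ran out while the best cost was still improving and
  the refinement had not reached a stationary point; the best-so-far result
  is returned either way.
* **Penalty normalization.** The penalty uses the *absolute* per-bin channel
  sum, time-averaged and normalized by the peak |CSD| of the estimate. A
  signed sum could cancel across bins and reward oscillating imbalance; the
  normalization makes $\lambda$ comparable across data scales. With
  $\lambda = 0$ the cost is exactly the relative MSE.
* **Degenerate inputs.** All-zero truth matrices are rejected in
  `relative_mse()` (undefined), all-zero CSD has channel-sum deviation 0 by
  definition, constant estimates get `NA` correlation in contribution
  matching rather than an error, and populations whose trapezoid covers no
  channel are named in an error (`infer_rates()`) or warned about
  (`build_spatial_matrix()`).
* **Channel classification.** A channel belongs to the unique population with
  positive trapezoid weight there (non-overlap guarantees uniqueness);
  channels with zero weight everywhere are assigned to the nearest support
  and flagged. A population is labelled with the layer its support overlaps
  most, measured in µm; ties go to the shallower layer and are messaged.
* **Default λ selection.** `select_lambda()` fits a grid and keeps the λ whose
  *estimate* has the smallest channel-sum deviation (ties to the smallest λ):
  the fit error itself grows with λ, so the deviation — not the cost — is the
  selection signal.

## The synthetic testbed

Validation does not rely on recorded data: `synth_config()` /
`make_recordings()` generate a laminar recording with known ground truth, and
the test suite and acceptance script score the decomposition against it.

The default fixture is desk-scale and mirrors a conventional mouse V1
recording geometry: 26 channels at 40 µm spacing spanning ~1000 µm across
five layers (L1, L2/3, L4, L5, L6), 750 ms stimulus-aligned trials at 1 ms
resolution with a 250 ms stimulus and 100 ms pre-stimulus baseline, 10
trials. Firing rates are baselines plus alpha-function transients peaking
tens of ms after stimulus onset and offset (per-population latencies spread
around 50 ms), with per-population private fluctuations and a shared template
mixed by a synchrony parameter $\rho \in [0, 1]$:
$r_n \propto (1-\rho)\,\mathrm{private}_n + \rho\,\mathrm{shared}$. At
$\rho = 1$ all laminar rates are identical up to amplitude — the regime in
which temporal-profile-based decomposition provably cannot attribute
contributions, which the tests demonstrate as a monotone degradation of the
contribution correlations and a growing condition number of the postsynaptic
profile matrix. The synchrony sweep is run with a 0.5% measurement-noise
floor on the CSD: with exactly noise-free data the pseudoinverse recovers the
planted profiles at *any* synchrony once the kernels are exact, so without a
noise floor the degradation would measure only optimizer precision; with it,
the ill-conditioned directions amplify noise and small kernel errors, which
is the physical failure mechanism. Three external structures are included: a fast feedforward
input ("LGN", early sharp transient), a slower feedback input ("FB", late
transient), and a weak diffuse background ("BKG"). The background's rate
trace is generated the way such a rate would be obtained in practice — from
spike counts of a constant-rate source, which after trial averaging and light
smoothing retains fast stochastic fluctuations; those fluctuations are what
makes its kernel identifiable at all.

Per-population field profiles are discrete dipoles (a Gaussian sink paired
with a Gaussian source scaled for an exactly zero channel sum); an
`imbalance` parameter adds an unbalanced bump to one population to exercise
the zero-sum penalty. The per-population contributions are stored and sum to
the stored clean CSD exactly; the LFP is produced from the CSD through the
same disc forward model the delta inverse-CSD inverts, so the CSD step is a
machine-precision identity on this testbed. Spikes are inhomogeneous Poisson
realizations of the rates (default 50 cells per population).

What the fixture does *not* emulate: biophysical morphologies and their
frequency-dependent filtering, correlated measurement noise, electrode drift,
non-exponential postsynaptic kernels, overlapping populations, and any
mismatch between the forward model assumed by the CSD estimator and the true
volume conduction. Passing the recovery tests therefore shows the algorithm
is correct and well-conditioned under its own model assumptions — not that
those assumptions hold in any particular recording.

## Problem sizes and budgets used in validation

The shipped tests and the acceptance script run the full 26-channel, 750-bin
fixture. The MUA fit uses a differential-evolution population of 100 for 150
iterations; the kernel fits use 100 × 200; the nine-point λ grid and unit
tests use smaller budgets (60 × 150 without local refinement, and a
12-channel/200-bin miniature). These sizes were chosen as the smallest at
which the recoveries are stable; they keep a full validation run in the
tens of minutes on a single core.

## Design choices that were genuinely open

* **Evaluation on trial averages.** Fitting the trial-averaged MUA (rather
  than concatenated single trials) matches how the signals are displayed and
  scored, and the least-squares structure makes the average the optimal
  single-trial summary under additive noise.
* **MUA fitting optimizer.** The kernel step's optimizer is a stated part of
  the method; for the trapezoid step any global derivative-free search would
  do, and the same differential-evolution machinery is used for both for
  coherence and reproducibility.
* **Appending external rates across scales.** MUA-derived internal amplitudes
  and spike-derived external rates are not on a common scale; whether they
  can be mixed directly is an open question of the method itself. The
  spatial-profile magnitudes can absorb per-row scale factors, so the default
  appends rates as-is; `standardize = TRUE` rescales every row to unit peak
  as an explicit, opt-in alternative.
* **ICA contrast.** The fixed-point scheme with the logcosh contrast and
  symmetric decorrelation is the standard default for this comparison; the
  baseline exists to be compared against, not tuned.

## Worked example

```{r example, eval = FALSE}
truth <- make_recordings(synth_config(seed = 1))

cfg <- analysis_config(n_populations = 5, rng_seed = 2)
mua_fit <- fit_mua(truth$mua, truth$geometry, cfg)
glance(mua_fit)
autoplot(mua_fit)

pred <- predict_channel_layers(mua_fit$populations, truth$geometry)
layer_scores(confusion_matrix(pred$predicted_layer,
                              channel_layers(truth$geometry)))

cfg8 <- analysis_config(8, rng_seed = 2)
csd_fit <- fit_csd(truth$csd, truth$rates, cfg8)
tidy(csd_fit)
match_contributions(csd_fit$contributions, truth$contributions)
autoplot(csd_fit)
```

## Known limitations

* Populations whose firing rates are strongly synchronous cannot be separated
  by any method that relies on temporal differences; the package warns, but
  the contributions it returns in that regime are cross-contaminated.
* A single temporal profile per population cannot represent excitatory and
  inhibitory inputs of opposite sign arriving with the same time course.
* The kernel family is a single causal exponential per population; bi-phasic
  or multi-compartment responses are outside the model.
* The delta inverse-CSD output is planar density up to the disc-radius
  assumption; a mismatched radius degrades the CSD estimate smoothly (shown
  in the tests) but is not diagnosed automatically.
* Differential evolution is stochastic: results are reproducible only through
  `rng_seed`, and very tight budgets can return flagged, non-converged fits.
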