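---
title: "Methods: light–nitrogen colimitation analysis of microhabitat arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: light–nitrogen colimitation analysis of microhabitat arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colimfit)
```

## The experimental design the package models

An 8×8 array of nanoliter culture chambers in a hydrogel device exposes
algal cells to 64 combinations of two resources. Perfused source and sink
channels (35.3 and 5.3 µM ammonium by default) hold a steady linear
diffusive nitrogen gradient across the rows; an optical gradient provides
light from 0.1 to 45 µmol·m⁻²·s⁻¹ PAR across the columns. Habitats are
seeded randomly with about 1–6 cells (some remain empty), fluorescence is
imaged every 4 h for 7 days, and background-subtracted intensity serves as
a proxy for cell number. Three replicate experiments are run.

The package covers the full analysis chain for such data — environment
calibration, growth-rate extraction, colimitation model fitting, and
prediction — plus a synthetic-data generator that emulates the design so
that every step can be validated end to end.

## The growth model family

The central model is multiplicative Monod colimitation,

$$\mu(L, N) \;=\; \mu_{max}\,
  \frac{L + L_0}{K_L + L + L_0}\;
  \frac{N + N_0}{K_N + N + N_0},$$

the product of two saturating factors, one per resource. Each factor
carries a *storage* offset: $L_0$ (µmol·m⁻²·s⁻¹) captures
light-independent energy from acetate in the medium (cells grow slowly in
the dark when acetate is present), and $N_0$ (µM) captures internal
nitrogen reserves. $K_L$ and $K_N$ are half-saturation constants in the
units of their resource; $\mu_{max}$ (day⁻¹) is the rate ceiling at
saturation. A generalized form multiplies any number of independent,
non-substitutable factors $\prod_i (E_i + E_{i0})/(K_{E_i} + E_i + E_{i0})$
and reduces bit-for-bit to the two-resource model.

Two rivals are provided for comparison. The *law-of-minimum* (Liebig)
form replaces the product with $\mu_{max}\min(f_L, f_N)$ over the **same**
saturating factors, keeping the two forms nested over one parameter
vector; since the algebraic details of a minimum-law analogue are a
modelling choice, we chose this construction deliberately so the
comparison is between "multiply" and "take the minimum" and nothing else.
The *reduced multiplicative* form drops both storages and frees the
ceiling: $\mu_0\,\frac{L}{K_L+L}\,\frac{N}{K_N+N}$.

### The fitting protocol

The default free/fixed split mirrors how such experiments are analysed:
$\mu_{max}$ is fixed at 2.4 day⁻¹ (a ceiling measured independently in
the same chambers, not identifiable from a gradient that never saturates
both resources), $N_0$ is fixed at 0 µM because cells are
nitrogen-starved before seeding, and $L_0$, $K_L$, $K_N$ are free. When
the medium carries no acetate there is no dark growth, so
`model_spec(acetate = FALSE)` fixes $L_0 = 0$ as well.

## Growth-rate extraction

Growth is quantified as $\ln(N/N_0)$ via background-subtracted intensity:
$\ln\big((I_t - b)/(I_0 - b)\big)$. The maximum specific growth rate of a
habitat is found by fitting every contiguous window of $n = 9$ points
(36 h at the 4-h cadence) to a straight line and taking the largest slope
among windows whose **center** lies at or beyond 1.3 days, converted to
day⁻¹. Two interpretation choices were genuinely open and are settled as
follows, both configurable:

- *Window anchor.* "After 1.3 days" could index the window's start,
  center, or end. We use the center: it is symmetric, and the returned
  rate is then stable under changes of window length (a start-anchored
  rule shifts the effective threshold by $n\Delta t/2$ as $n$ varies).
- *Standard error.* The SE attached to each maximum is the standard
  error of the $k = 4$ window slopes nearest the maximizer (positions
  max−1…max+2, clamped at the ends): the most literal reading of "points
  around each maximum growth rate" in terms of the quantities the scan
  actually produces. An alternative reading — 4 raw data points — would
  give a much noisier SE from a 4-point regression.

Windows containing masked points (intensity dipping below background at
$t > 0$) are skipped rather than silently interpolated; habitats with no
initial signal (`n0 = 0` or $I_0 \le b$) are excluded with reason codes
`EMPTY` / `NONPOSITIVE_I0`, and curves too short for the window or with
no admissible window raise `TOO_SHORT` / `NO_WINDOW`. Ties between window
slopes resolve to the earliest window. The background is a single scalar
per dataset, supplied explicitly or estimated as the mean intensity of
empty habitats (an estimator choice; the measurement protocol does not
prescribe one).

The window length matters little by design: on low-noise curves the
extracted rate changes by less than the noise scale for $n$ anywhere in
5–25, which the test suite checks.

## Weighted-bootstrap fitting

Parameter uncertainty comes from a replicate-resampling bootstrap. Each
of $B = 1000$ runs builds one growth-rate matrix by drawing, for every
(row, column) condition independently, one replicate's rate with
probability proportional to $1/\mathrm{SE}^2$, then fits the model to
that matrix by **unweighted** nonlinear least squares — the weights act
only in replicate selection, which is the literal reading of the
protocol. The reported estimate of each parameter is the mean of its $B$
values; spreads and pairwise correlations characterize uncertainty, and
two significance readings (a normal-approximation Wald p and a bootstrap
tail fraction) are reported because either could be meant by a bootstrap
"p-value".

Numerical choices:

- Weights are normalized *per condition*, the only reading that keeps
  the probabilities valid when a replicate is missing a record at some
  condition. Conditions with no record in any replicate are dropped with
  a warning.
- A record with SE = 0 (exactly noise-free data) receives the largest
  finite weight present at its condition, or a uniform weight if all SEs
  are zero — preserving the ordering "smaller SE, more weight" without
  infinities.
- The per-run minimizer is Levenberg–Marquardt with box constraints
  (all free parameters ≥ 0; $K_L, K_N \ge 10^{-6}$ so denominators never
  vanish). The pooled point fit uses 5 deterministic multi-starts
  (initial guess scaled by 1, 0.3, 3, 0.1, 10; data-driven initials:
  rate ceiling at the observed maximum, $K$'s at the grid medians, $L_0$
  at 10% of the maximum PAR), keeping the best SSE. Bootstrap runs
  warm-start from the pooled point fit with a single start: every
  resampled surface's optimum lies near it, and the degenerate
  identical-replicates case then collapses exactly onto the point fit.
- Model comparison (`compare_models`) fits all candidate forms to the
  *same* sequence of resampled matrices (a shared draw stream), so the
  SSE comparison is paired. SSE, R², and small-sample AIC (Gaussian
  likelihood, free-parameter count + 1 for the error variance) are all
  reported, covering any reasonable goodness-of-fit reading; forms
  failing to converge in more than 10% of runs are excluded.

## The synthetic-data generator

`simulate_array()` generates what the analysis assumes: per-habitat
exponential growth at the model rate for the habitat's (L, N), from a
uniform-integer initial count (1–6, empty with probability 0.05 by
default), observed through a fluorescence channel
`gain · cells · m + background` with a mean-one lognormal multiplier
(CV 0.05) and Gaussian background (level 100, sd 5, in arbitrary
intensity units; gain 1000 per cell). These noise defaults are our choice
of a realistic fluorescence read-out — the measurement protocol states no
noise model — and are deliberately modest so that the pipeline's
statistical behaviour, not the noise model, dominates test outcomes.

Trajectories use the exact exponential (or logistic, when a carrying
capacity is set) closed form per time point rather than an ODE stepper,
removing integrator tolerance from the test surface; the environment is
held at steady state, as the perfused device maintains it. Cell counts
are continuous (fluorescence measures biomass, not integers). A lag
option (`lag_h`) freezes growth initially to exercise the 1.3-day
threshold; it is off by default. Growth curves that plateau late in an
experiment (nutrient exhaustion, crowding, quenching — the mechanism is
not identified in such data) are emulated only through the optional
carrying capacity, also off by default.

What the generator does **not** emulate — spatial coupling between
habitats, photoacclimation, motility, image-level artifacts — bounds what
green tests mean: they validate the analysis chain against data that obey
its assumptions, not the biology of any particular experiment.
`simulate_rate_matrix()` additionally generates growth-rate matrices
directly (model surface + Gaussian rate noise), the natural input for
fitting-level studies where intensity-level detail is irrelevant.

## Environment construction

Row nitrogen values interpolate the steady linear gradient between the
channel concentrations at each row centerline. The default geometry —
2308 µm channel gap, 8 centerlines from the sink wall to 75% of the gap
(spacing ≈ 247 µm) — reproduces a 5.3–27.8 µM row range from 35.3/5.3 µM
channels and a slope of 1.3 µM per 100 µm; the sink-adjacent row sits at
the sink value. The geometry is fully configurable since habitat pitch
varies between devices. Column light values are the linear endpoint
convention (equally spaced from 0.1 to 45 PAR); the measured profile in
such devices is only approximately linear, but no tabulated profile
exists to integrate. Raw-signal conversions (dye fluorescence → µM, CCD
grayscale → PAR) are two-point linear calibrations.

## Problem sizes and reproducibility

The shipped analysis scripts and tests use the full study design (3 × 8×8
× 43 time points), $B = 1000$ for the headline fit, $B = 200$ for
bootstrap-level checks and 20–50 simulated datasets for comparison-level
checks — sizes at which every quantity reported here stabilizes while the
whole suite runs in minutes on one core. One master seed derives
per-stage substreams deterministically (`stage_seed`), so the pipeline is
byte-reproducible end to end and single stages can be rerun in isolation;
every artifact carries a provenance line (stage, seed, config hash,
package version).

## Known limitations

- The nitrogen response is calibrated over micromolar ammonium in
  starved cells; half-saturation constants depend on starvation history,
  light spectrum and nitrogen form, so fitted constants are
  condition-specific, not universal.
- $\mu_{max}$ is not identifiable from gradients that saturate neither
  resource; it must be supplied (default 2.4 day⁻¹).
- Estimation of the generalized product form beyond two factors is
  untested territory; the evaluator exists, but the fitting interface
  deliberately stops at light × nitrogen.
- The Liebig alternative is one reasonable law-of-minimum construction;
  conclusions about "multiplicative vs minimum" are conditional on the
  shared-factor parameterization described above.
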