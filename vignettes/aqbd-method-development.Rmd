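---
title: "Analytical Quality-by-Design computations for an HPLC assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytical Quality-by-Design computations for an HPLC assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromaqbd)
```

## The problem this package computes

Analytical Quality by Design (AQbD) develops a measurement method the way
process engineers develop a manufacturing step: define the target profile,
identify the controllable inputs (critical method parameters, CMPs) and the
measured outputs (critical method attributes, CMAs), model the
input-output relationship with designed experiments, and then delimit a
region of settings — the Method Operable Design Region (MODR) — inside
which every attribute stays within its acceptance window.

`chromaqbd` implements the full computational chain for an isocratic
reversed-phase HPLC assay of the three curcuminoids of *Curcuma longa*
(curcumin, demethoxycurcumin, bisdemethoxycurcumin):

1. **designs** — coded two-level full factorials with centre points, and
   the 12-run Plackett–Burman screening layout;
2. **response modelling** — per-CMA least-squares polynomial models with a
   complete ANOVA decomposition (per-term, lack of fit, pure error,
   optional curvature) and the summary statistics practitioners read
   (R², adjusted R², CV%, adequate precision);
3. **desirability** — Derringer–Suich multi-response optimization;
4. **MODR** — design-space overlay and automatic extraction of the
   largest operable box;
5. **Monte Carlo capability** — propagation of CMP variation through the
   models and the process-capability index Cpk per CMA;
6. **robustness** — Plackett–Burman effect estimation with three error
   models;
7. **validation** — ICH Q2 statistics: linearity, LOD/LOQ, recovery and
   precision, two-sample method comparison, and forced-degradation
   accounting from tabulated peak lists;
8. **synthetic data** — a chromatographic response generator that supplies
   statistically realistic inputs for every step.

## The models and their assumptions

### Coded designs and the polynomial response surface

Factors are coded so the operating range maps to $[-1, +1]$:
$x = (u - (u_{\mathrm{lo}} + u_{\mathrm{hi}})/2) / ((u_{\mathrm{hi}} -
u_{\mathrm{lo}})/2)$.  On a two-level design pure quadratic terms are not
estimable, so the default response surface is the interaction model

$$\hat y = b_0 + \sum_i b_i x_i + \sum_{i<j} b_{ij} x_i x_j,$$

with the three-factor interaction and a centre-point curvature contrast
available as optional terms.  Requesting a term the design cannot estimate
is an error that names the offending term rather than a silent aliasing.

The ANOVA uses sequential sums of squares (on these orthogonal designs
they coincide with partial ones).  With replicates, the residual splits
into lack of fit and pure error via the replicate groups; the
lack-of-fit F uses the pure-error mean square.  The curvature test is
implemented as a centred centre-point indicator regressor, which keeps
the decomposition exactly additive
($SS_{model} + SS_{resid} = SS_{total}$, checked to $10^{-8}$ relative in
the tests).

Adequate precision — the signal-to-noise summary whose conventional
acceptance floor is 4 — is not given a formula in most reports; we use
the widely documented definition
$(\max\hat y - \min\hat y) / \sqrt{p\,\mathrm{MSE}/n}$ over the design
points, with $p$ model parameters and $n$ runs.

### Desirability

Each CMA is mapped to $d \in [0,1]$: one-sided ramps for
maximize/minimize, a 0/1 indicator for in-range, a two-sided ramp for
target goals.  Acceptance rules stated as thresholds ("resolution
> 1.2", "plates > 2000") become `at_least` ramps from the threshold to
the observed maximum — the same convention desirability-based optimizers
in commercial DoE software apply, and the reason the ramp spans ship as
configuration rather than constants.  The overall score is the
importance-weighted geometric mean
$D = (\prod d_i^{v_i})^{1/\sum v_i}$, so any fully undesirable CMA vetoes
a candidate point.  Optimization is an exhaustive grid scan (default 51
points per factor) with ties broken by first point in scan order,
followed by cyclic coordinate descent polishing (tolerance $10^{-8}$ in
coded units).  The grid makes the search reproducible and auditable; the
polish recovers continuous optima.

### MODR extraction

The overlay marks a grid point feasible when every model prediction lies
inside its specification window.  Limits are closed and applied with a
$10^{-9}$ relative tolerance so a prediction numerically equal to a limit
counts as conforming.  Where practitioners typically draw the operating
box on the overlay by eye, `extract_modr()` automates the choice as the
maximum-volume axis-aligned box whose lattice points are all feasible —
exact (verified against brute-force enumeration) for up to three
factors, a documented greedy expansion beyond that — and a manual box can
be supplied to reproduce a hand-drawn region.  On uniform grids, volume
ties are broken toward the box containing more lattice points, then scan
order.

### Monte Carlo capability

Routine-use variation of the CMPs is modelled by independent uniform
(default), normal or triangular distributions, truncated to the factor
ranges by rejection.  Uniform-over-the-MODR is the default because it
assumes nothing beyond operability of the range.  Model error can be
transmitted as additive $N(0, \sqrt{\mathrm{MSE}})$ noise (default on;
switch it off for pure parameter-propagation studies).  Capability per
CMA is

$$C_{pk} = \min\!\left(\frac{USL - \mu}{3\sigma},
\frac{\mu - LSL}{3\sigma}\right),$$

with one-sided windows using the single finite term and a degenerate
zero-variance sample reported as $C_{pk} = \infty$.  The simulated Cpk is
cross-checked against the closed form on a normal linear model to within
2% at $10^5$ draws.

### Plackett–Burman robustness

Effects are the classical high-minus-low contrasts over the 12 two-level
rows; centre rows never enter the contrasts.  Three error estimates are
offered: the residual mean square of the main-effects regression
(default, because it applies to any printed two-level plan, including
non-standard ones), the root-mean-square of unassigned dummy-column
effects (available when the design was generated here), and pure error
from centre replicates.  A response that the main effects reproduce
exactly — which happens with heavily rounded published response tables —
would otherwise produce a floating-noise error variance; such variances
are clamped to zero and the effect reported with infinite t, making the
degeneracy visible instead of producing an astronomically large but
meaningless statistic.  Null simulations confirm the nominal type-I
error (rejection rate in [0.03, 0.07] at $\alpha = 0.05$).

### Validation statistics

Calibration lines are ordinary least squares; LOD and LOQ are
$3.3\sigma/s$ and $10\sigma/s$ from the response SD and slope, so
LOQ/LOD $= 10/3.3$ identically.  Method comparison uses the
pooled-variance two-sample t (Welch optional) and a variance-ratio F with
the larger variance in the numerator.  The F-test degrees of freedom are
exposed: published comparison tables sometimes quote critical values at
df conventions other than $(n_A-1, n_B-1)$, and reproducing such a table
requires matching its df (the packaged comparison fixture's critical
values correspond to df $(4, 4)$).  Forced-degradation accounting
consumes tabulated peak lists only: parents are matched between the
reference and stressed tables by retention time within ±0.2 min
(configurable), percent degradation is the relative loss of summed
parent area, and unmatched stressed peaks are reported as degradants.
Chromatogram signal processing (peak detection from raw traces) is out
of scope.

## What the synthetic generator emulates — and what it does not

The generator (`make_truth()`, `simulate_responses()`) is a
linear-solvent-strength retention model: per analyte,
$\ln k = \beta_0 + \beta_\varphi\,\Delta\varphi + \beta_{pH}\,\Delta pH +
\beta_T\,\Delta T$, retention time $t_R = t_0(1 + k)$ with dead time
$t_0 = 1$ min, a linear plate-count model, and peak resolutions from the
fundamental relation
$R_s = \frac{\sqrt{N}}{4}\,\frac{\alpha - 1}{\alpha}\,\frac{k_2}{1+k_2}$.

Default settings were fixed once to represent the assay's regime:

* at the optimum (54% ACN, pH 2.7, 33 °C) the three analytes elute at
  4.88, 5.37 and 5.92 min (bisdemethoxycurcumin first, curcumin last,
  the order the published retention tables support; the literature's
  log-P argument for the same ordering is noted, and the order is
  overridable because goal tables in the area are not always internally
  consistent about it);
* $\beta_{pH} = +0.15$ per pH unit, $\beta_T = -0.01$ per °C and
  $\beta_\varphi = -5$ per unit ACN fraction, reproducing the reported
  effect signs (pH raises retention; temperature and organic fraction
  lower it).  The magnitude of $\beta_\varphi$ was chosen so that, over
  the full 50–70% ACN screening range, retention spans roughly 2.7–7.6
  min and the interaction model's CV% stays in the reported <10% band
  with adequate precision above 4 on the triplicated 33-run screen;
  steeper values leave the log-linear curvature so strong that no
  two-level polynomial is an adequate summary, which is not the regime
  the published fit statistics describe;
* multiplicative Gaussian noise of 1% (retention), 2% (resolution) and
  3% (plates) relative SD.

The generator does **not** synthesize chromatogram traces, gradient
elution, peak tailing, carryover, or day/instrument random effects — so
passing tests demonstrate the *computational* chain is correct under the
stated statistical model, not that any particular laboratory system obeys
it.  Calibration noise is proportional to signal (so weighted fits are
the statistically exact oracle), and degradation tables lose exactly the
requested area fraction with the lost mass reappearing as early-eluting
degradant peaks.

## Numerical choices and degenerate inputs

* Problem sizes: the screening study is modelled at 33 runs (triplicated
  2³ + 3 centres); simulation-based checks use 100–300 replicates, the
  capability cross-check $10^5$ draws, grids of 21–51 points per axis.
* Rank deficiency errors before fitting, naming the unestimable terms.
* A zero-mean response makes CV% undefined: `fit_statistics()` raises an
  error, while the fitting path records `NA` so the rest of the summary
  survives.
* Ties in grid optimization and box extraction are broken
  deterministically (scan order), and every stochastic routine takes an
  explicit seed; identical seeds give bit-identical outputs.
* An infeasible overlay yields an empty MODR with a warning, not an
  error; an everywhere-zero desirability is reported as $D = 0$.

## Known limitations

* Quadratic curvature can be detected (centre points) but not located:
  that requires an augmented design outside the scope of two-level
  factorials.
* The MODR search is exact only up to three factors; beyond that the
  greedy heuristic may return a sub-maximal box.
* Plackett–Burman p-values assume i.i.d. Gaussian errors; with heavily
  rounded response tables the regression error model can make practically
  negligible effects statistically significant, which is why robustness
  conclusions should weigh effect magnitudes, not p-values alone.
* Printed robustness plans are ingested as data rather than regenerated:
  the packaged 14-run plan is not a standard cyclic Plackett–Burman
  fraction (it contains a duplicated run), and no attempt is made to
  "correct" it.
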