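# chromaqbd

Analytical Quality-by-Design (AQbD) computations for chromatographic
method development, built around the worked case of an isocratic
reversed-phase HPLC assay for the three curcuminoids of *Curcuma longa*
(curcumin, demethoxycurcumin, bisdemethoxycurcumin).

AQbD treats an analytical method as a process to be engineered: the
controllable inputs (critical method parameters, CMPs — here mobile-phase
pH, % acetonitrile, column temperature, buffer concentration) are related
to the measured outputs (critical method attributes, CMAs — peak
resolutions RS1/RS2, retention times, theoretical plate counts) through
designed experiments, and the method is released with a Method Operable
Design Region (MODR): the box of settings within which every CMA stays
inside its specification window.

The package is for analytical chemists and chemometricians who want that
chain as auditable, scriptable computation rather than point-and-click
software:

* **Designs** — coded two-level full factorials with centre points and
  replicates; the cyclic 12-run Plackett–Burman layout with dummy columns
  retained for error estimation.
* **Response surfaces** — per-CMA least-squares models in coded units
  with the full ANOVA (per-term, lack of fit vs pure error, optional
  curvature) and the summary statistics practitioners read: R², adjusted
  R², CV%, adequate precision
  `(max ŷ − min ŷ)/√(p·MSE/n)`.
* **Derringer–Suich desirability** — per-CMA ramps `d ∈ [0, 1]` combined
  as the importance-weighted geometric mean
  `D = (∏ dᵢ^{vᵢ})^{1/Σvᵢ}`, optimized by exhaustive grid scan plus
  coordinate-descent polish.
* **MODR extraction** — design-space overlay of all windows on a factor
  grid and automatic extraction of the maximum-volume all-feasible box.
* **Monte Carlo capability** — CMP variation propagated through the
  models; per-CMA `Cpk = min((USL−μ)/3σ, (μ−LSL)/3σ)` and out-of-spec
  fractions.
* **Robustness** — Plackett–Burman effects (high-minus-low contrasts)
  with regression-residual, dummy-column or centre-point error models.
* **ICH Q2 validation statistics** — calibration linearity,
  `LOD = 3.3σ/s`, `LOQ = 10σ/s`, % recovery and % RSD, pooled-variance
  t and variance-ratio F method comparison, and forced-degradation
  accounting from tabulated peak tables.
* **Synthetic data** — a linear-solvent-strength retention generator
  (`ln k` linear in ACN fraction, pH, temperature; `Rs` from the
  fundamental resolution relation) that produces realistic design
  responses, calibration series and pre/post-stress peak tables for every
  pipeline stage, plus packaged reference tables from the curcuminoid
  assay's development (factor levels, goals, windows, the 14-run
  robustness plan, calibration statistics, dosage-form comparisons).

## Worked example

Simulate a triplicated 2³ + 3-centre screening study, fit a resolution
model, optimize desirability, extract the MODR and check capability:

```r
library(chromaqbd)

fs   <- fixture_factors()                      # pH 2.5-3.5, ACN 50-70%, T 25-35 degC
des  <- full_factorial(fs, n_center = 3, n_replicates = 3, seed = 42)
resp <- simulate_responses(make_truth(seed = 42), des, seed = 42)

fit_response_model(resp, "RS1")
#> Response model for RS1 (33 runs, 6 terms)
#>     (Intercept)              pH             ACN     Temperature          pH:ACN
#>        1.453697        0.033188       -0.176653       -0.006851        0.000353
#>  pH:Temperature ACN:Temperature
#>       -0.005412        0.003495
#> R2 = 0.9597, adj R2 = 0.9504, CV% = 2.44, adeq precision = 26.80
```

The intercept is the grand-mean resolution; coefficients are per coded
unit, so ACN moving from its midpoint to 70% costs about 0.18 resolution
units, while pH helps slightly.  CV% below 10 and adequate precision far
above 4 mean the model is reproducible and has usable signal.

```r
models <- setNames(lapply(names(resp$responses),
                          function(cm) fit_response_model(resp, cm)),
                   names(resp$responses))

opt <- optimize_desirability(models, fixture_goals(), fs, n_grid = 31)
#> best: pH = 2.5, ACN = 50, Temperature = 35,  D = 0.688

ov <- overlay_feasibility(models, fixture_windows(), fs, n_grid = 21)
ov
#> Overlay over 21 x 21 x 21 grid: 89.1% of points feasible
extract_modr(ov)
#>        factor lower upper
#> 1          pH   2.5   3.5
#> 2         ACN  56.0  70.0
#> 3 Temperature  25.0  35.0
```

Under this simulated truth almost the whole screened region conforms, and
the largest fully-feasible box spans every pH and temperature but only
ACN ≥ 56% (below that, late peaks leave the 7-minute retention window at
low temperature).  Propagating uniform CMP variation over the operable
ranges:

```r
ranges <- fixture_mc_ranges()                  # ACN 54-57%, pH 2.5-2.9, T 32-35
dists  <- setNames(lapply(ranges, function(f)
            mc_distribution("uniform", min = f$low, max = f$high)),
          vapply(ranges, `[[`, "", "name"))
simulate_capability(models, fixture_windows(),
                    mc_config(dists, n_draws = 2e4, seed = 42))
#>         cma       mean        sd   cpk frac_out
#> 1       RS1    1.50966   0.03898 2.648    0e+00
#> 3    RT_CMN    5.80604   0.33970 1.171    1e-04
#> ...
```

Every CMA is capable (Cpk > 1); the binding attribute is the curcumin
retention time against its 7-minute upper limit.

Validation statistics reproduce published reference values exactly:

```r
compare_methods(27.15, 0.35, 3, 27.62, 0.26, 3, df_f = c(4, 4))
#> 27.15 +/- 0.35 (n=3) vs 27.62 +/- 0.26 (n=3): t = 1.87 (crit 2.78), F = 1.81 (crit 6.39)
#> means equivalent, variances equivalent at alpha = 0.05

round(lod_loq(0.335 * 1077486.9 / 3.3, 1077486.9), 3)
#>   lod   loq
#> 0.335 1.015

eff <- pb_effects(fixture_pb_table())
round(eff$effect[eff$factor == "pH" & eff$cma == "RS1"], 4)
#> [1] -0.0012
```

A command-line front end over the same functions ships as
`inst/exec/chromaqbd` (subcommands `design`, `simulate`, `fit`,
`optimize`, `modr`, `mc`, `robustness`, `validate`, `fixtures`); see
`?aqbd_cli`.

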