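---
title: "Optimizing ultrasonic extraction: response surfaces, neural surrogates and genetic search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing ultrasonic extraction: response surfaces, neural surrogates and genetic search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uaeopt)
```

`uaeopt` supports the now-standard workflow for optimizing
ultrasonic-assisted extraction of bioactive compounds: a Box–Behnken
design (BBD) over the process factors, a second-order response-surface
(RSM) fit with adequacy diagnostics, a small neural-network surrogate, a
genetic-algorithm search for the best settings, and a head-to-head
comparison of the two surrogates' prediction ability. This vignette
explains the models, the defaults and the design choices; the package's
tests compute every empirical claim made here.

## The experiment and its design

The packaged study (`sh_study()`) extracts polyphenols from the brown
seaweed *Sargassum horneri* with a multifrequency ultrasonic bath. Four
factors are varied over three levels each:

| factor | unit | low | center | high |
|---|---|---|---|---|
| ethanol concentration | % | 30 | 50 | 70 |
| sonication time | min | 20 | 35 | 50 |
| temperature | °C | 20 | 40 | 60 |
| ultrasonic frequency | kHz | 26 | 35 | 40 |

and four responses are measured per run: total phenolic content (TPC,
mg gallic-acid equivalents/g), total flavonoid content (TFC, mg catechin
equivalents/g), and DPPH and ABTS radical scavenging (% inhibition).

`build_bbd()` constructs the standard BBD: for each of the
`choose(k, 2)` factor pairs, the four (±1, ±1) corners with all other
factors at center, plus replicated all-center runs — for k = 4 and 3
center runs, 27 runs in total. Center replication is what funds the
pure-error estimate behind the lack-of-fit test, which is why
`validate_design(lack_of_fit = TRUE)` flags designs with fewer than 3
center points. Run order is canonical (pair-major); randomization of run
order is an execution-time concern outside the package's scope.

## Coding the factors — why the default is affine

All modelling happens on coded factors. Two schemes are implemented:

* **affine**: `x = (v − (low + high)/2) / ((high − low)/2)`;
* **ordinal**: low/center/high → −1/0/+1 by rank.

For equally spaced levels the two coincide. The frequency factor's levels
(26/35/40 kHz) are *not* equally spaced, so the schemes genuinely differ:
under affine coding 35 kHz sits at +2/7, not 0, and interaction columns
differ between the schemes. The package default is **affine**, settled
empirically: refitting the packaged study under affine coding reproduces
all 27 × 4 of the study's published RSM-predicted values to within ±0.02,
while ordinal coding misses some by more than 1 unit. The published
analysis therefore linearly rescaled actual values, and the package
follows it. One consequence worth knowing: under affine coding the model
intercept is the prediction at the *coded origin* (33 kHz), not at the 35
kHz center run; under ordinal coding the two coincide.

## The response-surface model and its diagnostics

`fit_quadratic()` fits the full 15-term second-order polynomial by
ordinary least squares (n = 27 leaves 12 residual df). `anova()` on the
fit reports:

* per-term **partial (type-III) SS** — each term has 1 df, so its partial
  SS is `t² · MSE` from the coefficient table. With the near-orthogonal
  coded BBD columns these are close to, but not identical with,
  sequential SS;
* **lack of fit**: residual SS is split into pure error (within
  replicated design points) and lack of fit; a non-significant
  lack-of-fit F supports the quadratic form;
* **adequacy**: plain and adjusted R², CV% (`100·√MSE/ȳ`) and adequate
  precision `(max ŷ − min ŷ)/√(p·MSE/n)` over the design points, the
  conventional signal-to-noise measure (> 4 is the usual bar). A fit
  whose residual MSE is numerically zero (exact interpolation) reports
  adequate precision as `Inf`.

On the packaged study all four responses land in the published regime:
R² between 0.91 and 0.94, adequate precision between 11.04 and 13.04,
lack of fit non-significant throughout — the acceptance tests assert
exactly this. `alpha = 0.05` is the significance level throughout.

## The neural surrogate

`train_ann()` fits a feed-forward network with `k` inputs (the coded
factors, already in or near [−1, 1]), `H` tanh hidden units and `m`
linear outputs; responses are min-max scaled to [−1, 1] per column and
inverse-scaled at prediction time. Options:

* **split**: runs are partitioned 65/20/15 into train/test/validation by
  largest-remainder apportionment (27 → 18/5/4) with seeded random
  membership. Training minimizes training-set MSE; the validation set
  selects among hidden sizes and restarts; the test set is only reported.
* **algorithm**: `"lm"` (default) is a damped Gauss–Newton
  (Levenberg–Marquardt) loop on the analytic network Jacobian — accepted
  steps only, so training MSE is monotone non-increasing; `"bfgs"`
  delegates to `stats::optim` with the analytic gradient. Defaults
  `max_iter = 500`, `tol = 1e-8` on the per-iteration MSE decrease.
* **initialization**: weights uniform in [−0.5, 0.5] from the seed;
  `n_restarts` re-initializes and keeps the best validation MSE.
* **cascade**: optional direct input→output connections.

Everything is deterministic given (data, seed, options) — the same call
twice yields bit-identical weights, and `ann_save()`/`ann_load()`
round-trip a surrogate exactly through JSON (17 significant digits).

`sweep_hidden_neurons()` trains H = 1…20 under a common split and picks
the validation-MSE minimizer (ties to the smaller network). With only 18
training rows a 4–10–4 network (94 parameters) interpolates its training
data; the validation partition is the only guard against that, which is
why selection never looks at training error. The published study selected
H = 10; with different random splits and initializations the sweep will
legitimately select other sizes — the published ANN prediction column is
*not* a reproduction target, and the package only asserts non-divergence
(selected validation MSE within twice the scaled-target variance) and
determinism on the packaged data.

## Genetic-algorithm optimization

`ga_optimize()` maximizes a scalarized prediction over the coded box.
The scalarization is the equal-weight (configurable) mean of
min-max-normalized predicted responses, normalized against the observed
response ranges — the simplest defensible way to combine four responses
on different scales; weights are exposed for anything more opinionated.

The GA is real-coded: tournament selection (size 2), blend (BLX-0.5)
crossover with probability 0.8, per-gene Gaussian mutation (probability
0.1, sd = 10% of the gene range), elitism 2, population 50, 100
generations, all seeded and deterministic. Seeding the initial population
with the design points guarantees the optimum is never worse than the
best design run. `grid_search_oracle()` — exhaustive evaluation on a
lattice (21 points per factor by default, 194,481 points) — is the
independent check; on the packaged study's response surfaces the GA
matches it to within 10⁻³ normalized fitness.

Only three ultrasonic frequencies physically exist on the instrument, so
the frequency factor is searched continuously but *reported* snapped to
the nearest level (`snap = "freq_kHz"` in the pipeline); snapping never
affects the search itself.

## Prediction-ability metrics

AAD and SEP have several variants in the literature; the package fixes
one of each and documents it:

* `aad` = (100/n) Σ |ŷᵢ − yᵢ| / yᵢ (relative to each observation);
* `sep` = 100 · RMSE / ȳ (relative to the observed mean);
* `rmse` = √(Σ(ŷ − y)²/n);
* `r2_score` = 1 − SSE/SST, which can go negative for predictors worse
  than the mean.

`compare_models()` computes the 2 × 4 metric grid and a per-response,
per-metric verdict. On the packaged study's two published prediction
columns the neural network wins every metric for every response.

## Assay calibrations

`calibration_lines()` bundles the study's published spectrophotometric
calibration lines (Folin–Ciocalteu TPC vs gallic acid, AlCl₃ TFC vs
catechin, DPPH and ABTS vs ascorbic acid), and
`concentration_from_absorbance()` / `percent_inhibition()` perform the
routine conversions. Two published lines required a typographic reading:
the TFC slope printed with a stray space is taken as 0.0336, and the ABTS
line printed without its x as y = 0.0369x + 0.0133; both readings are the
only dimensionally sensible ones. Fitting new calibration curves is out
of scope — it is a one-line `lm()` upstream.

## Synthetic studies and what they do (not) show

`generate_study()` draws responses from a known quadratic surface at the
coded BBD points plus i.i.d. Gaussian noise — the data-generating process
the RSM analysis assumes. `sh_truth()` is a realistic preset: its true
coefficients are the packaged study's own fitted surfaces and its noise
SDs their residual standard deviations (≈ 3.0 mg GAE/g for TPC), placing
simulations in the study's R² ≈ 0.91–0.94 regime. The generator
deliberately does **not** emulate heteroscedastic replicate error,
run-order drift, or curvature beyond second order; passing tests
therefore certify the estimation machinery under the model's own
assumptions, not robustness to real-world violations of them.

Simulation-based test sizes were chosen to keep the whole suite fast
while leaving negligible Monte-Carlo slack: 200 replicates for the 95%
CI coverage check (3,000 interval/term indicators, binomial SE ≈ 0.4
percentage points against a ±4-point acceptance band) and for the
parameter-recovery and R²-regime checks.

## Numerical choices and degenerate inputs

* Rank-deficient designs and constant response columns are errors, not
  warnings; mismatched lengths and missing values fail fast with the
  offending quantity named.
* Ordinal coding refuses off-level values; affine coding permits any
  value but `predict()` warns when extrapolating outside the box.
* Sweep ties break toward the smaller network; GA individuals with
  non-finite fitness are discarded with a warning; the lattice oracle
  refuses lattices above a configurable cap (5 × 10⁶ points).
* `percent_inhibition()` clips to [0, 100] with a warning; negative
  concentrations from below-blank absorbances are flagged but returned.
* Lack of fit is omitted (with a warning) when the design has no
  replicated points, rather than inventing a pure-error estimate.

## Limitations

* The ANN trainer is a purpose-built small-network optimizer, not a
  general deep-learning stack; it targets the ≤ 20-hidden-unit,
  ≤ few-hundred-run regime of design-of-experiments surrogates.
* One network predicts all four responses jointly (matching the 4–H–4
  topology convention); per-response networks can be had by calling
  `train_ann()` per column.
* Canonical analysis of the stationary point, desirability functions,
  Pareto multi-objective search, and alternative designs (central
  composite, D-optimal) are out of scope.
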