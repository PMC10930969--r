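---
title: "Methods: NIR calibration of passion-fruit epicarp hardness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NIR calibration of passion-fruit epicarp hardness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Passion fruit ripens and wrinkles quickly after harvest, and the mechanical
state of its peel is a direct quality indicator. A needle-probe puncture of
the fruit shows two successive force peaks: the first when the smooth outer
epicarp (P1) fractures, the second when the inner deep-purple epicarp (P2)
gives way, followed by a stable phase as the probe travels through the
spongy mesocarp. The forces at those two peaks — F1 and F2, in gN as the
texture analyzer reports them — quantify outer and inner peel hardness.
Measuring them destroys the fruit, so the package builds calibration models
that predict F1 and F2 from near-infrared diffuse-reflectance absorbance
spectra (10,000–4000 cm⁻¹), which can be acquired non-destructively.

`epinir` implements the full calibration workflow: texture peak extraction,
SPXY sample partitioning, moving-average (MA) and mean-centering (MC)
preprocessing, three feature-wavelength selectors (CARS, SPA, UVE) over a
shared PLS engine, a grid-searched random forest and a GA-tuned support
vector regression, and R²/RMSE/RPD assessment. Because no public dataset of
paired fruit spectra and puncture forces exists, the package ships a seeded
synthetic-data generator that emulates the statistical structure such a
study produces, and every stage is tested end to end on it.

## The synthetic cohort

`synthetic_config()` describes 120 fruits in six storage batches (one batch
every three days). Absorbance is a sum of Gaussian bands plus a per-sample
quadratic baseline and i.i.d. noise:

* **Bands.** Five bands at 8403, 6896 and 5154 cm⁻¹ (water: combination
  band and the O–H overtones), 7142 cm⁻¹ (cellulose O–H) and 4464 cm⁻¹
  (pectin C–H, the middle of the 4484–4444 cm⁻¹ region). Widths (σ
  90/80/90/70/50 cm⁻¹) are in the range of condensed-phase NIR bands and
  concentrate each band's information near its maximum.
* **Latent concentrations.** Bands of one constituent share a log-normal
  latent factor — the three water bands rise and fall together — with a
  small per-band log-normal "wobble" (sd 0.10 water, 0.08 others)
  representing band-specific variation. Water declines strongly across
  storage batches (log-trend ≈ −0.55), cellulose weakly, pectin moderately
  with an uptick in the final batch.
* **Responses.** Raw hardness scores are affine in the latent
  concentrations (F2 water-dominated; F1 dominated by the high-variance
  pectin factor, which makes it right-skewed) plus Gaussian noise (sd 0.01
  score units), then min–max mapped onto the configured ranges
  F1 ∈ [0.881, 3.721] gN and F2 ∈ [2.524, 4.201] gN, so the configured
  bounds are attained exactly. With the default seed the sample mean of F1
  falls in the documented target band 1.583 ± 0.4 gN and the batch means of
  F2 decline monotonically with storage.
* **Puncture curves.** Six per fruit: piecewise-linear traces over 0–10 mm
  through knots at the two planted peaks, a dip between them, and a gently
  declining plateau strictly below the second peak. Knots sit on the
  output grid, so at zero jitter peak extraction returns the planted forces
  exactly; the default 1% multiplicative jitter leaves the six-curve mean
  within 2% of truth.

All randomness flows from one master seed through `derive_seed(seed, tag)`,
so each stage has its own reproducible stream and stages can be re-run
independently.

**What the generator does not emulate.** Scatter effects
(multiplicative/Kubelka–Munk behaviour), instrument line-shape asymmetries,
wavelength-correlated noise, fruit-geometry effects, and — importantly —
the channel-level measurement noise of real spectrometers. Synthetic
spectra are smoother and cleaner than real ones, which has one visible
consequence discussed below: UVE retains many more channels here than it
does on real data. Passing tests therefore demonstrate correctness of the
algorithms and the plumbing, not field performance on real fruit.

## Stage-by-stage notes

### Texture analysis

`extract_peak_forces()` calls a peak a local maximum (flat tops allowed)
whose prominence exceeds a threshold, defaulting to 5% of the curve maximum
to ignore sensor ripple. F1 and F2 are the first two qualifying peaks in
displacement order — by design, not the two tallest: later peaks and the
plateau are ignored even if higher. If fewer than two peaks qualify the
error states how many were found. Per-fruit values are arithmetic means
over the (by default six) curves, and descriptive statistics use the
sample-SD convention (n − 1) throughout.

### SPXY partitioning

`spxy_split()` uses the joint distance
`d(i,j) = dX(i,j)/max dX + dy(i,j)/max dy` (Euclidean in the spectra,
absolute difference in the response), seeds the calibration set with the
pair at maximum joint distance and grows it by the max–min rule. Ties break
to the lowest sample index, so splits are platform-stable; there is no RNG
anywhere in the splitter. The calibration size is `floor(n × fraction)`
(90 of 120 at the study's 3:1 ratio). Distances are computed on raw
spectra, because the split precedes the preprocessing comparison and must
be common to all of its arms. Splits are made per response, since F1 and F2
order samples differently.

### Preprocessing

MA replaces each point by the mean of the `(2w+1)`-window centred on it;
edges use shrunken windows, which keeps the output length unchanged and
avoids edge NaNs. The default half-width `w = 3` (7-point window) is a mild
smoother for a 1 cm⁻¹ grid and is exposed as a parameter. MC subtracts the
calibration-set mean spectrum. Both follow the fit-on-calibration /
apply-to-both pattern (`preprocess_fit()` / `preprocess_apply()`), so no
prediction-set statistic can enter a fitted state — the leakage audit in
the test suite checks this by perturbing prediction rows and asserting all
fitted states are bit-identical.

### The PLS engine

The selectors share a univariate SIMPLS implementation (`pls_fit()`),
which for a single response coincides with PLS1/NIPALS; the test suite
cross-checks its predictions against an independent PLS implementation and
against ordinary least squares at full rank. The component count is chosen
by 5-fold cross-validation on deterministic rank-stratified folds, capped
at 10, taking the *smallest* count within 2% of the minimum RMSECV rather
than the strict argmin. The parsimony tolerance matters: near the CV
optimum the curve is flat, and needlessly high dimensions make the
coefficient vector unstable — which in turn destabilises UVE's stability
statistic. Inside UVE a wider 10% tolerance is used for the same reason.

### CARS

Fifty Monte-Carlo iterations; each fits PLS on a random 80% subsample of
calibration fruits, converts coefficients to weights `|b|/Σ|b|`, keeps the
top fraction prescribed by a two-parameter exponentially decreasing
schedule (all variables at iteration 1, two at iteration N), then applies
adaptive reweighted sampling — a weighted bootstrap among survivors. Each
iteration's subset is scored by 5-fold PLS RMSECV on the full calibration
set. The returned subset is the smallest one within 2% of the minimum
RMSECV over iterations (`rmse_tol = 0.02`; 0 gives the strict argmin). On
smooth spectra the RMSECV path is flat over a wide range of subset sizes,
so the strict argmin is an arbitrary draw among statistically
indistinguishable subsets; the tolerance yields stable subsets of tens of
variables. With one iteration, a retain-all schedule and resampling
disabled, CARS reduces exactly to top-weight thresholding of a single PLS
fit — the reduced case the tests exploit.

### SPA

Classic successive projections: starting from a candidate column, the
variable with the largest residual norm after projection onto the
orthogonal complement of the selected set is added, which by construction
picks minimally collinear wavelengths; exactly collinear columns project
to zero and are skipped with a warning. Chains grow to `k_max = 15` and
every (start, chain length ≥ 2) pair is scored by 5-fold CV RMSE of a
multiple linear regression. Candidate starts are limited to the
`n_starts = 10` columns most correlated with the response: scanning all p
starts is O(p²·k·n) and infeasible on dense spectral grids, and
high-correlation columns are where informative chains begin. SPA is fully
deterministic (rank-stratified folds, lowest-index tie-breaks).

### UVE

An equal-width block of uniform noise, scaled to 10⁻¹⁰ of `max|X|` (small
enough not to perturb the model, nonzero so coefficients vary), is appended
to the calibration matrix; PLS coefficients are collected under
leave-one-out resampling; each variable's stability is `mean(b)/sd(b)`
(sample SD; a zero SD maps to ±Inf with a warning). The threshold is the
largest |stability| in the noise block, so every retained real variable is
more stable than every known-uninformative one — an invariant the tests
assert directly.

Two honest observations from this implementation. First, the stability
contest degenerates if the PLS dimension is allowed to chase the CV
minimum into near-noise components — hence the conservative dimension rule
above. Second, on this package's smooth synthetic spectra UVE retains
hundreds of the ~1500 working channels, not the ~15 of 6001 reported on
real fruit data: almost every in-band channel here is genuinely
informative and stably weighted, and baseline-carrying channels acquire
small but stable structural coefficients. The null simulation in the test
suite (pure-noise response, 50 × 150 design, twenty seeds) confirms the
method keeps a median of zero real variables when there is nothing to
find; at much smaller variable counts a residual one or two chance
survivors are expected, because under the null the real and noise blocks
are nearly exchangeable and the threshold is an extreme order statistic of
the noise block.

### Grid-searched random forest

Every `(ntree, mtry)` pair is evaluated by k-fold CV with one fold
assignment shared across the grid (paired comparison), pooling held-out
squared errors into one MSE per pair; ties break to the smaller `ntree`,
then `mtry`. Each forest grows under a seed derived from
`(seed, ntree, mtry, fold)`, which makes every grid point independently
re-computable — the exhaustiveness oracle in the tests re-fits every point
and reproduces the CV table exactly. Default grids are
ntree ∈ {100, …, 1000} and five log-spaced mtry values between ⌈p/10⌉ and
p; the analysis scripts and acceptance script use compact grids
(ntree {100, 300}, three mtry values at full spectrum) as their documented
problem size.

### GA-tuned SVR

`(c, γ)` are encoded on the log₁₀ scale in [10⁻², 10²]. A "generation" is
one evaluated population and generation 1 is the random initial population,
so population 4 with one generation is exactly an exhaustive 4-point
argmin — the reduced-case oracle. Fitness is k-fold CV MSE of an RBF-kernel
ε-SVR (ε = 0.01, features unscaled so the kernel is exactly
`exp(−γ‖xᵢ−xⱼ‖²)` on the data as given); the GA *minimises* it. Rank-based
parent selection, blend crossover (rate 0.7), Gaussian log-scale mutation
(rate 0.05), strict elitism (the best individual is carried over, so the
best-fitness trajectory is non-increasing), and early stopping after 10
generations without > 10⁻⁶ improvement. Defaults are population 20 and 50
generations; the acceptance script uses 30 generations.

### Evaluation

R² is implemented as 1 − SSres/SStot. One printed form of the
R² formula in the chemometrics literature omits the "1 −", which would make
small values good; the package follows the universal convention, where
values near 1 mean a good fit, and flags the choice here rather than
silently normalising it. RMSE is the plain root mean square residual, and
RPD = SD(prediction-set observations)/RMSEP with the sample-SD convention.
The qualitative RPD bands are half-open: < 2 insufficient, [2, 2.5)
approximate quantitation, ≥ 2.5 strong (the 2.5 boundary closed on the
strong side, a convention the package documents because the verbal
definitions leave it open). `build_comparison()` ranks reports by
prediction-set R² and flags the best row per response.

## Problem sizes

Unit tests run on a 48-fruit, 121-channel cohort. The end-to-end
experiment in the tests and the acceptance script uses the full 120-fruit
cohort on a 1501-point grid (every 4th channel of the 6001-point axis —
matching the instrument's 4 cm⁻¹ acquisition resolution), with the compact
RF grids and 30 GA generations noted above. The full 48-combination sweep
in `analysis/05_fit_models.R` runs on a 751-point grid. These sizes are the
package's documented working configuration; all stage functions accept the
full 6001-point grid unchanged.

## Known limitations

* The generator's five Gaussian bands with shared constituent factors are a
  deliberately minimal model of NIR spectra; conclusions about selector
  behaviour on real fruit (especially UVE subset sizes) do not transfer.
* CARS retains its water-band coverage of the planted maxima in roughly 9
  of 10 random cohorts; it is guaranteed (and tested) only at the default
  seed.
* The gN force unit is carried verbatim from texture-analyzer output
  without conversion.
* SPA's restricted start set is an approximation to the all-starts
  algorithm; with orthogonal or well-separated informative bands it
  recovers the same chains, but adversarial designs could hide a better
  chain behind a low-correlation start.
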