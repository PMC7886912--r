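---
title: "Basis-restricted NMF for single-cell Raman spectra: models, parameters and design choices"
author: "gbrnmf authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Basis-restricted NMF for single-cell Raman spectra: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models implemented by `gbrnmf`, the parameters
that matter and their defaults, what the synthetic-data generator does and
does not emulate, and the numerical decisions taken where the design was
genuinely open.

## The factorisation model

A dataset is a non-negative matrix $X$ ($n$ spectra $\times$ $p$
wavenumbers, each row preprocessed to unit area). Given a library of $m$
reference spectra of pure biochemicals $B$ (rows on the same axis, treated
identically to cell spectra), the model is

$$X \approx W\,A\,S, \qquad W \ge 0,\; S \ge 0,\; A = \mathrm{diag}(a_j),\; a_j > 0,$$

with $S$ a $k \times p$ basis matrix whose first $m$ rows are *fixed* to
$B$ and whose remaining `n_free` rows (one by default) are estimated from
the data, absorbing signal the library does not represent. $A$ is a pure
reparameterisation: after the fit, $a_j$ is set to the column mean of the
raw scores and the column is divided by it, so every non-degenerate score
column of $W$ has mean exactly 1 and $W A S$ is unchanged. Scores are then
comparable across factors: a cell with glycogen score 2 carries twice the
study-average glycogen contribution.

### Optimiser

The paper-facing literature on this model specifies the factorisation, not
an algorithm, so the optimiser is the package's own choice:
block-coordinate alternating non-negative least squares.

* **Score step.** Each row of $W$ solves
  $\min_{w \ge 0} \lVert x_i - wS \rVert^2$ exactly, by a Lawson–Hanson
  active-set solver on the normal equations (implemented in C++; the
  $k \times k$ cross-product $SS^\top$ is shared across rows, so each row
  costs only small active-set iterations).
* **Free-basis step.** Holding $W$ and the fixed rows, the free rows solve
  the transposed subproblem: one NNLS per wavenumber against the free score
  columns. Fixed rows are never touched (they remain bit-identical to the
  input library).

Both half-steps are exact minimisers, so the recorded objective trace
$\lVert X - WS \rVert_F^2$ is non-increasing by construction; the test
suite asserts this on every fit. Convergence is declared when the relative
objective change falls below `tol` (default `1e-8`) or after `max_iter`
(default 500) alternations; non-convergence is reported in the model
object, not raised as an error. With `n_free = 0` a single pass is already
the global optimum (the problem separates by row). Initialisation is
deterministic: scores are fitted against the fixed library first, and each
free row starts from the non-negative part of a leading singular vector of
the residual (a random start is available via `init = "random"`, which is
the only use of the model `seed`). An all-zero factor (for example the free
factor on data the library explains completely) keeps $a_j = 1$, is
flagged `degenerate`, and is retained so column counts are stable.

## Preprocessing

The chain is fixed: despike → baseline subtraction → clip negatives →
area-normalise. Stage tags on every spectrum enforce the order.

**Cosmic-ray removal** (`window = 11`, `z_threshold = 8`). Candidate
pixels are found from the modified z-score of the first differences: a
spike produces an extreme rise and an extreme fall a few pixels apart, so
opposite-sign extremes are paired, strongest first, within at most 4
pixels. Band flanks also produce extreme differences — steep, noiseless
synthetic bands essentially always do — which motivates two safeguards
settled during development: an interior extreme with no partner is treated
as a band flank, not a spike (only edge extremes may stand alone), and a
candidate is confirmed only if it exceeds the chord through its nearest
unflagged neighbours by more than three times the chord level (and the
noise scale). A cosmic ray is 20–100$\times$ the local intensity and
passes easily; a band apex never exceeds roughly 1$\times$ its chord,
because the flanks two or three pixels out still carry most of the band
height. Confirmed pixels are replaced by linear interpolation from
unflagged neighbours; everything else is returned bit-identical, and the
repair mask is attached to the result.

**Baseline subtraction** (`smoothness = 1e6`, `asymmetry = 0.01`).
Asymmetric least squares (a Whittaker smoother with asymmetric weights):
the baseline minimises a weighted fit penalised by squared second
differences, with weight `asymmetry` above the baseline and
`1 - asymmetry` below, so the smooth curve tracks the fluorescence floor
under the Raman bands. The penalty weight is the one parameter that
matters: at $10^5$ (a common choice on coarser grids) the baseline is
flexible enough on a 1 cm$^{-1}$ grid to climb into clusters of bands,
which measurably biases the downstream scores (study-analog recovery
dropped to a minimum per-factor correlation of 0.91); $10^6$ removes the
planted cubic fluorescence while leaving bands intact (minimum 0.975), and
is the default. Pushing to $10^8$ makes the baseline too stiff to follow
realistic fluorescence at all. The penalty matrix is cached per spectrum
length, so batch preprocessing costs about 15 ms per 1351-point spectrum.

**Normalisation.** Negative residuals after baseline subtraction are
clipped to zero (the factorisation requires non-negative input), then the
spectrum is divided by its trapezoidal area over the wavenumber axis.
Re-normalising an already unit-area spectrum is the exact identity.

The library receives the identical clip-and-normalise treatment as cell
spectra — without a shared scale convention the scores would be
scale-confounded.

## The synthetic generator

The generator emulates the study design so that every stage has a known
ground truth: 3 cell lines (H460 and MCF7 radioresistant, LNCaP
radiosensitive) × single fractions of 0, 2, 4, 6, 8, 10 Gy × days 1–3
post-irradiation × 3 replicate cultures × 20 cells per sample = 3240
spectra on a 450–1800 cm$^{-1}$ axis, decomposed over a 30-chemical
library.

**Reference spectra** are sums of 3–10 Gaussian peaks with widths of
5–15 cm$^{-1}$, area-normalised, resampled until pairwise correlations
stay below 0.8. Lineshape sharpness is a deliberate identifiability
choice, not a convenience: Lorentzian tails from ~180 overlapping peaks
build a smooth continuum (mixtures never dropping below ~30% of their mean)
that an asymmetric-least-squares baseline cannot distinguish from
fluorescence. Whatever estimator is used, that continuum is stripped with
the baseline and the broad factors become unrecoverable — by any pipeline,
not just this one. Crystalline reference biochemicals do show sharp bands
with near-zero inter-band signal, so the default is Gaussian-dominated
narrow bands; `lorentzian_frac` and `width_range` expose the broad-band
regime for stress-testing.

**Scores.** Each factor's mean follows
`base × line_mult[line] × (1 + dose_slope[line]·dose) × (1 + day_slope·day)`
with multiplicative lognormal noise (mean 1, CV 5% by default — Gaussian
noise could go negative). The `paper_analog` preset plants a glycogen-like
factor rising with dose in the resistant lines only, a glucose-like factor
negatively coupled to it (target Pearson $r = -0.7$ within the resistant
lines, imposed through the Gaussian copula by inverting the
bivariate-lognormal correlation formula so the *score-scale* correlation
hits the target), a strongly line-separating phosphatidylcholine-like
factor, a handful of mildly line- or dose-structured factors (asparagine-,
arginine-, lactose-, citric-acid-like), and flat nuisance factors. Each
column is rescaled to grand mean exactly 1, mirroring the model's
convention, so truth and fitted scores are directly comparable.

**Spectra.** The clean signal is `scores %*% library`. Raw mode adds, per
spectrum: a random positive cubic fluorescence baseline scaled to 0.5–2×
the mean signal; additive Gaussian noise with SD 3% of the mean clean
intensity (a high-quality 10-s acquisition on a cooled CCD); and a
Bernoulli(0.1) single-pixel cosmic spike of 20–100× the local intensity.
Because the pipeline area-normalises measured spectra, the truth object
also carries `true_scores_effective` — the planted scores divided by each
clean spectrum's area, regridded to grand mean 1 — which is what a
factorisation of normalised spectra should recover.

**What the generator does not emulate**, and hence what passing tests do
not show about real data: instrument response and wavenumber calibration
drift, detector-dependent noise (shot noise scales with signal; here it is
additive), Mie scattering ripple, the true vibrational band structure of
the 30 biochemicals and their strong real-world collinearity, cell-cycle
and morphology heterogeneity beyond lognormal score jitter, and the
unresolvable biological continuum discussed above. Results on real spectra
depend on those factors; the synthetic suite demonstrates correctness of
the algorithms, not field performance.

## Statistics and classification

* PCA is computed on the fully preprocessed spectra by SVD after column
  mean-centring, with a deterministic sign convention (largest-magnitude
  loading element positive). Loadings are matched to library spectra by
  absolute Pearson correlation — the absolute value handles PCA's sign
  ambiguity.
* Group summaries report mean, standard error (sample SD/$\sqrt{n}$; NA
  and a flag for singleton groups) per (cell line, dose, day) and factor.
* The glucose–glycogen association uses Pearson correlation ("linear"
  association is what the score trends suggest); dosed groups are compared
  with same-day, same-line 0 Gy controls by Welch's t-test (robust to
  unequal variances; a Wilcoxon alternative is available). No multiplicity
  correction is applied by default, with Benjamini–Hochberg behind a flag
  — the choice is left visible because conventions differ between labs.
* Classification uses `randomForest` with 200 trees and `mtry = 5`, a
  stratified 75/25 split (stratification stabilises the 2:1 class
  imbalance), and importance measured as mean decrease in *held-out*
  accuracy: over `n_models = 10` independently seeded split+fit repeats,
  each test-set column is permuted (`n_perm` repeats, averaged) and the
  accuracy drop recorded; the table reports mean ± SD over models. Mean
  node impurity is deliberately not the primary importance measure.
  Metrics are computed for both orientations of the positive class, since
  printed sensitivity/specificity tables are not always reconcilable with
  one orientation; the false-positive share of the total dataset is
  reported alongside. Display values round to one decimal, stored values
  never do.

## Problem sizes and numerical tolerances

The test suite and the acceptance script use: the full 3240-spectrum
study-analog simulation on the 1351-point default axis for recovery (one
fit, about a minute); a half-density axis for the PCA validation preset
(the loading-match property does not depend on grid density); 600 cells
for the correlation preset; 20 seeds × 10 models for the
classification/importance study with `n_perm = 3` (the importance ranking
stabilises well before 10 permutations at this sample size); and toys of
15–50 spectra for solver-oracle equivalence (the solver is checked against
an independent active-set implementation, `pracma::lsqnonneg`, to
$10^{-6}$ relative). Frobenius-invariance of the scale extraction is
asserted to $10^{-12}$, the mean-1 convention to $10^{-10}$, and area
normalisation to $10^{-12}$.

## Known limitations

* The group-restriction half of the general method (structured constraints
  on $W$) is out of scope; only basis restriction is implemented.
* Active-set NNLS is exact but serial per row; a GPU or multiplicative
  variant would scale better beyond ~10⁵ spectra.
* The free factor absorbs shared unmodelled signal, but per-spectrum
  baseline residuals are idiosyncratic and partially leak into scores;
  with the default settings this costs a few points of truth-vs-fitted
  correlation.
* Resampling is linear interpolation; band-limited resampling would be
  preferable for very coarse source grids.
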