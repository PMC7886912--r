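# gbrnmf

Basis-restricted non-negative matrix factorisation and radio-sensitivity
classification for single-cell Raman spectra.

## The problem

Single-cell Raman microspectroscopy can track how the biochemistry of tumour
cells shifts after ionising radiation — radioresistant lines, for instance,
accumulate glycogen with dose while glucose falls. Principal component
analysis, the traditional workhorse, returns loadings that mix many
biochemicals with positive and negative features, which makes attributing a
score trend to a single metabolite difficult. The alternative implemented
here constrains the factorisation with a library of reference spectra of
pure biochemicals: the spectra matrix **X** (one preprocessed cell spectrum
per row) is decomposed as

    X ≈ W A S

where most rows of **S** are *fixed* to the library spectra, one row is
estimated freely from the data (absorbing whatever the library misses),
everything is non-negative, and the positive diagonal **A** carries the
scale so that each score column of **W** has mean 1. A cell's score on the
"glycogen" factor is then directly the contribution of the glycogen
reference spectrum to that cell's spectrum. Downstream, the scores feed
group statistics (dose/day trends, glucose–glycogen correlation) and a
random forest that classifies cells as radiosensitive or radioresistant,
with permutation (mean-decrease-accuracy) importance identifying the
discriminating biochemicals.

The package covers the full chain for spectroscopists and chemometricians:

* **Preprocessing** — cosmic-ray removal, asymmetric-least-squares baseline
  subtraction, area normalisation (`preprocess_dataset()`).
* **Factorisation** — block-coordinate alternating non-negative least
  squares with fixed library rows and optional free factors
  (`fit_gbrnmf()`, `project_scores()`).
* **Score analytics** — PCA validation and loading-to-basis matching,
  group means ± SE, correlations, dose-vs-control tests (`run_pca()`,
  `match_loading_to_basis()`, `score_summary()`, `correlate_scores()`,
  `compare_to_control()`).
* **Classification** — stratified splits, random forests (200 trees,
  mtry 5), held-out permutation importance, OOB hyperparameter grids
  (`classify_radiosensitivity()` and friends).
* **Synthetic data** — a generator that emulates the study design
  (3 cell lines × doses 0–10 Gy × days 1–3 × 3 replicates × 20 cells)
  with known ground truth, so every stage is testable without instrument
  data (`simulate_raman_study()`).

## Worked example

```r
library(gbrnmf)

# simulate the study-analog dataset: raw spectra with fluorescence
# baselines, detector noise and cosmic-ray spikes, plus the 30-chemical
# reference library and the planted ground truth
sim <- simulate_raman_study("paper_analog", seed = 11, raw = TRUE)

pp  <- preprocess_dataset(sim$dataset)     # despike -> baseline -> area 1
fit <- fit_gbrnmf(pp, sim$library, n_free = 1)
fit
#> <gbrnmf> 3240 spectra, 30 fixed + 1 free factor(s); 2 iterations
#> (converged), final SSE 0.05401

# how well are the planted scores recovered through the full raw pipeline?
range(diag(cor(fit$W[, 1:30], sim$truth$true_scores_effective)))
#> [1] 0.9766741 0.9998154

# classify radio-sensitivity from the scores
report <- classify_radiosensitivity(model_scores(fit), seed = 11)
report$confusion
#> <confusion_matrix> observed (rows) x predicted (columns)
#>                 predicted
#> observed         radiosensitive radioresistant
#>   radiosensitive            270              0
#>   radioresistant              0            540
head(report$importance, 3)
#>              variable  mda_mean      mda_sd rank
#> 1 phosphatidylcholine 0.4458025 0.003408441    1
#> 2            glycogen 0.0000000 0.000000000    2
#> 3             glucose 0.0000000 0.000000000    3
```

Per-factor truth-vs-fitted correlations stay above 0.97 even though the
spectra passed through spike repair, baseline estimation and
renormalisation; the classifier separates the radiosensitive line
perfectly, and the planted line-separating phosphatidylcholine-like factor
dominates the permutation importance.

The full pipeline (simulate/ingest → preprocess → fit → analyse →
classify) can also be driven from a YAML config via `run_pipeline()` or the
thin command-line front end in `inst/cli/gbrnmf.R`.

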