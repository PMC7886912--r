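#' Generate a synthetic basis library
#'
#' Each reference spectrum is a sum of Gaussian (optionally Lorentzian)
#' peaks with random centres inside the axis, area-normalised like a
#' measured reference. Pairs of bases whose Pearson correlation exceeds
#' `max_cor` are resampled so the library is not degenerate.
#'
#' @param m Number of reference spectra (default 30).
#' @param axis Wavenumber axis.
#' @param names Labels for the rows; defaults to `basis_01` ...
#' @param peaks_range Range of peaks per basis (default 3-10).
#' @param width_range Peak full-width range in cm^-1 (default 5-15: sharp,
#'   baseline-separable bands as in crystalline reference compounds).
#' @param lorentzian_frac Probability that a peak is Lorentzian rather than
#'   Gaussian (default 0). Lorentzian tails add a broad continuum that no
#'   baseline estimator can attribute, so they are off by default; raise
#'   this to stress-test preprocessing.
#' @param max_cor Maximum allowed pairwise Pearson correlation (default 0.8).
#' @param seed Integer seed; the library is bit-reproducible given the seed.
#' @return A `basis_library`.
#' @export
generate_basis_library <- function(m = 30, axis = default_axis(),
                                   names = NULL, peaks_range = c(3, 10),
                                   width_range = c(5, 15),
                                   lorentzian_frac = 0,
                                   max_cor = 0.8, seed = 1L) {
  if (m < 1L) stop_gbr("gbr_parameter_error", "m must be >= 1")
  validate_axis(axis)
  if (is.null(names)) names <- sprintf("basis_%02d", seq_len(m))
  if (length(names) != m)
    stop_gbr("gbr_length_error", "need %d names, got %d", m, length(names))
  set.seed(seed)
  p <- length(axis)
  B <- matrix(0, m, p)
  max_attempts <- 200L
  for (i in seq_len(m)) {
    ok <- FALSE
    for (attempt in seq_len(max_attempts)) {
      y <- random_peak_spectrum(axis, peaks_range, width_range,
                                lorentzian_frac)
      y <- y / pracma::trapz(axis, y)
      if (i == 1L ||
          max(abs(cor(y, t(B[seq_len(i - 1L), , drop = FALSE])))) <= max_cor) {
        B[i, ] <- y
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop_gbr("gbr_decorrelation_error",
               "could not draw basis %d with pairwise correlation <= %.2f",
               i, max_cor)
  }
  basis_library(B, names, axis)
}

random_peak_spectrum <- function(axis, peaks_range, width_range,
                                 lorentzian_frac) {
  n_peaks <- sample(peaks_range[1]:peaks_range[2], 1L)
  centers <- runif(n_peaks, min(axis), max(axis))
  widths <- runif(n_peaks, width_range[1], width_range[2])
  heights <- runif(n_peaks, 0.2, 1)
  lorentz <- runif(n_peaks) < lorentzian_frac
  y <- numeric(length(axis))
  for (q in seq_len(n_peaks)) {
    d <- axis - centers[q]
    y <- y + if (lorentz[q]) {
      heights[q] * widths[q]^2 / (d^2 + widths[q]^2)
    } else {
      heights[q] * exp(-d^2 / (2 * (widths[q] / 2.355)^2))
    }
  }
  y
}

#' Generate the full-factorial study design
#'
#' One metadata row per cell spectrum: every combination of cell line, dose,
#' day and replicate culture, with `cells_per_sample` cells measured per
#' combination.
#'
#' @param lines Cell-line labels (default the three study lines).
#' @param doses Dose set in Gy (default 0, 2, 4, 6, 8, 10).
#' @param days Analysis days post irradiation (default 1-3).
#' @param replicates Replicate cultures per dose (default 3).
#' @param cells_per_sample Cells measured per sample (default 20).
#' @return Metadata data frame with columns cell_line, dose_gy, day,
#'   replicate, cell_id.
#' @export
generate_design <- function(lines = c("H460", "MCF7", "LNCaP"),
                            doses = c(0, 2, 4, 6, 8, 10), days = 1:3,
                            replicates = 3, cells_per_sample = 20) {
  if (!length(doses)) stop_gbr("gbr_parameter_error", "dose set is empty")
  if (!length(lines) || replicates < 1 || cells_per_sample < 1 || !length(days))
    stop_gbr("gbr_parameter_error", "all design counts must be >= 1")
  g <- expand.grid(cell = seq_len(cells_per_sample),
                   replicate = paste0("R", seq_len(replicates)),
                   day = days, dose_gy = doses, cell_line = lines,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta <- data.frame(cell_line = g$cell_line, dose_gy = g$dose_gy,
                     day = g$day, replicate = g$replicate,
                     cell_id = sprintf("%s_d%dGy_day%d_%s_c%02d",
                                       g$cell_line, g$dose_gy, g$day,
                                       g$replicate, g$cell))
  validate_metadata(meta)
}

#' Trend configuration for one factor
#'
#' Describes how a factor's mean score depends on the design:
#' `mean = base * line_mult[line] * (1 + dose_slope[line] * dose) *
#' (1 + day_slope * day)`.
#'
#' @param base Baseline score level.
#' @param dose_slope Per-Gy relative slope; scalar or named by cell line.
#' @param day_slope Per-day relative slope.
#' @param line_mult Line-specific multiplier; scalar or named by cell line.
#' @return A list usable as one entry of the `trends` argument of
#'   [simulate_score_trends()].
#' @export
trend <- function(base = 1, dose_slope = 0, day_slope = 0, line_mult = 1) {
  list(base = base, dose_slope = dose_slope, day_slope = day_slope,
       line_mult = line_mult)
}

per_line <- function(x, lines) {
  if (is.null(names(x))) return(rep(x[1], length(lines)))
  out <- x[lines]
  out[is.na(out)] <- 0
  unname(out)
}

#' Simulate ground-truth factor scores over a design
#'
#' Mean scores follow the per-factor trend model (see [trend()]);
#' multiplicative lognormal noise with coefficient of variation `cv`
#' (mean 1) keeps scores non-negative. Factor pairs can be coupled through
#' the underlying Gaussian copula so the population Pearson correlation of
#' the scores hits a target value; the Gaussian correlation is obtained by
#' inverting the bivariate-lognormal correlation formula. Each factor is
#' finally rescaled to grand mean exactly 1, mirroring the factorisation's
#' scale convention, so truth and fitted scores are directly comparable.
#'
#' @param design Metadata table from [generate_design()].
#' @param trends Named list of [trend()] entries, one per factor.
#' @param couplings Optional list of couplings, each
#'   `list(a = , b = , r = , lines = NULL)`: factors `a` and `b` get noise
#'   correlated to target score correlation `r` on rows of the given cell
#'   lines (all rows when `lines` is NULL).
#' @param cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @return An object of class `synthetic_truth`: list with `true_scores`
#'   (n x k, grand column means exactly 1), `design`, `trends`,
#'   `couplings`, `cv`, `seed`.
#' @export
simulate_score_trends <- function(design, trends, couplings = NULL,
                                  cv = 0.05, seed = 1L) {
  k <- length(trends)
  if (is.null(names(trends)) || anyDuplicated(names(trends)))
    stop_gbr("gbr_parameter_error", "trends must be a uniquely named list")
  n <- nrow(design)
  lines <- as.character(design$cell_line)
  mu <- matrix(0, n, k, dimnames = list(NULL, names(trends)))
  for (f in names(trends)) {
    tr <- trends[[f]]
    ds <- per_line(tr$dose_slope, lines)
    lm <- per_line(tr$line_mult, lines)
    mu[, f] <- tr$base * lm * (1 + ds * design$dose_gy) *
      (1 + tr$day_slope * design$day)
  }
  if (any(mu <= 0))
    stop_gbr("gbr_trend_error",
             "trend configuration forces non-positive mean scores")
  set.seed(seed)
  if (cv > 0) {
    sigma <- sqrt(log(1 + cv^2))
    Z <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, names(trends)))
    for (cp in couplings) {
      if (!all(c(cp$a, cp$b) %in% names(trends)))
        stop_gbr("gbr_parameter_error", "coupling names factors not in trends")
      rows <- if (is.null(cp$lines)) seq_len(n) else which(lines %in% cp$lines)
      # invert the bivariate-lognormal correlation for equal sigmas
      arg <- 1 + cp$r * (exp(sigma^2) - 1)
      if (arg <= 0)
        stop_gbr("gbr_parameter_error",
                 "target correlation %.2f unattainable at cv %.2f", cp$r, cv)
      rho <- log(arg) / sigma^2
      if (abs(rho) > 1)
        stop_gbr("gbr_parameter_error",
                 "target correlation %.2f unattainable at cv %.2f", cp$r, cv)
      Z[rows, cp$b] <- rho * Z[rows, cp$a] +
        sqrt(1 - rho^2) * Z[rows, cp$b]
    }
    scores <- mu * exp(sigma * Z - sigma^2 / 2)
  } else {
    if (length(couplings) && any(vapply(couplings, `[[`, 0, "r") != 0))
      stop_gbr("gbr_parameter_error", "couplings require cv > 0")
    scores <- mu
  }
  scores <- sweep(scores, 2L, colMeans(scores), "/")
  structure(list(true_scores = scores, design = design, trends = trends,
                 couplings = couplings, cv = cv, seed = seed),
            class = "synthetic_truth")
}

#' Synthesise Raman spectra from ground-truth scores
#'
#' The clean signal of each cell is the score-weighted mixture of the
#' library spectra. With `raw = TRUE` the generator adds, per spectrum, a
#' smooth fluorescence-like baseline (random cubic polynomial with positive
#' coefficients, scaled to 0.5-2 times the mean signal), additive Gaussian
#' detector noise, and occasional single-pixel cosmic-ray spikes - the
#' artefacts the preprocessing chain is built to remove.
#'
#' Because the pipeline area-normalises every measured spectrum, the truth
#' object gains `true_scores_effective`: the planted scores divided by each
#' clean spectrum's area and rescaled to grand mean 1. These, not the raw
#' planted scores, are what a factorisation of preprocessed spectra should
#' recover.
#'
#' @param truth A `synthetic_truth` whose factor names match the library.
#' @param library A `basis_library` with one row per truth factor.
#' @param raw If TRUE, emit raw spectra with baseline/noise/spikes; if
#'   FALSE, emit the clean mixtures.
#' @param noise_sd_frac Additive noise SD as a fraction of each spectrum's
#'   mean clean intensity (default 0.03).
#' @param baseline_range Baseline mean as a multiple of the mean clean
#'   signal, drawn uniformly from this range (default 0.5-2).
#' @param spike_prob Per-spectrum probability of one cosmic-ray spike
#'   (default 0.1).
#' @param spike_range Spike magnitude in multiples of the local intensity
#'   (default 20-100).
#' @param keep_clean If TRUE, the clean mixture matrix is returned as
#'   element `clean`.
#' @param seed Integer seed.
#' @return List with `dataset` (a `spectral_dataset`, stage "raw" or
#'   "baselined"), `truth` (with `true_scores_effective` added) and
#'   optionally `clean`.
#' @export
synthesize_spectra <- function(truth, library, raw = TRUE,
                               noise_sd_frac = 0.03,
                               baseline_range = c(0.5, 2),
                               spike_prob = 0.1, spike_range = c(20, 100),
                               keep_clean = FALSE, seed = 1L) {
  W <- truth$true_scores
  if (ncol(W) != nrow(library$B))
    stop_gbr("gbr_length_error",
             "truth has %d factors but the library has %d spectra",
             ncol(W), nrow(library$B))
  axis <- library$axis
  p <- length(axis)
  clean <- W %*% library$B
  areas <- apply(clean, 1L, function(y) pracma::trapz(axis, y))
  eff <- W / areas
  eff <- sweep(eff, 2L, colMeans(eff), "/")
  truth$true_scores_effective <- eff

  if (raw) {
    set.seed(seed)
    Y <- clean
    t01 <- seq(0, 1, length.out = p)
    spiked <- integer(0)
    for (i in seq_len(nrow(Y))) {
      cf <- runif(4)
      b <- cf[1] + cf[2] * t01 + cf[3] * t01^2 + cf[4] * t01^3
      b <- b * runif(1, baseline_range[1], baseline_range[2]) *
        mean(clean[i, ]) / mean(b)
      y <- clean[i, ] + b +
        rnorm(p, 0, noise_sd_frac * mean(clean[i, ]))
      if (runif(1) < spike_prob) {
        j <- sample.int(p, 1L)
        local <- median(y[max(1, j - 5):min(p, j + 5)])
        y[j] <- y[j] + runif(1, spike_range[1], spike_range[2]) *
          max(local, 0.05 * mean(y))
        spiked <- c(spiked, i)
      }
      Y[i, ] <- y
    }
    ds <- spectral_dataset(Y, axis, truth$design, stage = "raw")
    attr(ds, "spiked_rows") <- spiked
  } else {
    ds <- spectral_dataset(clean, axis, truth$design, stage = "baselined")
  }
  out <- list(dataset = ds, truth = truth)
  if (keep_clean) out$clean <- clean
  out
}

paper_analog_factors <- c(
  "glycogen", "glucose", "phosphatidylcholine", "asparagine", "arginine",
  "lactose", "citric_acid", "glutamic_acid", "glutathione",
  "phosphatidylserine", "dna", "rna", "actin", "collagen", "albumin",
  "phenylalanine", "tryptophan", "tyrosine", "glycine", "alanine",
  "leucine", "serine", "threonine", "histidine", "cholesterol", "triolein",
  "phosphatidylethanolamine", "sphingomyelin", "fructose", "sucrose")

#' Built-in simulation presets
#'
#' Returns the full configuration (design sizes, per-factor trends,
#' couplings, noise level) of one of the named study-analog presets:
#'
#' * `"paper_analog"` - the full study design (3 cell lines x doses
#'   0-10 Gy x days 1-3 x 3 replicates x 20 cells = 3240 spectra) over a
#'   30-chemical library. Plants a glycogen-like factor rising with dose in
#'   the radioresistant lines only, a glucose-like factor negatively coupled
#'   to it (target r = -0.7 in the resistant lines), a strongly
#'   line-separating phosphatidylcholine-like factor, several mildly
#'   line-structured factors, and flat nuisance factors. Score CV 5%.
#' * `"glycogen_dominated"` - same design with the glycogen dose trend
#'   steepened and all other variation shrunk (CV 2%), so a single factor
#'   carries the bulk of the spectral variance; used to validate PCA
#'   loading-to-basis matching.
#' * `"coupled_pair"` - two factors on 600 cells of one line with no
#'   trends and score correlation planted at r = -0.7 (CV 20%); used to
#'   validate the correlation estimator.
#'
#' @param name Preset name.
#' @return List with elements `lines`, `doses`, `days`, `replicates`,
#'   `cells_per_sample`, `factors`, `trends`, `couplings`, `cv`.
#' @export
synthetic_preset <- function(name = c("paper_analog", "glycogen_dominated",
                                      "coupled_pair")) {
  name <- match.arg(name)
  if (name == "coupled_pair") {
    return(list(name = name, lines = "H460", doses = 0, days = 1,
                replicates = 1, cells_per_sample = 600,
                factors = c("glycogen", "glucose"),
                trends = list(glycogen = trend(), glucose = trend()),
                couplings = list(list(a = "glycogen", b = "glucose",
                                      r = -0.7, lines = NULL)),
                cv = 0.2))
  }
  resistant <- c("H460", "MCF7")
  trends <- stats::setNames(rep(list(trend()), length(paper_analog_factors)),
                            paper_analog_factors)
  if (name == "paper_analog") {
    trends$glycogen <- trend(dose_slope = c(H460 = 0.10, MCF7 = 0.07, LNCaP = 0),
                             day_slope = 0.05)
    trends$glucose <- trend(dose_slope = c(H460 = -0.04, MCF7 = -0.04, LNCaP = 0),
                            line_mult = c(H460 = 0.8, MCF7 = 1.3, LNCaP = 1.1))
    trends$phosphatidylcholine <-
      trend(line_mult = c(H460 = 1.5, MCF7 = 1.4, LNCaP = 0.4))
    trends$asparagine <- trend(line_mult = c(H460 = 1.15, MCF7 = 0.95, LNCaP = 0.85),
                               dose_slope = c(H460 = 0.03, MCF7 = 0, LNCaP = 0))
    trends$arginine <- trend(line_mult = c(H460 = 1.1, MCF7 = 0.95, LNCaP = 0.9))
    trends$lactose <- trend(line_mult = c(H460 = 1.3, MCF7 = 0.85, LNCaP = 0.85),
                            dose_slope = c(H460 = -0.02, MCF7 = 0, LNCaP = 0))
    trends$citric_acid <- trend(dose_slope = c(H460 = -0.03, MCF7 = -0.03,
                                               LNCaP = 0))
    trends$glutamic_acid <- trend(line_mult = c(H460 = 0.95, MCF7 = 1.15,
                                                LNCaP = 0.95))
    trends$glutathione <- trend(line_mult = c(H460 = 0.95, MCF7 = 1.1,
                                              LNCaP = 0.95))
    trends$phosphatidylserine <- trend(line_mult = c(H460 = 1.05, MCF7 = 1.05,
                                                     LNCaP = 0.9))
    couplings <- list(list(a = "glycogen", b = "glucose", r = -0.7,
                           lines = resistant))
    cv <- 0.05
  } else {                               # glycogen_dominated
    trends$glycogen <- trend(dose_slope = c(H460 = 0.15, MCF7 = 0.12, LNCaP = 0),
                             day_slope = 0.05)
    couplings <- NULL
    cv <- 0.02
  }
  list(name = name, lines = c("H460", "MCF7", "LNCaP"),
       doses = c(0, 2, 4, 6, 8, 10), days = 1:3, replicates = 3,
       cells_per_sample = 20, factors = paper_analog_factors,
       trends = trends, couplings = couplings, cv = cv)
}

#' One-call simulation of a study-analog dataset
#'
#' Builds the design, a synthetic basis library named after the preset's
#' factors, ground-truth scores, and (optionally) the spectra.
#'
#' @param preset Preset name, see [synthetic_preset()].
#' @param seed Integer base seed (library, scores and spectra use
#'   `seed`, `seed + 1`, `seed + 2`).
#' @param raw Passed to [synthesize_spectra()].
#' @param axis Wavenumber axis for the library and spectra.
#' @param spectra If FALSE, skip spectrum synthesis and return scores only
#'   (fast path for classification studies).
#' @param ... Overrides for the preset's design fields (e.g.
#'   `cells_per_sample = 5`).
#' @return List with `design`, `library` (NULL when `spectra = FALSE`),
#'   `truth`, `dataset` (NULL when `spectra = FALSE`) and `preset`.
#' @export
simulate_raman_study <- function(preset = "paper_analog", seed = 1L,
                                 raw = TRUE, axis = default_axis(),
                                 spectra = TRUE, ...) {
  cfg <- synthetic_preset(preset)
  cfg <- modifyList(cfg, list(...))
  design <- generate_design(lines = cfg$lines, doses = cfg$doses,
                            days = cfg$days, replicates = cfg$replicates,
                            cells_per_sample = cfg$cells_per_sample)
  truth <- simulate_score_trends(design, cfg$trends, cfg$couplings,
                                 cv = cfg$cv, seed = seed + 1L)
  out <- list(design = design, truth = truth, preset = cfg,
              library = NULL, dataset = NULL)
  if (spectra) {
    out$library <- generate_basis_library(length(cfg$factors), axis,
                                          names = cfg$factors, seed = seed)
    syn <- synthesize_spectra(truth, out$library, raw = raw, seed = seed + 2L)
    out$dataset <- syn$dataset
    out$truth <- syn$truth
  }
  out
}
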