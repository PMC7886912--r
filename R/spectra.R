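#' Default wavenumber axis
#'
#' The fingerprint-region acquisition window used throughout the package:
#' 450 to 1800 cm^-1. The default spacing of 1 cm^-1 is typical of a
#' 600 lines/mm grating dispersive Raman system.
#'
#' @param from,to Window limits in cm^-1.
#' @param by Grid spacing in cm^-1.
#' @return Numeric vector of strictly increasing Raman shifts.
#' @export
default_axis <- function(from = 450, to = 1800, by = 1) {
  validate_axis(seq(from, to, by = by))
}

#' Validate a wavenumber axis
#'
#' @param axis Numeric vector of Raman shifts (cm^-1).
#' @return The axis, invisibly unchanged, if valid.
#' @export
validate_axis <- function(axis) {
  if (!is.numeric(axis) || length(axis) < 2L)
    stop_gbr("gbr_axis_error", "axis must be numeric with at least 2 points")
  if (any(!is.finite(axis)))
    stop_gbr("gbr_axis_error", "axis contains non-finite values")
  if (any(diff(axis) <= 0))
    stop_gbr("gbr_axis_error", "axis must be strictly increasing")
  axis
}

#' Construct a Raman spectrum
#'
#' A spectrum is a wavenumber axis plus intensities and a processing-stage
#' tag. Stages advance in the fixed order raw -> despiked -> baselined ->
#' normalized; the preprocessing functions enforce the order.
#'
#' @param wavenumber Strictly increasing Raman shifts (cm^-1).
#' @param intensity Intensities, same length as `wavenumber`.
#' @param stage Processing stage, one of "raw", "despiked", "baselined",
#'   "normalized".
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(wavenumber, intensity,
                           stage = c("raw", "despiked", "baselined", "normalized")) {
  stage <- match.arg(stage)
  validate_axis(wavenumber)
  if (length(intensity) != length(wavenumber))
    stop_gbr("gbr_length_error", "intensity length (%d) != axis length (%d)",
             length(intensity), length(wavenumber))
  if (any(!is.finite(intensity)))
    stop_gbr("gbr_value_error", "intensity contains non-finite values")
  structure(list(wavenumber = as.numeric(wavenumber),
                 intensity = as.numeric(intensity),
                 stage = stage),
            class = "raman_spectrum")
}

#' @exportS3Method print raman_spectrum
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d points, %.0f-%.0f cm^-1, stage: %s\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
              x$stage))
  invisible(x)
}

#' Trapezoidal area under a spectrum
#'
#' @param spectrum A `raman_spectrum`.
#' @return Area under the intensity curve over the wavenumber axis.
#' @export
spectrum_area <- function(spectrum) {
  pracma::trapz(spectrum$wavenumber, spectrum$intensity)
}

required_meta_cols <- c("cell_line", "dose_gy", "day", "replicate", "cell_id")

validate_metadata <- function(meta, n = NULL) {
  if (!is.data.frame(meta))
    stop_gbr("gbr_metadata_error", "metadata must be a data.frame")
  missing_cols <- setdiff(required_meta_cols, names(meta))
  if (length(missing_cols))
    stop_gbr("gbr_metadata_error", "metadata missing required column(s): %s",
             paste(missing_cols, collapse = ", "))
  if (!is.null(n) && nrow(meta) != n)
    stop_gbr("gbr_rowcount_error",
             "metadata has %d rows but the matrix has %d spectra", nrow(meta), n)
  if (any(meta$dose_gy < 0))
    stop_gbr("gbr_metadata_error", "dose_gy must be non-negative")
  key <- do.call(paste, c(meta[required_meta_cols], sep = "\r"))
  if (anyDuplicated(key))
    stop_gbr("gbr_metadata_error",
             "duplicate (cell_line, dose_gy, day, replicate, cell_id) rows")
  meta
}

#' Construct a spectral dataset
#'
#' Bundles a spectra matrix (rows = spectra) on a shared axis with per-row
#' experimental metadata.
#'
#' @param X Numeric matrix, one spectrum per row, `length(axis)` columns.
#' @param axis Shared wavenumber axis.
#' @param meta Data frame with columns cell_line, dose_gy, day, replicate,
#'   cell_id; one row per spectrum, joined by row order.
#' @param stage Processing stage of the rows of `X`.
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(X, axis, meta,
                             stage = c("raw", "despiked", "baselined", "normalized")) {
  stage <- match.arg(stage)
  validate_axis(axis)
  X <- as.matrix(X)
  if (ncol(X) != length(axis))
    stop_gbr("gbr_length_error", "X has %d columns but axis has %d points",
             ncol(X), length(axis))
  if (any(!is.finite(X)))
    stop_gbr("gbr_value_error", "X contains non-finite values")
  validate_metadata(meta, n = nrow(X))
  if (stage == "normalized") {
    areas <- apply(X, 1L, function(y) pracma::trapz(axis, y))
    if (any(X < 0) || any(abs(areas - 1) > 1e-9))
      stop_gbr("gbr_stage_error",
               "stage 'normalized' requires non-negative rows with unit area")
  }
  structure(list(X = X, axis = as.numeric(axis),
                 meta = as.data.frame(meta), stage = stage),
            class = "spectral_dataset")
}

#' @exportS3Method print spectral_dataset
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d spectra x %d points (%.0f-%.0f cm^-1), stage: %s\n",
              nrow(x$X), ncol(x$X), min(x$axis), max(x$axis), x$stage))
  cat(sprintf("  cell lines: %s; doses (Gy): %s; days: %s\n",
              paste(unique(x$meta$cell_line), collapse = ", "),
              paste(sort(unique(x$meta$dose_gy)), collapse = ", "),
              paste(sort(unique(x$meta$day)), collapse = ", ")))
  invisible(x)
}

#' Construct a basis library
#'
#' Named reference spectra of pure biochemicals forming the fixed rows of
#' the factorisation basis. Rows are expected to have been preprocessed
#' identically to cell spectra (non-negative, unit area).
#'
#' @param B Numeric matrix, one reference spectrum per row.
#' @param names Unique labels, one per row (chemical names).
#' @param axis Wavenumber axis shared with the datasets it will model.
#' @return An object of class `basis_library`.
#' @export
basis_library <- function(B, names, axis) {
  validate_axis(axis)
  B <- as.matrix(B)
  if (nrow(B) < 1L)
    stop_gbr("gbr_length_error", "basis library must have at least one spectrum")
  if (ncol(B) != length(axis))
    stop_gbr("gbr_length_error", "B has %d columns but axis has %d points",
             ncol(B), length(axis))
  if (length(names) != nrow(B))
    stop_gbr("gbr_length_error", "need one name per basis row")
  if (anyDuplicated(names))
    stop_gbr("gbr_duplicate_name_error", "duplicate basis names: %s",
             paste(unique(names[duplicated(names)]), collapse = ", "))
  if (any(B < 0) || any(!is.finite(B)))
    stop_gbr("gbr_value_error", "basis spectra must be finite and non-negative")
  rownames(B) <- names
  structure(list(B = B, names = as.character(names), axis = as.numeric(axis)),
            class = "basis_library")
}

#' @exportS3Method print basis_library
print.basis_library <- function(x, ...) {
  cat(sprintf("<basis_library> %d reference spectra x %d points (%.0f-%.0f cm^-1)\n",
              nrow(x$B), ncol(x$B), min(x$axis), max(x$axis)))
  invisible(x)
}

#' Read a two-column spectrum file
#'
#' Delimited text with wavenumber in the first column and intensity in the
#' second; lines starting with '#' are comments.
#'
#' @param path File path.
#' @param stage Stage tag to record on the returned spectrum.
#' @return A `raman_spectrum`.
#' @export
read_spectrum <- function(path, stage = "raw") {
  tab <- read.table(path, header = FALSE, comment.char = "#")
  if (ncol(tab) < 2L)
    stop_gbr("gbr_io_error", "spectrum file '%s' needs two columns", path)
  raman_spectrum(tab[[1]], tab[[2]], stage = stage)
}

#' Write a spectrum as two-column text
#'
#' @param spectrum A `raman_spectrum`.
#' @param path Output path.
#' @param digits Significant digits for formatting.
#' @export
write_spectrum <- function(spectrum, path, digits = 10) {
  lines <- sprintf("%.*g %.*g", digits, spectrum$wavenumber,
                   digits, spectrum$intensity)
  writeLines(c("# wavenumber_cm-1 intensity", lines), path)
  invisible(path)
}

#' Load a spectral dataset from matrix + metadata CSV
#'
#' The matrix CSV has the wavenumber axis as its header row and one spectrum
#' per data row; the metadata CSV has one row per spectrum (matched by row
#' order) with columns cell_line, dose_gy, day, replicate, cell_id.
#'
#' @param matrix_path Path to the spectra matrix CSV.
#' @param metadata_path Path to the metadata CSV.
#' @param stage Stage the stored spectra are in (from the file's provenance).
#' @return A `spectral_dataset`.
#' @export
load_dataset <- function(matrix_path, metadata_path, stage = "raw") {
  mat <- as.matrix(read.csv(matrix_path, header = TRUE, comment.char = "#",
                            check.names = FALSE))
  axis <- suppressWarnings(as.numeric(colnames(mat)))
  if (any(is.na(axis)))
    stop_gbr("gbr_axis_error",
             "matrix CSV header must be numeric wavenumbers in '%s'", matrix_path)
  meta <- read.csv(metadata_path, comment.char = "#", check.names = FALSE)
  spectral_dataset(mat, axis, meta, stage = stage)
}

#' Write a spectral dataset
#'
#' @param dataset A `spectral_dataset`.
#' @param matrix_path,metadata_path Output CSV paths.
#' @param header_comment Optional '#'-prefixed provenance line written first.
#' @export
write_dataset <- function(dataset, matrix_path, metadata_path,
                          header_comment = NULL) {
  write_csv_commented(as.data.frame(dataset$X, check.names = FALSE) |>
                        stats::setNames(format(dataset$axis, trim = TRUE)),
                      matrix_path, header_comment)
  write_csv_commented(dataset$meta[required_meta_cols], metadata_path,
                      header_comment)
  invisible(matrix_path)
}

write_csv_commented <- function(df, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Load a basis library from spectrum files
#'
#' Each file is read, resampled to the target axis, and put through the same
#' clip-and-normalise treatment as cell spectra so that scores are on a
#' common scale.
#'
#' @param paths Character vector of two-column spectrum files.
#' @param names Unique labels, one per file.
#' @param axis Target wavenumber axis (the dataset axis).
#' @return A `basis_library` with unit-area rows.
#' @export
load_library <- function(paths, names, axis) {
  if (length(paths) != length(names))
    stop_gbr("gbr_length_error", "need one name per file")
  if (anyDuplicated(names))
    stop_gbr("gbr_duplicate_name_error", "duplicate basis names: %s",
             paste(unique(names[duplicated(names)]), collapse = ", "))
  validate_axis(axis)
  B <- matrix(0, length(paths), length(axis))
  for (i in seq_along(paths)) {
    s <- read_spectrum(paths[i], stage = "baselined")
    s <- resample_to_axis(s, axis)
    s <- normalize_area(s)
    B[i, ] <- s$intensity
  }
  basis_library(B, names, axis)
}

#' Resample a spectrum onto a target axis
#'
#' Linear interpolation; the target range must lie within the source range
#' (no extrapolation). Identity when the axes are equal.
#'
#' @param spectrum A `raman_spectrum`.
#' @param target Target wavenumber axis.
#' @return A `raman_spectrum` on `target`, same stage.
#' @export
resample_to_axis <- function(spectrum, target) {
  validate_axis(target)
  src <- spectrum$wavenumber
  if (length(target) == length(src) && all(target == src)) return(spectrum)
  if (min(target) < min(src) || max(target) > max(src))
    stop_gbr("gbr_coverage_error",
             "target axis [%.1f, %.1f] extends beyond source [%.1f, %.1f]",
             min(target), max(target), min(src), max(src))
  y <- stats::approx(src, spectrum$intensity, xout = target, method = "linear")$y
  raman_spectrum(target, y, stage = spectrum$stage)
}

#' Remove cosmic-ray spikes from a spectrum
#'
#' Spikes are located from the modified z-score of the first differences:
#' a cosmic ray produces a paired extreme rise and fall of the difference
#' series. Candidate pixels bracketed by such extremes are confirmed by
#' requiring their departure from the chord through the nearest unflagged
#' neighbours to exceed both the noise scale and the local band curvature,
#' so genuine Raman bands (whose flanks and apices also produce large
#' differences) are left untouched. Confirmed pixels are replaced by linear
#' interpolation from unflagged neighbours; all other pixels are unchanged.
#'
#' @param spectrum A `raman_spectrum` at stage "raw".
#' @param window Odd pixel count bounding the width of a spike and the
#'   repair neighbourhood.
#' @param z_threshold Modified z-score threshold on the first differences.
#' @return Despiked `raman_spectrum` (stage "despiked") with attribute
#'   `"spike_mask"`, a logical vector marking repaired pixels.
#' @export
remove_cosmic_rays <- function(spectrum, window = 11, z_threshold = 8) {
  if (spectrum$stage != "raw")
    stop_gbr("gbr_stage_error", "despiking expects a raw spectrum, got '%s'",
             spectrum$stage)
  p <- length(spectrum$intensity)
  if (window >= p)
    stop_gbr("gbr_window_error", "window (%d) must be smaller than the spectrum (%d)",
             window, p)
  if (window %% 2 == 0) window <- window + 1L

  y <- spectrum$intensity
  d <- diff(y)
  s <- mad(d)
  if (s == 0) s <- .Machine$double.eps
  z <- 0.6745 * (d - median(d)) / s

  ext <- abs(z) > z_threshold
  mask <- rep(FALSE, p)
  if (any(ext)) {
    # a cosmic ray spans at most a few pixels; band flanks produce extreme
    # differences too, but their rise and fall are much further apart.
    # Pair opposite-sign extremes, strongest first so a spike's own
    # rise/fall pair wins over any nearby band-flank extreme; the pixels
    # strictly between a pair are candidates.
    half <- min((window - 1L) %/% 2L, 4L)
    idx <- which(ext)
    ord <- idx[order(-abs(z[idx]))]
    used <- logical(p)
    for (j1 in ord) {
      if (used[j1]) next
      partners <- idx[!used[idx] & idx != j1 & abs(idx - j1) <= half &
                        sign(z[idx]) != sign(z[j1])]
      if (length(partners)) {
        j2 <- partners[order(abs(partners - j1), -abs(z[partners]))][1]
        mask[(min(j1, j2) + 1L):max(j1, j2)] <- TRUE
        used[c(j1, j2)] <- TRUE
      } else if (j1 <= half || j1 >= p - half) {
        # an unpaired extreme at the spectrum edge can still be a spike;
        # in the interior an unpaired extreme is a band flank, not a spike
        mask[c(j1, j1 + 1L)] <- TRUE
        used[j1] <- TRUE
      }
    }
    # confirmation: a cosmic ray towers over the chord through its nearest
    # non-candidate neighbours by a multiple of the local signal level,
    # whereas a Raman band apex never exceeds ~1x its chord (the flanks a
    # few pixels out still carry most of the band height); noise excursions
    # are screened by the difference scale
    cand <- which(mask)
    keep <- rep(FALSE, length(cand))
    sigma_d <- s / 0.6745
    for (t in seq_along(cand)) {
      i <- cand[t]
      b <- chord_value(y, mask, i)
      keep[t] <- abs(y[i] - b) > max(3 * abs(b), z_threshold * sigma_d)
    }
    mask[cand] <- keep
    # repair by interpolation from unflagged neighbours
    if (any(mask)) {
      good <- which(!mask)
      y[mask] <- stats::approx(good, y[good], xout = which(mask),
                               method = "linear", rule = 2)$y
    }
  }
  out <- raman_spectrum(spectrum$wavenumber, y, stage = "despiked")
  attr(out, "spike_mask") <- mask
  out
}

# linear interpolation at pixel i from the nearest pixels outside `excl`
chord_value <- function(y, excl, i) {
  left <- i - 1L
  while (left >= 1L && excl[left]) left <- left - 1L
  right <- i + 1L
  while (right <= length(y) && excl[right]) right <- right + 1L
  if (left < 1L) return(y[right])
  if (right > length(y)) return(y[left])
  y[left] + (y[right] - y[left]) * (i - left) / (right - left)
}

#' Subtract a fluorescence/substrate baseline
#'
#' Asymmetric least squares (Whittaker smoother with asymmetric weights):
#' the baseline minimises a weighted least-squares fit penalised by the
#' squared second differences, with weight `asymmetry` on points above the
#' baseline and `1 - asymmetry` below, so the smooth curve hugs the valleys
#' under the Raman peaks.
#'
#' @param spectrum A `raman_spectrum` (stage "despiked" or "raw").
#' @param smoothness Second-difference penalty weight (lambda); larger is
#'   stiffer. Default 1e6.
#' @param asymmetry Weight for points above the baseline (p); default 0.01.
#' @param max_iter Weight-reweighting iterations.
#' @return Baseline-subtracted `raman_spectrum` (stage "baselined") with
#'   attribute `"baseline"` holding the estimate.
#' @export
subtract_baseline <- function(spectrum, smoothness = 1e6, asymmetry = 0.01,
                              max_iter = 10) {
  if (!spectrum$stage %in% c("raw", "despiked"))
    stop_gbr("gbr_stage_error",
             "baseline subtraction expects a raw or despiked spectrum, got '%s'",
             spectrum$stage)
  if (smoothness <= 0)
    stop_gbr("gbr_parameter_error", "smoothness must be positive")
  if (asymmetry <= 0 || asymmetry >= 1)
    stop_gbr("gbr_parameter_error", "asymmetry must be in (0, 1)")
  y <- spectrum$intensity
  b <- als_baseline(y, lambda = smoothness, p = asymmetry, max_iter = max_iter)
  out <- raman_spectrum(spectrum$wavenumber, y - b, stage = "baselined")
  attr(out, "baseline") <- b
  out
}

# Whittaker/ALS smoother; DtD is cached per spectrum length across calls
als_env <- new.env(parent = emptyenv())

als_baseline <- function(y, lambda, p, max_iter = 10) {
  n <- length(y)
  key <- as.character(n)
  if (is.null(als_env[[key]])) {
    D <- Matrix::bandSparse(n - 2, n,
                            k = 0:2,
                            diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                             rep(1, n - 2)))
    als_env[[key]] <- Matrix::crossprod(D)
  }
  P <- lambda * als_env[[key]]
  w <- rep(1, n)
  b <- y
  for (it in seq_len(max_iter)) {
    Wd <- Matrix::Diagonal(n, w)
    b <- as.numeric(Matrix::solve(Wd + P, w * y))
    w_new <- ifelse(y > b, p, 1 - p)
    if (all(w_new == w)) break
    w <- w_new
  }
  b
}

#' Normalise a spectrum to unit area
#'
#' Negative residual values (possible after baseline subtraction) are
#' clipped to zero, then the spectrum is divided by its trapezoidal area
#' over the wavenumber axis.
#'
#' @param spectrum A `raman_spectrum` (any stage except already-normalized
#'   input is also accepted; normalisation is idempotent).
#' @return Unit-area `raman_spectrum` (stage "normalized").
#' @export
normalize_area <- function(spectrum) {
  y <- pmax(spectrum$intensity, 0)
  a <- pracma::trapz(spectrum$wavenumber, y)
  if (a <= 0)
    stop_gbr("gbr_zero_spectrum_error",
             "cannot area-normalise an all-zero (or all-negative) spectrum")
  # exact idempotence: re-normalising an already unit-area spectrum is the
  # identity (dividing by 1 + eps would perturb the last bits)
  if (abs(a - 1) > 1e-12) y <- y / a
  raman_spectrum(spectrum$wavenumber, y, stage = "normalized")
}

#' Preprocess a single spectrum through the full chain
#'
#' despike -> baseline subtraction -> clip/normalise, in that fixed order.
#'
#' @param spectrum A raw `raman_spectrum`.
#' @param despike_window,despike_z Cosmic-ray removal parameters.
#' @param smoothness,asymmetry Baseline parameters.
#' @return Unit-area `raman_spectrum`.
#' @export
preprocess_spectrum <- function(spectrum, despike_window = 11, despike_z = 8,
                                smoothness = 1e6, asymmetry = 0.01) {
  s <- remove_cosmic_rays(spectrum, window = despike_window,
                          z_threshold = despike_z)
  s <- subtract_baseline(s, smoothness = smoothness, asymmetry = asymmetry)
  normalize_area(s)
}

#' Preprocess a raw dataset
#'
#' Applies the fixed chain despike -> baseline -> clip/normalise to every
#' spectrum and reassembles the matrix. A failure in any spectrum is
#' re-raised with that spectrum's row index and cell id attached.
#'
#' @param dataset A `spectral_dataset` at stage "raw".
#' @param despike_window,despike_z,smoothness,asymmetry Chain parameters,
#'   see [remove_cosmic_rays()] and [subtract_baseline()].
#' @return A `spectral_dataset` at stage "normalized" with attribute
#'   `"n_spikes"`, the per-spectrum count of repaired pixels.
#' @export
preprocess_dataset <- function(dataset, despike_window = 11, despike_z = 8,
                               smoothness = 1e6, asymmetry = 0.01) {
  if (dataset$stage != "raw")
    stop_gbr("gbr_stage_error", "preprocess_dataset expects a raw dataset")
  n <- nrow(dataset$X)
  out <- matrix(0, n, ncol(dataset$X))
  n_spikes <- integer(n)
  for (i in seq_len(n)) {
    s <- tryCatch(
      {
        sp <- raman_spectrum(dataset$axis, dataset$X[i, ], stage = "raw")
        sp <- remove_cosmic_rays(sp, window = despike_window,
                                 z_threshold = despike_z)
        n_spikes[i] <- sum(attr(sp, "spike_mask"))
        sp <- subtract_baseline(sp, smoothness = smoothness,
                                asymmetry = asymmetry)
        normalize_area(sp)
      },
      gbrnmf_error = function(e) {
        stop_gbr("gbr_spectrum_error",
                 "preprocessing failed for spectrum %d (cell_id '%s'): %s",
                 i, dataset$meta$cell_id[i], conditionMessage(e))
      })
    out[i, ] <- s$intensity
  }
  ds <- spectral_dataset(out, dataset$axis, dataset$meta, stage = "normalized")
  attr(ds, "n_spikes") <- n_spikes
  ds
}
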