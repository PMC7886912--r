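test_that("dataset IO round-trips and rejects malformed inputs", {
  axis <- coarse_axis(50)
  X <- matrix(runif(2 * length(axis)), 2)
  ds <- spectral_dataset(X, axis, tiny_meta(2), stage = "raw")
  mp <- withr::local_tempfile(fileext = ".csv")
  dp <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, mp, dp)
  back <- load_dataset(mp, dp, stage = "raw")
  expect_equal(back$X, ds$X, ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(back$axis, axis)
  expect_equal(back$meta$cell_id, ds$meta$cell_id)

  # metadata row-count mismatch
  expect_error(spectral_dataset(X, axis, tiny_meta(3), stage = "raw"),
               class = "gbr_rowcount_error")
  # decreasing header axis
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("500,450", "1,2", "3,4"), bad)
  expect_error(load_dataset(bad, dp), class = "gbr_axis_error")
  # missing metadata column
  m2 <- tiny_meta(2)
  m2$cell_line <- NULL
  expect_error(spectral_dataset(X, axis, m2, stage = "raw"),
               class = "gbr_metadata_error")
})

test_that("basis library loading resamples, normalises, and checks names/coverage", {
  axis <- coarse_axis(10)
  paths <- character(3)
  for (i in 1:3) {
    paths[i] <- tempfile(fileext = ".txt")
    s <- raman_spectrum(coarse_axis(5), gaussian_bands(coarse_axis(5)) + i / 10)
    write_spectrum(s, paths[i])
  }
  lib <- load_library(paths, c("glycogen", "glucose", "dna"), axis)
  expect_equal(nrow(lib$B), 3)
  areas <- apply(lib$B, 1, function(y) pracma::trapz(axis, y))
  expect_equal(areas, rep(1, 3), tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(load_library(paths, c("glycogen", "glycogen", "dna"), axis),
               class = "gbr_duplicate_name_error")
  # file covering only up to 1500 cannot serve a 1800-end axis
  short <- withr::local_tempfile(fileext = ".txt")
  write_spectrum(raman_spectrum(seq(450, 1500, 10), rep(1, 106)), short)
  expect_error(load_library(c(paths[1:2], short), c("a", "b", "c"), axis),
               class = "gbr_coverage_error")
})

test_that("resampling is the identity on equal axes and exact on affine profiles", {
  axis <- coarse_axis(10)
  s <- raman_spectrum(axis, gaussian_bands(axis))
  expect_identical(resample_to_axis(s, axis)$intensity, s$intensity)

  lin <- raman_spectrum(axis, 2 * axis + 5)
  half <- seq(450, 1800, by = 5)
  out <- resample_to_axis(lin, half)
  expect_equal(out$intensity, 2 * half + 5, tolerance = 1e-12)

  expect_error(resample_to_axis(s, seq(450, 1900, 10)),
               class = "gbr_coverage_error")
})

test_that("cosmic-ray removal repairs exactly the planted pixels", {
  axis <- coarse_axis(5)
  y <- gaussian_bands(axis)

  # smooth spectrum, no spikes: untouched
  out <- remove_cosmic_rays(raman_spectrum(axis, y))
  expect_identical(out$intensity, y)
  expect_false(any(attr(out, "spike_mask")))

  # one pixel at 50x local median
  y1 <- y
  i <- 130
  y1[i] <- 50 * median(y[(i - 5):(i + 5)])
  out1 <- remove_cosmic_rays(raman_spectrum(axis, y1))
  mask <- attr(out1, "spike_mask")
  expect_identical(which(mask), as.integer(i))
  expect_identical(out1$intensity[-i], y1[-i])

  # two adjacent spikes
  y2 <- y
  y2[i:(i + 1)] <- y2[i:(i + 1)] + 40 * max(y)
  out2 <- remove_cosmic_rays(raman_spectrum(axis, y2))
  expect_identical(which(attr(out2, "spike_mask")), as.integer(i:(i + 1)))
  expect_identical(out2$intensity[-(i:(i + 1))], y2[-(i:(i + 1))])
  expect_lt(max(abs(out2$intensity[i:(i + 1)] - y[i:(i + 1)])),
            0.05 * max(y))

  expect_error(remove_cosmic_rays(raman_spectrum(axis, y), window = 1e4),
               class = "gbr_window_error")
})

test_that("baseline subtraction removes smooth backgrounds but keeps peaks", {
  axis <- coarse_axis(2)
  # all-zero spectrum stays zero
  z <- subtract_baseline(raman_spectrum(axis, rep(0, length(axis))))
  expect_equal(z$intensity, rep(0, length(axis)), tolerance = 1e-12)

  # pure linear ramp: residual under 1% of ramp range
  ramp <- 0.001 * (axis - 450)
  r <- subtract_baseline(raman_spectrum(axis, ramp))
  expect_lt(max(abs(r$intensity)), 0.01 * diff(range(ramp)))

  # three Gaussian peaks on a known quadratic: peak heights within 5%
  peaks <- gaussian_bands(axis, floor = 0) # floor 0: pure peaks
  quad <- 1e-6 * (axis - 400)^2 + 0.3
  b <- subtract_baseline(raman_spectrum(axis, peaks + quad))
  for (ctr in c(700, 1050, 1450)) {
    j <- which.min(abs(axis - ctr))
    expect_lt(abs(b$intensity[j] - peaks[j]) / peaks[j], 0.05)
  }

  expect_error(subtract_baseline(raman_spectrum(axis, ramp), smoothness = 0),
               class = "gbr_parameter_error")
})

test_that("area normalisation yields unit area, is idempotent and scale-invariant", {
  axis <- coarse_axis(5)
  s <- raman_spectrum(axis, gaussian_bands(axis), stage = "baselined")
  n1 <- normalize_area(s)
  expect_equal(pracma::trapz(axis, n1$intensity), 1, tolerance = 1e-12)
  expect_identical(normalize_area(n1)$intensity, n1$intensity)
  n7 <- normalize_area(raman_spectrum(axis, 7 * gaussian_bands(axis),
                                      stage = "baselined"))
  expect_equal(n7$intensity, n1$intensity, tolerance = 1e-12)
  expect_error(normalize_area(raman_spectrum(axis, rep(0, length(axis)))),
               class = "gbr_zero_spectrum_error")
})

test_that("the preprocessing chain enforces stage order and reports failing spectra", {
  axis <- coarse_axis(5)
  norm <- normalize_area(raman_spectrum(axis, gaussian_bands(axis)))
  expect_error(remove_cosmic_rays(norm), class = "gbr_stage_error")
  expect_error(subtract_baseline(norm), class = "gbr_stage_error")

  X <- t(replicate(10, gaussian_bands(axis) * runif(1, 0.5, 2) + 0.1))
  ds <- spectral_dataset(X, axis, tiny_meta(10), stage = "raw")
  pp <- preprocess_dataset(ds)
  expect_equal(pp$stage, "normalized")
  areas <- apply(pp$X, 1, function(y) pracma::trapz(axis, y))
  expect_equal(areas, rep(1, 10), tolerance = 1e-9, ignore_attr = TRUE)

  X[4, ] <- 0   # all-zero spectrum cannot be normalised
  bad <- spectral_dataset(X, axis, tiny_meta(10), stage = "raw")
  err <- expect_error(preprocess_dataset(bad), class = "gbr_spectrum_error")
  expect_match(conditionMessage(err), "spectrum 4")
  expect_match(conditionMessage(err), "c004")
})

test_that("preprocessed synthetic spectra sit close to the planted mixtures", {
  axis <- default_axis()
  design <- generate_design(lines = "H460", doses = c(0, 5), days = 1,
                            replicates = 1, cells_per_sample = 10)
  trends <- stats::setNames(rep(list(trend()), 5), paste0("chem", 1:5))
  truth <- simulate_score_trends(design, trends, cv = 0.05, seed = 2)
  lib <- generate_basis_library(5, axis, names = names(trends), seed = 3)
  syn <- synthesize_spectra(truth, lib, raw = TRUE, seed = 4)
  clean <- truth$true_scores %*% lib$B
  tn <- clean / apply(clean, 1, function(y) pracma::trapz(axis, y))
  pp <- preprocess_dataset(syn$dataset)
  rel <- sqrt(rowMeans((pp$X - tn)^2)) / sqrt(rowMeans(tn^2))
  expect_lt(median(rel), 0.02)
})
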