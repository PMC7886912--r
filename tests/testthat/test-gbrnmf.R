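test_that("row-wise NNLS matches closed forms and a brute-force grid", {
  lib <- toy_basis(3)
  B <- lib$B
  # spectrum equal to one basis row scores 1 on it, ~0 elsewhere
  W <- update_scores_nnls(B[2, , drop = FALSE], B)
  expect_equal(unname(W[1, ]), c(0, 1, 0), tolerance = 1e-8)

  # orthogonal rows: analytic projection clipped at zero
  S <- rbind(c(1, 0, 0, 0), c(0, 0, 2, 0))
  x <- c(3, 1, -4, 2)
  W2 <- update_scores_nnls(matrix(x, 1), S)
  expect_equal(unname(W2[1, ]), c(3, 0), tolerance = 1e-12)

  # 2-basis toy vs 0.001-step grid search
  set.seed(5)
  S3 <- matrix(runif(2 * 20), 2)
  w_true <- c(0.4, 1.3)
  x3 <- as.numeric(w_true %*% S3) + rnorm(20, 0, 0.05)
  grid <- seq(0, 2, by = 0.001)
  sse <- outer(grid, grid, Vectorize(function(a, b)
    sum((x3 - a * S3[1, ] - b * S3[2, ])^2)))
  best <- arrayInd(which.min(sse), dim(sse))
  W3 <- update_scores_nnls(matrix(x3, 1), S3)
  expect_equal(unname(W3[1, ]), c(grid[best[1]], grid[best[2]]),
               tolerance = 2e-3)

  expect_error(update_scores_nnls(matrix(1, 1, 5), matrix(1, 2, 4)),
               class = "gbr_length_error")
})

test_that("a rank-1 spectrum recovers its score profile and scale exactly", {
  lib <- toy_basis(1)
  set.seed(3)
  w <- runif(25, 0.5, 2)
  X <- outer(w, lib$B[1, ])
  ds <- spectral_dataset(X, lib$axis, tiny_meta(25), stage = "baselined")
  m <- fit_gbrnmf(ds, lib, n_free = 0)
  expect_equal(m$A[1], mean(w), tolerance = 1e-10)
  expect_equal(unname(m$W[, 1]), w / mean(w), tolerance = 1e-10)
  expect_lt(reconstruction_error(m, ds), 1e-18)
})

test_that("fits with no free factor equal the independent per-row NNLS oracle", {
  lib <- toy_basis(3)
  set.seed(11)
  W_true <- matrix(runif(50 * 3, 0, 2), 50)
  X <- W_true %*% lib$B
  ds <- spectral_dataset(X, lib$axis, tiny_meta(50), stage = "baselined")
  m <- fit_gbrnmf(ds, lib, n_free = 0)
  W_raw <- sweep(m$W, 2, m$A, "*")
  W_oracle <- nnls_oracle(X, lib$B)
  expect_lt(max(abs(W_raw - W_oracle)) / max(abs(W_oracle)), 1e-6)
  # and the oracle itself recovers the planted scores on noiseless data
  expect_lt(max(abs(W_oracle - W_true)) / max(abs(W_true)), 1e-6)
})

test_that("the factor count is the library size plus the free factors", {
  sim <- simulate_raman_study("paper_analog", seed = 2, raw = FALSE,
                              axis = coarse_axis(10), cells_per_sample = 1)
  m <- fit_gbrnmf(sim$dataset, sim$library, n_free = 1, max_iter = 5)
  expect_equal(ncol(m$W), 31)
  expect_equal(m$factor_names[31], "unconstrained_1")
})

test_that("free-basis updates recover planted residual profiles and never touch fixed rows", {
  lib <- toy_basis(2)
  axis <- lib$axis
  set.seed(8)
  profile <- exp(-(axis - 1200)^2 / (2 * 30^2))
  profile <- profile / pracma::trapz(axis, profile)
  w_fix <- matrix(runif(30 * 2, 0.5, 1.5), 30)
  w_free <- runif(30, 0.2, 2)
  X <- w_fix %*% lib$B + outer(w_free, profile)
  S <- rbind(lib$B, runif(length(axis)))
  W <- cbind(w_fix, w_free)
  S2 <- update_free_bases(X, W, S, c(TRUE, TRUE, FALSE))
  expect_identical(S2[1:2, ], S[1:2, ])
  cosine <- sum(S2[3, ] * profile) /
    sqrt(sum(S2[3, ]^2) * sum(profile^2))
  expect_gt(cosine, 0.999)

  # zero residual: free row collapses to zero
  X0 <- w_fix %*% lib$B
  S0 <- update_free_bases(X0, cbind(w_fix, w_free), S, c(TRUE, TRUE, FALSE))
  expect_equal(max(S0[3, ]), 0, tolerance = 1e-10)

  expect_error(update_free_bases(X, W, S, rep(TRUE, 3)),
               class = "gbr_parameter_error")
})

test_that("factor-scale extraction gives mean-1 columns and flags degenerate factors", {
  W_raw <- cbind(rep(2.5, 10), runif(10), rep(0, 10))
  ns <- normalize_factor_scale(W_raw)
  expect_equal(ns$A[1], 2.5)
  expect_equal(unname(ns$W[, 1]), rep(1, 10))
  expect_equal(colMeans(ns$W)[1:2], c(1, 1), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(ns$A[3], 1)
  expect_true(ns$degenerate[3])
  expect_false(any(ns$degenerate[1:2]))
  expect_equal(sweep(ns$W, 2, ns$A, "*"), W_raw, tolerance = 1e-14)
})

test_that("reconstruction error equals brute-force summation and survives rescaling", {
  lib <- toy_basis(2, axis = seq(450, 1800, length.out = 4))
  X <- matrix(c(1, 2, 0.5, 0.2,
                0.3, 1, 2, 0.1,
                0.7, 0.1, 0.2, 1), 3, byrow = TRUE)
  ds <- spectral_dataset(X, lib$axis, tiny_meta(3), stage = "baselined")
  m <- fit_gbrnmf(ds, lib, n_free = 0)
  R <- X - sweep(m$W, 2, m$A, "*") %*% m$S
  brute <- 0
  for (i in 1:3) for (j in 1:4) brute <- brute + R[i, j]^2
  expect_equal(reconstruction_error(m, ds), brute, tolerance = 1e-12)

  # W A S is invariant under the scale extraction
  err_raw <- sum((X - sweep(m$W, 2, m$A, "*") %*% m$S)^2)
  expect_equal(reconstruction_error(m, ds), err_raw, tolerance = 1e-12)
})

test_that("projection reproduces training scores and respects linearity", {
  lib <- toy_basis(3)
  set.seed(12)
  X <- matrix(runif(40 * 3, 0, 2), 40) %*% lib$B
  ds <- spectral_dataset(X, lib$axis, tiny_meta(40), stage = "baselined")
  m <- fit_gbrnmf(ds, lib, n_free = 0)
  proj <- project_scores(m, ds)
  expect_equal(proj$scores, m$W, tolerance = 1e-6)

  new <- spectral_dataset(2 * lib$B[2, , drop = FALSE], lib$axis,
                          tiny_meta(1), stage = "baselined")
  p2 <- project_scores(m, new)
  expect_equal(unname(p2$scores[1, 2]), 2 / m$A[2], tolerance = 1e-6)
  expect_lt(max(p2$scores[1, -2]), 1e-6)

  other <- spectral_dataset(matrix(1, 1, 50), seq(450, 1800, length.out = 50),
                            tiny_meta(1), stage = "baselined")
  expect_error(project_scores(m, other), class = "gbr_axis_error")
})

test_that("objective traces are non-increasing and factors stay non-negative", {
  lib <- toy_basis(3)
  set.seed(20)
  for (rep in 1:20) {
    W_true <- matrix(runif(20 * 3, 0, 2), 20)
    X <- pmax(W_true %*% lib$B + matrix(rnorm(20 * length(lib$axis), 0, 2e-4),
                                        20), 0)
    ds <- spectral_dataset(X, lib$axis, tiny_meta(20), stage = "baselined")
    m <- fit_gbrnmf(ds, lib, n_free = 1, max_iter = 40)
    expect_true(all(diff(m$objective_trace) <= 1e-8 * m$objective_trace[1]))
    expect_true(all(m$W >= 0) && all(m$S >= 0) && all(m$A > 0))
    expect_identical(unname(m$S[1:3, ]), unname(lib$B))
  }
})

test_that("rescaling the data rescales A and leaves normalised scores unchanged", {
  lib <- toy_basis(2)
  set.seed(30)
  X <- matrix(runif(15 * 2, 0.2, 2), 15) %*% lib$B
  ds1 <- spectral_dataset(X, lib$axis, tiny_meta(15), stage = "baselined")
  ds3 <- spectral_dataset(3 * X, lib$axis, tiny_meta(15), stage = "baselined")
  m1 <- fit_gbrnmf(ds1, lib, n_free = 0)
  m3 <- fit_gbrnmf(ds3, lib, n_free = 0)
  expect_equal(m1$W, m3$W, tolerance = 1e-10)
  expect_equal(3 * m1$A, m3$A, tolerance = 1e-8)
})

test_that("score tables round-trip through CSV", {
  sc <- matrix(runif(12), 4, 3,
               dimnames = list(NULL, c("glycogen", "glucose", "dna")))
  st <- score_table(sc, tiny_meta(4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_score_table(st, path, header_comment = "unit test")
  back <- read_score_table(path)
  expect_equal(back$scores, st$scores, tolerance = 1e-12)
  expect_equal(back$factor_names, st$factor_names)
})
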