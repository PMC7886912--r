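# Shared fixtures, all built in code.

coarse_axis <- function(by = 10) seq(450, 1800, by = by)

# a smooth multi-band test spectrum: three Gaussian bands on a flat floor
gaussian_bands <- function(axis = coarse_axis(5),
                           centers = c(700, 1050, 1450),
                           heights = c(1, 0.6, 0.8), sigma = 20,
                           floor = 0.02) {
  y <- rep(floor, length(axis))
  for (q in seq_along(centers))
    y <- y + heights[q] * exp(-(axis - centers[q])^2 / (2 * sigma^2))
  y
}

# minimal valid metadata for n spectra
tiny_meta <- function(n, cell_line = "H460", dose = 0, day = 1) {
  data.frame(cell_line = cell_line, dose_gy = dose, day = day,
             replicate = "R1", cell_id = sprintf("c%03d", seq_len(n)))
}

# small, well-separated non-negative basis for factorisation toys
toy_basis <- function(k = 3, axis = coarse_axis(10), seed = 99) {
  set.seed(seed)
  B <- matrix(0, k, length(axis))
  centers <- seq(550, 1700, length.out = k)
  for (i in seq_len(k)) {
    B[i, ] <- exp(-(axis - centers[i])^2 / (2 * 40^2)) +
      0.3 * exp(-(axis - centers[i] - 300)^2 / (2 * 25^2))
    B[i, ] <- B[i, ] / pracma::trapz(axis, B[i, ])
  }
  basis_library(B, paste0("chem_", seq_len(k)), axis)
}

# independent per-row NNLS oracle (pracma active-set, distinct from the
# package's C++ solver)
nnls_oracle <- function(X, S) {
  t(apply(X, 1L, function(x) pracma::lsqnonneg(t(S), x)$x))
}

# two-class score matrix with `n_informative` separating variables
separable_scores <- function(n_per_class = 100, n_vars = 10,
                             n_informative = 1, shift = 3, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_class * n_vars), ncol = n_vars)
  x[seq_len(n_per_class), seq_len(n_informative)] <-
    x[seq_len(n_per_class), seq_len(n_informative)] + shift
  colnames(x) <- paste0("v", seq_len(n_vars))
  list(x = x,
       y = factor(rep(c("a", "b"), each = n_per_class)))
}
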