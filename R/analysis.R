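#' Principal component analysis of a spectral dataset
#'
#' Column-mean-centred PCA via singular value decomposition. Loadings use a
#' deterministic sign convention: the largest-magnitude element of each
#' loading is positive.
#'
#' @param data A `spectral_dataset` (typically fully preprocessed).
#' @param n_components Number of components to retain.
#' @return An object of class `raman_pca` with `loadings` (c x p, rows are
#'   components), `scores` (n x c), `explained_variance_fraction` and
#'   `center`.
#' @export
run_pca <- function(data, n_components = 2) {
  X <- if (inherits(data, "spectral_dataset")) data$X else as.matrix(data)
  n <- nrow(X); p <- ncol(X)
  if (n_components > min(n, p))
    stop_gbr("gbr_parameter_error",
             "n_components (%d) exceeds min(n, p) = %d", n_components, min(n, p))
  if (n <= n_components)
    stop_gbr("gbr_parameter_error", "need more spectra than components")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc, nu = n_components, nv = n_components)
  V <- sv$v
  # sign convention: largest-|element| of each loading positive
  for (j in seq_len(n_components)) {
    s <- sign(V[which.max(abs(V[, j])), j])
    if (s < 0) { V[, j] <- -V[, j]; sv$u[, j] <- -sv$u[, j] }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  total_var <- sum(sv$d^2)
  structure(list(loadings = t(V),
                 scores = scores,
                 explained_variance_fraction =
                   sv$d[seq_len(n_components)]^2 / total_var,
                 center = ctr,
                 axis = if (inherits(data, "spectral_dataset")) data$axis),
            class = "raman_pca")
}

#' @exportS3Method print raman_pca
print.raman_pca <- function(x, ...) {
  cat(sprintf("<raman_pca> %d components; explained variance: %s\n",
              nrow(x$loadings),
              paste(sprintf("%.1f%%", 100 * x$explained_variance_fraction),
                    collapse = ", ")))
  invisible(x)
}

#' Match a PCA loading against a basis library
#'
#' Ranks the library by absolute Pearson correlation with the loading; the
#' absolute value makes the match invariant to the arbitrary sign of a
#' principal component.
#'
#' @param loading Length-p numeric vector on the library axis.
#' @param library A `basis_library`.
#' @return Data frame with columns `name` and `similarity`, sorted by
#'   decreasing similarity.
#' @export
match_loading_to_basis <- function(loading, library) {
  if (length(loading) != ncol(library$B))
    stop_gbr("gbr_length_error",
             "loading length (%d) != library axis length (%d)",
             length(loading), ncol(library$B))
  sim <- abs(apply(library$B, 1L, function(b) cor(loading, b)))
  out <- data.frame(name = library$names, similarity = as.numeric(sim))
  out[order(-out$similarity), , drop = FALSE]
}

#' Group means and standard errors of factor scores
#'
#' One row per observed grouping combination and factor, with the group
#' mean, the standard error of the mean (sample SD / sqrt(n)) and n.
#' Singleton groups get `se = NA` and are flagged.
#'
#' @param scores A `score_table`.
#' @param factors Factor names to summarise (default: all).
#' @param grouping Metadata columns to group by.
#' @return Data frame with columns `<grouping...>`, `factor`, `mean`, `se`,
#'   `n`, `singleton`.
#' @export
score_summary <- function(scores, factors = NULL,
                          grouping = c("cell_line", "dose_gy", "day")) {
  if (is.null(factors)) factors <- scores$factor_names
  unknown <- setdiff(factors, scores$factor_names)
  if (length(unknown))
    stop_gbr("gbr_unknown_factor_error", "unknown factor(s): %s",
             paste(unknown, collapse = ", "))
  missing_g <- setdiff(grouping, names(scores$meta))
  if (length(missing_g))
    stop_gbr("gbr_metadata_error", "unknown grouping column(s): %s",
             paste(missing_g, collapse = ", "))
  g <- interaction(scores$meta[grouping], drop = TRUE, lex.order = TRUE)
  if (nlevels(g) == 0)
    stop_gbr("gbr_empty_error", "no groups to summarise")
  rows <- lapply(levels(g), function(lev) {
    idx <- which(g == lev)
    keyvals <- scores$meta[idx[1], grouping, drop = FALSE]
    do.call(rbind, lapply(factors, function(f) {
      v <- scores$scores[idx, f]
      cbind(keyvals,
            data.frame(factor = f, mean = mean(v),
                       se = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
                       n = length(v), singleton = length(v) == 1L))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation between two factor scores
#'
#' @param scores A `score_table`.
#' @param factor_a,factor_b Factor names.
#' @param subset Optional named list of metadata filters, e.g.
#'   `list(cell_line = "H460")`; rows matching every filter are kept.
#' @return Data frame with `factor_a`, `factor_b`, `subset`, `r`, `p_value`,
#'   `n`.
#' @export
correlate_scores <- function(scores, factor_a, factor_b, subset = NULL) {
  for (f in c(factor_a, factor_b))
    if (!f %in% scores$factor_names)
      stop_gbr("gbr_unknown_factor_error", "unknown factor '%s'", f)
  idx <- subset_rows(scores$meta, subset)
  if (length(idx) < 3L)
    stop_gbr("gbr_empty_error", "subset has %d rows; need at least 3",
             length(idx))
  a <- scores$scores[idx, factor_a]
  b <- scores$scores[idx, factor_b]
  if (sd(a) == 0 || sd(b) == 0)
    stop_gbr("gbr_constant_error",
             "constant scores in subset; correlation undefined")
  ct <- cor.test(a, b, method = "pearson")
  data.frame(factor_a = factor_a, factor_b = factor_b,
             subset = subset_label(subset),
             r = unname(ct$estimate), p_value = ct$p.value, n = length(idx))
}

subset_rows <- function(meta, subset) {
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(subset)) {
    for (nm in names(subset)) {
      if (!nm %in% names(meta))
        stop_gbr("gbr_metadata_error", "unknown metadata column '%s'", nm)
      keep <- keep & meta[[nm]] %in% subset[[nm]]
    }
  }
  which(keep)
}

subset_label <- function(subset) {
  if (is.null(subset) || !length(subset)) return("all")
  paste(vapply(names(subset),
               function(nm) paste0(nm, "=", paste(subset[[nm]], collapse = "|")),
               character(1)),
        collapse = ",")
}

#' Compare dosed groups against same-day unirradiated controls
#'
#' For every (cell line, day, dose > 0) group, tests the factor scores
#' against the 0 Gy group of the same cell line and day. The default test is
#' Welch's two-sample t-test; a Mann-Whitney (Wilcoxon rank-sum) alternative
#' is available. No multiplicity correction is applied by default;
#' Benjamini-Hochberg is available via `p_adjust`.
#'
#' @param scores A `score_table`.
#' @param factor Factor name to test.
#' @param alpha Significance level for the `significant` flag.
#' @param test `"welch"` or `"wilcoxon"`.
#' @param p_adjust `"none"` or `"BH"`.
#' @return Data frame with `cell_line`, `day`, `dose_gy`, `n`, `n_control`,
#'   `p_value`, `significant`.
#' @export
compare_to_control <- function(scores, factor, alpha = 0.05,
                               test = c("welch", "wilcoxon"),
                               p_adjust = c("none", "BH")) {
  test <- match.arg(test)
  p_adjust <- match.arg(p_adjust)
  if (!factor %in% scores$factor_names)
    stop_gbr("gbr_unknown_factor_error", "unknown factor '%s'", factor)
  meta <- scores$meta
  v <- scores$scores[, factor]
  combos <- unique(meta[meta$dose_gy > 0, c("cell_line", "day", "dose_gy")])
  if (nrow(combos) == 0)
    stop_gbr("gbr_empty_error", "no dosed groups to compare")
  combos <- combos[order(combos$cell_line, combos$day, combos$dose_gy), ]
  res <- lapply(seq_len(nrow(combos)), function(i) {
    cl <- combos$cell_line[i]; dy <- combos$day[i]; dg <- combos$dose_gy[i]
    trt <- v[meta$cell_line == cl & meta$day == dy & meta$dose_gy == dg]
    ctl <- v[meta$cell_line == cl & meta$day == dy & meta$dose_gy == 0]
    if (length(ctl) == 0)
      stop_gbr("gbr_missing_control_error",
               "no 0 Gy control for cell line '%s', day %s", cl, dy)
    p <- if (test == "welch") t.test(trt, ctl)$p.value
         else stats::wilcox.test(trt, ctl, exact = FALSE)$p.value
    data.frame(cell_line = cl, day = dy, dose_gy = dg,
               n = length(trt), n_control = length(ctl), p_value = p)
  })
  out <- do.call(rbind, res)
  out$p_value <- p.adjust(out$p_value, method = if (p_adjust == "BH") "BH" else "none")
  out$significant <- out$p_value < alpha
  rownames(out) <- NULL
  out
}
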