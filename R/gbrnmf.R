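#' Row-wise non-negative least squares scores
#'
#' For each spectrum (row of `X`) solves min ||x - w %*% basis||^2 subject
#' to w >= 0, with an active-set solver sharing one cross-product across
#' rows.
#'
#' @param X n x p matrix of spectra.
#' @param basis k x p matrix of basis spectra (rows not all zero).
#' @return n x k non-negative score matrix.
#' @export
update_scores_nnls <- function(X, basis) {
  X <- as.matrix(X); basis <- as.matrix(basis)
  if (ncol(X) != ncol(basis))
    stop_gbr("gbr_length_error", "X has %d columns but basis has %d",
             ncol(X), ncol(basis))
  if (any(rowSums(basis != 0) == 0))
    stop_gbr("gbr_value_error", "basis contains an all-zero row")
  nnls_rows_cpp(X, basis)
}

#' Update the free rows of the basis matrix
#'
#' Holding the scores and the fixed (library) rows constant, the free rows
#' are re-estimated to minimise the reconstruction error subject to
#' non-negativity. The subproblem is the transpose of the score update: one
#' NNLS per wavenumber against the free score columns.
#'
#' @param X n x p data matrix.
#' @param W n x k current scores.
#' @param S k x p current basis.
#' @param fixed_mask Logical length-k vector, TRUE for library rows.
#' @return `S` with the free rows replaced; fixed rows are returned
#'   untouched.
#' @export
update_free_bases <- function(X, W, S, fixed_mask) {
  if (all(fixed_mask))
    stop_gbr("gbr_parameter_error", "no free basis rows to update")
  free <- which(!fixed_mask)
  R <- X - W[, fixed_mask, drop = FALSE] %*% S[fixed_mask, , drop = FALSE]
  Wf <- W[, free, drop = FALSE]
  if (all(colSums(Wf) == 0)) return(S)   # degenerate free factors: leave as-is
  # rows of t(R) are wavenumbers; design is t(Wf)
  S_free_t <- nnls_rows_cpp(t(R), t(Wf))        # p x n_free
  S[free, ] <- t(S_free_t)
  S
}

#' Extract the factor-scale (auxiliary) diagonal
#'
#' Reparameterises raw scores so that every non-degenerate factor has mean
#' score 1: the auxiliary diagonal entry of a factor is the column mean of
#' the raw scores, and the scores are divided by it. The product
#' `W %*% diag(A) %*% S` is unchanged. An all-zero column gets auxiliary
#' entry 1, is left unchanged, and is flagged degenerate.
#'
#' @param W_raw n x k non-negative raw score matrix.
#' @return List with `W` (mean-1 scores), `A` (length-k positive diagonal
#'   as a vector) and `degenerate` (logical length-k).
#' @export
normalize_factor_scale <- function(W_raw) {
  W_raw <- as.matrix(W_raw)
  A <- colMeans(W_raw)
  degenerate <- A <= 0
  A[degenerate] <- 1
  W <- sweep(W_raw, 2L, A, "/")
  list(W = W, A = A, degenerate = degenerate)
}

#' Fit the basis-restricted non-negative factorisation
#'
#' Decomposes the spectra matrix X (n x p) as X ~ W A S where the first
#' m rows of S are fixed, bit for bit, to the reference library, `n_free`
#' additional rows are estimated freely from the data, all factors are
#' non-negative, and the positive diagonal A carries the scale so that each
#' non-degenerate score column of W has mean 1.
#'
#' The optimiser is block-coordinate alternating NNLS: scores are solved
#' exactly per spectrum given the current basis, then (if `n_free > 0`) the
#' free basis rows are solved exactly per wavenumber given the scores. Both
#' half-steps are exact minimisers of the squared Frobenius objective, so
#' the recorded objective trace is non-increasing. A is extracted once after
#' convergence; it is a pure reparameterisation.
#'
#' @param data A `spectral_dataset` (any stage; typically "normalized").
#' @param library A `basis_library` on the same axis.
#' @param n_free Number of unconstrained basis rows (default 1).
#' @param max_iter Maximum alternations (default 500).
#' @param tol Relative objective-change convergence tolerance (default 1e-8).
#' @param seed Integer recorded with the model; used only if a random
#'   restart of the free rows is requested via `init = "random"`.
#' @param init Free-row initialisation: `"svd"` (non-negative part of the
#'   leading residual singular vector) or `"random"`.
#' @return An object of class `gbrnmf` with elements `W`, `A`, `S`,
#'   `factor_names`, `n_fixed`, `objective_trace`, `converged`,
#'   `iterations`, `degenerate`, `axis`, `settings`.
#' @export
fit_gbrnmf <- function(data, library, n_free = 1, max_iter = 500,
                       tol = 1e-8, seed = 1L, init = c("svd", "random")) {
  init <- match.arg(init)
  if (!inherits(data, "spectral_dataset"))
    stop_gbr("gbr_type_error", "data must be a spectral_dataset")
  if (!inherits(library, "basis_library"))
    stop_gbr("gbr_type_error", "library must be a basis_library")
  if (length(data$axis) != length(library$axis) ||
      any(data$axis != library$axis))
    stop_gbr("gbr_axis_error", "data and library are on different axes")
  if (n_free < 0)
    stop_gbr("gbr_parameter_error", "n_free must be >= 0")
  X <- data$X
  n <- nrow(X)
  if (n < 1L) stop_gbr("gbr_empty_error", "dataset has no spectra")

  B <- library$B
  m <- nrow(B)
  k <- m + n_free
  factor_names <- c(library$names,
                    if (n_free > 0) paste0("unconstrained_", seq_len(n_free)))
  fixed_mask <- c(rep(TRUE, m), rep(FALSE, n_free))

  # initialise: scores against the fixed library, free rows from the
  # non-negative part of the leading residual singular vector
  W <- matrix(0, n, k)
  W[, seq_len(m)] <- nnls_rows_cpp(X, B)
  S <- matrix(0, k, ncol(X))
  S[seq_len(m), ] <- B
  if (n_free > 0) {
    R <- X - W[, seq_len(m), drop = FALSE] %*% B
    if (init == "random") {
      set.seed(seed)
      S[m + seq_len(n_free), ] <- matrix(runif(n_free * ncol(X)),
                                         n_free, ncol(X))
    } else {
      sv <- svd(R, nu = 0, nv = n_free)
      for (j in seq_len(n_free)) {
        v <- sv$v[, j]
        v <- if (sum(pmax(v, 0)) >= sum(pmax(-v, 0))) pmax(v, 0) else pmax(-v, 0)
        if (all(v == 0)) v <- rep(1 / ncol(X), ncol(X))
        S[m + j, ] <- v
      }
    }
  }

  obj <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    W <- nnls_rows_cpp(X, S)
    if (n_free > 0) S <- update_free_bases(X, W, S, fixed_mask)
    obj[it] <- sum((X - W %*% S)^2)
    if (it > 1L) {
      rel <- (obj[it - 1L] - obj[it]) / max(obj[1L], .Machine$double.eps)
      if (abs(rel) < tol) { converged <- TRUE; break }
    } else if (n_free == 0) {
      # with no free rows a single exact NNLS pass is the global optimum
      converged <- TRUE
      break
    }
  }

  ns <- normalize_factor_scale(W)
  colnames(ns$W) <- factor_names
  rownames(S) <- factor_names
  structure(list(W = ns$W, A = ns$A, S = S,
                 factor_names = factor_names, n_fixed = m,
                 objective_trace = obj, converged = converged,
                 iterations = it, degenerate = ns$degenerate,
                 axis = data$axis, meta = data$meta,
                 settings = list(n_free = n_free, max_iter = max_iter,
                                 tol = tol, seed = seed, init = init)),
            class = "gbrnmf")
}

#' @exportS3Method print gbrnmf
print.gbrnmf <- function(x, ...) {
  cat(sprintf(paste0("<gbrnmf> %d spectra, %d fixed + %d free factor(s); ",
                     "%d iterations (%s), final SSE %.4g\n"),
              nrow(x$W), x$n_fixed, length(x$factor_names) - x$n_fixed,
              x$iterations, if (x$converged) "converged" else "not converged",
              utils::tail(x$objective_trace, 1)))
  invisible(x)
}

#' Squared Frobenius reconstruction error of a fitted model
#'
#' @param model A `gbrnmf` model.
#' @param data The `spectral_dataset` it was fitted to (or any dataset of
#'   matching shape).
#' @return `||X - W A S||_F^2`.
#' @export
reconstruction_error <- function(model, data) {
  X <- if (inherits(data, "spectral_dataset")) data$X else as.matrix(data)
  if (nrow(X) != nrow(model$W) || ncol(X) != ncol(model$S))
    stop_gbr("gbr_length_error", "data shape does not match the model")
  sum((X - model$W %*% (model$A * model$S))^2)
}

#' Score new spectra on a fitted basis
#'
#' Each new spectrum is solved by NNLS against the scaled basis `A S`, so
#' the returned scores are on the model's mean-1 scale.
#'
#' @param model A `gbrnmf` model.
#' @param new_data A `spectral_dataset` on the model's axis.
#' @return A `score_table`.
#' @export
project_scores <- function(model, new_data) {
  if (length(new_data$axis) != length(model$axis) ||
      any(new_data$axis != model$axis))
    stop_gbr("gbr_axis_error", "new data is on a different axis than the model")
  W <- nnls_rows_cpp(new_data$X, model$A * model$S)
  colnames(W) <- model$factor_names
  score_table(W, new_data$meta)
}

#' Construct a score table
#'
#' Per-spectrum factor scores joined (by row order) to experimental
#' metadata; the common currency of all downstream statistics.
#'
#' @param scores n x k non-negative matrix with factor names as column
#'   names.
#' @param meta Metadata data frame, one row per spectrum.
#' @return An object of class `score_table`.
#' @export
score_table <- function(scores, meta) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores)))
    stop_gbr("gbr_parameter_error", "scores must have factor names as colnames")
  if (any(scores < 0))
    stop_gbr("gbr_value_error", "scores must be non-negative")
  validate_metadata(meta, n = nrow(scores))
  structure(list(scores = scores, factor_names = colnames(scores),
                 meta = as.data.frame(meta)),
            class = "score_table")
}

#' Extract the training score table from a fitted model
#'
#' @param model A `gbrnmf` model.
#' @return A `score_table` of the model's mean-1 scores with the training
#'   metadata.
#' @export
model_scores <- function(model) {
  score_table(model$W, model$meta)
}

#' @exportS3Method print score_table
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> %d spectra x %d factors\n",
              nrow(x$scores), length(x$factor_names)))
  invisible(x)
}

#' @export
as.data.frame.score_table <- function(x, ...) {
  cbind(x$meta[required_meta_cols],
        as.data.frame(x$scores, check.names = FALSE))
}

#' Write a score table as CSV (metadata columns, then factor columns)
#'
#' @param x A `score_table`.
#' @param path Output path.
#' @param header_comment Optional '#'-prefixed provenance line.
#' @export
write_score_table <- function(x, path, header_comment = NULL) {
  write_csv_commented(as.data.frame(x), path, header_comment)
}

#' Read a score table written by [write_score_table()]
#'
#' @param path CSV path.
#' @return A `score_table`.
#' @export
read_score_table <- function(path) {
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  fac <- setdiff(names(df), required_meta_cols)
  score_table(as.matrix(df[fac]), df[required_meta_cols])
}

#' Serialise a fitted model to a directory of plain-text files
#'
#' Matrices are written as CSV and the fit settings and diagnostics as a
#' JSON sidecar, so a model round-trips without binary formats.
#'
#' @param model A `gbrnmf` model.
#' @param dir Output directory (created if needed).
#' @export
write_gbrnmf <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(factor = model$factor_names, A = model$A,
                       degenerate = model$degenerate),
            file.path(dir, "auxiliary.csv"), row.names = FALSE)
  utils::write.csv(model$W, file.path(dir, "scores.csv"), row.names = FALSE)
  utils::write.csv(model$S, file.path(dir, "basis.csv"), row.names = FALSE)
  utils::write.csv(model$meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  jsonlite::write_json(
    c(model$settings,
      list(axis = model$axis, factor_names = model$factor_names,
           n_fixed = model$n_fixed, converged = model$converged,
           iterations = model$iterations,
           objective_trace = model$objective_trace)),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
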