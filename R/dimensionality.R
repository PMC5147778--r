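#' @title PCA basis patterns and cumulative-variance dimensionality
#' @name pca_patterns
#' @description
#' `pca_patterns()` extracts the leading principal axes ("basis patterns")
#' of a centered samples-by-features matrix and keeps the minimal number
#' whose cumulative explained-variance fraction reaches `variance_threshold`
#' (inclusive at equality).  `dimensionality()` returns that count alone,
#' and `cumulative_variance_curve()` returns the whole nondecreasing curve.
#'
#' Each basis pattern is a unit vector in feature space (one coefficient per
#' neuron or pixel block).  Variance fractions come from the singular values
#' of the centered matrix; singular values below `1e-12` times the largest
#' are treated as exactly zero.  Pattern signs are fixed so the largest-
#' magnitude coefficient of each pattern is positive.
#'
#' @param matrix A centered [data_matrix()] with at least 2 samples.
#' @param variance_threshold Cumulative variance fraction in (0, 1];
#'   default 0.9.
#' @return `pca_patterns()`: an object of class `basis_patterns` with
#'   elements `patterns` (features x k orthonormal matrix),
#'   `variance_fractions` (descending, over all principal axes),
#'   `variance_threshold`, `ambient_dim`, `k`.
NULL

## Singular values -> variance fractions, with the numerical-rank floor.
.variance_fractions <- function(d) {
  if (d[1] <= 0) stop("degenerate data: total variance is zero")
  d[d < 1e-12 * d[1]] <- 0
  v <- d^2
  v / sum(v)
}

.k_at_threshold <- function(fractions, variance_threshold) {
  if (!is.numeric(variance_threshold) || length(variance_threshold) != 1L ||
      variance_threshold <= 0 || variance_threshold > 1)
    stop("'variance_threshold' must be a single number in (0, 1]")
  cf <- cumsum(fractions)
  ## inclusive tie rule, with a guard for accumulated floating-point error
  which(cf >= variance_threshold - 1e-12)[1]
}

.check_pca_input <- function(matrix) {
  stopifnot(inherits(matrix, "data_matrix"))
  if (!matrix$centered)
    stop("PCA requires a centered matrix; call center_features() first")
  if (nrow(matrix$values) < 2L)
    stop("need at least 2 samples")
}

#' @rdname pca_patterns
#' @export
pca_patterns <- function(matrix, variance_threshold = 0.9) {
  .check_pca_input(matrix)
  sv <- svd(matrix$values)
  fr <- .variance_fractions(sv$d)
  k <- .k_at_threshold(fr, variance_threshold)
  pat <- sv$v[, seq_len(k), drop = FALSE]
  ## reproducible sign convention: largest-|coefficient| entry positive
  for (j in seq_len(k)) {
    i <- which.max(abs(pat[, j]))
    if (pat[i, j] < 0) pat[, j] <- -pat[, j]
  }
  structure(
    list(patterns = pat, variance_fractions = fr,
         variance_threshold = variance_threshold,
         ambient_dim = ncol(matrix$values), k = k),
    class = "basis_patterns")
}

#' @export
print.basis_patterns <- function(x, ...) {
  cat(sprintf(
    "basis_patterns: k = %d of ambient %d (threshold %.0f%%, top pattern %.1f%% var)\n",
    x$k, x$ambient_dim, 100 * x$variance_threshold,
    100 * x$variance_fractions[1]))
  invisible(x)
}

#' @rdname pca_patterns
#' @export
dimensionality <- function(matrix, variance_threshold = 0.9) {
  .check_pca_input(matrix)
  d <- svd(matrix$values, nu = 0, nv = 0)$d
  .k_at_threshold(.variance_fractions(d), variance_threshold)
}

#' @rdname pca_patterns
#' @export
cumulative_variance_curve <- function(matrix) {
  .check_pca_input(matrix)
  d <- svd(matrix$values, nu = 0, nv = 0)$d
  fr <- .variance_fractions(d)
  n <- min(nrow(matrix$values) - 1L, ncol(matrix$values))
  cf <- cumsum(fr)
  ## pad (rank-deficient case): the curve has one value per possible axis
  if (length(cf) < n) cf <- c(cf, rep(1, n - length(cf)))
  cf[seq_len(n)]
}
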