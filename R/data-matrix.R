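#' Samples-by-features data matrix with centering metadata
#'
#' The common container fed to every dimensionality analysis: rows are
#' samples (movie frames, or time bins of a PSTH set) and columns are
#' features (block-averaged pixels, or neurons).  Centering is performed at
#' most once and recorded, because all windowed analyses must share a single
#' reference frame (see [center_features()]).
#'
#' @param values Numeric matrix, samples x features.  All entries must be
#'   finite.
#' @param centered Logical flag; `TRUE` means every feature column already
#'   has mean zero.
#' @param feature_means Per-feature means recorded at centering time (or
#'   `NULL` if not centered).
#' @param provenance Free-text label describing where the matrix came from.
#' @return An object of class `data_matrix`.
#' @export
#' @examples
#' m <- data_matrix(matrix(rnorm(20), 5, 4))
#' center_features(m)
data_matrix <- function(values, centered = FALSE, feature_means = NULL,
                        provenance = "") {
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values)))
    stop("'values' must be a numeric matrix with finite entries")
  if (centered) {
    cm <- colMeans(values)
    cn <- sqrt(colSums(values^2))
    if (any(abs(cm) > 1e-9 * pmax(cn, 1)))
      stop("matrix declared centered but feature means are not zero")
  }
  structure(
    list(values = values, centered = isTRUE(centered),
         feature_means = feature_means, provenance = provenance),
    class = "data_matrix")
}

#' @export
print.data_matrix <- function(x, ...) {
  cat(sprintf("data_matrix: %d samples x %d features%s%s\n",
              nrow(x$values), ncol(x$values),
              if (x$centered) ", centered" else ", uncentered",
              if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else ""))
  invisible(x)
}

#' @export
dim.data_matrix <- function(x) dim(x$values)

#' Centre every feature column of a data matrix
#'
#' Subtracts the column (feature) mean from each feature and records the
#' means, so that subsequent analyses study fluctuations around the mean.
#' Centering a matrix twice is refused with a warning (identity), so that a
#' globally centered matrix can be sliced into time windows without the
#' window-local mean ever being re-subtracted.
#'
#' @param matrix A [data_matrix()].
#' @return A centered `data_matrix` with `feature_means` filled in.
#' @export
center_features <- function(matrix) {
  stopifnot(inherits(matrix, "data_matrix"))
  if (matrix$centered) {
    warning("matrix is already centered; returning it unchanged")
    return(matrix)
  }
  mu <- colMeans(matrix$values)
  out <- sweep(matrix$values, 2L, mu, "-")
  data_matrix(out, centered = TRUE, feature_means = mu,
              provenance = matrix$provenance)
}

## Coerce foreign objects to data_matrix -------------------------------------

#' Coerce to a data matrix
#'
#' @param x Object to coerce: a plain matrix (treated as uncentered) or a
#'   [psth_set()] (transposed so time bins are samples and neurons are
#'   features).
#' @param ... Unused.
#' @return A [data_matrix()].
#' @export
as_data_matrix <- function(x, ...) UseMethod("as_data_matrix")

#' @export
as_data_matrix.data_matrix <- function(x, ...) x

#' @export
as_data_matrix.matrix <- function(x, ...) data_matrix(x)

#' @rdname as_data_matrix
#' @export
as_data_matrix.psth_set <- function(x, ...) {
  data_matrix(t(x$rates), centered = x$centered,
              feature_means = if (x$centered) x$feature_means else NULL,
              provenance = "psth_set")
}
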