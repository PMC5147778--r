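#' Window specification for time-resolved analyses
#'
#' @param window_length Window length in seconds (default 1).
#' @param bin_width Bin width in ms (default 20, so a 1-s window holds 50
#'   bins).
#' @param mode `"tiled"` (non-overlapping windows covering the record) or
#'   `"growing"` (windows anchored at the record start).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(window_length = 1, bin_width = 20,
                        mode = c("tiled", "growing")) {
  mode <- match.arg(mode)
  bins <- window_length * 1000 / bin_width
  if (bins <= 0 || abs(bins - round(bins)) > 1e-9)
    stop("'window_length' must be a positive multiple of the bin width")
  structure(list(window_length = window_length, bin_width = bin_width,
                 n_bins = as.integer(round(bins)), mode = mode),
            class = "window_spec")
}

## Row slice of a globally centered matrix.  The slice keeps the centered
## flag: the window-local mean is deliberately never re-subtracted, so all
## windows share one reference frame.
.slice_rows <- function(matrix, rows) {
  out <- data_matrix(matrix$values[rows, , drop = FALSE], centered = FALSE,
                     provenance = matrix$provenance)
  out$centered <- matrix$centered
  out$feature_means <- matrix$feature_means
  out
}

.window_starts <- function(n_rows, n_bins) {
  if (n_bins > n_rows) stop("window is longer than the record")
  seq.int(1L, n_rows - n_bins + 1L, by = n_bins)
}

#' Dimensionality in tiled time windows
#'
#' Splits the (globally centered) record into consecutive non-overlapping
#' windows and computes the cumulative-variance dimensionality of each
#' window's rows.
#'
#' @param matrix A centered [data_matrix()] (time bins x features).
#' @param spec A [window_spec()].
#' @param variance_threshold Cumulative-variance threshold.
#' @return Integer vector of per-window dimensionalities, named by window
#'   start bin.
#' @export
windowed_dimensionality <- function(matrix, spec = window_spec(),
                                    variance_threshold = 0.9) {
  stopifnot(inherits(matrix, "data_matrix"), inherits(spec, "window_spec"))
  if (!matrix$centered)
    stop("windowed analyses require a globally centered matrix")
  starts <- .window_starts(nrow(matrix$values), spec$n_bins)
  out <- vapply(starts, function(s) {
    dimensionality(.slice_rows(matrix, s:(s + spec$n_bins - 1L)),
                   variance_threshold)
  }, 1L)
  names(out) <- starts
  out
}

#' Dimensionality with growing windows
#'
#' Windows always start at the beginning of the record and grow in steps of
#' the base window length; the final (full-record) value equals
#' `dimensionality(matrix)`.
#'
#' @inheritParams windowed_dimensionality
#' @return Integer vector of dimensionalities, one per window length.
#' @export
growing_window_dimensionality <- function(matrix, spec = window_spec(),
                                          variance_threshold = 0.9) {
  stopifnot(inherits(matrix, "data_matrix"), inherits(spec, "window_spec"))
  if (!matrix$centered)
    stop("windowed analyses require a globally centered matrix")
  n <- nrow(matrix$values)
  if (spec$n_bins > n) stop("window is longer than the record")
  ends <- unique(c(seq.int(spec$n_bins, n, by = spec$n_bins), n))
  out <- vapply(ends, function(e) {
    dimensionality(.slice_rows(matrix, seq_len(e)), variance_threshold)
  }, 1L)
  names(out) <- ends
  out
}

#' Gaussian smoothing of a time series
#'
#' Convolution with a discretized Gaussian kernel; at the edges the kernel
#' is truncated and renormalized to sum to 1 over the available support, so
#' constant series pass through unchanged.
#'
#' @param values Numeric series sampled at uniform intervals.
#' @param kernel_sd Kernel standard deviation in the same time units as
#'   `spacing` (default 1.5, i.e. 1.5 s for 1-s samples).
#' @param spacing Sampling interval (default 1).
#' @return The smoothed series.
#' @export
smooth_curve <- function(values, kernel_sd = 1.5, spacing = 1) {
  n <- length(values)
  if (n == 0L) return(values)
  half <- max(1L, ceiling(4 * kernel_sd / spacing))
  offs <- (-half):half
  w <- stats::dnorm(offs * spacing, sd = kernel_sd)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- i + offs
    ok <- j >= 1L & j <= n
    out[i] <- sum(values[j[ok]] * w[ok]) / sum(w[ok])
  }
  out
}

#' Shuffle time bins
#'
#' Permutes the rows (time bins) of the matrix, identically across all
#' features.  Whole-record dimensionality is exactly invariant; windowed
#' dimensionality is not, which is the point: shuffling breaks temporal
#' correlations, so temporally smooth data shows higher short-window
#' dimensionality after shuffling.
#'
#' @param matrix A [data_matrix()].
#' @param rng_seed Optional RNG seed.
#' @return A `data_matrix` with permuted rows.
#' @export
shuffle_time <- function(matrix, rng_seed = NULL) {
  stopifnot(inherits(matrix, "data_matrix"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  .slice_rows(matrix, sample.int(nrow(matrix$values)))
}

#' Subsampled dimensionality estimates
#'
#' Error bars for dimensionality: repeatedly subsample a fraction of the
#' time bins without replacement, recompute the dimensionality, and report
#' the distribution (its standard deviation is the error bar).
#'
#' @param matrix A centered [data_matrix()].
#' @param fraction Fraction of rows kept per repeat (default 0.5).
#' @param n_repeats Number of repeats (default 100).
#' @param variance_threshold Cumulative-variance threshold.
#' @param rng_seed Optional RNG seed.
#' @return An integer vector of length `n_repeats` with attributes `mean`
#'   and `sd`.
#' @export
subsample_dimensionality <- function(matrix, fraction = 0.5, n_repeats = 100,
                                     variance_threshold = 0.9,
                                     rng_seed = NULL) {
  stopifnot(inherits(matrix, "data_matrix"))
  if (!matrix$centered)
    stop("subsampling analyses require a globally centered matrix")
  n <- nrow(matrix$values)
  n_take <- floor(fraction * n)
  if (n_take < 2L) stop("subsample too small (", n_take, " rows)")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  ks <- vapply(seq_len(n_repeats), function(i) {
    rows <- if (n_take == n) seq_len(n) else sample.int(n, n_take)
    dimensionality(.slice_rows(matrix, rows), variance_threshold)
  }, 1L)
  attr(ks, "mean") <- mean(ks)
  attr(ks, "sd") <- stats::sd(ks)
  ks
}

#' Cross-window similarity matrix
#'
#' Splits the record into tiled windows, extracts each window's basis
#' patterns, and fills a symmetric matrix whose (i, j) entry is the
#' similarity index between the pattern sets of windows i and j (chance via
#' [chance_distribution()] at the matrix's ambient dimension; chance draws
#' are cached per pair of set sizes).  Zero-variance windows are flagged
#' missing (`NA`) and excluded from the off-diagonal mean.
#'
#' @inheritParams windowed_dimensionality
#' @param t Rank threshold.
#' @param n_draws Monte-Carlo draws per distinct size pair.
#' @param rng_seed Optional RNG seed.
#' @return An object of class `similarity_matrix`: `s_values` (symmetric),
#'   `mean_offdiag`, `k_windows`.
#' @export
window_similarity_matrix <- function(matrix, spec = window_spec(),
                                     variance_threshold = 0.9, t = 0.5,
                                     n_draws = 100, rng_seed = NULL) {
  stopifnot(inherits(matrix, "data_matrix"), inherits(spec, "window_spec"))
  if (!matrix$centered)
    stop("windowed analyses require a globally centered matrix")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  starts <- .window_starts(nrow(matrix$values), spec$n_bins)
  if (length(starts) < 2L) stop("need at least two windows")
  pats <- lapply(starts, function(s) {
    sub <- .slice_rows(matrix, s:(s + spec$n_bins - 1L))
    if (max(abs(sub$values)) == 0) return(NULL)  # degenerate window
    pca_patterns(sub, variance_threshold)$patterns
  })
  nw <- length(starts)
  ks <- vapply(pats, function(p) if (is.null(p)) NA_integer_ else ncol(p), 1L)
  ambient <- ncol(matrix$values)
  cache <- new.env(parent = emptyenv())
  chance_mean <- function(ka, kb) {
    key <- paste(sort(c(ka, kb)), collapse = "_")
    if (is.null(cache[[key]]))
      cache[[key]] <- chance_distribution(c(ka, kb), ambient, t = t,
                                          n_draws = n_draws)$mean_chance
    cache[[key]]
  }
  s <- matrix(NA_real_, nw, nw)
  for (i in seq_len(nw)) for (j in i:nw) {
    if (is.na(ks[i]) || is.na(ks[j])) next
    k_agg <- effective_rank(cbind(pats[[i]], pats[[j]]), t = t)
    s[i, j] <- s[j, i] <-
      similarity_index(k_agg, chance_mean(ks[i], ks[j]), c(ks[i], ks[j]))
  }
  off <- s[row(s) != col(s)]
  structure(list(s_values = s, mean_offdiag = mean(off, na.rm = TRUE),
                 k_windows = ks, t = t,
                 variance_threshold = variance_threshold),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix: %d windows, mean off-diagonal s = %.3f\n",
              nrow(x$s_values), x$mean_offdiag))
  invisible(x)
}
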