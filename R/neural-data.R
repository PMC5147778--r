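#' Trial-resolved spike-count raster
#'
#' @param counts Non-negative integer array indexed (neuron, trial, bin).
#' @param bin_width Bin width in milliseconds (default 20).
#' @return An object of class `trial_raster`.
#' @export
trial_raster <- function(counts, bin_width = 20) {
  counts <- as.array(counts)
  if (length(dim(counts)) != 3L)
    stop("'counts' must be a 3-d array (neuron x trial x bin)")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must contain non-negative integers")
  if (any(dim(counts) == 0L)) stop("empty raster")
  stopifnot(bin_width > 0)
  structure(list(counts = counts, bin_width = bin_width),
            class = "trial_raster")
}

#' Trial-averaged firing rates (PSTH set)
#'
#' Rates are in spikes/s (trial-averaged counts divided by the bin width in
#' seconds); the count-vs-rate choice is a pure global scaling and leaves
#' every dimensionality result unchanged.
#'
#' @param rates Numeric matrix, neurons x time bins, spikes/s.
#' @param bin_width Bin width in ms.
#' @param centered Whether each neuron's temporal mean has been removed.
#' @param feature_means Per-neuron mean rates recorded at centering.
#' @return An object of class `psth_set`.
#' @export
psth_set <- function(rates, bin_width = 20, centered = FALSE,
                     feature_means = NULL) {
  rates <- as.matrix(rates)
  if (centered) {
    rs <- rowMeans(rates)
    rn <- sqrt(rowSums(rates^2))
    if (any(abs(rs) > 1e-9 * pmax(rn, 1)))
      stop("declared centered but row means are not zero")
  }
  structure(list(rates = rates, bin_width = bin_width,
                 centered = isTRUE(centered), feature_means = feature_means),
            class = "psth_set")
}

#' @export
print.psth_set <- function(x, ...) {
  cat(sprintf("psth_set: %d neurons x %d bins of %g ms%s\n",
              nrow(x$rates), ncol(x$rates), x$bin_width,
              if (x$centered) " (centered)" else ""))
  invisible(x)
}

#' Build a PSTH set from a trial raster
#'
#' Averages spike counts across trials and converts to spikes/s.
#'
#' @param raster A [trial_raster()].
#' @return An uncentered [psth_set()].
#' @export
#' @examples
#' counts <- array(c(1L, 3L), dim = c(1, 2, 1))
#' build_psth(trial_raster(counts))$rates  # 100 spikes/s
build_psth <- function(raster) {
  stopifnot(inherits(raster, "trial_raster"))
  rates <- apply(raster$counts, c(1L, 3L), mean) / (raster$bin_width / 1000)
  if (is.null(dim(rates))) rates <- matrix(rates, nrow = dim(raster$counts)[1])
  psth_set(rates, bin_width = raster$bin_width)
}

#' Drop low-firing neurons
#'
#' Retains exactly the neurons whose mean rate over all bins is strictly
#' greater than `min_rate` (default 1 spike/s), preserving order.
#'
#' @param psth An uncentered [psth_set()].
#' @param min_rate Threshold in spikes/s.
#' @return A [psth_set()] with the retained neurons (possibly none).
#' @export
rate_filter <- function(psth, min_rate = 1) {
  stopifnot(inherits(psth, "psth_set"))
  if (psth$centered)
    stop("rate_filter() must be applied before centering")
  keep <- rowMeans(psth$rates) > min_rate
  psth_set(psth$rates[keep, , drop = FALSE], bin_width = psth$bin_width)
}

#' Direction-selectivity index
#'
#' `1 - null_response / preferred_response`; 1 means fully direction
#' selective, 0 means equal responses to the two drift directions.
#'
#' @param preferred_response Response to the preferred drift direction,
#'   spikes/s; must be positive.
#' @param null_response Response to the opposite direction, spikes/s.
#' @return The direction index.
#' @export
direction_index <- function(preferred_response, null_response) {
  if (any(preferred_response <= 0))
    stop("direction index undefined for preferred_response <= 0")
  if (any(null_response < 0)) stop("'null_response' must be >= 0")
  1 - null_response / preferred_response
}

#' Planted low-dimensional structure for synthetic PSTHs
#'
#' Describes trial-averaged activity as a weighted sum of orthonormal basis
#' patterns plus a per-neuron mean offset and Gaussian noise, i.e. exactly
#' the decomposition the dimensionality analyses are designed to recover.
#'
#' @param true_patterns Neurons x K matrix with mutually orthonormal columns
#'   (checked to 1e-10).
#' @param latent_weights K x T matrix of time-varying weights.
#' @param mean_offsets Per-neuron constant offsets (recycled scalar allowed).
#' @param noise_sd Standard deviation of additive Gaussian noise, spikes/s.
#' @return An object of class `planted_structure`.
#' @export
planted_structure <- function(true_patterns, latent_weights,
                              mean_offsets = 0, noise_sd = 0) {
  true_patterns <- as.matrix(true_patterns)
  latent_weights <- as.matrix(latent_weights)
  g <- crossprod(true_patterns)
  if (max(abs(g - diag(ncol(true_patterns)))) > 1e-10)
    stop("'true_patterns' must have mutually orthonormal columns")
  if (nrow(latent_weights) != ncol(true_patterns))
    stop("one row of 'latent_weights' per pattern is required")
  stopifnot(noise_sd >= 0)
  structure(list(true_patterns = true_patterns,
                 latent_weights = latent_weights,
                 mean_offsets = rep_len(mean_offsets, nrow(true_patterns)),
                 noise_sd = noise_sd),
            class = "planted_structure")
}

#' Smoothed Gaussian latent-weight series
#'
#' Default latent generator for planted structures: independent standard
#' Gaussian series smoothed with a 3-bin moving average, so planted data has
#' the temporal smoothness of real PSTHs.
#'
#' @param k Number of latent series.
#' @param n_bins Series length.
#' @param seed Optional RNG seed.
#' @param smooth Moving-average width in bins (default 3; 1 disables).
#' @return A k x n_bins matrix.
#' @export
planted_latents <- function(k, n_bins, seed = NULL, smooth = 3) {
  if (!is.null(seed)) set.seed(seed)
  w <- matrix(stats::rnorm(k * n_bins), k, n_bins)
  if (smooth > 1) {
    kern <- rep(1 / smooth, smooth)
    w <- t(apply(w, 1L, function(x)
      stats::filter(x, kern, sides = 2, circular = TRUE)))
  }
  w
}

#' Simulate a PSTH set with planted basis patterns
#'
#' Generates `rates = mean_offsets + patterns %*% weights + noise`.  The
#' ground-truth structure is returned alongside so downstream analyses can
#' be scored against it.
#'
#' @param structure A [planted_structure()].
#' @param n_bins Number of time bins; must equal `ncol(latent_weights)`.
#' @param rng_seed Optional RNG seed for the noise.
#' @param bin_width Bin width in ms (default 20).
#' @return A list with elements `psth` (an uncentered [psth_set()]) and
#'   `structure` (the ground truth).
#' @export
simulate_psths <- function(structure, n_bins = ncol(structure$latent_weights),
                           rng_seed = NULL, bin_width = 20) {
  stopifnot(inherits(structure, "planted_structure"))
  if (ncol(structure$latent_weights) != n_bins)
    stop("'latent_weights' must have n_bins columns")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- nrow(structure$true_patterns)
  rates <- structure$mean_offsets +
    structure$true_patterns %*% structure$latent_weights
  if (structure$noise_sd > 0)
    rates <- rates + matrix(stats::rnorm(n * n_bins, sd = structure$noise_sd),
                            n, n_bins)
  list(psth = psth_set(rates, bin_width = bin_width),
       structure = structure)
}

#' Random orthonormal basis
#'
#' Orthonormalizes an n x k standard-Gaussian matrix; by rotation invariance
#' the resulting subspace is uniform on the Grassmann manifold.  Used for
#' planted structures and for Monte-Carlo chance draws.
#'
#' @param n Ambient dimension.
#' @param k Number of columns; `k <= n`.
#' @return An n x k matrix with orthonormal columns.
#' @export
random_orthonormal <- function(n, k) {
  if (k > n) stop("cannot draw ", k, " orthonormal vectors in dimension ", n)
  qr.Q(qr(matrix(stats::rnorm(n * k), n, k)))[, seq_len(k), drop = FALSE]
}
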