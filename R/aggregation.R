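#' Effective rank of aggregated unit-norm patterns
#'
#' The pattern aggregation statistic: gather unit-norm feature-space vectors
#' (basis patterns from one or more conditions) as the columns of a matrix
#' `V` and count its singular values strictly greater than the rank
#' threshold `t`.  An absolute floor of `1e-10` times the largest singular
#' value is always applied, so exact duplicate columns never inflate the
#' rank even at `t = 0`.
#'
#' With two unit columns at angle `theta` the singular values are
#' `sqrt(1 + |cos theta|)` and `sqrt(1 - |cos theta|)`, so the rank rises
#' from 1 to 2 when `|cos theta| < 1 - t^2`; at the default `t = 0.5` the
#' transition sits near 41 degrees, and as `t` approaches 1 the two patterns
#' must be orthogonal to count separately.
#'
#' @param columns Numeric matrix whose columns are unit-norm (within 1e-8)
#'   feature-space vectors; typically `cbind()` of pattern sets.
#' @param t Rank threshold in (0, 1] (0 is also accepted; the absolute
#'   floor then governs).
#' @return Integer count of singular values above the threshold.
#' @export
#' @examples
#' v <- cbind(c(1, 0), c(cos(pi / 3), sin(pi / 3)))
#' effective_rank(v, t = 0.5)  # 2: sigma_2 = sqrt(1 - cos 60) ~ 0.707
effective_rank <- function(columns, t = 0.5) {
  columns <- as.matrix(columns)
  if (ncol(columns) < 1L) stop("need at least one column")
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t > 1)
    stop("rank threshold 't' must be a single number in [0, 1]")
  nrm <- sqrt(colSums(columns^2))
  if (any(abs(nrm - 1) > 1e-8))
    stop("all columns must be unit vectors (norm 1 within 1e-8)")
  d <- svd(columns, nu = 0, nv = 0)$d
  sum(d > max(t, 1e-10 * d[1]))
}

#' Aggregated dimensionality of several basis-pattern sets
#'
#' Concatenates the pattern sets column-wise and returns the effective rank
#' of the aggregate.  The result always lies in the bracket
#' `[max_i k_i, sum_i k_i]`: it equals the max when every set spans the same
#' subspace and the sum when the sets are mutually orthogonal.
#'
#' @param sets A list of [pca_patterns()] results (or plain orthonormal
#'   matrices) sharing the same ambient (feature) dimension.
#' @param t Rank threshold, see [effective_rank()].
#' @return Integer aggregated dimensionality.
#' @export
aggregate_dimensionality <- function(sets, t = 0.5) {
  cols <- .gather_pattern_columns(sets)
  effective_rank(cols, t = t)
}

.pattern_matrix <- function(x) {
  if (inherits(x, "basis_patterns")) x$patterns else as.matrix(x)
}

.gather_pattern_columns <- function(sets) {
  if (!is.list(sets) || length(sets) < 1L)
    stop("'sets' must be a non-empty list of pattern sets")
  mats <- lapply(sets, .pattern_matrix)
  n <- vapply(mats, nrow, 1L)
  if (length(unique(n)) != 1L)
    stop("all pattern sets must share the same ambient dimension")
  do.call(cbind, mats)
}

#' Monte-Carlo chance level for aggregated dimensionality
#'
#' Repeatedly draws, for each set size `k_i`, an independent uniformly
#' random `k_i`-dimensional orthonormal basis in an `ambient_dim`-dimensional
#' space, and records the aggregated dimensionality of each draw.  When the
#' ambient dimension greatly exceeds the total number of patterns, random
#' subspaces are near-orthogonal and the chance level sits at
#' `sum(set_sizes)`.
#'
#' Drawing from a constrained `M`-dimensional space (`M < N`, e.g. because
#' circuit constraints limit the patterns a population can express) is the
#' same call with `ambient_dim = M`.
#'
#' @param set_sizes Integer vector of per-set pattern counts `k_i`.
#' @param ambient_dim Ambient dimension `N` (or constrained `M`).
#' @param t Rank threshold.
#' @param n_draws Number of Monte-Carlo draws (default 1000; use 1e5 for
#'   tail probabilities).
#' @param rng_seed Optional RNG seed.
#' @return An object of class `chance_dist` with elements `samples`,
#'   `ambient_dim`, `n_draws`, `mean_chance`, `set_sizes`, `t`.
#' @export
chance_distribution <- function(set_sizes, ambient_dim, t = 0.5,
                                n_draws = 1000, rng_seed = NULL) {
  set_sizes <- as.integer(set_sizes)
  stopifnot(length(set_sizes) >= 1L, all(set_sizes >= 1L), n_draws >= 1)
  if (any(set_sizes > ambient_dim))
    stop("cannot draw ", max(set_sizes), " orthonormal patterns in an ",
         ambient_dim, "-dimensional space")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  samples <- vapply(seq_len(n_draws), function(i) {
    cols <- do.call(cbind, lapply(set_sizes, function(k)
      random_orthonormal(ambient_dim, k)))
    effective_rank(cols, t = t)
  }, 1L)
  structure(list(samples = samples, ambient_dim = ambient_dim,
                 n_draws = as.integer(n_draws),
                 mean_chance = mean(samples),
                 set_sizes = set_sizes, t = t),
            class = "chance_dist")
}

#' @export
print.chance_dist <- function(x, ...) {
  cat(sprintf(
    "chance_dist: mean %.2f (sd %.2f) over %d draws; sets (%s) in N = %d, t = %g\n",
    x$mean_chance, stats::sd(x$samples), x$n_draws,
    paste(x$set_sizes, collapse = ", "), x$ambient_dim, x$t))
  invisible(x)
}

#' Similarity index
#'
#' Normalizes the gap between the mean chance dimensionality and the
#' observed aggregated dimensionality by the spread between the two
#' extremes: `s = (mean_chance - k_agg) / (sum(k) - max(k))`.  `s > 0`
#' means the pattern sets overlap more than randomly drawn subspaces would;
#' `s < 0` means they are closer to orthogonal than chance.  For more than
#' two sets the same normalization is used with the max over all sets.
#'
#' @param k_agg Observed aggregated dimensionality.
#' @param mean_chance Mean of the chance distribution (or a
#'   [chance_distribution()] object).
#' @param set_sizes Per-set pattern counts.
#' @return The similarity index; lies in `[-1, 1]` whenever `mean_chance`
#'   lies inside the bracket.
#' @export
#' @examples
#' similarity_index(80, 88, c(24, 64))  # 8/24 = 0.33
similarity_index <- function(k_agg, mean_chance, set_sizes) {
  if (inherits(mean_chance, "chance_dist")) mean_chance <- mean_chance$mean_chance
  stopifnot(length(set_sizes) >= 1L)
  denom <- sum(set_sizes) - max(set_sizes)
  if (denom == 0)
    stop("similarity index undefined for a single pattern set")
  (mean_chance - k_agg) / denom
}

#' Permutation probability against the random-subspace null
#'
#' Tail probability of the observed aggregated dimensionality under the
#' Monte-Carlo chance distribution, with the add-one (pseudo-count)
#' estimator so the probability is never exactly zero:
#' for `alternative = "overlap"` (patterns more shared than chance),
#' `p = (1 + #\{samples <= k_agg\}) / (1 + n_draws)`; for
#' `"orthogonal"` the tail is mirrored.
#'
#' @param k_agg Observed aggregated dimensionality.
#' @param chance A [chance_distribution()] result.
#' @param alternative `"overlap"` or `"orthogonal"`.
#' @return The permutation probability.
#' @export
permutation_pvalue <- function(k_agg, chance,
                               alternative = c("overlap", "orthogonal")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(chance, "chance_dist"), length(chance$samples) >= 1L)
  hits <- switch(alternative,
                 overlap = sum(chance$samples <= k_agg),
                 orthogonal = sum(chance$samples >= k_agg))
  (1 + hits) / (1 + chance$n_draws)
}

#' Pattern-aggregation similarity analysis
#'
#' The package's central estimator.  Given two or more conditions - each a
#' centered [data_matrix()] (patterns are extracted at
#' `variance_threshold`), a [pca_patterns()] result, or a plain orthonormal
#' matrix - it computes the per-condition dimensionalities, the aggregated
#' dimensionality under the rank threshold, the Monte-Carlo chance level,
#' the similarity index, and the permutation probability of the observed
#' overlap.
#'
#' @param sets List of conditions (see above).
#' @param variance_threshold Cumulative-variance threshold used when a
#'   condition is supplied as a data matrix.
#' @param t Rank threshold for the effective rank.
#' @param n_draws Monte-Carlo draws for the chance level.
#' @param rng_seed Optional RNG seed for the chance draws.
#' @param alternative Tail for the permutation probability.
#' @return An object of class `pattern_similarity`: `k_sets`, `k_agg`,
#'   `lower_bound`, `upper_bound`, `chance`, `s`, `p_value`, plus the
#'   thresholds used.
#' @export
#' @examples
#' n <- 40
#' a <- random_orthonormal(n, 3)
#' x1 <- data_matrix(matrix(rnorm(60 * 3), 60, 3) %*% t(a)) |> center_features()
#' x2 <- data_matrix(matrix(rnorm(60 * 3), 60, 3) %*% t(a)) |> center_features()
#' fit <- pattern_similarity(list(x1, x2), n_draws = 100, rng_seed = 1)
#' fit
pattern_similarity <- function(sets, variance_threshold = 0.9, t = 0.5,
                               n_draws = 1000, rng_seed = NULL,
                               alternative = c("overlap", "orthogonal")) {
  alternative <- match.arg(alternative)
  if (!is.list(sets) || length(sets) < 2L)
    stop("need at least two conditions to compare")
  pats <- lapply(sets, function(x) {
    if (inherits(x, "data_matrix"))
      pca_patterns(x, variance_threshold)$patterns
    else .pattern_matrix(x)
  })
  k_sets <- vapply(pats, ncol, 1L)
  ambient <- nrow(pats[[1]])
  k_agg <- aggregate_dimensionality(pats, t = t)
  chance <- chance_distribution(k_sets, ambient, t = t, n_draws = n_draws,
                                rng_seed = rng_seed)
  s <- similarity_index(k_agg, chance, k_sets)
  p <- permutation_pvalue(k_agg, chance, alternative)
  structure(
    list(k_sets = k_sets, k_agg = k_agg,
         lower_bound = max(k_sets), upper_bound = sum(k_sets),
         chance = chance, s = s, p_value = p,
         variance_threshold = variance_threshold, t = t,
         alternative = alternative, ambient_dim = ambient),
    class = "pattern_similarity")
}

#' @export
print.pattern_similarity <- function(x, ...) {
  cat("Pattern-aggregation similarity\n")
  cat(sprintf("  per-condition dimensionalities: %s (ambient %d)\n",
              paste(x$k_sets, collapse = ", "), x$ambient_dim))
  cat(sprintf("  aggregated dimensionality k = %d  [bracket %d-%d]\n",
              x$k_agg, x$lower_bound, x$upper_bound))
  cat(sprintf("  chance %.2f (%d draws)  similarity index s = %.2f  p = %.3g (%s)\n",
              x$chance$mean_chance, x$chance$n_draws, x$s, x$p_value,
              x$alternative))
  invisible(x)
}

#' @export
summary.pattern_similarity <- function(object, ...) {
  out <- c(k_agg = object$k_agg, lower = object$lower_bound,
           upper = object$upper_bound, chance = object$chance$mean_chance,
           chance_sd = stats::sd(object$chance$samples),
           s = object$s, p = object$p_value)
  class(out) <- "summary.pattern_similarity"
  out
}

#' @export
print.summary.pattern_similarity <- function(x, ...) {
  print(round(unclass(x), 4))
  invisible(x)
}

#' Aggregated dimensionality with an equalized pattern budget
#'
#' Control analysis for comparing aggregated dimensionality across different
#' numbers of conditions: a larger condition count mechanically aggregates
#' more patterns, so for each condition count `m` (using the first `m`
#' conditions) patterns are gathered from repeated time-bin subsamples of
#' each condition, with the number of subsampled pattern sets per condition
#' chosen as `ceiling(n_conditions * n_subsamples / m)` so every condition
#' count contributes the same total number of pattern sets.
#'
#' With `n_subsamples = 1, subsample_fraction = 1` the largest condition
#' count reduces to plain [aggregate_dimensionality()], and duplicated
#' full-data subsamples add no rank.
#'
#' @param matrices List of centered [data_matrix()] objects sharing a
#'   feature space, one per condition.
#' @param n_conditions Number of condition counts to sweep (1..n).
#' @param variance_threshold Per-condition PCA threshold.
#' @param t Rank threshold.
#' @param subsample_fraction Fraction of time bins drawn (without
#'   replacement) per subsample.
#' @param n_subsamples Subsampled pattern sets per condition at the largest
#'   condition count.
#' @param rng_seed Optional RNG seed.
#' @return Named integer vector of aggregated dimensionalities, one per
#'   condition count `1..n_conditions`.
#' @export
equalized_aggregate <- function(matrices, n_conditions = length(matrices),
                                variance_threshold = 0.9, t = 0.5,
                                subsample_fraction = 0.5, n_subsamples = 10,
                                rng_seed = NULL) {
  stopifnot(is.list(matrices), n_conditions >= 1L,
            n_conditions <= length(matrices))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  budget <- n_conditions * n_subsamples
  out <- integer(n_conditions)
  for (m in seq_len(n_conditions)) {
    reps <- ceiling(budget / m)
    cols <- list()
    for (ci in seq_len(m)) {
      mat <- matrices[[ci]]
      stopifnot(inherits(mat, "data_matrix"))
      n_rows <- nrow(mat$values)
      n_take <- floor(subsample_fraction * n_rows)
      if (n_take < 2L)
        stop("subsample of ", n_take, " rows is too small to extract patterns")
      for (r in seq_len(reps)) {
        rows <- if (n_take == n_rows) seq_len(n_rows)
                else sample.int(n_rows, n_take)
        sub <- data_matrix(mat$values[rows, , drop = FALSE], centered = FALSE)
        ## global centering is the reference frame; do not re-center rows
        sub$centered <- TRUE
        cols[[length(cols) + 1L]] <- pca_patterns(sub, variance_threshold)$patterns
      }
    }
    out[m] <- effective_rank(do.call(cbind, cols), t = t)
  }
  names(out) <- seq_len(n_conditions)
  out
}
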