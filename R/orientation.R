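#' Dimensionality versus number of consecutive orientations
#'
#' For each condition count `m = 1..n`, aggregates the basis-pattern sets
#' of every cyclic run of `m` consecutive orientation conditions (all `n`
#' starting orientations contribute at every `m`, wrapping around 360
#' degrees) and reports the mean and standard error of the aggregated
#' dimensionality over starts, together with a Monte-Carlo chance curve
#' computed from the same per-condition pattern counts.
#'
#' @param psths List of conditions, one per orientation, each a centered
#'   [data_matrix()], a [pca_patterns()] result, or an orthonormal matrix.
#' @param variance_threshold Per-condition PCA threshold.
#' @param t Rank threshold.
#' @param n_chance_draws Draws per chance evaluation (kept modest; the
#'   chance level is smooth in the set sizes).
#' @param rng_seed Optional RNG seed for the chance draws.
#' @return An object of class `orientation_sweep`: data frame `sweep` with
#'   columns `m`, `mean_k`, `se_k`, `chance`, plus `k_single` (the
#'   per-orientation dimensionalities).
#' @export
consecutive_orientation_sweep <- function(psths, variance_threshold = 0.9,
                                          t = 0.5, n_chance_draws = 50,
                                          rng_seed = NULL) {
  pats <- .sweep_patterns(psths, variance_threshold)
  n <- length(pats)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  ks <- vapply(pats, ncol, 1L)
  ambient <- nrow(pats[[1]])
  rows <- lapply(seq_len(n), function(m) {
    kk <- vapply(seq_len(n), function(start) {
      idx <- ((start - 1 + seq_len(m) - 1) %% n) + 1
      if (m == 1L) ks[idx] else aggregate_dimensionality(pats[idx], t = t)
    }, 1L)
    ## chance from the same set sizes (first start; sizes differ little)
    ch <- if (m == 1L) mean(ks) else
      chance_distribution(ks[((seq_len(m) - 1) %% n) + 1], ambient, t = t,
                          n_draws = n_chance_draws)$mean_chance
    data.frame(m = m, mean_k = mean(kk),
               se_k = stats::sd(kk) / sqrt(length(kk)), chance = ch)
  })
  structure(list(sweep = do.call(rbind, rows), k_single = ks,
                 variance_threshold = variance_threshold, t = t),
            class = "orientation_sweep")
}

.sweep_patterns <- function(psths, variance_threshold) {
  if (!is.list(psths) || length(psths) < 2L)
    stop("need a list with one condition per orientation")
  lapply(psths, function(x) {
    if (inherits(x, "data_matrix"))
      pca_patterns(x, variance_threshold)$patterns
    else .pattern_matrix(x)
  })
}

#' @export
print.orientation_sweep <- function(x, ...) {
  cat("orientation sweep (dimensionality vs number of conditions)\n")
  print(x$sweep, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Dimensionality versus angular offset between two orientations
#'
#' For each offset (one orientation step up to 180 degrees), aggregates the
#' basis patterns of every orientation pair at that offset.  The 0-degree
#' reference aggregates, for each orientation, the patterns of several
#' time-bin subsampled runs of the *same* condition, so that the number of
#' aggregated patterns is equalized with the two-condition offsets.
#'
#' @inheritParams consecutive_orientation_sweep
#' @param n_zero_subsamples Subsampled pattern sets used for the 0-degree
#'   reference (default 2, matching the two sets aggregated at nonzero
#'   offsets).
#' @param subsample_fraction Fraction of time bins per subsampled run.
#' @return An object of class `orientation_sweep` whose `sweep` data frame
#'   has columns `offset_deg`, `mean_k`, `se_k`, `chance`.
#' @export
angle_offset_sweep <- function(psths, variance_threshold = 0.9, t = 0.5,
                               n_chance_draws = 50, n_zero_subsamples = 2,
                               subsample_fraction = 0.5, rng_seed = NULL) {
  n <- length(psths)
  step <- 360 / n
  pats <- .sweep_patterns(psths, variance_threshold)
  ks <- vapply(pats, ncol, 1L)
  ambient <- nrow(pats[[1]])
  if (!is.null(rng_seed)) set.seed(rng_seed)
  offsets <- seq_len(n %/% 2) * step
  rows <- lapply(seq_along(offsets), function(oi) {
    kk <- vapply(seq_len(n), function(start) {
      j <- ((start - 1 + oi) %% n) + 1
      aggregate_dimensionality(list(pats[[start]], pats[[j]]), t = t)
    }, 1L)
    ch <- chance_distribution(c(ks[1], ks[1 + oi]), ambient, t = t,
                              n_draws = n_chance_draws)$mean_chance
    data.frame(offset_deg = offsets[oi], mean_k = mean(kk),
               se_k = stats::sd(kk) / sqrt(length(kk)), chance = ch)
  })
  ## 0-degree reference with an equalized pattern count
  zero <- vapply(seq_len(n), function(ci) {
    x <- psths[[ci]]
    if (!inherits(x, "data_matrix"))
      return(ks[ci])                     # pattern sets cannot be subsampled
    nr <- nrow(x$values)
    n_take <- max(2L, floor(subsample_fraction * nr))
    cols <- lapply(seq_len(n_zero_subsamples), function(r) {
      sub <- .slice_rows(x, sample.int(nr, n_take))
      pca_patterns(sub, variance_threshold)$patterns
    })
    effective_rank(do.call(cbind, cols), t = t)
  }, 1L)
  rows <- c(list(data.frame(offset_deg = 0, mean_k = mean(zero),
                            se_k = stats::sd(zero) / sqrt(n),
                            chance = NA_real_)), rows)
  structure(list(sweep = do.call(rbind, rows), k_single = ks,
                 variance_threshold = variance_threshold, t = t),
            class = "orientation_sweep")
}

#' Sweep curves over a grid of variance and rank thresholds
#'
#' Repeats [consecutive_orientation_sweep()] for every combination of
#' cumulative-variance threshold and rank threshold.
#'
#' @inheritParams consecutive_orientation_sweep
#' @param variance_thresholds Vector of cumulative-variance thresholds.
#' @param rank_thresholds Vector of rank thresholds.
#' @return A list of `orientation_sweep` objects indexed
#'   `[[variance]][[rank]]` with names giving the thresholds.
#' @export
threshold_grid <- function(psths, variance_thresholds = c(0.7, 0.8, 0.9),
                           rank_thresholds = 0.5, n_chance_draws = 50,
                           rng_seed = NULL) {
  out <- lapply(variance_thresholds, function(v) {
    inner <- lapply(rank_thresholds, function(tt)
      consecutive_orientation_sweep(psths, variance_threshold = v, t = tt,
                                    n_chance_draws = n_chance_draws,
                                    rng_seed = rng_seed))
    names(inner) <- as.character(rank_thresholds)
    inner
  })
  names(out) <- as.character(variance_thresholds)
  out
}
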