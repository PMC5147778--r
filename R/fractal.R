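#' Neighbor-count curve for correlation (fractal) dimensionality
#'
#' For each radius `r`, counts the mean number of *other* points within
#' Euclidean distance `r` of each point.  Plotted as log mean count against
#' log radius, the slope in the scaling region is the correlation (fractal)
#' dimensionality of the point cloud.  Natural logarithms are used
#' throughout (the slope is base-invariant when both axes share the base).
#'
#' @param points A numeric matrix (rows are points) or a [data_matrix()].
#' @param radii Optional increasing positive radii; by default 50
#'   logarithmically spaced radii between the 1st and 99th percentiles of
#'   the pairwise distances.
#' @param n_radii Number of default radii.
#' @return An object of class `neighbor_curve` with `radii`, `log_counts`
#'   (`-Inf` where no neighbors fall inside), and `n_points`.
#' @export
neighbor_curve <- function(points, radii = NULL, n_radii = 50) {
  if (inherits(points, "data_matrix")) points <- points$values
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 points")
  dv <- as.numeric(stats::dist(points))
  if (max(dv) == 0) stop("degenerate cloud: all points identical")
  if (is.null(radii)) {
    qs <- stats::quantile(dv[dv > 0], c(0.01, 0.99), names = FALSE)
    radii <- exp(seq(log(qs[1]), log(qs[2]), length.out = n_radii))
  }
  if (any(diff(radii) <= 0) || any(radii <= 0))
    stop("'radii' must be positive and increasing")
  dv <- sort(dv)
  ## each unordered pair counted once in dv; each point sees the pair once
  counts <- 2 * findInterval(radii, dv) / n
  structure(list(radii = radii, log_counts = log(counts), n_points = n),
            class = "neighbor_curve")
}

#' @export
print.neighbor_curve <- function(x, ...) {
  cat(sprintf("neighbor_curve: %d radii over %d points, log N in [%.2f, %.2f]\n",
              length(x$radii), x$n_points,
              min(x$log_counts[is.finite(x$log_counts)]), max(x$log_counts)))
  invisible(x)
}

#' @export
plot.neighbor_curve <- function(x, ...) {
  graphics::plot(log(x$radii), x$log_counts, type = "b",
                 xlab = "log r", ylab = "log N(r)", ...)
  invisible(x)
}

#' Fractal dimensionality from a neighbor curve
#'
#' Ordinary least-squares slope of log neighbor count versus log radius,
#' restricted to the curve points whose log count lies inside `bounds`
#' (bounds are on the log-neighbor axis; the default (6, 12) suits clouds
#' of hundreds-to-thousands of points, (4, 10) smaller ones).
#'
#' @param curve A [neighbor_curve()].
#' @param bounds Length-2 interval on log N.
#' @return The fitted slope (fractal dimensionality).
#' @export
#' @examples
#' pts <- cbind(runif(2000), runif(2000))       # points on a plane
#' nc <- neighbor_curve(pts)
#' fractal_dimensionality(nc, bounds = c(3, 6)) # about 2
fractal_dimensionality <- function(curve, bounds = c(6, 12)) {
  stopifnot(inherits(curve, "neighbor_curve"), length(bounds) == 2L)
  keep <- is.finite(curve$log_counts) &
    curve$log_counts >= min(bounds) & curve$log_counts <= max(bounds)
  if (sum(keep) < 2L)
    stop("fewer than 2 curve points inside the log-count bounds")
  fit <- stats::lm(curve$log_counts[keep] ~ log(curve$radii[keep]))
  unname(stats::coef(fit)[2])
}
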