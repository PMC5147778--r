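#' Read and write PSTH sets as CSV
#'
#' One row per neuron; the header row holds the bin start times in ms.
#'
#' @param psth A [psth_set()].
#' @param path File path.
#' @return `read_psth_csv()` returns a [psth_set()];
#'   `write_psth_csv()` returns `path` invisibly.
#' @export
write_psth_csv <- function(psth, path) {
  stopifnot(inherits(psth, "psth_set"))
  starts <- (seq_len(ncol(psth$rates)) - 1L) * psth$bin_width
  m <- psth$rates
  colnames(m) <- starts
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_psth_csv
#' @export
read_psth_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  starts <- as.numeric(colnames(m))
  bw <- if (length(starts) > 1L) starts[2] - starts[1] else 20
  dimnames(m) <- NULL
  psth_set(m, bin_width = bw)
}

#' Read and write basis-pattern sets as CSV
#'
#' Patterns are stored as columns; the variance fractions and threshold go
#' in a commented header line.
#'
#' @param patterns A [pca_patterns()] result.
#' @param path File path.
#' @return `read_patterns_csv()` returns a `basis_patterns` object;
#'   the writer returns `path` invisibly.
#' @export
write_patterns_csv <- function(patterns, path) {
  stopifnot(inherits(patterns, "basis_patterns"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# variance_threshold=%.17g", patterns$variance_threshold), con)
  writeLines(paste0("# variance_fractions=",
                    paste(sprintf("%.17g", patterns$variance_fractions),
                          collapse = ",")), con)
  utils::write.table(patterns$patterns, con, sep = ",", row.names = FALSE,
                     col.names = paste0("pattern", seq_len(patterns$k)))
  invisible(path)
}

#' @rdname write_patterns_csv
#' @export
read_patterns_csv <- function(path) {
  lines <- readLines(path, n = 2L)
  thr <- as.numeric(sub("# variance_threshold=", "", lines[1], fixed = TRUE))
  fr <- as.numeric(strsplit(sub("# variance_fractions=", "", lines[2],
                                fixed = TRUE), ",")[[1]])
  m <- as.matrix(utils::read.csv(path, comment.char = "#"))
  dimnames(m) <- NULL
  structure(list(patterns = m, variance_fractions = fr,
                 variance_threshold = thr, ambient_dim = nrow(m),
                 k = ncol(m)),
            class = "basis_patterns")
}

#' Serialize a pattern-similarity result to JSON
#'
#' Writes the observed per-set dimensionalities, aggregated dimensionality,
#' bracket bounds, chance summary (mean, sd, draws), similarity index,
#' permutation probability and the thresholds used - enough to regenerate a
#' summary figure from the file alone.
#'
#' @param result A [pattern_similarity()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_json <- function(result, path) {
  stopifnot(inherits(result, "pattern_similarity"))
  obj <- list(
    k_sets = result$k_sets, k_agg = result$k_agg,
    lower_bound = result$lower_bound, upper_bound = result$upper_bound,
    chance = list(mean = result$chance$mean_chance,
                  sd = stats::sd(result$chance$samples),
                  n_draws = result$chance$n_draws,
                  ambient_dim = result$chance$ambient_dim),
    s = result$s, p_value = result$p_value,
    variance_threshold = result$variance_threshold, t = result$t,
    alternative = result$alternative)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write or read a movie as multi-page grayscale TIFF
#'
#' Frames are clamped to [0, 1] for storage.  Requires the `tiff` package.
#'
#' @param movie A [movie_stimulus()].
#' @param path File path.
#' @return The reader returns a [movie_stimulus()]; the writer returns
#'   `path` invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF output")
  stopifnot(inherits(movie, "movie_stimulus"))
  frames <- lapply(seq_len(dim(movie$frames)[1]), function(f)
    pmin(pmax(movie$frames[f, , ], 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @param frame_duration_ms Frame duration to attach on read.
#' @export
read_movie_tiff <- function(path, frame_duration_ms = 40) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF input")
  frames <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(length(frames), nrow(frames[[1]]), ncol(frames[[1]])))
  for (f in seq_along(frames)) arr[f, , ] <- frames[[f]]
  movie_stimulus(arr, frame_duration_ms = frame_duration_ms)
}

#' Write or read receptive-field parameter sets as YAML
#'
#' One block per neuron plus the distribution config.  Requires the `yaml`
#' package.
#'
#' @param params An `rf_params` object.
#' @param path File path.
#' @return The reader returns an `rf_params` object; the writer returns
#'   `path` invisibly.
#' @export
write_rf_params_yaml <- function(params, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for YAML output")
  stopifnot(inherits(params, "rf_params"))
  yaml::write_yaml(list(config = params$config, neurons = params$neurons),
                   path, precision = 17)
  invisible(path)
}

#' @rdname write_rf_params_yaml
#' @export
read_rf_params_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for YAML input")
  obj <- yaml::read_yaml(path)
  structure(list(neurons = obj$neurons, config = obj$config),
            class = "rf_params")
}
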