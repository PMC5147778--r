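#' Default parameter distributions for the V1 receptive-field model
#'
#' Fixed values follow the model description (temporal frequency 6.25 Hz;
#' untuned-filter scales 20 and 30 px; temporal support 15 frames; RF
#' centers Gaussian with mean 160 px and variance 20, taken literally so the
#' sd is about 4.5 px; envelope base `sigma_x = 20 + |standard normal|`).
#' The remaining per-neuron parameters have no published closed form, so
#' plausible, fully overridable defaults are shipped: aspect ratio `c`
#' lognormal (median 1.7, log-sd 0.3); spatial frequency `gamma_s`
#' lognormal (median 0.13 cycles/px, log-sd 0.4); suppression weight
#' `omega` half-normal (sd 0.5); normalization offset `sigma_offset`
#' lognormal (median 0.1, log-sd 0.5); output exponent `q` uniform(1, 3);
#' direction-selectivity constant `d` uniform(0, 1), with the temporal
#' envelope `sigma_t = 8 d`.
#'
#' @param center_mean Mean of the RF-center coordinates in px (160 centers
#'   the RFs on a 320-px frame).
#' @param center_var Variance of the RF-center coordinates (px^2).
#' @return A list of distribution settings consumed by
#'   [sample_rf_params()].
#' @export
default_rf_config <- function(center_mean = 160, center_var = 20) {
  list(center_mean = center_mean, center_sd = sqrt(center_var),
       sigma_x_base = 20, sigma1 = 20, sigma2 = 30, T = 15,
       temporal_freq = 6.25,
       c_meanlog = log(1.7), c_sdlog = 0.3,
       gamma_s_meanlog = log(0.13), gamma_s_sdlog = 0.4,
       omega_sd = 0.5,
       sigma_offset_meanlog = log(0.1), sigma_offset_sdlog = 0.5,
       q_min = 1, q_max = 3,
       d_min = 0, d_max = 1)
}

#' Sample receptive-field model neurons
#'
#' Draws per-neuron parameters: RF center (Gaussian), spatial phase `phi`
#' uniform on [0, 2 pi), orientation `theta` uniform on [0, pi), drift
#' direction `beta` from \{0, pi\}, `sigma_x = sigma_x_base + |N(0,1)|`,
#' `sigma_y = c sigma_x`, `sigma_t = 8 d`, and the config-driven
#' distributions of [default_rf_config()].
#'
#' @param n_neurons Number of model neurons (at least 2; divisive
#'   normalization pools over the other neurons).
#' @param rng_seed Optional RNG seed.
#' @param config Distribution settings, see [default_rf_config()].
#' @return An object of class `rf_params`: a list of per-neuron parameter
#'   lists with the config attached.
#' @export
sample_rf_params <- function(n_neurons, rng_seed = NULL,
                             config = default_rf_config()) {
  if (n_neurons < 2L) stop("the model needs at least 2 neurons")
  for (nm in c("q_min", "q_max", "d_min", "d_max"))
    if (!is.numeric(config[[nm]])) stop("invalid config: missing ", nm)
  if (config$q_min > config$q_max || config$d_min > config$d_max ||
      config$d_min < 0 || config$d_max > 1)
    stop("invalid config ranges")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  neurons <- lapply(seq_len(n_neurons), function(i) {
    cc <- stats::rlnorm(1, config$c_meanlog, config$c_sdlog)
    sx <- config$sigma_x_base + abs(stats::rnorm(1))
    d <- stats::runif(1, config$d_min, config$d_max)
    list(
      x_loc = stats::rnorm(1, config$center_mean, config$center_sd),
      y_loc = stats::rnorm(1, config$center_mean, config$center_sd),
      phi = stats::runif(1, 0, 2 * pi),
      theta = stats::runif(1, 0, pi),
      beta = sample(c(0, pi), 1),
      sigma_x = sx, sigma_y = cc * sx, c = cc,
      gamma_s = stats::rlnorm(1, config$gamma_s_meanlog, config$gamma_s_sdlog),
      gamma_t = config$temporal_freq,
      d = d, sigma_t = 8 * d,
      omega = abs(stats::rnorm(1, 0, config$omega_sd)),
      sigma_offset = stats::rlnorm(1, config$sigma_offset_meanlog,
                                   config$sigma_offset_sdlog),
      q = stats::runif(1, config$q_min, config$q_max))
  })
  structure(list(neurons = neurons, config = config), class = "rf_params")
}

#' @export
print.rf_params <- function(x, ...) {
  cat(sprintf("rf_params: %d model neurons (T = %d frames)\n",
              length(x$neurons), x$config$T))
  invisible(x)
}

#' Build a neuron's 3-d Gabor filter
#'
#' The filter is the real part of a Gaussian envelope times a complex
#' sinusoid, on coordinates first rotated in space by the orientation
#' `theta`, then in (y, t) by the drift direction `beta`, with the envelope
#' axes scaled by `(sigma_x, sigma_y, sigma_t)` before rotation.  The time
#' index runs over the past `T` frames (`t = -(T-1) .. 0` relative to the
#' current frame).  The stored weights are divided by their Frobenius norm.
#' A direction constant `d = 0` gives `sigma_t = 0`, implemented as its
#' limit: a single-frame temporal delta.
#'
#' @param params One neuron's parameter list (an element of
#'   `sample_rf_params()$neurons`).
#' @param size Spatial support in px (filters are evaluated on the full
#'   frame).
#' @param T Temporal support in frames (default 15).
#' @param frame_rate Frame rate in Hz used to convert the temporal
#'   frequency to cycles/frame (default 25).
#' @return An object of class `gabor_filter`: `weights` (y, x, T) array
#'   with unit Frobenius norm, `norm` (the pre-normalization norm), `T`.
#' @export
build_gabor <- function(params, size, T = 15, frame_rate = 25) {
  p <- params
  xs <- seq_len(size) - p$x_loc
  ys <- seq_len(size) - p$y_loc
  ct <- cos(p$theta); st <- sin(p$theta)
  cb <- cos(p$beta)                      # beta in {0, pi}: +1 or -1
  ## spatially rotated coordinates (beta leaves x untouched and only flips
  ## the sign of y and t, which the squared envelope ignores)
  xr <- outer(ys * (-st), xs * ct, "+")          # x' = ct*dx - st*dy
  xe <- outer(ys * (-st / p$sigma_y), xs * ct / p$sigma_x, "+")
  ye <- outer(ys * (ct / p$sigma_y), xs * st / p$sigma_x, "+")
  env2d <- exp(-0.5 * (xe^2 + ye^2))
  gamma_t_cpf <- p$gamma_t / frame_rate          # cycles per frame
  w <- array(0, dim = c(size, size, T))
  for (tau in seq_len(T)) {
    t_rel <- tau - T                             # -(T-1) .. 0
    t_env <- if (p$sigma_t == 0) as.numeric(t_rel == 0)
             else exp(-0.5 * (t_rel / p$sigma_t)^2)
    if (t_env == 0) next
    arg <- 2 * pi * (p$gamma_s * xr + p$phi + gamma_t_cpf * cb * t_rel)
    w[, , tau] <- env2d * t_env * cos(arg)
  }
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) stop("degenerate filter: zero norm")
  structure(list(weights = w / nrm, norm = nrm, T = T),
            class = "gabor_filter")
}

#' Untuned suppressive filter (difference of 2-d Gaussians)
#'
#' `G_sigma1 - G_sigma2` centered at the neuron's RF location, with each
#' Gaussian carrying the `1/(2 pi sigma^2)` normalization so it integrates
#' to about 1 on sufficient support (hence a constant image yields a near-
#' zero untuned drive).
#'
#' @inheritParams build_gabor
#' @param sigma1,sigma2 Center/surround scales in px (defaults 20, 30).
#' @return A `size x size` matrix of weights.
#' @export
untuned_filter <- function(params, size, sigma1 = 20, sigma2 = 30) {
  g2 <- function(sig) {
    gx <- exp(-0.5 * ((seq_len(size) - params$x_loc) / sig)^2)
    gy <- exp(-0.5 * ((seq_len(size) - params$y_loc) / sig)^2)
    outer(gy, gx) / (2 * pi * sig^2)
  }
  g2(sigma1) - g2(sigma2)
}

#' Model component 1: oriented Gabor filtering with rectification
#'
#' `L1(t)` is the inner product of the 3-d Gabor filter with the past `T`
#' frames; `R1 = max(0, L1)`.  The first `T - 1` timesteps have no full
#' history and are returned as `NA`.
#'
#' @param movie A [movie_stimulus()].
#' @param filter A [build_gabor()] filter.
#' @return A list with numeric vectors `L1` and `R1` (length = frame
#'   count; leading `NA`s).
#' @export
rf_component1 <- function(movie, filter) {
  stopifnot(inherits(movie, "movie_stimulus"), inherits(filter, "gabor_filter"))
  d <- dim(movie$frames)
  T <- filter$T
  if (d[1] < T) stop("movie shorter than the filter's temporal support (",
                     T, " frames)")
  npix <- d[2] * d[3]
  fm <- matrix(movie$frames, d[1], npix)         # frames x pixels
  gm <- matrix(filter$weights, npix, T)          # pixels x lag
  D <- fm %*% gm                                 # frame x lag dot products
  L1 <- rep(NA_real_, d[1])
  for (t in T:d[1])
    L1[t] <- sum(D[cbind(t - T + seq_len(T), seq_len(T))])
  list(L1 = L1, R1 = pmax(0, L1))
}

#' Model component 2: subtraction of untuned suppression
#'
#' The untuned drive `L2` is the inner product of the difference-of-
#' Gaussians filter with the current frame; the rectified, weighted drive
#' `S2 = max(0, omega L2)` is subtracted from `R1`.
#'
#' @param R1 Rectified component-1 response (vector over frames).
#' @param movie A [movie_stimulus()].
#' @param params The neuron's parameter list (uses `omega` and the RF
#'   center).
#' @param sigma1,sigma2 Untuned-filter scales.
#' @return A list with `L2`, `S2` and `R2` vectors.
#' @export
rf_component2 <- function(R1, movie, params, sigma1 = 20, sigma2 = 30) {
  d <- dim(movie$frames)
  gu <- untuned_filter(params, d[2], sigma1, sigma2)
  fm <- matrix(movie$frames, d[1], d[2] * d[3])
  L2 <- as.numeric(fm %*% as.vector(gu))
  S2 <- pmax(0, params$omega * L2)
  list(L2 = L2, S2 = S2, R2 = R1 - S2)
}

#' Model component 3: divisive normalization
#'
#' Each neuron's component-2 output is divided by its offset plus the mean
#' component-1 output of all *other* neurons at the same timestep; the
#' denominator is always at least `sigma_offset > 0` because `R1 >= 0`.
#'
#' @param R2 Neuron x time matrix of component-2 outputs.
#' @param R1 Neuron x time matrix of component-1 outputs.
#' @param sigma_offset Per-neuron positive offsets.
#' @return Neuron x time matrix `R3`.
#' @export
rf_component3 <- function(R2, R1, sigma_offset) {
  R2 <- as.matrix(R2); R1 <- as.matrix(R1)
  n <- nrow(R1)
  if (n < 2L) stop("divisive normalization needs at least 2 neurons")
  stopifnot(all(sigma_offset > 0), length(sigma_offset) %in% c(1L, n))
  other_mean <- (matrix(colSums(R1), n, ncol(R1), byrow = TRUE) - R1) / (n - 1)
  R2 / (sigma_offset + other_mean)
}

#' Model component 4: pointwise nonlinearity
#'
#' `R4 = max(0, R3)^q` elementwise.
#'
#' @param R3 Neuron x time matrix (or vector).
#' @param q Per-neuron positive exponents.
#' @return `R4` with the same shape.
#' @export
rf_component4 <- function(R3, q) {
  stopifnot(all(q > 0))
  r <- as.matrix(R3)
  r[r < 0] <- 0
  r^q
}

#' Run the full four-component receptive-field model
#'
#' Applies components 1-4 of the model to a movie for every neuron in an
#' [sample_rf_params()] set.  The first `T - 1` frames, which lack a full
#' filter history, are dropped from the outputs so downstream
#' dimensionality analyses see no artificial onset transient.
#'
#' @param movie A [movie_stimulus()].
#' @param params An `rf_params` object.
#' @return An object of class `rf_response`: matrices `R1`, `R2`, `R3`,
#'   `R4`, `L1`, `L2` (neuron x retained timestep) and `t_index`, the
#'   frame indices retained.
#' @export
run_rf_model <- function(movie, params) {
  stopifnot(inherits(movie, "movie_stimulus"), inherits(params, "rf_params"))
  cfg <- params$config
  d <- dim(movie$frames)
  if (d[2] != d[3]) stop("the model expects square frames")
  frame_rate <- 1000 / movie$frame_duration_ms
  T <- cfg$T
  n <- length(params$neurons)
  keep <- T:d[1]
  L1 <- R1 <- R2 <- L2 <- matrix(0, n, length(keep))
  for (i in seq_len(n)) {
    p <- params$neurons[[i]]
    flt <- build_gabor(p, size = d[2], T = T, frame_rate = frame_rate)
    c1 <- rf_component1(movie, flt)
    c2 <- rf_component2(c1$R1, movie, p, cfg$sigma1, cfg$sigma2)
    L1[i, ] <- c1$L1[keep]
    R1[i, ] <- c1$R1[keep]
    L2[i, ] <- c2$L2[keep]
    R2[i, ] <- c2$R2[keep]
  }
  soff <- vapply(params$neurons, `[[`, 1.0, "sigma_offset")
  qs <- vapply(params$neurons, `[[`, 1.0, "q")
  R3 <- rf_component3(R2, R1, soff)
  R4 <- rf_component4(R3, qs)
  structure(list(L1 = L1, R1 = R1, L2 = L2, R2 = R2, R3 = R3, R4 = R4,
                 t_index = keep),
            class = "rf_response")
}

#' @export
print.rf_response <- function(x, ...) {
  cat(sprintf("rf_response: %d neurons x %d timesteps (first valid frame %d)\n",
              nrow(x$R1), ncol(x$R1), x$t_index[1]))
  invisible(x)
}

#' Dimensionality of a model component's responses
#'
#' Convenience wrapper: takes a component matrix (neuron x time), treats
#' timesteps as samples, centers, and computes the cumulative-variance
#' dimensionality.
#'
#' @param response An `rf_response` object.
#' @param component One of `"R1"`..`"R4"`.
#' @param variance_threshold Cumulative-variance threshold.
#' @return The dimensionality (integer).
#' @export
rf_dimensionality <- function(response, component = "R4",
                              variance_threshold = 0.9) {
  stopifnot(inherits(response, "rf_response"),
            component %in% c("R1", "R2", "R3", "R4"))
  m <- center_features(data_matrix(t(response[[component]]),
                                   provenance = component))
  dimensionality(m, variance_threshold)
}
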