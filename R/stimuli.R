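#' Grayscale movie stimulus
#'
#' Frames are stored as a numeric array `(frame, y, x)` with luminance in
#' arbitrary units on [0, 1] (mean luminance 0.5); absolute luminance and
#' display gamma are irrelevant to every dimensionality analysis (scale and
#' offset invariance) and are not modelled.
#'
#' @param frames Numeric array `(n_frames, height, width)`, finite values.
#' @param frame_duration_ms Duration of one frame in ms (default 40, i.e.
#'   an effective frame rate of 25 Hz).
#' @return An object of class `movie_stimulus`.
#' @export
movie_stimulus <- function(frames, frame_duration_ms = 40) {
  frames <- as.array(frames)
  if (length(dim(frames)) != 3L)
    stop("'frames' must be a 3-d array (frame, y, x)")
  if (any(!is.finite(frames))) stop("frames must be finite")
  structure(list(frames = frames, frame_duration_ms = frame_duration_ms),
            class = "movie_stimulus")
}

#' @export
print.movie_stimulus <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("movie_stimulus: %d frames of %d x %d px, %g ms/frame (%.3g s)\n",
              d[1], d[2], d[3], x$frame_duration_ms,
              d[1] * x$frame_duration_ms / 1000))
  invisible(x)
}

#' @export
dim.movie_stimulus <- function(x) dim(x$frames)

#' Drifting-gratings movie
#'
#' A pseudo-random sequence of full-contrast drifting sinusoidal gratings:
#' `n_orientations` equally spaced drift directions covering 360 degrees
#' plus `n_blanks` mean-gray elements, each element lasting `element_ms`.
#' At the default 25 Hz effective frame rate, 300 ms is 7.5 frames, so
#' elements alternate 8 and 7 frames and 100 elements give exactly 750
#' frames.  Each grating drifts at `temporal_freq` (phase advances 1/4
#' cycle per frame at the defaults) inside a circular aperture of diameter
#' `aperture` on a mean-gray surround; each element starts at phase 0.
#'
#' @param n_orientations Number of drift directions (default 98, i.e.
#'   3.67 degrees apart).
#' @param spatial_freq Spatial frequency in cycles/degree (default 1.3).
#' @param temporal_freq Drift rate in Hz (default 6.25).
#' @param element_ms Duration of one stimulus element in ms (default 300).
#' @param n_blanks Number of blank (mean-gray) elements inserted at random
#'   positions (default 2).
#' @param size Frame side in pixels (default 640).
#' @param aperture Aperture diameter in pixels (default 640).
#' @param px_per_deg Pixels per degree of visual angle (default 80, i.e.
#'   8 degrees across a 640-px frame).
#' @param contrast Michelson contrast in [0, 1] (default 1).
#' @param frame_rate Effective frame rate in Hz (default 25).
#' @param rng_seed Optional RNG seed for the element sequence.
#' @return A [movie_stimulus()]; the element sequence is attached as
#'   attribute `sequence` (orientation in degrees, `NA` for blanks).
#' @export
gratings_movie <- function(n_orientations = 98, spatial_freq = 1.3,
                           temporal_freq = 6.25, element_ms = 300,
                           n_blanks = 2, size = 640, aperture = 640,
                           px_per_deg = 80, contrast = 1, frame_rate = 25,
                           rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  step <- 360 / n_orientations
  oris <- seq(0, 360 - step, by = step)
  seq_el <- sample(c(sample(oris), rep(NA_real_, n_blanks)))
  n_el <- length(seq_el)
  frames_per <- element_ms * frame_rate / 1000
  if (abs(frames_per - round(frames_per)) < 1e-9) {
    lens <- rep(as.integer(round(frames_per)), n_el)
  } else {
    ## half-integer frame count: alternate ceiling and floor so the total
    ## is exact (300 ms at 25 Hz: 8, 7, 8, 7, ...)
    lens <- rep(c(ceiling(frames_per), floor(frames_per)),
                length.out = n_el)
  }
  n_frames <- sum(lens)
  gs <- spatial_freq / px_per_deg        # cycles per pixel
  dphase <- temporal_freq / frame_rate   # cycles per frame
  cx <- (size + 1) / 2
  xs <- (1:size) - cx
  ys <- (1:size) - cx
  in_ap <- outer(ys^2, xs^2, "+") <= (aperture / 2)^2
  frames <- array(0.5, dim = c(n_frames, size, size))
  f <- 1L
  for (e in seq_len(n_el)) {
    th <- seq_el[e]
    if (is.na(th)) { f <- f + lens[e]; next }
    ## projection onto the drift axis (degrees counterclockwise from the
    ## horizontal): rows are y, columns are x
    u <- outer(ys * sinpi(th / 180), xs * cospi(th / 180), "+")
    for (j in seq_len(lens[e])) {
      g <- 0.5 + 0.5 * contrast * sin(2 * pi * (gs * u - (j - 1) * dphase))
      g[!in_ap] <- 0.5
      frames[f, , ] <- g
      f <- f + 1L
    }
  }
  out <- movie_stimulus(frames, frame_duration_ms = 1000 / frame_rate)
  attr(out, "sequence") <- seq_el
  out
}

#' Jittered white-noise movie
#'
#' Each frame is a grid of `grid x grid` squares of `square x square`
#' pixels, each square's intensity drawn independently (in space and time)
#' from a uniform distribution on [0, 1].  To avoid a static grid artefact
#' the square lattice is shifted by an independent horizontal and vertical
#' jitter of 1..`square` pixels on every frame, with fresh squares entering
#' at the edges.
#'
#' @param n_frames Number of frames (default 750, 30 s at 25 Hz).
#' @param grid Squares per side (default 40).
#' @param square Square side in pixels (default 8; frame side is
#'   `grid * square` = 320 px).
#' @param jitter Logical; disable to keep the lattice aligned with the
#'   fixed preprocessing blocks.
#' @param frame_rate Effective frame rate in Hz (default 25).
#' @param rng_seed Optional RNG seed.
#' @return A [movie_stimulus()] of `grid * square`-pixel square frames.
#' @export
noise_movie <- function(n_frames = 750, grid = 40, square = 8,
                        jitter = TRUE, frame_rate = 25, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  size <- grid * square
  frames <- array(0, dim = c(n_frames, size, size))
  for (f in seq_len(n_frames)) {
    ## one extra row/column of squares so a jittered crop stays covered
    cells <- matrix(stats::runif((grid + 1)^2), grid + 1, grid + 1)
    big <- cells[rep(seq_len(grid + 1), each = square),
                 rep(seq_len(grid + 1), each = square)]
    j <- if (jitter) sample.int(square, 2, replace = TRUE) else c(0L, 0L)
    frames[f, , ] <- big[j[1] + seq_len(size), j[2] + seq_len(size)]
  }
  movie_stimulus(frames, frame_duration_ms = 1000 / frame_rate)
}

#' Synthetic natural-movie surrogate
#'
#' A procedurally generated stand-in for a natural film, reproducing three
#' of its statistical signatures: a 1/f^2 spatial power spectrum, frame-to-
#' frame correlation (first-order autoregressive dynamics on the Fourier
#' coefficients), and a slow global-luminance drift such as zooming or
#' panning produces.  It contains no objects, occlusions or higher-order
#' structure, so conclusions about real films must rest on the spectra and
#' correlations it does emulate.
#'
#' @param n_frames Number of frames (default 750).
#' @param size Frame side in pixels (default 320).
#' @param temporal_correlation AR(1) coefficient of the Fourier field in
#'   [0, 1] (default 0.8; 1 freezes the movie).
#' @param luminance_drift_amplitude Amplitude (luminance sd) of the slow
#'   additive global luminance component (default 0.2, which makes the
#'   leading pixel principal component the global-luminance direction, as
#'   zooming/panning does in real films).
#' @param frame_rate Effective frame rate in Hz (default 25).
#' @param rng_seed Optional RNG seed.
#' @return A [movie_stimulus()].
#' @export
natural_surrogate <- function(n_frames = 750, size = 320,
                              temporal_correlation = 0.8,
                              luminance_drift_amplitude = 0.2,
                              frame_rate = 25, rng_seed = NULL) {
  stopifnot(n_frames >= 1, size >= 2,
            temporal_correlation >= 0, temporal_correlation <= 1,
            luminance_drift_amplitude >= 0)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  ## radial frequency grid (cycles per image side)
  fx <- c(0:(size %/% 2), -((size - size %/% 2 - 1):1)) / size
  fgrid <- sqrt(outer(fx^2, fx^2, "+"))
  amp <- 1 / pmax(fgrid, 1 / size)  # amplitude ~ 1/f  => power ~ 1/f^2
  amp[1, 1] <- 0                    # DC handled by the luminance term
  rho <- temporal_correlation
  innov_sd <- sqrt(1 - rho^2)
  z <- matrix(complex(real = stats::rnorm(size^2),
                      imaginary = stats::rnorm(size^2)), size, size)
  ## slow global luminance: smoothed random walk around mean gray
  if (n_frames >= 2 && luminance_drift_amplitude > 0) {
    wlen <- min(25L, n_frames)
    dv <- as.numeric(stats::filter(stats::rnorm(n_frames), rep(1 / wlen, wlen),
                                   sides = 2, circular = TRUE))
    dv <- dv - mean(dv)
    if (stats::sd(dv) > 0) dv <- dv / stats::sd(dv)
    drift <- luminance_drift_amplitude * dv
  } else {
    drift <- rep(0, n_frames)
  }
  frames <- array(0, dim = c(n_frames, size, size))
  sc <- 0.12 * size  # puts typical pixel contrast well inside [0, 1]
  for (f in seq_len(n_frames)) {
    if (f > 1L && innov_sd > 0) {
      e <- matrix(complex(real = stats::rnorm(size^2),
                          imaginary = stats::rnorm(size^2)), size, size)
      z <- rho * z + innov_sd * e
    }
    img <- Re(stats::fft(amp * z, inverse = TRUE)) / size^2
    frames[f, , ] <- 0.5 + drift[f] + sc * img
  }
  movie_stimulus(frames, frame_duration_ms = 1000 / frame_rate)
}

#' Individual drifting-grating trials
#'
#' One movie per drift direction: `n_orientations` equally spaced
#' directions covering 360 degrees (default 12, 30 degrees apart), each
#' presented for `duration_ms` (default 1280 ms; downstream analyses use
#' the first second).  Directions `i` and `i + n/2` share the spatial
#' pattern and differ only in drift direction.
#'
#' @inheritParams gratings_movie
#' @param duration_ms Trial duration in ms (default 1280).
#' @return A list of [movie_stimulus()] objects, named by direction in
#'   degrees.
#' @export
individual_grating_trials <- function(n_orientations = 12, spatial_freq = 1.3,
                                      temporal_freq = 6.25,
                                      duration_ms = 1280, size = 640,
                                      aperture = 640, px_per_deg = 80,
                                      contrast = 1, frame_rate = 25) {
  step <- 360 / n_orientations
  oris <- seq(0, 360 - step, by = step)
  n_frames <- as.integer(floor(duration_ms * frame_rate / 1000))
  gs <- spatial_freq / px_per_deg
  dphase <- temporal_freq / frame_rate
  cx <- (size + 1) / 2
  xs <- (1:size) - cx
  ys <- (1:size) - cx
  in_ap <- outer(ys^2, xs^2, "+") <= (aperture / 2)^2
  out <- lapply(oris, function(th) {
    u <- outer(ys * sinpi(th / 180), xs * cospi(th / 180), "+")
    frames <- array(0.5, dim = c(n_frames, size, size))
    for (j in seq_len(n_frames)) {
      g <- 0.5 + 0.5 * contrast * sin(2 * pi * (gs * u - (j - 1) * dphase))
      g[!in_ap] <- 0.5
      frames[j, , ] <- g
    }
    movie_stimulus(frames, frame_duration_ms = 1000 / frame_rate)
  })
  names(out) <- as.character(oris)
  out
}

#' Preprocess a movie into a centered pixel data matrix
#'
#' The fixed pipeline applied before stimulus PCA: center-crop each frame
#' to `crop x crop` pixels (default 320), average each fixed
#' `block x block` pixel square (default 8, giving 40 x 40 block means),
#' flatten to a vector, stack frames as samples, and centre the features.
#'
#' @param movie A [movie_stimulus()] with frames at least `crop` pixels on
#'   each side.
#' @param crop Side of the central crop in pixels.
#' @param block Side of the averaging block in pixels; must divide `crop`.
#' @return A centered [data_matrix()] (frames x `(crop/block)^2`).
#' @export
preprocess_movie <- function(movie, crop = 320, block = 8) {
  stopifnot(inherits(movie, "movie_stimulus"))
  d <- dim(movie$frames)
  if (d[2] < crop || d[3] < crop)
    stop("frames are smaller than the ", crop, "-pixel crop")
  if (crop %% block != 0) stop("'block' must divide 'crop'")
  y0 <- (d[2] - crop) %/% 2
  x0 <- (d[3] - crop) %/% 2
  nb <- crop %/% block
  ## sparse block-averaging operator: pixel (y, x) -> block column index
  byx <- as.vector(outer(ceiling(seq_len(crop) / block),
                         (ceiling(seq_len(crop) / block) - 1L) * nb, "+"))
  P <- Matrix::sparseMatrix(i = seq_len(crop * crop), j = byx,
                            x = 1 / block^2, dims = c(crop * crop, nb * nb))
  n <- d[1]
  vals <- matrix(0, n, nb * nb)
  for (f in seq_len(n)) {
    fr <- movie$frames[f, y0 + seq_len(crop), x0 + seq_len(crop)]
    vals[f, ] <- as.vector(Matrix::crossprod(P, as.vector(fr)))
  }
  center_features(data_matrix(vals, provenance = "preprocessed movie"))
}

#' Adjust per-image contrast
#'
#' For every frame: subtract that frame's mean luminance, scale the
#' deviations by `level`/100, and add the mean back.  100 is the identity;
#' 0 collapses each frame to its own mean.
#'
#' @param movie A [movie_stimulus()].
#' @param level Contrast level in percent (>= 0).
#' @return A [movie_stimulus()].
#' @export
adjust_contrast <- function(movie, level) {
  stopifnot(inherits(movie, "movie_stimulus"), level >= 0)
  frames <- movie$frames
  mu <- apply(frames, 1L, mean)
  frames <- (frames - mu) * (level / 100) + mu  # mu recycles over (y, x)
  movie_stimulus(frames, movie$frame_duration_ms)
}

## Phase-offset matrix with Hermitian antisymmetry: offsets are uniform on
## [-alpha, alpha] over one half-plane, the conjugate partner gets the
## negated offset, and self-conjugate frequencies (DC, Nyquist rows) get 0,
## so the perturbed image stays real and mean luminance is conserved.
.conjugate_partner <- function(h, w) {
  uu <- (seq_len(h) - 1L)
  vv <- (seq_len(w) - 1L)
  pu <- (h - uu) %% h
  pv <- (w - vv) %% w
  lin <- outer(uu, vv * h, "+") + 1L          # own linear index
  plin <- outer(pu, pv * h, "+") + 1L         # partner linear index
  list(lin = lin, partner = plin)
}

#' Randomize image phases
#'
#' Adds an independent random offset, uniform on `[-alpha, alpha]` degrees,
#' to each Fourier phase of every frame (conjugate symmetry preserved, DC
#' untouched).  Magnitudes are unchanged, so the power spectrum is exactly
#' preserved; at `alpha = 180` the image statistics become pink noise.
#'
#' @param movie A [movie_stimulus()].
#' @param alpha Half-range of the phase offset in degrees, in [0, 180].
#' @param rng_seed Optional RNG seed.
#' @return A [movie_stimulus()].
#' @export
randomize_phases <- function(movie, alpha, rng_seed = NULL) {
  stopifnot(inherits(movie, "movie_stimulus"), alpha >= 0, alpha <= 180)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  d <- dim(movie$frames)
  cp <- .conjugate_partner(d[2], d[3])
  owner <- cp$lin < cp$partner           # one representative per pair
  selfc <- cp$lin == cp$partner
  frames <- movie$frames
  a <- alpha * pi / 180
  for (f in seq_len(d[1])) {
    F <- stats::fft(frames[f, , ])
    off <- numeric(d[2] * d[3])
    off[cp$lin[owner]] <- stats::runif(sum(owner), -a, a)
    off[cp$partner[owner]] <- -off[cp$lin[owner]]
    off[cp$lin[selfc]] <- 0
    F <- F * exp(1i * off)
    frames[f, , ] <- Re(stats::fft(F, inverse = TRUE)) / (d[2] * d[3])
  }
  movie_stimulus(frames, movie$frame_duration_ms)
}

#' Flatten the image power spectrum
#'
#' Per frame, the power spectrum `P` (squared Fourier magnitudes) is
#' normalized by its sum `lambda`, raised to the exponent `q`, and rescaled
#' by `lambda`; phases are preserved and the output is real.  `q = 1` is
#' the identity; `q = 0` makes all power values equal (white noise);
#' intermediate `q` turns a `1/f^2` spectrum into `1/f^(2q)`.
#'
#' @param movie A [movie_stimulus()].
#' @param q Spectral exponent in [0, 1].
#' @return A [movie_stimulus()].
#' @export
flatten_spectrum <- function(movie, q) {
  stopifnot(inherits(movie, "movie_stimulus"), q >= 0, q <= 1)
  d <- dim(movie$frames)
  frames <- movie$frames
  npix <- d[2] * d[3]
  for (f in seq_len(d[1])) {
    F <- stats::fft(frames[f, , ])
    P <- Mod(F)^2
    lambda <- sum(P)
    if (lambda == 0) stop("degenerate spectrum: frame ", f, " has zero power")
    Pn <- lambda * (P / lambda)^q
    fac <- sqrt(Pn / P)
    fac[P == 0] <- 0
    F <- F * fac
    frames[f, , ] <- Re(stats::fft(F, inverse = TRUE)) / npix
  }
  movie_stimulus(frames, movie$frame_duration_ms)
}

#' Radially averaged log-log power-spectrum slope
#'
#' Utility for checking spectral shape: averages the 2-d power spectrum of
#' each frame in radial frequency bins and regresses log power on log
#' frequency.
#'
#' @param movie A [movie_stimulus()].
#' @param n_frames Number of frames to average (default up to 20).
#' @return The fitted slope (e.g. about -2 for a 1/f^2 spectrum).
#' @export
radial_spectrum_slope <- function(movie, n_frames = 20) {
  stopifnot(inherits(movie, "movie_stimulus"))
  d <- dim(movie$frames)
  use <- seq_len(min(n_frames, d[1]))
  size <- d[2]
  fx <- c(0:(size %/% 2), -((size - size %/% 2 - 1):1)) / size
  fr <- sqrt(outer(fx^2, fx^2, "+"))
  P <- 0
  for (f in use) P <- P + Mod(stats::fft(movie$frames[f, , ]))^2
  P <- P / length(use)
  keep <- fr > 1.5 / size & fr <= 0.5
  bins <- cut(log(fr[keep]), breaks = 24)
  lf <- tapply(log(fr[keep]), bins, mean)
  lp <- tapply(log(P[keep]), bins, mean)
  ok <- is.finite(lf) & is.finite(lp)
  unname(stats::coef(stats::lm(lp[ok] ~ lf[ok]))[2])
}
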