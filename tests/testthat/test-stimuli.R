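test_that("gratings movie has the right element structure and aperture", {
  g <- gratings_movie(n_orientations = 6, size = 160, aperture = 120,
                      rng_seed = 1)
  ## 8 elements (6 orientations + 2 blanks) alternating 8- and 7-frame
  ## elements: 300 ms at 25 Hz
  expect_equal(dim(g$frames)[1], 60L)
  expect_equal(g$frame_duration_ms, 40)
  seqs <- attr(g, "sequence")
  expect_equal(sum(is.na(seqs)), 2L)
  expect_setequal(seqs[!is.na(seqs)], seq(0, 300, by = 60))

  ## outside the aperture every frame is mean gray
  cx <- (160 + 1) / 2
  outside <- outer(((1:160) - cx)^2, ((1:160) - cx)^2, "+") > 60^2
  for (f in c(1, 20, 60))
    expect_true(all(g$frames[f, , ][outside] == 0.5))

  ## 6.25 Hz at 25 Hz sampling: phase repeats every 4 frames, so frames 1
  ## and 5 of an 8-frame grating element are identical
  first_grating <- which(!is.na(seqs))[1]
  offset <- sum(rep(c(8L, 7L), 4)[seq_len(first_grating - 1)])
  expect_equal(g$frames[offset + 1, , ], g$frames[offset + 5, , ],
               tolerance = 1e-12)
})

test_that("the 320-px central crop is identical whether frames are 640 or 320", {
  g640 <- gratings_movie(n_orientations = 3, n_blanks = 0, size = 640,
                         rng_seed = 2)
  g320 <- gratings_movie(n_orientations = 3, n_blanks = 0, size = 320,
                         aperture = 640, rng_seed = 2)
  expect_equal(preprocess_movie(g640)$values, preprocess_movie(g320)$values,
               tolerance = 1e-12)
})

test_that("noise movie geometry and spatial correlation behave as designed", {
  nm <- noise_movie(n_frames = 750, rng_seed = 3)
  expect_equal(dim(nm$frames), c(750L, 320L, 320L))

  adjacent_cor <- function(movie, jitter_free = FALSE) {
    pm <- preprocess_movie(movie)$values
    idx <- cbind(sample(1:1599, 30), 0)
    idx[, 2] <- idx[, 1] + 1
    idx <- idx[idx[, 1] %% 40 != 0, , drop = FALSE]   # same-column pairs
    mean(vapply(seq_len(nrow(idx)), function(i)
      cor(pm[, idx[i, 1]], pm[, idx[i, 2]]), 1.0))
  }
  set.seed(4)
  aligned <- noise_movie(n_frames = 750, jitter = FALSE, rng_seed = 5)
  expect_lt(abs(adjacent_cor(aligned)), 0.05)  # independent squares
  expect_gt(adjacent_cor(nm), 0.2)             # jitter mixes neighbors
})

test_that("natural surrogate has 1/f^2 spectra and controllable dynamics", {
  frozen <- natural_surrogate(n_frames = 5, size = 64,
                              temporal_correlation = 1,
                              luminance_drift_amplitude = 0, rng_seed = 6)
  for (f in 2:5)
    expect_equal(frozen$frames[f, , ], frozen$frames[1, , ], tolerance = 1e-12)

  ns <- natural_surrogate(n_frames = 20, size = 128, rng_seed = 7)
  expect_equal(radial_spectrum_slope(ns), -2, tolerance = 0.3)

  ## stronger temporal correlation lowers short-window dimensionality
  k1s <- function(rho) {
    m <- natural_surrogate(n_frames = 150, size = 64,
                           temporal_correlation = rho, rng_seed = 8)
    dm <- preprocess_movie(m, crop = 64, block = 8)
    mean(windowed_dimensionality(dm, window_spec(1, 40), 0.9))
  }
  expect_lt(k1s(0.95), k1s(0.3))
})

test_that("individual grating trials pair opposite drift directions", {
  tr <- individual_grating_trials(size = 96, aperture = 96)
  expect_length(tr, 12L)
  expect_equal(names(tr), as.character(seq(0, 330, by = 30)))
  expect_equal(dim(tr[[1]]$frames)[1], 32L)  # 1.28 s at 25 Hz

  ## 180-degree pairs share the spatial pattern with reversed drift: the
  ## 6.25 Hz phase walk maps frame j of one onto frame (4 - j) mod 4 + ...
  f0 <- tr[["0"]]$frames; f180 <- tr[["180"]]$frames
  expect_equal(f180[1, , ], f0[3, , ], tolerance = 1e-12)
  expect_equal(f180[2, , ], f0[2, , ], tolerance = 1e-12)
  expect_equal(f180[3, , ], f0[1, , ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(f180[1, , ], f0[1, , ])))
})

test_that("preprocessing crops, block-averages, flattens and centers", {
  ## two constant frames: block means are the constants; centering splits
  ## them symmetrically
  fr <- array(0, c(2, 320, 320)); fr[1, , ] <- 3; fr[2, , ] <- 7
  pm <- preprocess_movie(movie_stimulus(fr))
  expect_equal(dim(pm$values), c(2L, 1600L))
  expect_true(all(abs(pm$values[1, ] + 2) < 1e-12))
  expect_true(all(abs(pm$values[2, ] - 2) < 1e-12))
  expect_equal(pm$feature_means, rep(5, 1600))

  ## a single lit 8x8 block lands in exactly one feature with its mean
  fr2 <- array(0, c(2, 320, 320))
  fr2[1, 9:16, 17:24] <- 64   # block row 2, block column 3
  pm2 <- preprocess_movie(movie_stimulus(fr2))
  feat <- 2 + (3 - 1) * 40
  expect_equal(pm2$values[1, feat], 32)   # 64 centered across two frames
  expect_equal(pm2$values[1, -feat], rep(0, 1599))

  expect_error(preprocess_movie(movie_stimulus(array(0, c(2, 100, 100)))),
               "smaller")
  ## frame reordering permutes sample rows identically
  g <- noise_movie(n_frames = 6, grid = 40, rng_seed = 9)
  rev_g <- movie_stimulus(g$frames[6:1, , ], g$frame_duration_ms)
  expect_equal(preprocess_movie(rev_g)$values,
               preprocess_movie(g)$values[6:1, ])
})

test_that("contrast adjustment scales per-frame deviations about each mean", {
  m <- toy_movie(4, 32, seed = 10)
  expect_equal(adjust_contrast(m, 100)$frames, m$frames, tolerance = 1e-12)

  flat <- adjust_contrast(m, 0)
  for (f in 1:4)
    expect_equal(flat$frames[f, , ],
                 matrix(mean(m$frames[f, , ]), 32, 32), tolerance = 1e-12)

  half <- adjust_contrast(m, 50)
  for (f in 1:4) {
    d0 <- m$frames[f, , ] - mean(m$frames[f, , ])
    d1 <- half$frames[f, , ] - mean(half$frames[f, , ])
    expect_equal(sqrt(sum(d1^2)), sqrt(sum(d0^2)) / 2, tolerance = 1e-12)
  }
  ## total pixel variance is non-increasing in contrast level
  v <- vapply(c(100, 75, 50, 25, 5), function(l)
    sum(scale(matrix(adjust_contrast(m, l)$frames, 4), scale = FALSE)^2), 1.0)
  expect_true(all(diff(v) < 0))
})

test_that("phase randomization preserves magnitudes and realness", {
  m <- toy_movie(3, 32, seed = 11)
  same <- randomize_phases(m, alpha = 0, rng_seed = 12)
  expect_equal(same$frames, m$frames, tolerance = 1e-9)

  rp <- randomize_phases(m, alpha = 120, rng_seed = 13)
  for (f in 1:3) {
    expect_equal(Mod(fft(rp$frames[f, , ])), Mod(fft(m$frames[f, , ])),
                 tolerance = 1e-9)
    expect_equal(mean(rp$frames[f, , ]), mean(m$frames[f, , ]),
                 tolerance = 1e-9)                  # DC untouched
  }

  ## alpha = 180 decorrelates pixels from the original but keeps spectra
  ns <- natural_surrogate(n_frames = 2, size = 128, rng_seed = 14)
  pink <- randomize_phases(ns, alpha = 180, rng_seed = 15)
  expect_lt(abs(cor(as.vector(pink$frames[1, , ]),
                    as.vector(ns$frames[1, , ]))), 0.1)
  expect_equal(radial_spectrum_slope(pink, 2), radial_spectrum_slope(ns, 2),
               tolerance = 1e-6)
})

test_that("spectral flattening interpolates between pink and white noise", {
  m <- toy_movie(2, 32, seed = 16)
  expect_equal(flatten_spectrum(m, 1)$frames, m$frames, tolerance = 1e-9)

  white <- flatten_spectrum(m, 0)
  P <- Mod(fft(white$frames[1, , ]))^2
  expect_lt(diff(range(P)) / mean(P), 1e-9)  # all power values equal

  ns <- natural_surrogate(n_frames = 3, size = 128, rng_seed = 17)
  for (q in c(0.75, 0.5, 0.25)) {
    fq <- flatten_spectrum(ns, q)
    expect_equal(radial_spectrum_slope(fq, 3), -2 * q, tolerance = 0.35)
    expect_equal(dim(fq$frames), dim(ns$frames))
  }
})
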