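test_that("parameter sampling is deterministic and respects stated supports", {
  p1 <- sample_rf_params(50, rng_seed = 1)
  p2 <- sample_rf_params(50, rng_seed = 1)
  expect_identical(p1$neurons, p2$neurons)

  betas <- vapply(p1$neurons, `[[`, 1.0, "beta")
  expect_true(all(betas %in% c(0, pi)))
  thetas <- vapply(p1$neurons, `[[`, 1.0, "theta")
  expect_true(all(thetas >= 0 & thetas < pi))
  sx <- vapply(p1$neurons, `[[`, 1.0, "sigma_x")
  expect_true(all(sx >= 20))
  expect_equal(vapply(p1$neurons, `[[`, 1.0, "sigma_t"),
               8 * vapply(p1$neurons, `[[`, 1.0, "d"))

  ## RF centers: mean within 4 standard errors of 160 (variance 20)
  big <- sample_rf_params(1000, rng_seed = 2)
  xl <- vapply(big$neurons, `[[`, 1.0, "x_loc")
  expect_lt(abs(mean(xl) - 160), 4 * sqrt(20 / 1000))

  expect_error(sample_rf_params(1), "at least 2")
  bad <- default_rf_config(); bad$q_min <- 5
  expect_error(sample_rf_params(3, config = bad), "config")
})

test_that("gabor filters are unit-norm and mirror in time under beta", {
  set.seed(3)
  p <- sample_rf_params(2, rng_seed = 3, config = small_config())$neurons[[1]]
  flt <- build_gabor(p, size = 32, T = 5)
  expect_equal(sqrt(sum(flt$weights^2)), 1, tolerance = 1e-9)

  ## beta = 0 vs beta = pi: temporal term flips sign, so the two filters
  ## agree at the current frame and mirror (up to the one-sided envelope)
  p0 <- p; p0$beta <- 0
  ppi <- p; ppi$beta <- pi
  f0 <- build_gabor(p0, 32, T = 5)
  fpi <- build_gabor(ppi, 32, T = 5)
  expect_equal(f0$weights[, , 5] * f0$norm, fpi$weights[, , 5] * fpi$norm,
               tolerance = 1e-9)
  expect_false(isTRUE(all.equal(f0$weights, fpi$weights)))

  ## d = 0: single-frame temporal delta
  pd <- p; pd$d <- 0; pd$sigma_t <- 0
  fd <- build_gabor(pd, 32, T = 5)
  expect_true(all(fd$weights[, , 1:4] == 0))
  expect_gt(sum(fd$weights[, , 5]^2), 0)
})

test_that("component 1 is a rectified matched filter", {
  set.seed(4)
  p <- sample_rf_params(2, rng_seed = 4, config = small_config())$neurons[[1]]
  flt <- build_gabor(p, 32, T = 5)

  zero <- movie_stimulus(array(0, c(8, 32, 32)))
  c1 <- rf_component1(zero, flt)
  expect_true(all(is.na(c1$L1[1:4])))
  expect_true(all(c1$R1[5:8] == 0))

  ## replay the filter itself: at alignment the unit-norm autocorrelation
  ## peaks at exactly 1
  replay <- array(0, c(5, 32, 32))
  for (tau in 1:5) replay[tau, , ] <- flt$weights[, , tau]
  c1r <- rf_component1(movie_stimulus(replay), flt)
  expect_equal(c1r$L1[5], 1, tolerance = 1e-9)

  expect_error(rf_component1(movie_stimulus(array(0, c(3, 32, 32))), flt),
               "shorter")
})

test_that("matched gratings drive component 1 harder than orthogonal ones", {
  cfg <- small_config()
  p <- sample_rf_params(2, rng_seed = 5, config = cfg)$neurons[[1]]
  p$d <- 0.5; p$sigma_t <- 4
  grating_movie <- function(theta) {
    xs <- (1:32) - 16.5
    ## drift axis in the filter's own convention: x' = cos(theta) dx - sin(theta) dy
    u <- outer(xs * (-sin(theta)), xs * cos(theta), "+")
    fr <- array(0, c(20, 32, 32))
    for (j in 1:20)
      fr[j, , ] <- 0.5 + 0.5 * sin(2 * pi * (p$gamma_s * u - (j - 1) * 0.25))
    movie_stimulus(fr)
  }
  flt <- build_gabor(p, 32, T = cfg$T)
  matched <- rf_component1(grating_movie(p$theta), flt)
  ortho <- rf_component1(grating_movie(p$theta + pi / 2), flt)
  expect_gt(mean(matched$R1, na.rm = TRUE), mean(ortho$R1, na.rm = TRUE))
})

test_that("untuned suppression vanishes for constant frames and bites for center-surround", {
  cfg <- small_config()
  p <- sample_rf_params(2, rng_seed = 6, config = cfg)$neurons[[1]]
  p$omega <- 0.7
  p$x_loc <- 16; p$y_loc <- 16
  const <- movie_stimulus(array(0.6, c(3, 32, 32)))
  c2 <- rf_component2(rep(1, 3), const, p, cfg$sigma1, cfg$sigma2)
  ## both Gaussians integrate to about 1, so the untuned drive nearly cancels
  expect_lt(max(abs(c2$L2)), 0.05)
  expect_equal(c2$R2, rep(1, 3), tolerance = 0.05)

  p0 <- p; p0$omega <- 0
  expect_equal(rf_component2(rep(1, 3), const, p0, cfg$sigma1, cfg$sigma2)$R2,
               rep(1, 3))

  ## bright center, dark surround: positive untuned drive suppresses R2
  xs <- (1:32) - 16
  disk <- outer(xs^2, xs^2, "+") <= 4^2
  fr <- array(-0.5, c(2, 32, 32))
  fr[1, , ][disk] <- 1; fr[2, , ][disk] <- 1
  cs <- rf_component2(rep(1, 2), movie_stimulus(fr), p, cfg$sigma1, cfg$sigma2)
  expect_true(all(cs$L2 > 0))
  expect_true(all(cs$R2 < 1))
})

test_that("divisive normalization and the output nonlinearity follow their formulas", {
  R3 <- rf_component3(matrix(c(4, 0), 2, 1), matrix(c(4, 2), 2, 1),
                      sigma_offset = c(1, 1))
  expect_equal(as.numeric(R3), c(4 / 3, 0))

  R2 <- matrix(c(3, -1), 2, 1)
  expect_equal(rf_component3(R2, matrix(0, 2, 1), c(0.5, 0.25)),
               R2 / c(0.5, 0.25))

  ## loop-based oracle on random inputs
  set.seed(7)
  R2m <- matrix(rnorm(5 * 8), 5, 8); R1m <- matrix(rexp(5 * 8), 5, 8)
  soff <- runif(5, 0.1, 1)
  got <- rf_component3(R2m, R1m, soff)
  for (i in 1:5) for (tt in 1:8) {
    pool <- mean(R1m[-i, tt])
    expect_equal(got[i, tt], R2m[i, tt] / (soff[i] + pool), tolerance = 1e-12)
  }
  expect_error(rf_component3(matrix(1, 1, 3), matrix(1, 1, 3), 1), "2 neurons")

  expect_equal(rf_component4(matrix(-2), 2), matrix(0))
  expect_equal(rf_component4(matrix(c(0, 1, 3)), 1), matrix(c(0, 1, 3)))
  expect_equal(rf_component4(matrix(3), 2), matrix(9))
  expect_error(rf_component4(matrix(1), 0), "q > 0")
})

test_that("the full cascade matches a straight-line reimplementation", {
  cfg <- small_config()
  params <- sample_rf_params(3, rng_seed = 8, config = cfg)
  movie <- toy_movie(10, 32, seed = 9)
  got <- run_rf_model(movie, params)
  want <- oracle_rf_model(movie, params)
  expect_equal(got$L1, want$L1, tolerance = 1e-9)
  expect_equal(got$R1, want$R1, tolerance = 1e-9)
  expect_equal(got$R2, want$R2, tolerance = 1e-9)
  expect_equal(got$R3, want$R3, tolerance = 1e-9)
  expect_equal(got$R4, want$R4, tolerance = 1e-9)
  expect_true(all(got$R1 >= 0))
  expect_true(all(got$R4 >= 0))
})

test_that("a zero-contrast movie silences every component", {
  cfg <- small_config()
  params <- sample_rf_params(3, rng_seed = 10, config = cfg)
  zero <- movie_stimulus(array(0, c(12, 32, 32)))
  r <- run_rf_model(zero, params)
  expect_true(all(r$R1 == 0) && all(r$R2 == 0) &&
              all(r$R3 == 0) && all(r$R4 == 0))
})

test_that("doubling contrast never decreases component-1 output", {
  cfg <- small_config()
  p <- sample_rf_params(2, rng_seed = 11, config = cfg)$neurons[[1]]
  flt <- build_gabor(p, 32, T = cfg$T)
  m <- toy_movie(12, 32, seed = 12)
  m2 <- movie_stimulus(2 * m$frames)
  r1 <- rf_component1(m, flt)$R1
  r2 <- rf_component1(m2, flt)$R1
  expect_true(all(r2 >= r1 - 1e-12, na.rm = TRUE))
})
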