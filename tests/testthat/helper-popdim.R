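## Shared fixtures and independent oracles, built in code at test time.

## Brute-force dimensionality: full eigendecomposition of the sample
## covariance with explicit cumulative summation (independent of the svd
## path used by the package).
oracle_dimensionality <- function(x, threshold) {
  x <- sweep(x, 2L, colMeans(x), "-")
  ev <- eigen(stats::cov(x), symmetric = TRUE, only.values = TRUE)$values
  ev[ev < 0] <- 0
  cf <- cumsum(ev) / sum(ev)
  which(cf >= threshold - 1e-12)[1]
}

## A centered data_matrix whose rows live exactly in the span of `basis`
## (features x k orthonormal), with latent rows scaled to equal variance so
## the 90% threshold keeps all k patterns.
planted_matrix <- function(basis, n_rows, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- ncol(basis)
  w <- matrix(rnorm(n_rows * k), n_rows, k)
  w <- sweep(w, 2L, colMeans(w), "-")
  w <- sweep(w, 2L, apply(w, 2L, sd), "/")
  dm <- data_matrix(w %*% t(basis), centered = FALSE)
  dm$centered <- TRUE  # rows are exactly mean-zero by construction
  dm
}

## Two synthetic PSTH-style matrices, either sharing a planted subspace or
## planted in orthogonal subspaces of an N-dimensional feature space.
planted_pair <- function(n_features = 100, k = 5, n_rows = 200,
                         shared = TRUE, seed = 1) {
  set.seed(seed)
  if (shared) {
    b <- random_orthonormal(n_features, k)
    list(planted_matrix(b, n_rows), planted_matrix(b, n_rows))
  } else {
    b <- random_orthonormal(n_features, 2 * k)
    list(planted_matrix(b[, 1:k], n_rows),
         planted_matrix(b[, (k + 1):(2 * k)], n_rows))
  }
}

## Scaled-down RF-model configuration for toy frames (32 px, 5-frame
## filters): envelope and suppressive-filter scales shrunk with the frame.
small_config <- function() {
  cfg <- default_rf_config(center_mean = 16, center_var = 4)
  cfg$sigma_x_base <- 4
  cfg$sigma1 <- 4
  cfg$sigma2 <- 6
  cfg$T <- 5
  cfg
}

## Tiny toy movie with reproducible content.
toy_movie <- function(n_frames = 10, size = 16, seed = 1) {
  set.seed(seed)
  movie_stimulus(array(runif(n_frames * size * size),
                       dim = c(n_frames, size, size)))
}

## Straight-line reimplementation of the four model equations, explicit
## rotation matrices and nested loops throughout.
oracle_gabor <- function(p, size, T, frame_rate) {
  Rb <- matrix(c(1, 0, 0,
                 0, cos(p$beta), sin(p$beta),
                 0, -sin(p$beta), cos(p$beta)), 3, 3)
  Rt <- matrix(c(cos(p$theta), sin(p$theta), 0,
                 -sin(p$theta), cos(p$theta), 0,
                 0, 0, 1), 3, 3)
  R <- Rb %*% Rt
  w <- array(0, c(size, size, T))
  for (yi in seq_len(size)) for (xi in seq_len(size)) for (tau in seq_len(T)) {
    t <- tau - T
    dx <- xi - p$x_loc; dy <- yi - p$y_loc
    v <- R %*% c(dx, dy, t)
    if (p$sigma_t == 0) {
      H <- if (t == 0) exp(-0.5 * sum((R %*% c(dx / p$sigma_x, dy / p$sigma_y, 0))^2)) else 0
    } else {
      H <- exp(-0.5 * sum((R %*% c(dx / p$sigma_x, dy / p$sigma_y, t / p$sigma_t))^2))
    }
    S <- exp(-1i * 2 * pi * (p$gamma_s * v[1] + p$phi +
                             (p$gamma_t / frame_rate) * v[3]))
    w[yi, xi, tau] <- Re(H * S)
  }
  w / sqrt(sum(w^2))
}

oracle_rf_model <- function(movie, params) {
  cfg <- params$config
  d <- dim(movie$frames)
  frame_rate <- 1000 / movie$frame_duration_ms
  T <- cfg$T
  n <- length(params$neurons)
  keep <- T:d[1]
  L1 <- R1 <- R2 <- matrix(0, n, length(keep))
  for (i in seq_len(n)) {
    p <- params$neurons[[i]]
    g <- oracle_gabor(p, d[2], T, frame_rate)
    gu <- matrix(0, d[2], d[3])
    for (yi in seq_len(d[2])) for (xi in seq_len(d[3])) {
      g1 <- exp(-0.5 * ((xi - p$x_loc)^2 + (yi - p$y_loc)^2) / cfg$sigma1^2) /
        (2 * pi * cfg$sigma1^2)
      g2 <- exp(-0.5 * ((xi - p$x_loc)^2 + (yi - p$y_loc)^2) / cfg$sigma2^2) /
        (2 * pi * cfg$sigma2^2)
      gu[yi, xi] <- g1 - g2
    }
    for (ti in seq_along(keep)) {
      t <- keep[ti]
      acc <- 0
      for (m in (t - T + 1):t)
        acc <- acc + sum(g[, , m - t + T] * movie$frames[m, , ])
      L1[i, ti] <- acc
      R1[i, ti] <- max(0, acc)
      L2 <- sum(gu * movie$frames[t, , ])
      R2[i, ti] <- R1[i, ti] - max(0, p$omega * L2)
    }
  }
  R3 <- matrix(0, n, length(keep))
  for (i in seq_len(n)) for (ti in seq_along(keep)) {
    pool <- mean(R1[-i, ti, drop = FALSE])
    R3[i, ti] <- R2[i, ti] /
      (params$neurons[[i]]$sigma_offset + pool)
  }
  R4 <- R3
  for (i in seq_len(n))
    R4[i, ] <- pmax(0, R3[i, ])^params$neurons[[i]]$q
  list(L1 = L1, R1 = R1, R2 = R2, R3 = R3, R4 = R4)
}
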