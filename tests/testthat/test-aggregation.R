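test_that("effective rank handles duplicate, orthonormal, and angled columns", {
  v <- c(1, 0, 0)
  expect_equal(effective_rank(cbind(v, v), t = 0.5), 1L)
  expect_equal(effective_rank(cbind(v, v), t = 0), 1L)  # absolute floor

  for (m in c(2, 5, 9)) {
    q <- random_orthonormal(12, m)
    expect_equal(effective_rank(q, t = 0.5), m)
  }

  ## 60 degrees: singular values sqrt(1 +/- cos 60) = {1.225, 0.707}
  u <- c(1, 0); w <- c(cos(pi / 3), sin(pi / 3))
  expect_equal(effective_rank(cbind(u, w), t = 0.5), 2L)
  expect_equal(svd(cbind(u, w))$d, sqrt(c(1.5, 0.5)), tolerance = 1e-12)

  expect_error(effective_rank(cbind(c(2, 0))), "unit")
})

test_that("effective rank is invariant to column permutation and sign flips", {
  set.seed(1)
  q <- random_orthonormal(20, 6)
  q[, 3] <- (q[, 2] + q[, 3]) / sqrt(sum((q[, 2] + q[, 3])^2))  # correlated col
  r0 <- effective_rank(q, 0.5)
  perm <- q[, sample(ncol(q))]
  flip <- sweep(q, 2L, sample(c(-1, 1), ncol(q), TRUE), "*")
  expect_equal(effective_rank(perm, 0.5), r0)
  expect_equal(effective_rank(flip, 0.5), r0)
})

test_that("two-vector transition angle equals arccos(1 - t^2)", {
  grid <- seq(0.5, 89.5, by = 0.5)  # degrees
  for (t in seq(0.1, 0.9, by = 0.1)) {
    ranks <- vapply(grid, function(a) {
      w <- c(cospi(a / 180), sinpi(a / 180))
      effective_rank(cbind(c(1, 0), w), t = t)
    }, 1L)
    transition <- grid[which(ranks == 2L)[1]]
    expect_lte(abs(transition - acos(1 - t^2) * 180 / pi), 0.5)
  }
  ## t = 0.5 transitions near 45 degrees (exactly arccos(0.75) = 41.4)
  expect_equal(acos(1 - 0.25) * 180 / pi, 41.41, tolerance = 1e-3)
})

test_that("aggregation respects the max/sum bracket at the extremes", {
  set.seed(2)
  a <- random_orthonormal(30, 4)
  rot <- qr.Q(qr(matrix(rnorm(16), 4, 4)))  # same subspace, new basis
  expect_equal(aggregate_dimensionality(list(a, a %*% rot), 0.5), 4L)

  big <- random_orthonormal(30, 7)
  expect_equal(aggregate_dimensionality(list(big[, 1:4], big[, 5:7]), 0.5), 7L)

  expect_error(aggregate_dimensionality(
    list(random_orthonormal(10, 2), random_orthonormal(11, 2))),
    "ambient")
})

test_that("bracket bounds hold for arbitrary planted overlaps", {
  set.seed(3)
  for (rep in 1:10) {
    n <- 25
    ka <- sample(2:6, 1); kb <- sample(2:6, 1)
    base <- random_orthonormal(n, ka + kb)
    shared <- sample(0:min(ka, kb), 1)
    a <- base[, 1:ka]
    b <- cbind(base[, seq_len(shared), drop = FALSE],
               base[, ka + seq_len(kb - shared), drop = FALSE])
    k <- aggregate_dimensionality(list(a, b), 0.5)
    expect_gte(k, max(ka, kb))
    expect_lte(k, ka + kb)
  }
})

test_that("chance distribution saturates, matches an angle-sampling oracle, and hits 88", {
  ## full-space saturation: both sets span the whole space
  cd <- chance_distribution(c(3, 3), ambient_dim = 3, t = 0.5, n_draws = 20,
                            rng_seed = 4)
  expect_true(all(cd$samples == 3L))

  ## (1, 1) in a plane: rank-2 fraction matches independent angle sampling
  t <- 0.5
  cd2 <- chance_distribution(c(1, 1), 2, t = t, n_draws = 2000, rng_seed = 5)
  frac <- mean(cd2$samples == 2L)
  set.seed(6)
  ang <- runif(20000, 0, 2 * pi)           # angle between two random directions
  frac_oracle <- mean(1 - abs(cos(ang)) > t^2)
  expect_lt(abs(frac - frac_oracle),
            4 * sqrt(frac_oracle * (1 - frac_oracle) / 2000))

  ## random 24- and 64-dim subspaces of a 1600-dim space are orthogonal
  cd3 <- chance_distribution(c(24, 64), 1600, t = 0.5, n_draws = 25,
                             rng_seed = 7)
  expect_true(all(cd3$samples == 88L))
  expect_equal(cd3$mean_chance, 88)

  expect_error(chance_distribution(c(5, 2), 4), "orthonormal patterns")
})

test_that("similarity index reproduces its defining arithmetic", {
  expect_equal(similarity_index(50, 50, c(10, 20)), 0)
  expect_equal(similarity_index(20, 30, c(10, 20)), 1)  # overlap vs orthogonal
  expect_equal(similarity_index(80, 88, c(24, 64)), 1 / 3, tolerance = 1e-12)
  expect_equal(round(similarity_index(80, 88, c(24, 64)), 2), 0.33)
  expect_error(similarity_index(5, 5, c(7)), "single pattern set")
})

test_that("permutation p-value uses the add-one tail estimator", {
  ch <- structure(list(samples = c(5L, 6L, 7L, 8L), n_draws = 4L),
                  class = "chance_dist")
  ## exhaustive tail counts
  expect_equal(permutation_pvalue(4, ch, "overlap"), 1 / 5)
  expect_equal(permutation_pvalue(6, ch, "overlap"), 3 / 5)
  expect_equal(permutation_pvalue(9, ch, "overlap"), 1)
  expect_equal(permutation_pvalue(9, ch, "orthogonal"), 1 / 5)
  expect_equal(permutation_pvalue(6, ch, "orthogonal"), 4 / 5)

  ## extreme tail with many draws: p = 1/(n+1), never zero
  big <- structure(list(samples = rep(10L, 1e5), n_draws = 100000L),
                   class = "chance_dist")
  expect_equal(permutation_pvalue(2, big, "overlap"), 1 / 100001)
  expect_lt(permutation_pvalue(2, big, "overlap"), 1e-4)
})

test_that("pattern_similarity recovers planted overlap structure", {
  pr <- planted_pair(n_features = 100, k = 5, shared = TRUE, seed = 8)
  fit <- pattern_similarity(pr, variance_threshold = 0.9, t = 0.5,
                            n_draws = 100, rng_seed = 9)
  expect_equal(fit$k_agg, fit$lower_bound)
  expect_gt(fit$s, 0.9)
  expect_lt(fit$p_value, 0.05)

  po <- planted_pair(n_features = 100, k = 5, shared = FALSE, seed = 10)
  fito <- pattern_similarity(po, variance_threshold = 0.9, t = 0.5,
                             n_draws = 100, rng_seed = 11)
  expect_equal(fito$k_agg, fito$upper_bound)
  expect_lt(abs(fito$s), 0.1)
})

test_that("equalized aggregation reduces correctly and ranks shared < orthogonal", {
  ## duplicated full-data subsamples add no rank; m = n reduces to the
  ## plain aggregate
  pr <- planted_pair(60, k = 3, n_rows = 80, shared = FALSE, seed = 12)
  eq <- equalized_aggregate(pr, n_conditions = 2, variance_threshold = 0.9,
                            t = 0.5, subsample_fraction = 1, n_subsamples = 1,
                            rng_seed = 13)
  p1 <- pca_patterns(pr[[1]], 0.9); p2 <- pca_patterns(pr[[2]], 0.9)
  expect_equal(unname(eq["1"]), p1$k)
  expect_equal(unname(eq["2"]),
               aggregate_dimensionality(list(p1, p2), 0.5))

  sh <- planted_pair(60, k = 3, n_rows = 80, shared = TRUE, seed = 14)
  eq_sh <- equalized_aggregate(sh, 2, 0.9, 0.5, subsample_fraction = 0.5,
                               n_subsamples = 5, rng_seed = 15)
  eq_or <- equalized_aggregate(pr, 2, 0.9, 0.5, subsample_fraction = 0.5,
                               n_subsamples = 5, rng_seed = 15)
  expect_lt(eq_sh["2"], eq_or["2"])
})
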