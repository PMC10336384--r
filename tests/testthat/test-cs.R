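test_that("eps_grid spans the stated quantiles and respects geometry", {
  pts <- statecausal:::local_seed(15, matrix(rnorm(600), 300, 2))
  emb <- list(points = pts)
  g2 <- eps_grid(emb, n_eps = 2L, max_pairs = 1e6)
  d <- dist(pts)
  expect_equal(g2, unname(quantile(d, c(0.01, 0.5))), tolerance = 1e-12)
  g <- eps_grid(emb, n_eps = 12L)
  expect_true(all(diff(g) > 0))
  # rigid rotation preserves the grid; scaling by 10 scales it by 10
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(eps_grid(list(points = pts %*% R), n_eps = 12L), g,
               tolerance = 1e-12)
  expect_equal(eps_grid(list(points = pts * 10), n_eps = 12L), 10 * g,
               tolerance = 1e-12)
  expect_error(eps_grid(list(points = matrix(1, 50, 2))), "degenerate")
})

test_that("independent series have near-zero continuity strength", {
  slopes <- vapply(1:100, function(s) {
    xy <- noise_pair(400, 700 + s)
    cs_strength(xy[, 1], xy[, 2], seed = s)$strength
  }, numeric(1))
  coupled <- mean(vapply(1:20, function(s) {
    v <- lm_pair(400, seed = 800 + s)$values
    cs_strength(v[, 1], v[, 2], seed = s)$strength
  }, numeric(1)))
  expect_lt(abs(mean(slopes)), 0.05 * coupled)
})

test_that("a smooth invertible relation yields positive slopes both ways", {
  x <- lm_pair(400, seed = 34, C2 = 0)$values[, "x1"]
  y <- x^3
  # clearly above the null slope scale (|null| < 0.005), in both directions
  expect_gt(cs_strength(x, y, seed = 1)$strength, 0.02)
  expect_gt(cs_strength(y, x, seed = 1)$strength, 0.02)
})

test_that("the coupled direction dominates in at least 95 of 100 seeds", {
  wins <- 0L
  for (s in 1:100) {
    v <- lm_pair(400, seed = 1100 + s)$values
    fwd <- cs_strength(v[, 1], v[, 2], seed = s)$strength
    rev <- cs_strength(v[, 2], v[, 1], seed = s)$strength
    wins <- wins + (fwd > rev)
  }
  expect_gte(wins, 95L)
})

test_that("built-in standardization makes the slope affine-invariant", {
  v <- lm_pair(300, seed = 35)$values
  base <- cs_strength(v[, 1], v[, 2], seed = 2)
  # cause side: distances change smoothly, so the slope is exact to rounding
  expect_equal(base$strength,
               cs_strength(3 * v[, 1] + 1, v[, 2], seed = 2)$strength,
               tolerance = 1e-10)
  # effect side: rounding can flip borderline ball memberships, so the
  # invariance is near-exact rather than bitwise
  expect_equal(base$strength,
               cs_strength(v[, 1], 0.2 * v[, 2] - 5, seed = 2)$strength,
               tolerance = 0.05)
  # and the result is reproducible in full
  again <- cs_strength(v[, 1], v[, 2], seed = 2)
  expect_identical(base$delta_values, again$delta_values)
  expect_identical(base$eps_grid, again$eps_grid)
})

test_that("the containing-ball pre-image radius is monotone in epsilon", {
  for (s in 1:20) {
    v <- lm_pair(300, seed = 1200 + s)$values
    res <- cs_strength(v[, 1], v[, 2], member_agg = "max", seed = s)
    expect_true(all(diff(res$delta_values) >= 0))
  }
})

test_that("strength responds monotonically to the coupling", {
  C2s <- c(0, 0.05, 0.1, 0.2, 0.4)
  means <- vapply(seq_along(C2s), function(ci) {
    mean(vapply(1:40, function(s) {
      v <- lm_pair(400, seed = 1300 + 50 * ci + s, C2 = C2s[ci])$values
      cs_strength(v[, 1], v[, 2], seed = s)$strength
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(C2s, means, method = "spearman"), 0)
  expect_gt(means[5], means[1])
})
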