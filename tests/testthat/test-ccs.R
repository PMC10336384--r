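test_that("rank_transform yields evenly spaced unit ranks", {
  expect_equal(rank_transform(c(0.3, 0.1, 0.2)), c(1, 0, 0.5))
  expect_equal(rank_transform(rep(3, 7)), rep(0.5, 7))     # total tie
  d <- statecausal:::local_seed(8, runif(50))
  expect_equal(rank_transform(d), rank_transform(exp(4 * d)))  # order-preserving map
  expect_error(rank_transform(1), "two values")
})

test_that("cross-map weights are exponential in relative distance", {
  # a centre point with three exactly equidistant nearest neighbours
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1), c(-1, 0), c(5, 5), c(6, 5),
               c(5, 6), c(-6, 4), c(7, -5), c(0, -8))
  emb <- structure(list(points = pts, time_index = 0:9, dim = 2L, lag = 1L),
                   class = "delay_embedding")
  target <- c(10, 1, 2, 3, 0, 0, 0, 0, 0, 0)
  res <- ccm_cross_map(emb, target)
  # equidistant neighbours share weight 1/3 -> reconstruction is their mean
  expect_equal(res$reconstruction[1], mean(c(1, 2, 3)))
})

test_that("self cross-map is nearly perfect and nulls are centred", {
  x <- lm_pair(500, seed = 31, C2 = 0)$values[, "x1"]
  emb <- delay_embed(x, 2, 1)
  expect_gt(ccm_cross_map(emb, x[emb$time_index + 1])$rho, 0.99)
  rhos <- vapply(1:100, function(s) {
    xy <- noise_pair(500, 400 + s)
    e <- delay_embed(xy[, 1], 2, 1)
    ccm_cross_map(e, xy[e$time_index + 1, 2])$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.05)
  expect_error(ccm_cross_map(emb, rep(1, nrow(emb$points))), "constant")
})

test_that("cross-map skill converges with library length on the coupled pair", {
  Ls <- c(100, 200, 400, 800)
  mean_rho <- vapply(Ls, function(L) {
    mean(vapply(1:20, function(s) {
      v <- lm_pair(L, seed = 900 + s)$values
      e <- delay_embed(v[, "x2"], 2, 1)     # response geometry reconstructs driver
      ccm_cross_map(e, v[e$time_index + 1, "x1"])$rho
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(seq_along(Ls), mean_rho, method = "spearman"), 0)
  expect_gt(mean_rho[4], mean_rho[1])
})

test_that("ccs score is exactly invariant under positive affine maps", {
  v <- lm_pair(300, seed = 32)$values
  base <- ccs_score(v[, 1], v[, 2], seed = 3)
  scaled_y <- ccs_score(v[, 1], 5 * v[, 2] + 2, seed = 3)
  scaled_x <- ccs_score(100 * v[, 1] - 7, v[, 2], seed = 3)
  expect_identical(base$error, scaled_y$error)   # bit-equal rank curves
  expect_identical(base$error, scaled_x$error)
  expect_identical(base$score, scaled_y$score)
})

test_that("independent series score near zero; coupling orients the score", {
  nulls <- vapply(1:60, function(s) {
    xy <- noise_pair(400, 500 + s)
    ccs_score(xy[, 1], xy[, 2], seed = s)$score
  }, numeric(1))
  expect_lt(mean(nulls), 0.1)
  sc <- t(vapply(1:60, function(s) {
    v <- lm_pair(400, seed = 600 + s)$values
    c(fwd = ccs_score(v[, 1], v[, 2], seed = s)$score,
      rev = ccs_score(v[, 2], v[, 1], seed = s)$score)
  }, numeric(2)))
  expect_gt(mean(sc[, "fwd"]), mean(sc[, "rev"]))
})

test_that("random sorting calibrates the error curve to one at every level", {
  v <- lm_pair(400, seed = 33)$values
  ex <- delay_embed(v[, 1], 2, 1)
  ey <- delay_embed(v[, 2], 2, 1)
  pr <- statecausal:::sample_pairs(nrow(ex$points), 5000L, 12L)
  dx <- statecausal:::row_dist(ex$points, pr$i, pr$j)
  dy <- statecausal:::row_dist(ey$points, pr$i, pr$j)
  levels <- seq(0.05, 1, by = 0.05)
  curves <- statecausal:::local_seed(13, vapply(1:100, function(k) {
    statecausal:::ccs_rank_curve(sample(dx), dy, levels)$error
  }, numeric(length(levels))))
  m <- rowMeans(curves)
  expect_true(all(m > 0.9 & m < 1.1))
  # the full-curve normalizer is E|U-V| = 1/3, verified by shuffling
  obs_full <- statecausal:::local_seed(14, mean(vapply(1:100, function(k) {
    mean(abs(rank_transform(sample(dx)) - rank_transform(dy)))
  }, numeric(1))))
  expect_lt(abs(obs_full - 1 / 3), 0.01)
})
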