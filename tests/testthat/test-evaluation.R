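test_that("rank AUC equals the brute-force pair count", {
  expect_equal(auc(c(0.9, 0.8), c(0.7, 0.85)), 0.75)
  expect_equal(auc(c(2, 3), c(0, 1)), 1)
  expect_equal(auc(0.5, 0.5), 0.5)
  for (s in 1:10) {
    sc <- statecausal:::local_seed(s, {
      list(p = round(runif(sample(3:100, 1)), 2),
           n = round(runif(sample(3:100, 1)), 2))
    })
    expect_equal(auc(sc$p, sc$n), auc_brute(sc$p, sc$n))
  }
  expect_error(auc(numeric(0), 1), "non-empty")
})

test_that("stationary bootstrap resamples blocks with the right mean length", {
  x <- statecausal:::local_seed(21, rnorm(200))
  surr <- stationary_bootstrap(x, mean_block = 5, n = 50, seed = 3)
  expect_equal(dim(surr), c(200L, 50L))
  expect_true(all(surr %in% x))                 # multiset inclusion
  # realized block count -> mean length within 5% (geometric mean)
  tot_blocks <- statecausal:::local_seed(4, {
    sum(vapply(1:300, function(i)
      statecausal:::sb_index_one(500L, 10)$n_blocks, integer(1)))
  })
  expect_lt(abs(300 * 500 / tot_blocks - 10) / 10, 0.05)
  # mean_block = 1 degenerates to i.i.d. resampling: no forced continuations
  idx <- statecausal:::local_seed(5,
    statecausal:::sb_index_one(1000L, 1)$idx)
  expect_equal(statecausal:::local_seed(5,
    statecausal:::sb_index_one(1000L, 1)$n_blocks), 1000L)
  expect_identical(stationary_bootstrap(x, 1, 2, seed = 9),
                   stationary_bootstrap(x, 1, 2, seed = 9))
  expect_error(stationary_bootstrap(x[1:5], 2, 3), "too short")
})

test_that("the automatic block rule lengthens with serial dependence", {
  wn <- statecausal:::local_seed(22, rnorm(1000))
  ar <- statecausal:::local_seed(23,
    as.numeric(arima.sim(list(ar = 0.9), 1000)))
  expect_gt(politis_white_block(ar), politis_white_block(wn))
  expect_gte(politis_white_block(wn), 1)
})

test_that("significance respects the add-one p-value floor and detects coupling", {
  v <- lm_pair(400, seed = 41)$values
  res <- significance("cs", v[, 1], v[, 2], n_surrogates = 100L, seed = 6)
  expect_gte(res$p_value, 1 / 101)
  expect_equal(res$p_value, 1 / 101)            # strong effect hits the floor
  detected <- vapply(1:100, function(s) {
    v <- lm_pair(400, seed = 1600 + s)$values
    significance("cs", v[, 1], v[, 2], n_surrogates = 100L,
                 seed = s)$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(detected), 0.85)
})

test_that("both methods hold their size on the independent-noise null", {
  for (m in c("cs", "ccs")) {
    rej <- vapply(1:100, function(s) {
      xy <- noise_pair(200, 1700 + s)
      significance(m, xy[, 1], xy[, 2], n_surrogates = 50L,
                   seed = s)$p_value <= 0.05
    }, logical(1))
    expect_gte(mean(rej), 0.01)
    expect_lte(mean(rej), 0.10)
  }
})

test_that("causality ratio floors the denominator and flags it", {
  expect_equal(as.numeric(causality_ratio(0.4, 0.2)), 2)
  expect_equal(as.numeric(causality_ratio(0.3, 0.3)), 1)
  r <- causality_ratio(0.4, 0)
  expect_equal(as.numeric(r), 4e5)
  expect_true(attr(r, "floored")["den"])
  expect_false(attr(r, "floored")["num"])
})

test_that("rmse matches hand computations", {
  expect_equal(rmse(c(0.1, 0.2), c(0, 0)), sqrt(0.025))
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(1, 0), 1)
  expect_error(rmse(numeric(0), numeric(0)), "empty")
  expect_error(rmse(1:3, 1:2), "mismatch")
})

test_that("a zero-coupling sweep carries no directional information", {
  sw <- run_sweep("coupling", "lm", "cs", levels = 0, reps = 40,
                  L = 300, seed = 51)
  expect_true(all(abs(sw$auc_by_value$auc - 0.5) < 0.2))
  expect_false(any(sw$records$truth))
})

test_that("sweep results carry one record per realization and direction", {
  sw <- run_sweep("length", "lm", "both", levels = c(150, 300), reps = 5,
                  L = 300, seed = 52, diagnostics = TRUE)
  expect_equal(nrow(sw$records), 2 * 5 * 2 * 2)
  expect_true(all(c("correlation", "mi") %in% names(sw$records)))
  expect_true(all(is.finite(sw$records$mi)))
  expect_equal(nrow(sw$auc_by_value), 4)
})

test_that("the bidirectional grid honours its record contract and guards", {
  g <- grid_bidirectional("cs", grid_size = 3, reps = 2, L = 300,
                          n_surrogates = 20, seed = 53)
  expect_equal(nrow(g$records), 3 * 3 * 2 * 2)
  expect_error(grid_bidirectional("cs", grid_size = 3, c_max = 0),
               "zero")
  s <- g$summaries$cs
  expect_true(s$auc >= 0 && s$auc <= 1)
  expect_true(all(c(s$rmse_c1, s$rmse_c2, s$rmse_diff) >= 0))
})

test_that("score-based and significance-based AUC agree on a clear benchmark", {
  scores_f <- scores_r <- pvals_f <- pvals_r <- numeric(15)
  for (s in 1:15) {
    v <- lm_pair(400, seed = 1800 + s)$values
    sf <- significance("cs", v[, 1], v[, 2], n_surrogates = 50L, seed = s)
    sr <- significance("cs", v[, 2], v[, 1], n_surrogates = 50L, seed = s)
    scores_f[s] <- sf$observed; scores_r[s] <- sr$observed
    pvals_f[s] <- sf$p_value;  pvals_r[s] <- sr$p_value
  }
  auc_score <- auc(scores_f, scores_r)
  auc_sig <- auc(1 - pvals_f, 1 - pvals_r)
  expect_gt(auc_score, 0.9)
  expect_gt(auc_sig, 0.9)
})
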