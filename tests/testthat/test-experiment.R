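make_config <- function(dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- modifyList(list(name = "lm_length_sweep_small", system = "lm",
                         method = "cs", design = "length",
                         levels = c(100, 200), reps = 3, L = 200, seed = 77,
                         output_dir = dir),
                    list(...))
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, path)
  path
}

test_that("the bundled sweep config parses and validates", {
  bundled <- system.file("extdata", "lm_length_sweep_small.yaml",
                         package = "statecausal")
  cfg <- yaml::read_yaml(bundled)
  expect_silent(statecausal:::validate_config(cfg))
  expect_equal(cfg$design, "length")
  expect_equal(length(cfg$levels), 3L)
})

test_that("a bundled-style sweep config runs end to end, deterministically", {
  dir <- file.path(tempdir(), "exp1")
  cfg <- make_config(dir)
  res <- suppressMessages(run_experiment(cfg))
  expect_s3_class(res, "sweep_result")
  expect_equal(nrow(res$auc_by_value), 2)       # one row per level
  rec <- file.path(dir, "lm_length_sweep_small_records.csv")
  expect_true(file.exists(rec))
  summ <- jsonlite::read_json(file.path(dir,
    "lm_length_sweep_small_summary.json"), simplifyVector = TRUE)
  expect_equal(summ$config$reps, 3)
  expect_equal(summ$config$n_surrogates, 50)    # defaults materialized
  first <- readBin(rec, "raw", file.size(rec))
  suppressMessages(run_experiment(cfg))
  expect_identical(readBin(rec, "raw", file.size(rec)), first)
})

test_that("config validation rejects malformed experiments before computing", {
  dir <- file.path(tempdir(), "exp2")
  expect_error(run_experiment(list(name = "x", system = "lm", method = "cs",
                                   design = "length", reps = 0, seed = 1,
                                   levels = 100)),
               "reps")
  expect_error(run_experiment(list(system = "lm", method = "cs",
                                   design = "length", reps = 1, seed = 1)),
               "missing")
  expect_error(run_experiment(list(name = "x", system = "nope", method = "cs",
                                   design = "length", reps = 1, seed = 1,
                                   levels = 1)),
               "system")
})

test_that("file scoring equals in-memory scoring and surfaces parse errors", {
  ts <- lm_pair(300, seed = 61)
  path <- file.path(tempdir(), "scored.csv")
  write_time_series(ts, path)
  out <- score_file(path, "cs", "x1", "x2", seed = 5)
  mem_f <- cs_strength(ts$values[, "x1"], ts$values[, "x2"], seed = 5)$strength
  mem_r <- cs_strength(ts$values[, "x2"], ts$values[, "x1"], seed = 5)$strength
  expect_equal(out$score_forward, mem_f)
  expect_equal(out$score_reverse, mem_r)
  expect_equal(out$ratio_cause_effect,
               as.numeric(causality_ratio(mem_f, mem_r)))
  expect_error(score_file(path, "cs", "x1", "zz"), "zz")
  # constant column surfaces the standardization error with the channel
  bad <- time_series_set(cbind(a = rep(1, 120), b = rnorm(120)))
  bp <- file.path(tempdir(), "bad.csv")
  write_time_series(bad, bp)
  expect_error(score_file(bp, "cs", "a", "b"), "constant")
})

test_that("chemostat-shaped data runs end to end", {
  # two positive, intermittent channels of length ~350 at dt != 1
  L <- 350
  raw <- statecausal:::local_seed(62, {
    base <- abs(arima.sim(list(ar = 0.95), L)) + 0.05
    prey <- as.numeric(base * exp(0.3 * rnorm(L)))
    pred <- as.numeric((stats::filter(prey, rep(0.25, 4), sides = 1)))
    pred[is.na(pred)] <- prey[1:3]
    cbind(algae = prey, rotifer = abs(pred * exp(0.2 * rnorm(L))))
  })
  ts <- time_series_set(raw, dt = 0.5)
  path <- file.path(tempdir(), "chemostat_synthetic.csv")
  write_time_series(ts, path)
  out <- score_file(path, "ccs", "algae", "rotifer", n_surrogates = 20L,
                    seed = 8)
  expect_true(is.finite(out$score_forward))
  expect_true(is.finite(out$score_reverse))
  expect_true(out$significance_forward > 0 && out$significance_forward <= 1)
})
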