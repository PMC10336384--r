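# Evaluation harness: ROC/AUC, stationary-bootstrap significance, causality
# ratios, RMSE, and the sweep/grid experiment designs.

#' Rank-based AUC
#'
#' `P(pos > neg) + 0.5 * P(pos = neg)`, the normalized Mann-Whitney U
#' statistic: the probability that a randomly chosen positive score exceeds
#' a randomly chosen negative one.
#'
#' @param scores_pos scores of the positive class (true causal directions).
#' @param scores_neg scores of the negative class.
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(0.9, 0.8), c(0.7, 0.85))
#' @export
auc <- function(scores_pos, scores_neg) {
  np <- length(scores_pos); nn <- length(scores_neg)
  if (np == 0 || nn == 0) stop("both score sets must be non-empty")
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Stationary-bootstrap surrogates
#'
#' Block resampling with geometrically distributed block lengths (expected
#' length `mean_block`) and circular wrap-around. With `mean_block = 1`
#' every sample is drawn independently. Surrogates preserve the marginal
#' distribution and short-range autocorrelation of the input but destroy its
#' relation to any other series, which is the null hypothesis used by
#' [significance()].
#'
#' @param x numeric series (length >= 10).
#' @param mean_block expected block length, >= 1 (may be fractional).
#' @param n number of surrogates.
#' @param seed integer RNG seed.
#' @return matrix `length(x)` x `n`, one surrogate per column.
#' @export
stationary_bootstrap <- function(x, mean_block, n, seed = 1L) {
  x <- as.numeric(x)
  L <- length(x)
  if (L < 10) stop("series too short for block resampling (need >= 10)")
  stopifnot_scalar(mean_block, "mean_block")
  if (mean_block < 1) stop("'mean_block' must be >= 1")
  stopifnot_scalar(n, "n", positive = TRUE, integer = TRUE)
  local_seed(seed, {
    out <- matrix(NA_real_, L, n)
    for (s in seq_len(n)) out[, s] <- x[sb_index_one(L, mean_block)$idx]
    out
  })
}

# One stationary-bootstrap index vector; also reports the number of blocks
# (used to verify the geometric mean block length). Consumes the current RNG
# stream.
sb_index_one <- function(L, mean_block) {
  p <- 1 / mean_block
  restart <- runif(L) < p
  restart[1] <- TRUE
  g <- cumsum(restart)
  nb <- g[L]
  starts <- sample.int(L, nb, replace = TRUE)
  run_start_pos <- which(restart)
  off <- seq_len(L) - run_start_pos[g]
  idx <- ((starts[g] + off - 1L) %% L) + 1L
  list(idx = idx, n_blocks = nb)
}

#' Automatic mean block length for the stationary bootstrap
#'
#' The Politis-White (2004) automatic rule: autocorrelations are screened
#' against a 2*sqrt(log10(N)/N) band to pick the lag window, a flat-top
#' kernel estimates the spectral quantities G and D, and the block length is
#' `(2 G^2 / D)^(1/3) * N^(1/3)`, clamped to a sane range.
#'
#' @param x numeric series.
#' @return expected block length (>= 1, possibly fractional).
#' @export
politis_white_block <- function(x) {
  x <- as.numeric(x)
  N <- length(x)
  if (N < 20) return(max(1, N^(1/3)))
  Kn <- max(5, ceiling(sqrt(log10(N))))
  mmax <- ceiling(sqrt(N)) + Kn
  ac <- drop(acf(x, lag.max = mmax + Kn, plot = FALSE)$acf)[-1]
  thresh <- 2 * sqrt(log10(N) / N)
  m <- mmax
  for (k in 0:(mmax - 1)) {
    if (all(abs(ac[(k + 1):(k + Kn)]) < thresh)) { m <- max(k, 1); break }
  }
  M <- min(2 * m, mmax)
  R0 <- var(x) * (N - 1) / N
  Rk <- ac[seq_len(M)] * R0
  lam <- function(t) ifelse(abs(t) <= 0.5, 1,
                            ifelse(abs(t) <= 1, 2 * (1 - abs(t)), 0))
  k <- seq_len(M)
  w <- lam(k / M)
  G <- 2 * sum(w * k * Rk)
  Dsb <- 2 * (R0 + 2 * sum(w * Rk))^2
  if (!is.finite(G) || !is.finite(Dsb) || Dsb <= 0) return(max(1, N^(1/3)))
  b <- (2 * G^2 / Dsb)^(1/3) * N^(1/3)
  min(max(b, 1), ceiling(min(3 * sqrt(N), N / 3)))
}

#' Causality strength ratio
#'
#' `r_c(1 -> 2) = C(1 -> 2) / C(2 -> 1)` after flooring each strength at
#' 1e-6; recommended as a relative indicator instead of the raw strengths.
#' The result carries a `floored` attribute flagging whether numerator or
#' denominator hit the floor.
#'
#' @param strength_12,strength_21 finite directed strengths.
#' @return the ratio, with attribute `floored` (named logical pair).
#' @examples
#' causality_ratio(0.4, 0.2)
#' @export
causality_ratio <- function(strength_12, strength_21) {
  stopifnot_scalar(strength_12, "strength_12")
  stopifnot_scalar(strength_21, "strength_21")
  floor_at <- 1e-6
  num <- max(strength_12, floor_at)
  den <- max(strength_21, floor_at)
  structure(num / den,
            floored = c(num = strength_12 < floor_at,
                        den = strength_21 < floor_at))
}

#' Root-mean-square error
#' @param detected,actual numeric vectors of equal, non-zero length.
#' @return `sqrt(mean((detected - actual)^2))`.
#' @export
rmse <- function(detected, actual) {
  if (length(detected) == 0) stop("empty input")
  if (length(detected) != length(actual)) stop("length mismatch")
  sqrt(mean((detected - actual)^2))
}

# ---- directed scoring helpers -------------------------------------------

# Embedding defaults: maps use dim 2 / lag 1 / no Theiler window. Flows use
# dim 6 — the driven subsystem of two coupled 3-D flows lives on the joint
# attractor, and under-embedding the effect side reverses the comparison —
# with an autocorrelation-selected lag per channel and a dim*lag Theiler
# window.
resolve_embedding <- function(system, cause, effect, embedding = NULL) {
  if (!is.null(embedding)) return(embedding)
  if (system == "lm") {
    list(dim_x = 2L, lag_x = 1L, dim_y = 2L, lag_y = 1L, theiler = 0L)
  } else {
    lx <- select_lag(cause, 30L)
    ly <- select_lag(effect, 30L)
    list(dim_x = 6L, lag_x = lx, dim_y = 6L, lag_y = ly,
         theiler = 6L * max(lx, ly))
  }
}

score_direction <- function(method, cause, effect, emb, seed,
                            n_ref = 200L, n_eps = 12L, max_pairs = 20000L) {
  if (method == "cs") {
    cs_strength(cause, effect,
                dim_x = emb$dim_x, lag_x = emb$lag_x,
                dim_y = emb$dim_y, lag_y = emb$lag_y,
                n_ref = n_ref, n_eps = n_eps, theiler = emb$theiler,
                seed = seed)$strength
  } else {
    ccs_score(cause, effect,
              dim_x = emb$dim_x, lag_x = emb$lag_x,
              dim_y = emb$dim_y, lag_y = emb$lag_y,
              max_pairs = max_pairs, theiler = emb$theiler,
              seed = seed)$score
  }
}

#' Stationary-bootstrap significance of a directed causality score
#'
#' The candidate cause channel is replaced by stationary-bootstrap
#' surrogates (destroying its dynamical relation to the effect while
#' preserving its marginal and short-range autocorrelation) and the directed
#' score is recomputed per surrogate. The p-value uses the add-one rule
#' `p = (1 + #{surrogate >= observed}) / (1 + n_valid)`, so the minimum
#' attainable p with 100 surrogates is 1/101.
#'
#' @param method `"cs"` or `"ccs"`.
#' @param x candidate cause channel.
#' @param y candidate effect channel.
#' @param n_surrogates surrogate count (100 by default).
#' @param seed integer seed.
#' @param mean_block expected surrogate block length; `NULL` selects it
#'   automatically with [politis_white_block()].
#' @param embedding optional list (`dim_x`, `lag_x`, `dim_y`, `lag_y`,
#'   `theiler`); defaults to map settings.
#' @param ... passed to the scorer (`n_ref`, `n_eps`, `max_pairs`).
#' @return a `significance_result`: `observed`, `surrogate_scores`,
#'   `p_value`, `n_surrogates` (valid count), `mean_block`.
#' @export
significance <- function(method = c("cs", "ccs"), x, y, n_surrogates = 100L,
                         seed = 1L, mean_block = NULL, embedding = NULL, ...) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  emb <- if (is.null(embedding))
    list(dim_x = 2L, lag_x = 1L, dim_y = 2L, lag_y = 1L, theiler = 0L)
  else embedding
  if (is.null(mean_block)) mean_block <- politis_white_block(x)
  surr <- stationary_bootstrap(x, mean_block, n_surrogates,
                               seed = derive_seed(seed, "sb"))
  st <- surrogate_test(method, x, y, emb, seed, surr, ...)[[method]]
  structure(list(observed = st$observed,
                 surrogate_scores = st$surrogate_scores,
                 p_value = st$p_value,
                 n_surrogates = length(st$surrogate_scores),
                 mean_block = mean_block, method = method),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf("<significance_result> %s: observed = %.4f, p = %.4f (%d surrogates, mean block %.1f)\n",
              x$method, x$observed, x$p_value, x$n_surrogates, x$mean_block))
  invisible(x)
}

# ---- sweep experiments ---------------------------------------------------

sweep_config <- function(system, coupling) {
  switch(system,
    lm = list(cause = "x1", effect = "x2", coupling = coupling %||% 0.1),
    rl = list(cause = "x2", effect = "y2", coupling = coupling %||% 2),
    rr = list(cause = "x1", effect = "y1", coupling = coupling %||% 0.1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

simulate_system <- function(system, L, coupling, seed, level = NULL,
                            design = "length") {
  if (system == "lm") {
    simulate_logistic_pair(logistic_params(C1 = 0, C2 = coupling,
                                           L = L, seed = seed))
  } else if (system == "rl") {
    simulate_rossler_lorenz(rossler_lorenz_params(a = 6, C = coupling,
                                                  L = L, seed = seed))
  } else {
    om2 <- if (design == "frequency") 1 / level else 1
    simulate_rossler_rossler(rossler_rossler_params(omega1 = 1, omega2 = om2,
                                                    C = coupling, L = L,
                                                    seed = seed))
  }
}

#' Run a benchmark sweep and compute per-level detection AUC
#'
#' Four designs over the simulated systems: `length` (swept value is the
#' series length L), `coupling` (swept value is the driving coupling),
#' `noise` (swept value is the SNR in dB; noise is added to both channels),
#' and `frequency` (Roessler-Roessler only; swept value is the frequency
#' ratio r = omega1/omega2, with omega1 fixed at 1). Each level is simulated
#' `reps` times with seeds derived from the master seed, both directions are
#' scored, and the per-level score-based AUC uses the true-direction scores
#' as positives and the reverse-direction scores as negatives.
#'
#' @param design sweep design.
#' @param system `"lm"` (coupled logistic maps, x1 -> x2), `"rl"`
#'   (Roessler-Lorenz, x2 -> y2) or `"rr"` (Roessler-Roessler, x1 -> y1).
#' @param method `"cs"`, `"ccs"` or `"both"`.
#' @param levels swept values (non-empty).
#' @param reps realizations per level.
#' @param L series length for non-length designs.
#' @param coupling driving coupling for non-coupling designs (defaults:
#'   lm 0.1, rl 2, rr 0.1).
#' @param snr_db SNR applied in non-noise designs (`NULL` = no noise).
#' @param seed master seed.
#' @param embedding optional embedding override (see [significance()]).
#' @param diagnostics also record Pearson correlation and KSG mutual
#'   information between the two channels per realization.
#' @param n_ref,n_eps,max_pairs scorer settings.
#' @return a `sweep_result`: `design`, `records` (one row per realization,
#'   direction and method), `auc_by_value` (per level and method), and
#'   `failures`.
#' @export
run_sweep <- function(design = c("length", "coupling", "noise", "frequency"),
                      system = c("lm", "rl", "rr"),
                      method = c("cs", "ccs", "both"),
                      levels, reps = 100L, L = 400L, coupling = NULL,
                      snr_db = NULL, seed = 1L, embedding = NULL,
                      diagnostics = FALSE,
                      n_ref = 200L, n_eps = 12L, max_pairs = 20000L) {
  design <- match.arg(design)
  system <- match.arg(system)
  method <- match.arg(method)
  methods <- if (method == "both") c("cs", "ccs") else method
  if (length(levels) == 0) stop("'levels' must be non-empty")
  stopifnot_scalar(reps, "reps", positive = TRUE, integer = TRUE)
  if (design == "frequency" && system != "rr")
    stop("the frequency design applies to the Roessler-Roessler system only")

  cfg <- sweep_config(system, coupling)
  rows <- vector("list", length(levels) * reps * 2L * length(methods))
  fails <- list()
  ri <- 0L
  for (li in seq_along(levels)) {
    lev <- levels[li]
    for (rep_i in seq_len(reps)) {
      seed_r <- derive_seed(seed, design, li, rep_i)
      L_r <- if (design == "length") as.integer(lev) else as.integer(L)
      coup <- if (design == "coupling") lev else cfg$coupling
      snr <- if (design == "noise") lev else snr_db
      sim <- tryCatch(
        simulate_system(system, L_r, coup, seed_r, level = lev,
                        design = design),
        error = function(e) e)
      if (inherits(sim, "error")) {
        fails[[length(fails) + 1L]] <-
          data.frame(level = lev, rep = rep_i, stage = "simulate",
                     message = conditionMessage(sim))
        next
      }
      if (!is.null(snr))
        sim <- add_noise(sim, snr, seed = derive_seed(seed_r, "noise"))
      cause <- channel(sim, cfg$cause)
      effect <- channel(sim, cfg$effect)
      emb <- tryCatch(resolve_embedding(system, cause, effect, embedding),
                      error = function(e) e)
      if (inherits(emb, "error")) {
        fails[[length(fails) + 1L]] <-
          data.frame(level = lev, rep = rep_i, stage = "embedding",
                     message = conditionMessage(emb))
        next
      }
      diag_cor <- diag_mi <- NA_real_
      if (diagnostics) {
        diag_cor <- correlation(cause, effect)
        diag_mi <- ksg_mi(cause, effect, seed = seed_r)$mi
      }
      for (m in methods) {
        for (dir in c("fwd", "rev")) {
          sc <- tryCatch(
            if (dir == "fwd")
              score_direction(m, cause, effect, emb, seed_r,
                              n_ref, n_eps, max_pairs)
            else
              score_direction(m, effect, cause, emb, seed_r,
                              n_ref, n_eps, max_pairs),
            error = function(e) e)
          if (inherits(sc, "error")) {
            fails[[length(fails) + 1L]] <-
              data.frame(level = lev, rep = rep_i,
                         stage = paste(m, dir), message = conditionMessage(sc))
            next
          }
          ri <- ri + 1L
          rows[[ri]] <- data.frame(
            design = design, system = system, level = lev, rep = rep_i,
            seed = seed_r, method = m, direction = dir,
            cause = if (dir == "fwd") cfg$cause else cfg$effect,
            effect = if (dir == "fwd") cfg$effect else cfg$cause,
            truth = (dir == "fwd") && coup > 0,
            score = sc, dim = emb$dim_x,
            lag_cause = if (dir == "fwd") emb$lag_x else emb$lag_y,
            correlation = diag_cor, mi = diag_mi)
        }
      }
    }
  }
  records <- do.call(rbind, rows[seq_len(ri)])
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(level = numeric(), rep = integer(), stage = character(),
               message = character())
  # drop levels with more than 20% failed realizations
  for (lev in unique(failures$level)) {
    n_fail <- sum(failures$level == lev & failures$stage == "simulate")
    if (n_fail > 0.2 * reps)
      records <- records[records$level != lev, ]
  }
  aucs <- list()
  for (lev in unique(records$level)) {
    for (m in methods) {
      sub <- records[records$level == lev & records$method == m, ]
      aucs[[length(aucs) + 1L]] <- data.frame(
        level = lev, method = m,
        auc = auc(sub$score[sub$direction == "fwd"],
                  sub$score[sub$direction == "rev"]),
        n = nrow(sub))
    }
  }
  structure(list(design = design, system = system,
                 records = records,
                 auc_by_value = do.call(rbind, aucs),
                 failures = failures,
                 config = list(levels = levels, reps = reps, L = L,
                               coupling = cfg$coupling, snr_db = snr_db,
                               seed = seed)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s sweep on %s (%d records)\n",
              x$design, x$system, nrow(x$records)))
  print(x$auc_by_value, row.names = FALSE)
  invisible(x)
}

# ---- bidirectional grid --------------------------------------------------

# Min-max rescale `d` onto the range of `target` (heat-map comparison of
# detected strengths against couplings, which live in different units).
rescale_to <- function(d, target) {
  rd <- range(d)
  rt <- range(target)
  if (rd[2] == rd[1]) return(rep(mean(rt), length(d)))
  (d - rd[1]) / (rd[2] - rd[1]) * (rt[2] - rt[1]) + rt[1]
}

#' Bidirectionally coupled logistic-map grid experiment
#'
#' Simulates the logistic pair over a `grid_size` x `grid_size` grid of
#' couplings (C1, C2) in \[0, c_max\], `reps` realizations per cell. Each
#' realization and direction gets a strength and a stationary-bootstrap
#' p-value; the detection AUC uses `1 - p` as score against the ground-truth
#' labels (the generating coupling into the effect is > 0). Cells on the
#' zero rows/columns supply the negatives. Per method, the detected-strength
#' maps (per-cell means over realizations) are min-max rescaled onto the
#' actual coupling range and compared by RMSE: strength(x2 -> x1) against
#' C1, strength(x1 -> x2) against C2, and their difference against C2 - C1.
#'
#' @param method `"cs"`, `"ccs"` or `"both"` (shared simulations and
#'   surrogates).
#' @param grid_size grid points per axis (>= 2).
#' @param reps realizations per cell.
#' @param L series length.
#' @param n_surrogates surrogates per realization and direction.
#' @param seed master seed.
#' @param c_max largest coupling on the grid.
#' @param r1,r2 growth rates.
#' @param mean_block surrogate block length (`NULL` = automatic per series).
#' @param n_ref,n_eps,max_pairs scorer settings.
#' @return a `grid_result`: `records` (one row per realization, direction
#'   and method), `summaries` (per method: `auc`, `rmse_c1`, `rmse_c2`,
#'   `rmse_diff`), `maps`, `failures`, `config`.
#' @export
grid_bidirectional <- function(method = c("cs", "ccs", "both"),
                               grid_size = 9L, reps = 10L, L = 400L,
                               n_surrogates = 50L, seed = 1L, c_max = 1,
                               r1 = 3.6, r2 = 3.7, mean_block = NULL,
                               n_ref = 200L, n_eps = 12L,
                               max_pairs = 20000L) {
  method <- match.arg(method)
  methods <- if (method == "both") c("cs", "ccs") else method
  stopifnot_scalar(grid_size, "grid_size", positive = TRUE, integer = TRUE)
  if (grid_size < 2) stop("'grid_size' must be >= 2")
  cvals <- seq(0, c_max, length.out = grid_size)
  if (all(cvals == 0))
    stop("all couplings are zero: no positive directions, AUC undefined")
  emb <- list(dim_x = 2L, lag_x = 1L, dim_y = 2L, lag_y = 1L, theiler = 0L)

  rows <- vector("list", grid_size^2 * reps * 2L * length(methods))
  fails <- list()
  ri <- 0L
  for (i1 in seq_along(cvals)) {
    for (i2 in seq_along(cvals)) {
      C1 <- cvals[i1]; C2 <- cvals[i2]
      for (rep_i in seq_len(reps)) {
        seed_r <- derive_seed(seed, "grid", i1, i2, rep_i)
        sim <- tryCatch(
          simulate_logistic_pair(logistic_params(r1 = r1, r2 = r2,
                                                 C1 = C1, C2 = C2,
                                                 L = L, seed = seed_r)),
          error = function(e) e)
        if (inherits(sim, "error")) {
          fails[[length(fails) + 1L]] <-
            data.frame(C1 = C1, C2 = C2, rep = rep_i, stage = "simulate",
                       message = conditionMessage(sim))
          next
        }
        x1 <- sim$values[, "x1"]; x2 <- sim$values[, "x2"]
        dirs <- list(
          list(label = "x1->x2", cause = x1, effect = x2, truth = C2 > 0),
          list(label = "x2->x1", cause = x2, effect = x1, truth = C1 > 0))
        for (d in dirs) {
          if (sd(d$cause) == 0 || sd(d$effect) == 0) {
            fails[[length(fails) + 1L]] <-
              data.frame(C1 = C1, C2 = C2, rep = rep_i,
                         stage = paste("constant", d$label),
                         message = "collapsed channel")
            next
          }
          mb <- mean_block %||% politis_white_block(d$cause)
          surr <- stationary_bootstrap(d$cause, mb, n_surrogates,
                                       seed = derive_seed(seed_r, d$label))
          for (m in methods) {
            st <- tryCatch(
              surrogate_test(m, d$cause, d$effect, emb, seed_r, surr,
                             n_ref = n_ref, n_eps = n_eps,
                             max_pairs = max_pairs)[[m]],
              error = function(e) e)
            if (inherits(st, "error")) {
              fails[[length(fails) + 1L]] <-
                data.frame(C1 = C1, C2 = C2, rep = rep_i,
                           stage = paste(m, d$label),
                           message = conditionMessage(st))
              next
            }
            ri <- ri + 1L
            rows[[ri]] <- data.frame(
              C1 = C1, C2 = C2, rep = rep_i, seed = seed_r,
              direction = d$label, truth = d$truth, method = m,
              strength = st$observed, p_value = st$p_value,
              n_surr = length(st$surrogate_scores), mean_block = mb)
          }
        }
      }
    }
  }
  records <- do.call(rbind, rows[seq_len(ri)])
  if (is.null(records) || !any(records$truth))
    stop("no positive directions were scored; AUC undefined")

  summaries <- list()
  maps <- list()
  for (m in methods) {
    rm_ <- records[records$method == m, ]
    auc_m <- auc(1 - rm_$p_value[rm_$truth], 1 - rm_$p_value[!rm_$truth])
    cell <- paste(format(rm_$C1, digits = 12), format(rm_$C2, digits = 12),
                  sep = "|")
    s12 <- tapply(rm_$strength[rm_$direction == "x1->x2"],
                  cell[rm_$direction == "x1->x2"], mean)
    s21 <- tapply(rm_$strength[rm_$direction == "x2->x1"],
                  cell[rm_$direction == "x2->x1"], mean)
    key <- sort(intersect(names(s12), names(s21)))
    s12 <- s12[key]; s21 <- s21[key]
    cc <- do.call(rbind, strsplit(key, "|", fixed = TRUE))
    aC1 <- as.numeric(cc[, 1]); aC2 <- as.numeric(cc[, 2])
    summaries[[m]] <- list(
      auc = auc_m,
      rmse_c1 = rmse(rescale_to(s21, aC1), aC1),
      rmse_c2 = rmse(rescale_to(s12, aC2), aC2),
      rmse_diff = rmse(rescale_to(s12 - s21, aC2 - aC1), aC2 - aC1))
    maps[[m]] <- data.frame(C1 = aC1, C2 = aC2, s12 = as.numeric(s12),
                            s21 = as.numeric(s21))
  }
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(C1 = numeric(), C2 = numeric(), rep = integer(),
               stage = character(), message = character())
  structure(list(records = records, summaries = summaries, maps = maps,
                 failures = failures,
                 config = list(grid_size = grid_size, reps = reps, L = L,
                               n_surrogates = n_surrogates, seed = seed,
                               c_max = c_max, r1 = r1, r2 = r2)),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("<grid_result> %dx%d grid, %d reps, %d records (%d failures)\n",
              x$config$grid_size, x$config$grid_size, x$config$reps,
              nrow(x$records), nrow(x$failures)))
  for (m in names(x$summaries)) {
    s <- x$summaries[[m]]
    cat(sprintf("  %s: AUC = %.4f, RMSE C1/C2/diff = %.3f/%.3f/%.3f\n",
                m, s$auc, s$rmse_c1, s$rmse_c2, s$rmse_diff))
  }
  invisible(x)
}
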