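# Batched directed scoring for surrogate tests. All candidate causes are
# scored against one fixed effect channel, so the effect-space geometry
# (radius grid, ball membership, conditioning ranks, pair sample) is
# computed once. The first element of `causes` is conventionally the
# observed channel; the rest are surrogates.

score_batch_cs <- function(causes, effect, emb, seed,
                           n_ref = 200L, n_eps = 12L,
                           cover_q = 0.6, hi_q = 0.25) {
  effect <- standardize(as.numeric(effect))
  ey <- delay_embed(effect, emb$dim_y, emb$lag_y)
  ex1 <- delay_embed(as.numeric(causes[[1]]), emb$dim_x, emb$lag_x)
  al <- align_embeddings(ex1, ey)
  pe <- ey$points[al$iy, , drop = FALSE]
  tms <- al$times
  n <- length(tms)
  if (n < 30L) stop("too few aligned points for continuity scaling")
  pts <- lapply(causes, function(ch) {
    ch <- tryCatch(standardize(as.numeric(ch)), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    delay_embed(ch, emb$dim_x, emb$lag_x)$points[al$ix, , drop = FALSE]
  })
  ok <- !vapply(pts, is.null, TRUE)
  if (!ok[1]) stop("observed cause channel cannot be standardized")
  refs <- local_seed(derive_seed(seed, "cs_refs"),
                     sample.int(n, min(n_ref, n)))
  res <- cs_scan_multi_cpp(pts[ok], pe, as.integer(tms),
                           as.integer(refs - 1L), as.integer(n_eps),
                           as.integer(emb$theiler), 3L, cover_q, hi_q)
  if (res$skipped_frac > 0.5)
    stop(sprintf(paste0("%.0f%% of reference neighbourhoods had fewer than 3 ",
                        "members at the smallest radius; increase the ",
                        "minimum epsilon or supply longer series"),
                 100 * res$skipped_frac))
  lx <- log(res$eps)
  lxc <- lx - mean(lx)
  slopes_ok <- drop(res$delta %*% lxc) / sum(lxc^2)
  slopes <- rep(NA_real_, length(causes))
  slopes[ok] <- slopes_ok
  slopes
}

score_batch_ccs <- function(causes, effect, emb, seed,
                            max_pairs = 20000L, n_levels = 20L) {
  effect <- as.numeric(effect)
  ey <- delay_embed(effect, emb$dim_y, emb$lag_y)
  ex1 <- delay_embed(as.numeric(causes[[1]]), emb$dim_x, emb$lag_x)
  al <- align_embeddings(ex1, ey)
  pe <- ey$points[al$iy, , drop = FALSE]
  tms <- al$times
  n <- length(tms)
  if (n < 20L) stop("too few aligned points for rank curves")
  pairs <- sample_pairs(n, max_pairs, derive_seed(seed, "ccs_pairs"))
  if (emb$theiler > 0L) {
    keep <- abs(tms[pairs$i] - tms[pairs$j]) > emb$theiler
    pairs$i <- pairs$i[keep]; pairs$j <- pairs$j[keep]
  }
  dy <- row_dist(pe, pairs$i, pairs$j)
  ro <- ccs_rank_order_cpp(dy)
  levels <- seq_len(n_levels) / n_levels
  vapply(causes, function(ch) {
    px <- tryCatch(
      delay_embed(as.numeric(ch), emb$dim_x, emb$lag_x)$points[al$ix, ,
                                                               drop = FALSE],
      error = function(e) NULL)
    if (is.null(px)) return(NA_real_)
    dx <- row_dist(px, pairs$i, pairs$j)
    cv <- ccs_curve_fixed_cpp(dx, ro$ry, ro$order, levels)
    norm_err <- cv$obs / cv$rand
    keep <- !is.na(norm_err) & cv$count >= 10L
    fit <- fit_rank_curve(levels[keep], 1 - norm_err[keep])
    max(0, fit$e0)
  }, numeric(1))
}

# Shared observed + surrogate scoring for one direction; returns the
# observed score, surrogate scores and the add-one p-value per method.
surrogate_test <- function(methods, cause, effect, emb, seed, surr,
                           n_ref = 200L, n_eps = 12L, max_pairs = 20000L) {
  causes <- c(list(cause), lapply(seq_len(ncol(surr)), function(s) surr[, s]))
  out <- list()
  for (m in methods) {
    scores <- if (m == "cs")
      score_batch_cs(causes, effect, emb, seed, n_ref, n_eps)
    else
      score_batch_ccs(causes, effect, emb, seed, max_pairs)
    obs <- scores[1]
    if (is.na(obs)) stop("observed scoring failed")
    sv <- scores[-1]
    okv <- !is.na(sv)
    if (mean(!okv) > 0.2)
      stop(sprintf("%d of %d surrogate scorings failed",
                   sum(!okv), length(sv)))
    out[[m]] <- list(observed = obs, surrogate_scores = sv[okv],
                     p_value = (1 + sum(sv[okv] >= obs)) / (1 + sum(okv)))
  }
  out
}
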