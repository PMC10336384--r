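# Convergent cross sorting, and the exponential-weight cross-map
# reconstruction (CCM) it extends.

#' Dimensionless distance ranks on \[0, 1\]
#'
#' Sorted ascending values receive evenly spaced ranks (k - 1)/(n - 1) for
#' k = 1..n, returned in the input order; ties share the mean of their
#' would-be ranks. Any strictly increasing transform of the input yields the
#' same output.
#'
#' @param distances numeric vector, length >= 2.
#' @return numeric vector of ranks in \[0, 1\].
#' @examples
#' rank_transform(c(0.3, 0.1, 0.2))
#' @export
rank_transform <- function(distances) {
  n <- length(distances)
  if (n < 2) stop("need at least two values to rank")
  (rank(distances, ties.method = "average") - 1) / (n - 1)
}

#' Cross-map reconstruction with exponential weights
#'
#' For each point of `source_embedding`, the `dim + 1` nearest neighbours
#' (Euclidean distance) define weights `exp(-d_i / d_1)`, normalized to sum
#' 1, and the target is reconstructed as the weighted neighbour average. The
#' returned skill is the Pearson correlation between the target and its
#' reconstruction. Under the cross-map convention, "x causes y" is assessed
#' by how well y's embedding reconstructs x, i.e.
#' `ccm_cross_map(delay_embed(y, ...), x_aligned)`.
#'
#' If the nearest-neighbour distance is zero, the weights degenerate to a
#' uniform distribution over the zero-distance set (not an error).
#'
#' @param source_embedding a [delay_embed()] result.
#' @param target numeric vector aligned with the embedding rows (i.e. the
#'   target sampled at `time_index`).
#' @param theiler Theiler exclusion window in samples.
#' @return a `ccm_result`: list with `rho`, `reconstruction`, `weights_stat`
#'   (summary of the largest normalized weight), `dim`, `lag`.
#' @export
ccm_cross_map <- function(source_embedding, target, theiler = 0L) {
  stopifnot(inherits(source_embedding, "delay_embedding"))
  target <- as.numeric(target)
  n <- nrow(source_embedding$points)
  if (length(target) != n)
    stop("'target' must be aligned with the embedding rows")
  if (sd(target) == 0) stop("'target' is constant; correlation undefined")
  k <- source_embedding$dim + 1L
  if (n < k + 2L) stop(sprintf("need at least %d points", k + 2L))
  nn <- knn_search(source_embedding, k, theiler = theiler)
  w1 <- numeric(n)
  yhat <- numeric(n)
  for (i in seq_len(n)) {
    d <- nn$dist[i, ]
    if (d[1] == 0) {
      w <- as.numeric(d == 0)
    } else {
      w <- exp(-d / d[1])
    }
    w <- w / sum(w)
    w1[i] <- max(w)
    yhat[i] <- sum(w * target[nn$index[i, ]])
  }
  structure(list(rho = cor(target, yhat), reconstruction = yhat,
                 weights_stat = c(mean_top = mean(w1), sd_top = sd(w1)),
                 dim = source_embedding$dim, lag = source_embedding$lag),
            class = "ccm_result")
}

#' @export
print.ccm_result <- function(x, ...) {
  cat(sprintf("<ccm_result> rho = %.4f (dim = %d, lag = %d)\n",
              x$rho, x$dim, x$lag))
  invisible(x)
}

# Align two embeddings of equally long channels onto their common original
# sample times; returns row indices into each.
align_embeddings <- function(ex, ey) {
  common <- intersect(ex$time_index, ey$time_index)
  list(ix = match(common, ex$time_index),
       iy = match(common, ey$time_index),
       times = common)
}

# Sorting-error and sorting-skill curves over sampled point pairs.
# `dx`, `dy`: pairwise distances in the two reconstructed spaces. Pairs are
# conditioned on their rank in the `dy` space. Returns the curve at `levels`.
ccs_rank_curve <- function(dx, dy, levels) {
  cv <- ccs_error_curve_cpp(dx, dy, levels)
  norm_err <- cv$obs / cv$rand
  keep <- !is.na(norm_err) & cv$count >= 10L
  list(r_values = levels[keep],
       error = norm_err[keep],
       skill = 1 - norm_err[keep],
       count = cv$count[keep])
}

# Bounded exponential fit E(R) = a + b * exp(c * R). Returns the fit and the
# intercept E(0) = a + b; falls back to linear extrapolation of the two
# smallest-R values on failure.
fit_rank_curve <- function(r, e) {
  a0 <- min(max(e[length(e)], 0), 2)
  b0 <- min(max(e[1] - e[length(e)], -2), 2)
  fit <- tryCatch({
    out <- suppressWarnings(minpack.lm::nls.lm(
      par = list(a = a0, b = b0, c = -5),
      lower = c(0, -2, -50), upper = c(2, 2, -1e-8),
      fn = function(p) e - (p$a + p$b * exp(p$c * r)),
      control = minpack.lm::nls.lm.control(maxiter = 200)))
    p <- out$par
    if (!all(is.finite(unlist(p)))) stop("non-finite fit")
    list(a = p$a, b = p$b, c = p$c, fallback = FALSE)
  }, error = function(err) NULL)
  if (is.null(fit)) {
    # linear extrapolation through the two smallest-R points
    slope <- (e[2] - e[1]) / (r[2] - r[1])
    e0 <- e[1] - slope * r[1]
    fit <- list(a = NA_real_, b = NA_real_, c = NA_real_, fallback = TRUE)
    fit$e0 <- e0
  } else {
    fit$e0 <- fit$a + fit$b
  }
  fit
}

#' Convergent cross sorting causality score
#'
#' Scores "x causes y" under the cross-map convention: if x drives y, the
#' geometry of y's reconstruction determines x's, so point pairs that are
#' close in the y-embedding must be close in the x-embedding. Pairwise
#' distance ranks ([rank_transform()]) are computed in both embeddings over
#' sampled point pairs; pairs are ordered by their y-space rank, and at each
#' ranking level R the mean absolute discrepancy between the two ranks
#' (normalized by the random-sorting expectation, 1/3 over the full curve)
#' gives the sorting-error curve. The sorting-skill curve, 1 minus the
#' normalized error, is fitted by `a + b*exp(c*R)`; the score is the fitted
#' skill at R = 0, clipped to be non-negative: ~1 under strong coupling, ~0
#' for independent series. The rank-based pipeline makes the score exactly
#' invariant under positive affine transformations of either input.
#'
#' @param x candidate cause channel (numeric vector).
#' @param y candidate effect channel, same length.
#' @param dim_x,lag_x,dim_y,lag_y embedding parameters per side.
#' @param max_pairs point-pair sample cap (pairs are sampled without
#'   replacement with a seed derived from `seed`).
#' @param n_levels number of ranking levels on (0, 1].
#' @param theiler Theiler window: pairs closer in time are excluded.
#' @param seed integer seed controlling pair sampling.
#' @return a `ccs_result`: list with `score`, `r_values`, `skill`, `error`
#'   (normalized sorting error), `fit` (a, b, c, fallback), `n_pairs`,
#'   embedding parameters.
#' @examples
#' ts <- simulate_logistic_pair(logistic_params(C2 = 0.1, L = 300, seed = 2))
#' ccs_score(ts$values[, "x1"], ts$values[, "x2"])$score
#' @export
ccs_score <- function(x, y, dim_x = 2L, lag_x = 1L, dim_y = 2L, lag_y = 1L,
                      max_pairs = 20000L, n_levels = 20L, theiler = 0L,
                      seed = 1L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  ex <- delay_embed(x, dim_x, lag_x)
  ey <- delay_embed(y, dim_y, lag_y)
  al <- align_embeddings(ex, ey)
  px <- ex$points[al$ix, , drop = FALSE]
  py <- ey$points[al$iy, , drop = FALSE]
  tms <- al$times
  n <- length(tms)
  if (n < 20L) stop("too few aligned points for rank curves")

  pairs <- sample_pairs(n, max_pairs, derive_seed(seed, "ccs_pairs"))
  if (theiler > 0L) {
    keep <- abs(tms[pairs$i] - tms[pairs$j]) > theiler
    pairs$i <- pairs$i[keep]; pairs$j <- pairs$j[keep]
  }
  dx <- row_dist(px, pairs$i, pairs$j)
  dy <- row_dist(py, pairs$i, pairs$j)
  levels <- seq_len(n_levels) / n_levels
  curve <- ccs_rank_curve(dx, dy, levels)
  fit <- fit_rank_curve(curve$r_values, curve$skill)
  structure(list(score = max(0, fit$e0),
                 r_values = curve$r_values, skill = curve$skill,
                 error = curve$error,
                 fit = fit, n_pairs = length(dx),
                 dim_x = dim_x, lag_x = lag_x, dim_y = dim_y, lag_y = lag_y),
            class = "ccs_result")
}

#' @export
print.ccs_result <- function(x, ...) {
  cat(sprintf("<ccs_result> score = %.4f (fit a=%.3f b=%.3f c=%.2f%s)\n",
              x$score, x$fit$a, x$fit$b, x$fit$c,
              if (x$fit$fallback) ", fallback" else ""))
  invisible(x)
}

# Sample up to `max_pairs` unordered point pairs i < j without replacement.
sample_pairs <- function(n, max_pairs, seed) {
  total <- n * (n - 1) / 2
  if (total <= max_pairs) {
    i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    j <- sequence((n - 1L):1L) + i
    return(list(i = i, j = j))
  }
  local_seed(seed, {
    flat <- sample(total, max_pairs) - 1
    # unrank: pair index -> (i, j), row-major over the upper triangle
    i <- floor(n - 0.5 - sqrt((n - 0.5)^2 - 2 * (flat + 1) + 0.25)) + 1
    before <- (i - 1) * n - i * (i - 1) / 2
    j <- flat + 1 - before + i
    list(i = as.integer(i), j = as.integer(j))
  })
}

row_dist <- function(p, i, j) {
  d2 <- rowSums((p[i, , drop = FALSE] - p[j, , drop = FALSE])^2)
  sqrt(d2)
}
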