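# Delay-coordinate reconstruction and neighbour queries.

#' Delay-coordinate embedding of a scalar series
#'
#' The point for time t (0-based) is `(s_t, s_{t-lag}, ...,
#' s_{t-(dim-1)*lag})`: the first coordinate is the most recent sample. The
#' first embedded time is `(dim - 1) * lag`, so the point count is
#' `L - (dim - 1) * lag`.
#'
#' @param series numeric vector (a single channel).
#' @param dim embedding dimension, >= 1.
#' @param lag delay in samples, >= 1.
#' @return a `delay_embedding`: list with `points` (matrix, n_points x dim),
#'   `time_index` (0-based original sample index per row, strictly
#'   increasing), `dim`, `lag`.
#' @examples
#' delay_embed(1:5, dim = 2, lag = 1)$points
#' @export
delay_embed <- function(series, dim, lag = 1L) {
  series <- as.numeric(series)
  stopifnot_scalar(dim, "dim", positive = TRUE, integer = TRUE)
  stopifnot_scalar(lag, "lag", positive = TRUE, integer = TRUE)
  L <- length(series)
  span <- (dim - 1L) * lag
  if (L <= span)
    stop(sprintf("series too short: need L > %d for dim=%d, lag=%d",
                 span, dim, lag))
  n <- L - span
  pts <- matrix(NA_real_, n, dim)
  for (j in seq_len(dim))
    pts[, j] <- series[(span + 1L - (j - 1L) * lag):(L - (j - 1L) * lag)]
  structure(list(points = pts, time_index = span + seq_len(n) - 1L,
                 dim = as.integer(dim), lag = as.integer(lag)),
            class = "delay_embedding")
}

#' @export
print.delay_embedding <- function(x, ...) {
  cat(sprintf("<delay_embedding> %d points, dim = %d, lag = %d\n",
              nrow(x$points), x$dim, x$lag))
  invisible(x)
}

#' Choose an embedding delay from the autocorrelation function
#'
#' Scans lags upward and returns the first lag that is either a local
#' minimum of the autocorrelation function or the first drop below 1/e,
#' whichever occurs at the smaller lag; if neither occurs within `max_lag`,
#' returns 1. For decorrelated series (white noise, chaotic maps) this gives
#' 1; for a pure sinusoid of period P it gives the 1/e crossing of the
#' cosine autocorrelation, `acos(1/e)/(2*pi) * P`, roughly P/4.
#'
#' @param series numeric vector.
#' @param max_lag largest lag considered.
#' @return an integer lag >= 1.
#' @export
select_lag <- function(series, max_lag = 20L) {
  series <- as.numeric(series)
  stopifnot_scalar(max_lag, "max_lag", positive = TRUE, integer = TRUE)
  if (length(series) <= 2L * max_lag)
    stop("series too short: need L > 2 * max_lag")
  a <- drop(acf(series, lag.max = max_lag, plot = FALSE,
                demean = TRUE)$acf)  # a[1] = lag 0
  for (k in seq_len(max_lag)) {
    if (a[k + 1] < exp(-1)) return(k)
    if (k < max_lag && a[k + 1] < a[k] && a[k + 1] < a[k + 2]) return(k)
  }
  1L
}

# k-nearest neighbours by Euclidean distance over embedding points, with a
# Theiler window (neighbours with |t_i - t_j| <= theiler excluded) and ties
# broken by lower time index. Brute force; point clouds here are small.
knn_search <- function(embedding, k, theiler = 0L) {
  pts <- embedding$points
  tms <- embedding$time_index
  n <- nrow(pts)
  if (k >= n) stop("k must be smaller than the number of points")
  dm <- as.matrix(dist(pts))
  idx <- matrix(NA_integer_, n, k)
  dst <- matrix(NA_real_, n, k)
  for (i in seq_len(n)) {
    d <- dm[i, ]
    d[abs(tms - tms[i]) <= theiler] <- Inf
    o <- order(d, tms)[seq_len(k)]
    idx[i, ] <- o
    dst[i, ] <- d[o]
  }
  list(index = idx, dist = dst)
}
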