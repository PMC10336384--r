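# k-nearest-neighbour information-theoretic diagnostics, reported alongside
# causality scores to flag synchronization regimes.

jitter_ties <- function(x, seed) {
  s <- sd(x)
  if (s == 0) s <- 1
  x + local_seed(seed, rnorm(length(x))) * 1e-10 * s
}

#' Mutual information by the Kraskov-Stoegbauer-Grassberger estimator
#'
#' KSG algorithm 1 with max-norm neighbourhoods:
#' `psi(k) + psi(N) - mean(psi(n_x + 1) + psi(n_y + 1))`, in nats. A
#' deterministic jitter at 1e-10 of the channel scale breaks ties. The raw
#' estimate can dip slightly negative for independent data; both the raw and
#' the zero-clamped value are returned.
#'
#' @param x,y numeric channels of equal length (>= 50).
#' @param k neighbour count (default 4).
#' @param seed seed for the tie-breaking jitter.
#' @return list with `mi` (clamped at 0) and `mi_raw`, in nats.
#' @export
ksg_mi <- function(x, y, k = 4L, seed = 1L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 50) stop("need at least 50 samples")
  stopifnot_scalar(k, "k", positive = TRUE, integer = TRUE)
  if (k >= length(x)) stop("k must be smaller than the sample size")
  raw <- ksg_mi_cpp(jitter_ties(x, derive_seed(seed, "mi_x")),
                    jitter_ties(y, derive_seed(seed, "mi_y")), as.integer(k))
  list(mi = max(0, raw), mi_raw = raw)
}

#' Differential entropy by the Kozachenko-Leonenko estimator
#'
#' Nearest-neighbour differential entropy of a scalar series, in nats.
#'
#' @param x numeric channel (>= 50 samples).
#' @param k neighbour count (default 4).
#' @param seed seed for the tie-breaking jitter.
#' @return entropy estimate in nats.
#' @export
kl_entropy <- function(x, k = 4L, seed = 1L) {
  x <- as.numeric(x)
  if (length(x) < 50) stop("need at least 50 samples")
  stopifnot_scalar(k, "k", positive = TRUE, integer = TRUE)
  if (k >= length(x)) stop("k must be smaller than the sample size")
  kl_entropy_cpp(jitter_ties(x, derive_seed(seed, "ent")), as.integer(k))
}

#' Pearson correlation with constant-input guards
#'
#' @param x,y numeric channels of equal length, neither constant.
#' @return the Pearson coefficient in \[-1, 1\].
#' @export
correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant input")
  cor(x, y)
}
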