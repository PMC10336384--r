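# Shared fixtures and independent oracles, built in code at test time.

# Independent white-noise channel pair of length L.
noise_pair <- function(L, seed) {
  statecausal:::local_seed(seed, matrix(rnorm(2 * L), L, 2))
}

# Brute-force AUC oracle: count over all (pos, neg) pairs.
auc_brute <- function(pos, neg) {
  wins <- ties <- 0
  for (p in pos) for (q in neg) {
    if (p > q) wins <- wins + 1
    else if (p == q) ties <- ties + 1
  }
  (wins + 0.5 * ties) / (length(pos) * length(neg))
}

# Independent re-implementation of the coupled logistic recursion (the
# simulator oracle): plain loop, no rejection logic.
logistic_oracle <- function(x0, r1, r2, C1, C2, n) {
  out <- matrix(NA_real_, n, 2)
  x <- x0
  for (t in seq_len(n)) {
    out[t, ] <- x
    x <- c(x[1] * (r1 - r1 * x[1] - C1 * x[2]),
           x[2] * (r2 - r2 * x[2] - C2 * x[1]))
  }
  out
}

# Map-default embedding settings used across directed-scoring tests.
map_embedding <- function() {
  list(dim_x = 2L, lag_x = 1L, dim_y = 2L, lag_y = 1L, theiler = 0L)
}

# A logistic benchmark pair (x1 drives x2 when C2 > 0).
lm_pair <- function(L, seed, C1 = 0, C2 = 0.1) {
  simulate_logistic_pair(logistic_params(C1 = C1, C2 = C2, L = L, seed = seed))
}
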