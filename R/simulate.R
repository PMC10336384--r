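# Benchmark system simulators: coupled logistic maps (pairs and networks),
# the Roessler-Lorenz flow and two coupled Roessler oscillators.

#' Parameters of a bidirectionally coupled logistic-map pair
#'
#' The pair evolves as
#' `x1(t+1) = x1(t) * (r1 - r1*x1(t) - C1*x2(t))` and
#' `x2(t+1) = x2(t) * (r2 - r2*x2(t) - C2*x1(t))`,
#' so `C1` is the coupling of `x2` into `x1` (direction x2 -> x1) and `C2`
#' the coupling of `x1` into `x2`. Defaults `r1 = 3.6`, `r2 = 3.7` place both
#' maps in the chaotic band used throughout the benchmark experiments.
#'
#' @param r1,r2 growth rates (dimensionless).
#' @param C1,C2 coupling strengths, >= 0.
#' @param L retained series length (samples).
#' @param transient burn-in steps discarded before retaining samples.
#' @param seed integer RNG seed for the initial conditions.
#' @return a `logistic_params` list.
#' @export
logistic_params <- function(r1 = 3.6, r2 = 3.7, C1 = 0, C2 = 0,
                            L = 400L, transient = 1000L, seed = 1L) {
  stopifnot_scalar(r1, "r1", positive = TRUE)
  stopifnot_scalar(r2, "r2", positive = TRUE)
  stopifnot_scalar(C1, "C1")
  stopifnot_scalar(C2, "C2")
  if (C1 < 0 || C2 < 0) stop("couplings must be non-negative")
  stopifnot_scalar(L, "L", positive = TRUE, integer = TRUE)
  stopifnot_scalar(transient, "transient", integer = TRUE)
  if (transient < 0) stop("'transient' must be >= 0")
  structure(list(r1 = r1, r2 = r2, C1 = C1, C2 = C2,
                 L = as.integer(L), transient = as.integer(transient),
                 seed = as.integer(seed)),
            class = "logistic_params")
}

logistic_step <- function(x1, x2, r1, r2, C1, C2) {
  c(x1 * (r1 - r1 * x1 - C1 * x2),
    x2 * (r2 - r2 * x2 - C2 * x1))
}

# Iterate the pair from x0; returns L x 2 matrix or NULL if the trajectory
# leaves [0, 1] or loses finiteness.
logistic_run <- function(x0, p) {
  n_total <- p$transient + p$L
  out <- matrix(NA_real_, p$L, 2)
  x <- x0
  for (t in seq_len(n_total)) {
    if (t > p$transient) out[t - p$transient, ] <- x
    x <- logistic_step(x[1], x[2], p$r1, p$r2, p$C1, p$C2)
    if (!all(is.finite(x)) || any(x < 0) || any(x > 1)) return(NULL)
  }
  out
}

#' Simulate a coupled logistic-map pair
#'
#' Initial conditions are drawn uniformly from (0.05, 0.95); trajectories
#' that leave the unit interval are rejected and resampled up to
#' `max_resample` times (the number of resamples taken is recorded in the
#' result metadata).
#'
#' @param params a [logistic_params()] object.
#' @param x0 optional length-2 vector of initial conditions, bypassing the
#'   random draw (used for controlled experiments and tests).
#' @param max_resample resample attempts before failing.
#' @return a `time_series_set` with channels `x1`, `x2`, length `L`.
#' @examples
#' ts <- simulate_logistic_pair(logistic_params(C2 = 0.1, L = 200, seed = 7))
#' ts
#' @export
simulate_logistic_pair <- function(params, x0 = NULL, max_resample = 20L) {
  stopifnot(inherits(params, "logistic_params"))
  local_seed(params$seed, {
    resamples <- 0L
    repeat {
      init <- if (is.null(x0) || resamples > 0L) runif(2, 0.05, 0.95) else x0
      traj <- logistic_run(init, params)
      if (!is.null(traj)) break
      resamples <- resamples + 1L
      if (resamples > max_resample)
        stop(sprintf(paste0("logistic simulation failed (left [0,1]) after %d ",
                            "resamples: r1=%g r2=%g C1=%g C2=%g"),
                     max_resample, params$r1, params$r2, params$C1, params$C2))
    }
    colnames(traj) <- c("x1", "x2")
    time_series_set(traj, dt = 1,
                    meta = list(system = "logistic_pair",
                                params = unclass(params),
                                resamples = resamples))
  })
}

#' Topology of a logistic-map network
#'
#' Chain ("linear array with unidirectional causality"): node i drives node
#' i + 1, n - 1 directed edges. Ring: additionally node n drives node 1, n
#' directed edges, every node has exactly one parent.
#'
#' @param topology `"chain"` or `"ring"`.
#' @param n_nodes number of maps (the benchmark uses 20).
#' @param node_growth_rates per-node growth parameters; defaults to values
#'   uniformly spaced on \[3.6, 3.8\].
#' @param coupling scalar coupling applied along each directed edge.
#' @return a `network_spec` list with an explicit `parent` vector
#'   (`NA` for a node without parent).
#' @export
network_spec <- function(topology = c("chain", "ring"), n_nodes = 20L,
                         node_growth_rates = seq(3.6, 3.8, length.out = n_nodes),
                         coupling = 0.1) {
  topology <- match.arg(topology)
  stopifnot_scalar(n_nodes, "n_nodes", positive = TRUE, integer = TRUE)
  if (n_nodes < 2) stop("'n_nodes' must be >= 2")
  if (length(node_growth_rates) != n_nodes)
    stop("'node_growth_rates' must have one entry per node")
  stopifnot_scalar(coupling, "coupling")
  if (coupling < 0) stop("'coupling' must be >= 0")
  parent <- c(NA_integer_, seq_len(n_nodes - 1L))
  if (topology == "ring") parent[1L] <- n_nodes
  structure(list(topology = topology, n_nodes = as.integer(n_nodes),
                 node_growth_rates = node_growth_rates, coupling = coupling,
                 parent = parent),
            class = "network_spec")
}

#' Adjacency matrix of a network specification
#'
#' Entry (i, j) is 1 when node i drives node j.
#'
#' @param spec a [network_spec()].
#' @return an `n_nodes` x `n_nodes` 0/1 matrix.
#' @export
network_adjacency <- function(spec) {
  A <- matrix(0L, spec$n_nodes, spec$n_nodes)
  for (j in seq_len(spec$n_nodes))
    if (!is.na(spec$parent[j])) A[spec$parent[j], j] <- 1L
  A
}

#' Simulate a chain or ring of coupled logistic maps
#'
#' Each node evolves as `x_j(t+1) = x_j(t) * (r_j - r_j*x_j(t) -
#' C*x_parent(j)(t))`; a node without parent is an uncoupled map.
#'
#' @param spec a [network_spec()].
#' @param L retained length.
#' @param transient discarded burn-in steps.
#' @param seed RNG seed for initial conditions.
#' @param x0 optional initial-condition vector (length `n_nodes`).
#' @param max_resample resample attempts before failing.
#' @return a `time_series_set` with channels `x1..xn`.
#' @export
simulate_logistic_network <- function(spec, L = 400L, transient = 1000L,
                                      seed = 1L, x0 = NULL,
                                      max_resample = 20L) {
  stopifnot(inherits(spec, "network_spec"))
  stopifnot_scalar(L, "L", positive = TRUE, integer = TRUE)
  n <- spec$n_nodes
  r <- spec$node_growth_rates
  C <- spec$coupling
  par <- spec$parent
  has_par <- !is.na(par)
  local_seed(seed, {
    resamples <- 0L
    repeat {
      x <- if (is.null(x0) || resamples > 0L) runif(n, 0.05, 0.95) else x0
      out <- matrix(NA_real_, L, n)
      ok <- TRUE
      for (t in seq_len(transient + L)) {
        if (t > transient) out[t - transient, ] <- x
        forcing <- numeric(n)
        forcing[has_par] <- C * x[par[has_par]]
        x <- x * (r - r * x - forcing)
        if (!all(is.finite(x)) || any(x < 0) || any(x > 1)) { ok <- FALSE; break }
      }
      if (ok) break
      resamples <- resamples + 1L
      if (resamples > max_resample)
        stop(sprintf("network simulation failed after %d resamples (topology=%s, coupling=%g)",
                     max_resample, spec$topology, C))
    }
    colnames(out) <- paste0("x", seq_len(n))
    time_series_set(out, dt = 1,
                    meta = list(system = "logistic_network",
                                topology = spec$topology, coupling = C,
                                node_growth_rates = r, seed = seed,
                                resamples = resamples))
  })
}

check_sampling <- function(dt, sample_every) {
  stopifnot_scalar(dt, "dt", positive = TRUE)
  stopifnot_scalar(sample_every, "sample_every", positive = TRUE)
  if (sample_every < dt) stop("'sample_every' must be >= dt")
  k <- sample_every / dt
  if (abs(k - round(k)) > 1e-8)
    stop("'sample_every' must be an integer multiple of dt")
  as.integer(round(k))
}

#' Parameters of the coupled Roessler-Lorenz system
#'
#' A Roessler oscillator with time-scale factor `a` drives a Lorenz system
#' through the term `C * x2^2` in the second Lorenz equation (coupling
#' direction x2 -> y2). The Lorenz constants 10, 28 and 8/3 and the Roessler
#' shape constants 0.2 and 5.7 are fixed.
#'
#' @param a Roessler time-scale factor (6 or 10 in the benchmarks).
#' @param C coupling strength x2 -> y2.
#' @param dt integrator step (time units).
#' @param sample_every sampling stride (time units, integer multiple of dt).
#' @param transient_time discarded burn-in (time units).
#' @param L number of retained samples.
#' @param seed RNG seed for initial conditions.
#' @return a `rossler_lorenz_params` list.
#' @export
rossler_lorenz_params <- function(a = 6, C = 0, dt = 0.005, sample_every = 0.3,
                                  transient_time = 500, L = 400L, seed = 1L) {
  stopifnot_scalar(a, "a", positive = TRUE)
  stopifnot_scalar(C, "C")
  keep_every <- check_sampling(dt, sample_every)
  stopifnot_scalar(transient_time, "transient_time")
  if (transient_time < 0) stop("'transient_time' must be >= 0")
  stopifnot_scalar(L, "L", positive = TRUE, integer = TRUE)
  structure(list(a = a, C = C, dt = dt, sample_every = sample_every,
                 keep_every = keep_every, transient_time = transient_time,
                 L = as.integer(L), seed = as.integer(seed)),
            class = "rossler_lorenz_params")
}

#' Simulate the coupled Roessler-Lorenz system
#'
#' Fixed-step RK4 integration; the transient is discarded before sampling at
#' the configured stride. Initial conditions are drawn uniformly from boxes
#' around the two attractors.
#'
#' @param params a [rossler_lorenz_params()] object.
#' @param state0 optional length-6 initial state `(x1,x2,x3,y1,y2,y3)`.
#' @return a `time_series_set` with channels `x1..x3`, `y1..y3`.
#' @export
simulate_rossler_lorenz <- function(params, state0 = NULL) {
  stopifnot(inherits(params, "rossler_lorenz_params"))
  local_seed(params$seed, {
    if (is.null(state0))
      state0 <- c(runif(2, -4, 4), runif(1, 0, 2),
                  runif(2, -10, 10), runif(1, 5, 30))
    n_burn <- as.integer(round(params$transient_time / params$dt))
    vals <- rk4_rossler_lorenz_cpp(state0, params$a, params$C, params$dt,
                                   n_burn, params$L, params$keep_every)
    colnames(vals) <- c("x1", "x2", "x3", "y1", "y2", "y3")
    time_series_set(vals, dt = params$sample_every,
                    meta = list(system = "rossler_lorenz",
                                params = unclass(params), state0 = state0))
  })
}

#' Parameters of two diffusively coupled Roessler oscillators
#'
#' The driver (angular frequency `omega1`) couples into the first equation of
#' the response (angular frequency `omega2`) through `C * (x1 - y1)`; the
#' frequency ratio `omega1 / omega2` is derived by [frequency_ratio()],
#' never stored. Shape
#' parameters default to the canonical Roessler values a = 0.15, b = 0.2,
#' c = 10.
#'
#' @param omega1,omega2 angular frequencies of driver and response.
#' @param a1,a2,b1,b2,c Roessler shape parameters.
#' @param C diffusive coupling strength x1 -> y1.
#' @param dt,sample_every,transient_time,L,seed as in
#'   [rossler_lorenz_params()].
#' @param rr_y3_sign `"standard"` uses the usual third response equation
#'   `y3' = y3*(y1 - c) + b2`; `"flipped"` uses `y3*(y1 + c) + b2` (a
#'   non-Roessler variant kept available behind this flag; it diverges for
#'   typical parameters and exists for completeness only).
#' @return a `rossler_rossler_params` list.
#' @export
rossler_rossler_params <- function(omega1 = 1, omega2 = 1,
                                   a1 = 0.15, a2 = 0.15, b1 = 0.2, b2 = 0.2,
                                   c = 10, C = 0.1,
                                   dt = 0.005, sample_every = 0.3,
                                   transient_time = 500, L = 400L, seed = 1L,
                                   rr_y3_sign = c("standard", "flipped")) {
  stopifnot_scalar(omega1, "omega1", positive = TRUE)
  stopifnot_scalar(omega2, "omega2", positive = TRUE)
  for (nm in c("a1", "a2", "b1", "b2", "c", "C"))
    stopifnot_scalar(get(nm), nm)
  keep_every <- check_sampling(dt, sample_every)
  stopifnot_scalar(L, "L", positive = TRUE, integer = TRUE)
  structure(list(omega1 = omega1, omega2 = omega2,
                 a1 = a1, a2 = a2, b1 = b1, b2 = b2, c = c, C = C,
                 dt = dt, sample_every = sample_every,
                 keep_every = keep_every, transient_time = transient_time,
                 L = as.integer(L), seed = as.integer(seed),
                 rr_y3_sign = match.arg(rr_y3_sign)),
            class = "rossler_rossler_params")
}

#' Frequency ratio of a Roessler-Roessler parameter set
#' @param params a [rossler_rossler_params()] object.
#' @return `omega1 / omega2`.
#' @export
frequency_ratio <- function(params) params$omega1 / params$omega2

#' Simulate two coupled Roessler oscillators
#'
#' @param params a [rossler_rossler_params()] object.
#' @param state0 optional length-6 initial state.
#' @return a `time_series_set` with channels `x1..x3`, `y1..y3`.
#' @export
simulate_rossler_rossler <- function(params, state0 = NULL) {
  stopifnot(inherits(params, "rossler_rossler_params"))
  local_seed(params$seed, {
    if (is.null(state0))
      state0 <- c(runif(2, -4, 4), runif(1, 0, 2),
                  runif(2, -4, 4), runif(1, 0, 2))
    n_burn <- as.integer(round(params$transient_time / params$dt))
    vals <- rk4_rossler_rossler_cpp(state0, params$omega1, params$omega2,
                                    params$a1, params$a2, params$b1, params$b2,
                                    params$c, params$C, params$dt,
                                    n_burn, params$L, params$keep_every,
                                    as.integer(params$rr_y3_sign == "standard"))
    colnames(vals) <- c("x1", "x2", "x3", "y1", "y2", "y3")
    time_series_set(vals, dt = params$sample_every,
                    meta = list(system = "rossler_rossler",
                                params = unclass(params), state0 = state0))
  })
}
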