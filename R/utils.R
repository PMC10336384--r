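# Seed plumbing shared by simulators, scorers and experiment designs.

#' Derive a reproducible child seed from a master seed and labels
#'
#' Experiment designs give every realization its own seed so that any single
#' cell of a sweep or grid can be re-run in isolation. The derivation is a
#' plain polynomial hash over the master seed and the labels, reduced modulo
#' 2^31 - 2 so the result is always a valid positive integer seed.
#'
#' @param master integer master seed.
#' @param ... further labels (character or numeric scalars) identifying the
#'   design, level and repetition.
#' @return a positive integer seed.
#' @examples
#' derive_seed(1, "length", 3, 17)
#' @export
derive_seed <- function(master, ...) {
  key <- paste(c(format(master), vapply(list(...), format, "")), collapse = "|")
  bytes <- utf8ToInt(key)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483646
  as.integer(h + 1)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopifnot_scalar <- function(x, name, positive = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("'%s' must be a whole number", name), call. = FALSE)
  invisible(x)
}
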