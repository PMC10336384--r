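#' Multichannel time-series container
#'
#' Holds one or more aligned real-valued series (time in rows, channels in
#' columns) together with the sampling interval and a provenance record
#' sufficient to regenerate simulated series exactly (system, parameters,
#' seed).
#'
#' @param values numeric matrix, time x channels, no missing values.
#' @param channel_names character vector of channel labels; defaults to the
#'   column names of `values`.
#' @param dt sampling interval (1 for maps).
#' @param meta named list of provenance fields.
#' @return an object of class `time_series_set`.
#' @examples
#' ts <- time_series_set(cbind(a = sin(1:50), b = cos(1:50)), dt = 0.1)
#' ts
#' @export
time_series_set <- function(values, channel_names = colnames(values),
                            dt = 1, meta = list()) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be numeric")
  if (anyNA(values) || any(!is.finite(values)))
    stop("'values' must not contain missing or non-finite entries")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(ncol(values)))
  if (length(channel_names) != ncol(values))
    stop("'channel_names' must match the number of columns")
  stopifnot_scalar(dt, "dt", positive = TRUE)
  colnames(values) <- channel_names
  structure(list(values = values, dt = dt, meta = meta),
            class = "time_series_set")
}

#' @export
print.time_series_set <- function(x, ...) {
  cat(sprintf("<time_series_set> %d samples x %d channels (dt = %g)\n",
              nrow(x$values), ncol(x$values), x$dt))
  cat("  channels:", paste(colnames(x$values), collapse = ", "), "\n")
  if (!is.null(x$meta$system))
    cat("  system:", x$meta$system, "\n")
  invisible(x)
}

#' @export
as.data.frame.time_series_set <- function(x, ...) {
  as.data.frame(x$values)
}

#' Number of samples in a time-series set
#' @param x a `time_series_set`.
#' @return integer sample count.
#' @export
n_samples <- function(x) nrow(x$values)

# Extract one channel as a plain numeric vector.
channel <- function(x, name) {
  if (inherits(x, "time_series_set")) {
    if (!name %in% colnames(x$values))
      stop(sprintf("channel '%s' not found", name))
    x$values[, name]
  } else as.numeric(x)
}

#' Standardize every channel to zero mean and unit standard deviation
#'
#' Uses the sample standard deviation (divisor n - 1). Standardization makes
#' the continuity-scaling strength invariant under positive affine maps of
#' either input, and is recommended before any causality scoring so results
#' do not depend on measurement units.
#'
#' @param x a `time_series_set`, numeric matrix, or numeric vector.
#' @return object of the same shape with each channel standardized.
#' @examples
#' standardize(c(1, 2, 3))
#' @export
standardize <- function(x) {
  if (inherits(x, "time_series_set")) {
    x$values <- standardize(x$values)
    return(x)
  }
  if (is.matrix(x)) {
    for (j in seq_len(ncol(x))) x[, j] <- standardize_vec(x[, j], colnames(x)[j])
    return(x)
  }
  standardize_vec(as.numeric(x), NULL)
}

standardize_vec <- function(v, name) {
  s <- sd(v)
  if (!is.finite(s) || s == 0)
    stop(sprintf("channel %s is constant; standard deviation is zero",
                 if (is.null(name) || is.na(name)) "" else sQuote(name)))
  (v - mean(v)) / s
}

#' Add Gaussian white measurement noise at a given signal-to-noise ratio
#'
#' Per channel, adds zero-mean Gaussian noise with standard deviation
#' `sd(signal) * 10^(-snr_db / 20)`, independent across time and channels.
#' The input series is not modified.
#'
#' @param series a `time_series_set` or numeric vector/matrix.
#' @param snr_db signal-to-noise ratio in decibels; 0 dB means noise variance
#'   equal to signal variance.
#' @param seed integer RNG seed for the noise draw.
#' @return noisy copy of `series`.
#' @export
add_noise <- function(series, snr_db, seed = 1L) {
  stopifnot_scalar(snr_db, "snr_db")
  vals <- if (inherits(series, "time_series_set")) series$values else as.matrix(series)
  sds <- apply(vals, 2, sd)
  if (any(sds == 0))
    stop("cannot add noise at a fixed SNR to a constant channel")
  factor <- 10^(-snr_db / 20)
  noise <- local_seed(seed, matrix(rnorm(length(vals)), nrow(vals), ncol(vals)))
  noisy <- vals + sweep(noise, 2, sds * factor, `*`)
  if (inherits(series, "time_series_set")) {
    out <- series
    out$values <- noisy
    out$meta$snr_db <- snr_db
    out$meta$noise_seed <- seed
    out
  } else if (is.matrix(series)) noisy else drop(noisy)
}

#' Write a time-series set as delimited text with a JSON metadata sidecar
#'
#' The CSV has a header row of channel names and one row per time step
#' (UTF-8, '.' decimal separator). `<path>.json` records `dt` and the
#' provenance metadata.
#'
#' @param x a `time_series_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_time_series <- function(x, path) {
  stopifnot(inherits(x, "time_series_set"))
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(dt = x$dt, meta = x$meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a time-series set written by [write_time_series()]
#'
#' Plain CSV files without a sidecar are accepted (dt defaults to 1, empty
#' metadata), so arbitrary two-column user series can be loaded.
#'
#' @param path CSV path.
#' @return a `time_series_set`.
#' @export
read_time_series <- function(path) {
  df <- read.csv(path)
  bad <- !vapply(df, is.numeric, TRUE)
  if (any(bad))
    stop(sprintf("non-numeric column(s): %s", paste(names(df)[bad], collapse = ", ")))
  if (anyNA(df)) {
    idx <- which(is.na(as.matrix(df)), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at row %d, column '%s'",
                 idx[1], names(df)[idx[2]]))
  }
  dt <- 1
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    info <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(info$dt)) dt <- info$dt
    if (!is.null(info$meta)) meta <- info$meta
  }
  time_series_set(as.matrix(df), dt = dt, meta = meta)
}
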