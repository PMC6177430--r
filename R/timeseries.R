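#' Uniformly sampled time series
#'
#' The basic carrier for stimuli, receptor currents and synthetic recordings:
#' a numeric sample vector with a sample rate, a unit label, a start time and
#' free-form provenance metadata (generator name, parameters, RNG seed).
#'
#' @param samples numeric vector, at least 2 samples.
#' @param sample_rate sampling rate in Hz, positive.
#' @param units non-empty unit label, e.g. `"nm"`, `"nA"`, `"uV"`, `"um/s"`.
#' @param t0 start time in seconds.
#' @param meta named list of provenance entries.
#' @return An object of class `time_series`.
#' @examples
#' x <- time_series(sin(2 * pi * 5 * seq(0, 1, by = 1e-3)), 1000, "nm")
#' duration(x)
#' @export
time_series <- function(samples, sample_rate, units, t0 = 0, meta = list()) {
  if (!is.numeric(samples) || length(samples) < 2L) {
    stop("time_series(): 'samples' must be numeric with at least 2 values")
  }
  if (any(!is.finite(samples))) stop("time_series(): samples must be finite")
  stop_if_not_scalar(sample_rate, "sample_rate", positive = TRUE)
  if (!is.character(units) || length(units) != 1L || !nzchar(units)) {
    stop("time_series(): 'units' must be a non-empty string")
  }
  stop_if_not_scalar(t0, "t0")
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate,
         units = units, t0 = t0, meta = meta),
    class = "time_series"
  )
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %d samples @ %g Hz [%s], duration %.6g s\n",
              length(x$samples), x$sample_rate, x$units, duration(x)))
  invisible(x)
}

#' @export
length.time_series <- function(x) length(x$samples)

#' @rdname time_series
#' @param x a `time_series`.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "time_series"))
  length(x$samples) / x$sample_rate
}

#' Time axis of a time series
#' @param x a `time_series`.
#' @return numeric vector of sample times in seconds, starting at `t0`.
#' @export
time_axis <- function(x) {
  stopifnot(inherits(x, "time_series"))
  x$t0 + (seq_along(x$samples) - 1) / x$sample_rate
}

#' @export
as.data.frame.time_series <- function(x, ...) {
  data.frame(time_s = time_axis(x), value = x$samples)
}

#' Write / read a time series as CSV with a JSON sidecar
#'
#' The CSV holds `time_s,value`; the sidecar (same path with `.json` appended)
#' records sample rate, units, start time and metadata so the object
#' round-trips exactly.
#'
#' @param x a `time_series`.
#' @param path CSV file path.
#' @return `write_time_series_csv()` returns `path` invisibly;
#'   `read_time_series_csv()` returns a `time_series`.
#' @export
write_time_series_csv <- function(x, path) {
  stopifnot(inherits(x, "time_series"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  side <- list(sample_rate = x$sample_rate, units = x$units, t0 = x$t0,
               meta = x$meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_time_series_csv
#' @export
read_time_series_csv <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  time_series(df$value, side$sample_rate, side$units, t0 = side$t0,
              meta = as.list(side$meta))
}
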