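#' Single-sided amplitude spectrum
#'
#' Rectangular-window DFT of a time series, in the peak-amplitude convention:
#' a pure sinusoid of amplitude `A` lying on an exact bin yields a bin value
#' of `A`. The DC bin is reported separately in `$dc`. The complex DFT is kept
#' internally so that spectra can be filtered/corrected and inverse-transformed
#' without loss.
#'
#' @param x a `time_series` of length at least 16.
#' @return An object of class `amp_spectrum` with fields `freqs` (Hz, from
#'   `df` up to Nyquist), `amps` (single-sided amplitudes, input units),
#'   `df` (bin width in Hz), `dc`, `units`, and `source_meta`.
#' @examples
#' x <- time_series(2 * sin(2 * pi * 100 * seq(0, 1, by = 1e-3)[-1001]), 1000, "nm")
#' s <- amplitude_spectrum(x)
#' component_amplitude(s, 100)  # 2
#' @export
amplitude_spectrum <- function(x) {
  stopifnot(inherits(x, "time_series"))
  n <- length(x$samples)
  if (n < 16) stop("amplitude_spectrum(): need at least 16 samples")
  X <- stats::fft(x$samples)
  df <- x$sample_rate / n
  nhalf <- floor(n / 2)
  k <- seq_len(nhalf)           # bins 1 .. n/2 (exclude DC)
  amps <- 2 * Mod(X[k + 1]) / n
  if (n %% 2 == 0) amps[nhalf] <- Mod(X[nhalf + 1]) / n  # Nyquist not doubled
  structure(
    list(freqs = k * df, amps = amps, df = df, dc = Re(X[1]) / n,
         units = x$units, n = n, sample_rate = x$sample_rate,
         fft = X, source_meta = x$meta),
    class = "amp_spectrum"
  )
}

#' @export
print.amp_spectrum <- function(x, ...) {
  cat(sprintf("<amp_spectrum> %d bins, df=%g Hz, Nyquist=%g Hz [%s]\n",
              length(x$freqs), x$df, max(x$freqs), x$units))
  invisible(x)
}

#' Amplitude of a single spectral component
#'
#' Looks up the component at `f`, which must align with a Fourier bin: the
#' package's analysis convention is exact-bin (records span an integer number
#' of periods of every component of interest, rectangular window), so a
#' frequency falling between bins indicates a mis-set record length and is an
#' error rather than a value to interpolate.
#'
#' @param s an `amp_spectrum`.
#' @param f frequency in Hz; must lie within `tol` of a bin centre.
#' @param tol alignment tolerance as a fraction of the bin width `df`
#'   (default `1e-6`).
#' @param floor_rel amplitudes below `floor_rel * max(amps)` are reported at
#'   that floor rather than as arbitrarily small values, keeping later dB
#'   arithmetic finite. Set to 0 to disable.
#' @return amplitude at the bin, in the spectrum's units.
#' @export
component_amplitude <- function(s, f, floor_rel = 0, tol = 1e-6) {
  stopifnot(inherits(s, "amp_spectrum"))
  stop_if_not_scalar(f, "f", positive = TRUE)
  k <- round(f / s$df)
  if (k < 1 || k > length(s$freqs)) {
    stop("component_amplitude(): frequency outside the spectrum")
  }
  if (abs(f - k * s$df) > s$df * tol) {
    stop("bin misalignment: ", f, " Hz does not fall on a Fourier bin (df = ",
         s$df, " Hz)")
  }
  a <- s$amps[k]
  if (floor_rel > 0) a <- max(a, floor_rel * max(s$amps))
  a
}

#' Distortion-product frequencies of a three-tone complex
#'
#' Given the lowest primary `f1` and the spacing `f_e`, computes the primaries
#' \eqn{f_2 = f_1 + f_e}, \eqn{f_3 = f_1 + 2 f_e}, the low-frequency envelope
#' products `f_e`, `2 f_e`, `3 f_e`, and the named high-frequency
#' intermodulation products `2f1-f2`, `3f1-2f2` and `2f3-f2`.
#'
#' @param f1 lowest primary frequency (Hz).
#' @param f_e component spacing (Hz).
#' @return A list with `primaries` (named: f1, f2, f3), `envelope` (named:
#'   fe, 2fe, 3fe) and `hf_products` (named: `2f1-f2`, `3f1-2f2`, `2f3-f2`).
#' @examples
#' distortion_frequencies(17000, 500)$hf_products[["2f3-f2"]]  # 18500
#' @export
distortion_frequencies <- function(f1, f_e) {
  stop_if_not_scalar(f1, "f1", positive = TRUE)
  stop_if_not_scalar(f_e, "f_e", positive = TRUE)
  f2 <- f1 + f_e
  f3 <- f1 + 2 * f_e
  list(
    primaries = c(f1 = f1, f2 = f2, f3 = f3),
    envelope = c("fe" = f_e, "2fe" = 2 * f_e, "3fe" = 3 * f_e),
    hf_products = c("2f1-f2" = 2 * f1 - f2,
                    "3f1-2f2" = 3 * f1 - 2 * f2,
                    "2f3-f2" = 2 * f3 - f2)
  )
}

#' Tip-to-tail ratio of a phase sweep
#'
#' Phase sweeps of envelope-locked components are V-shaped: maximal response
#' ("tip") at centre-tone phases 0/180 deg (peaked envelope) and minimal
#' ("tail") at 90 deg (flat envelope). The tip level is the mean of the levels
#' at 0 and 180 deg (the 0-deg level if 180 is absent), the tail level is the
#' 90-deg level, and the ratio is their dB difference.
#'
#' @param sweep a [phase_sweep_result()].
#' @param component component label present in `sweep$levels`.
#' @return tip-to-tail ratio in dB.
#' @export
tip_to_tail <- function(sweep, component = "fe") {
  stopifnot(inherits(sweep, "phase_sweep_result"))
  lv <- sweep$levels[[component]]
  if (is.null(lv)) stop("tip_to_tail(): no such component: ", component)
  ph <- sweep$phases
  need <- function(p) {
    i <- which(abs(ph - p) < 1e-9)
    if (!length(i)) NA_real_ else lv[i[1]]
  }
  at0 <- need(0); at90 <- need(90); at180 <- need(180)
  if (is.na(at0) || is.na(at90)) {
    stop("tip_to_tail(): sweep must include phases 0 and 90 deg")
  }
  tip <- if (is.na(at180)) at0 else mean(c(at0, at180))
  db_ratio(tip, at90)
}

#' First-order electrode filter: response, forward application, correction
#'
#' A glass microelectrode behaves as a first-order low-pass filter
#' \eqn{H(f) = 1 / (1 + i f / f_c)}. `apply_electrode_filter()` applies it to
#' a time series in the frequency domain; `correct_electrode_filter()` undoes
#' it by dividing each complex bin by `H(f)`, with the boost magnitude capped
#' at its value at `10 * cutoff` (about 20 dB) so that high-frequency noise is
#' not amplified without bound. Both operate on a `time_series` or an
#' `amp_spectrum`; the time-series methods go through the (inverse) FFT.
#'
#' @param x a `time_series` or `amp_spectrum`.
#' @param cutoff filter cutoff frequency in Hz, positive.
#' @param boost_cap_mult cap the correction boost at its value at
#'   `boost_cap_mult * cutoff` (default 10; `Inf` disables the cap).
#' @return an object of the same class as `x`.
#' @name electrode_filter
NULL

electrode_gain <- function(f, cutoff) 1 / (1 + 1i * f / cutoff)

# signed bin frequencies of an n-point DFT at sample rate fs
dft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k * fs / n
}

#' @rdname electrode_filter
#' @export
apply_electrode_filter <- function(x, cutoff) {
  stopifnot(inherits(x, "time_series"))
  stop_if_not_scalar(cutoff, "cutoff", positive = TRUE, finite = FALSE)
  if (!is.finite(cutoff)) return(x)
  n <- length(x$samples)
  f <- dft_freqs(n, x$sample_rate)
  y <- Re(stats::fft(stats::fft(x$samples) * electrode_gain(f, cutoff),
                     inverse = TRUE)) / n
  x$samples <- y
  x$meta$electrode_cutoff <- cutoff
  x
}

correction_gain <- function(f, cutoff, boost_cap_mult = 10) {
  g <- 1 + 1i * f / cutoff       # 1 / H(f)
  if (is.finite(boost_cap_mult)) {
    gmax <- sqrt(1 + boost_cap_mult^2)
    over <- Mod(g) > gmax
    g[over] <- g[over] * (gmax / Mod(g[over]))
  }
  g
}

#' @rdname electrode_filter
#' @export
correct_electrode_filter <- function(x, cutoff, boost_cap_mult = 10) {
  stop_if_not_scalar(cutoff, "cutoff", positive = TRUE, finite = FALSE)
  if (inherits(x, "time_series")) {
    if (!is.finite(cutoff)) return(x)
    n <- length(x$samples)
    f <- dft_freqs(n, x$sample_rate)
    y <- Re(stats::fft(stats::fft(x$samples) *
                         correction_gain(f, cutoff, boost_cap_mult),
                       inverse = TRUE)) / n
    x$samples <- y
    x$meta$electrode_corrected <- cutoff
    return(x)
  }
  stopifnot(inherits(x, "amp_spectrum"))
  if (!is.finite(cutoff)) return(x)
  n <- x$n
  f <- dft_freqs(n, x$sample_rate)
  X <- x$fft * correction_gain(f, cutoff, boost_cap_mult)
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  out <- amplitude_spectrum(time_series(y, x$sample_rate, x$units,
                                        meta = x$source_meta))
  out$source_meta$electrode_corrected <- cutoff
  out
}

#' Inverse transform of a spectrum back to a time trace
#'
#' Companion to the frequency-domain electrode correction: rebuilds the time
#' series from the complex DFT carried by the spectrum.
#'
#' @param s an `amp_spectrum`.
#' @return a `time_series`.
#' @export
spectrum_to_time_series <- function(s) {
  stopifnot(inherits(s, "amp_spectrum"))
  y <- Re(stats::fft(s$fft, inverse = TRUE)) / s$n
  time_series(y, s$sample_rate, s$units, meta = s$source_meta)
}

#' Estimate the local noise floor around a target frequency
#'
#' Median amplitude of the bins within `half_width` bins of `f`, excluding the
#' signal bins listed in `exclude` (each masked with a one-bin guard band).
#'
#' @param s an `amp_spectrum`.
#' @param f target frequency (Hz).
#' @param exclude frequencies of deterministic components to mask out (Hz).
#' @param half_width half-width of the estimation window in bins.
#' @return estimated floor amplitude in the spectrum's units.
#' @export
noise_floor_estimate <- function(s, f, exclude = numeric(), half_width = 20) {
  stopifnot(inherits(s, "amp_spectrum"))
  k <- round(f / s$df)
  idx <- max(1, k - half_width):min(length(s$amps), k + half_width)
  bad <- unique(c(k, unlist(lapply(round(exclude / s$df), function(j) (j - 1):(j + 1)))))
  idx <- setdiff(idx, bad)
  if (!length(idx)) stop("noise_floor_estimate(): no bins left to estimate from")
  stats::median(s$amps[idx])
}

#' Write a spectrum to CSV
#'
#' Columns `freq_hz`, `amplitude`, `units`.
#'
#' @param s an `amp_spectrum`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "amp_spectrum"))
  utils::write.csv(
    data.frame(freq_hz = s$freqs, amplitude = s$amps, units = s$units),
    path, row.names = FALSE)
  invisible(path)
}
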