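#' Three-tone stimulus parameters
#'
#' Defines a complex of three equal-amplitude tones with constant frequency
#' separation `f_e`:
#' \deqn{x(t) = A \sin(2\pi f_1 t) + A \sin(2\pi f_2 t + \varphi)
#'            + A \sin(2\pi f_3 t)}
#' with \eqn{f_2 = f_1 + f_e} and \eqn{f_3 = f_1 + 2 f_e}. The centre-tone
#' phase \eqn{\varphi} controls the peakiness of the envelope without changing
#' the magnitude spectrum: at 0 deg the envelope has large peaks recurring at
#' `f_e`, at 90 deg it is flat at `f_e` and dominated by `2 f_e`. The derived
#' frequencies `f2` and `f3` are always recomputed from `f1` and `f_e`, never
#' stored.
#'
#' @param A per-component amplitude (nm for bundle displacement, Pa or
#'   normalized for acoustics); non-negative.
#' @param f1 lowest component frequency in Hz, positive.
#' @param f_e component spacing in Hz, equal to the envelope repetition rate;
#'   positive.
#' @param phi centre-tone phase in degrees (applies to the middle tone only).
#' @param duration signal length in seconds.
#' @param ramp rise/fall time in seconds; `2 * ramp <= duration`.
#' @param ramp_shape `"cos2"` for a cosine-squared gate or `"none"`.
#' @param exact_bins if `TRUE` (default), require `duration` to be an integer
#'   multiple of `1 / f_e` so that all components and their integer-combination
#'   distortion products fall on exact Fourier bins of a rectangular window.
#' @return An object of class `three_tone_params`.
#' @seealso [synthesize_three_tone()], [distortion_frequencies()]
#' @examples
#' three_tone_params(f1 = 16000, f_e = 500)  # components at 16, 16.5, 17 kHz
#' @export
three_tone_params <- function(A = 1, f1 = 16000, f_e = 500, phi = 0,
                              duration = 0.1, ramp = 0,
                              ramp_shape = c("cos2", "none"),
                              exact_bins = TRUE) {
  ramp_shape <- match.arg(ramp_shape)
  for (nm in c("A", "f1", "f_e", "phi", "duration", "ramp")) {
    stop_if_not_scalar(get(nm), nm)
  }
  if (A < 0) stop("three_tone_params(): 'A' must be >= 0")
  if (f1 <= 0 || f_e <= 0) stop("three_tone_params(): 'f1' and 'f_e' must be > 0")
  if (duration <= 0) stop("three_tone_params(): 'duration' must be > 0")
  if (ramp < 0 || 2 * ramp > duration) {
    stop("three_tone_params(): need 0 <= 2 * ramp <= duration")
  }
  if (exact_bins) {
    cycles <- duration * f_e
    if (abs(cycles - round(cycles)) > 1e-9 * max(1, cycles)) {
      stop("three_tone_params(): with exact_bins, 'duration' must be an ",
           "integer multiple of 1/f_e")
    }
  }
  structure(
    list(A = A, f1 = f1, f_e = f_e, phi = phi, duration = duration,
         ramp = ramp, ramp_shape = ramp_shape, exact_bins = exact_bins),
    class = "three_tone_params"
  )
}

#' @export
print.three_tone_params <- function(x, ...) {
  cat(sprintf(
    "<three_tone_params> A=%g, f=%g/%g/%g Hz, phi=%g deg, dur=%g s, ramp=%g s\n",
    x$A, x$f1, x$f1 + x$f_e, x$f1 + 2 * x$f_e, x$phi, x$duration, x$ramp))
  invisible(x)
}

#' Preset stimulus protocols
#'
#' `stimulus_preset("in_vivo")` gives the animal protocol (100 ms stimulus,
#' 5 ms cos-squared ramps, 500 Hz spacing); `"human"` gives the human protocol
#' (30 ms, 1 ms ramps).
#'
#' @param name `"in_vivo"` or `"human"`.
#' @param ... overrides passed to [three_tone_params()].
#' @return A `three_tone_params` object.
#' @export
stimulus_preset <- function(name = c("in_vivo", "human"), ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    in_vivo = list(A = 1, f1 = 16000, f_e = 500, phi = 0,
                   duration = 0.1, ramp = 0.005),
    human = list(A = 1, f1 = 3750, f_e = 312.5, phi = 0,
                 duration = 0.03, ramp = 0.001, exact_bins = FALSE)
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(three_tone_params, args)
}

#' Default sample rate for a three-tone stimulus
#'
#' Sixteen times the highest component frequency (at least 64 kHz), giving
#' clean headroom for third-order distortion products well below Nyquist.
#'
#' @param params a `three_tone_params`.
#' @return sample rate in Hz.
#' @export
default_sample_rate <- function(params) {
  stopifnot(inherits(params, "three_tone_params"))
  max(16 * (params$f1 + 2 * params$f_e), 64000)
}

#' Synthesize a three-tone complex
#'
#' Generates the three-tone waveform on a uniform grid, then applies the
#' configured onset/offset ramp. The phase convention applies `phi` to the
#' centre tone only, converted from degrees to radians internally.
#'
#' @param params a [three_tone_params()] object.
#' @param sample_rate sampling rate in Hz. Must exceed
#'   `16 * (f1 + 2 f_e)` (headroom for distortion analysis); defaults to
#'   [default_sample_rate()].
#' @param units unit label for the output (default `"nm"`, stereocilia
#'   displacement).
#' @param two_speaker if `TRUE`, return a list of two `time_series` (flanking
#'   tones on one channel, centre tone on the other) that sum to the standard
#'   stimulus, emulating a two-speaker presentation.
#' @return A `time_series` (or a list of two when `two_speaker = TRUE`).
#' @examples
#' p <- three_tone_params(f1 = 16000, f_e = 500, phi = 0, duration = 0.1)
#' x <- synthesize_three_tone(p)
#' @export
synthesize_three_tone <- function(params, sample_rate = default_sample_rate(params),
                                  units = "nm", two_speaker = FALSE) {
  stopifnot(inherits(params, "three_tone_params"))
  stop_if_not_scalar(sample_rate, "sample_rate", positive = TRUE)
  f3 <- params$f1 + 2 * params$f_e
  if (sample_rate < 16 * f3) {
    stop("sampling rate too low: need sample_rate >= 16 * (f1 + 2*f_e) = ",
         16 * f3, " Hz")
  }
  n <- round(params$duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  phi <- deg2rad(params$phi)
  A <- params$A
  flank <- A * sin(2 * pi * params$f1 * t) + A * sin(2 * pi * f3 * t)
  centre <- A * sin(2 * pi * (params$f1 + params$f_e) * t + phi)
  meta <- list(generator = "synthesize_three_tone", params = unclass(params))
  if (two_speaker) {
    out <- list(
      flanking = apply_ramp(time_series(flank, sample_rate, units, meta = meta),
                            params$ramp, params$ramp_shape),
      centre = apply_ramp(time_series(centre, sample_rate, units, meta = meta),
                          params$ramp, params$ramp_shape)
    )
    return(out)
  }
  apply_ramp(time_series(flank + centre, sample_rate, units, meta = meta),
             params$ramp, params$ramp_shape)
}

#' Apply a cosine-squared onset/offset gate
#'
#' Multiplies the waveform by a gate that rises as \eqn{\cos^2} from 0 to 1
#' over `[0, ramp]`, stays at unity, and falls as the mirror image over the
#' final `ramp` seconds. The sample count is unchanged.
#'
#' @param x a `time_series`.
#' @param ramp rise/fall time in seconds; `2 * ramp <= duration(x)`.
#' @param shape `"cos2"` or `"none"` (identity).
#' @return A gated `time_series`.
#' @export
apply_ramp <- function(x, ramp, shape = c("cos2", "none")) {
  stopifnot(inherits(x, "time_series"))
  shape <- match.arg(shape)
  stop_if_not_scalar(ramp, "ramp")
  if (ramp < 0) stop("apply_ramp(): 'ramp' must be >= 0")
  if (shape == "none" || ramp == 0) return(x)
  if (2 * ramp > duration(x)) {
    stop("ramp too long: 2 * ramp exceeds the signal duration")
  }
  n <- length(x$samples)
  t <- (seq_len(n) - 1) / x$sample_rate
  gate <- rep(1, n)
  dur <- n / x$sample_rate
  rise <- t < ramp
  gate[rise] <- sin(pi * t[rise] / (2 * ramp))^2
  fall <- t > dur - ramp
  gate[fall] <- sin(pi * (dur - t[fall]) / (2 * ramp))^2
  x$samples <- x$samples * gate
  x
}

#' Check that a stimulus carries no energy at the envelope frequency
#'
#' The three-tone complex changes its envelope with centre-tone phase while
#' containing no spectral component at `f_e` itself; this check verifies that
#' property on a synthesized (or recorded) waveform. The level at `f_e` is
#' measured relative to the level at `f1` on the analysed window, which must
#' span an integer number of `f_e` periods (analyse the unramped plateau).
#'
#' @param x a `time_series`.
#' @param f_e envelope frequency in Hz.
#' @param f1 lowest primary frequency in Hz (reference level). If missing and
#'   `x` carries generator metadata, it is taken from there.
#' @param tol_db pass threshold: the check passes when the `f_e` level is below
#'   `tol_db` dB re the `f1` level.
#' @return A list with `pass` (logical) and `level_db` (the `f_e` level re
#'   `f1`, `-Inf` for an all-zero input).
#' @export
assert_no_envelope_component <- function(x, f_e, f1 = NULL, tol_db = -100) {
  stopifnot(inherits(x, "time_series"))
  stop_if_not_scalar(f_e, "f_e", positive = TRUE)
  if (is.null(f1)) {
    f1 <- x$meta$params$f1
    if (is.null(f1)) stop("assert_no_envelope_component(): supply 'f1'")
  }
  if (all(x$samples == 0)) {
    return(list(pass = TRUE, level_db = -Inf))
  }
  s <- amplitude_spectrum(x)
  a_fe <- component_amplitude(s, f_e)
  a_f1 <- component_amplitude(s, f1)
  if (a_f1 == 0) stop("assert_no_envelope_component(): no energy at f1")
  level <- db_ratio(max(a_fe, .Machine$double.xmin), a_f1)
  list(pass = level < tol_db, level_db = level)
}
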