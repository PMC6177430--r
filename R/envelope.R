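#' Envelope of a signal via the analytic signal
#'
#' Computes the magnitude of the analytic signal (the Hilbert envelope) by the
#' standard FFT method: the DFT of the input is doubled on positive
#' frequencies, zeroed on negative frequencies (DC and Nyquist kept once), and
#' inverse-transformed. For the three-tone complex with centre-tone phase
#' \eqn{\varphi} the envelope is, in closed form,
#' \eqn{A\sqrt{3 + 4\cos\varphi \cos(2\pi f_e t) + 2\cos(4\pi f_e t)}}: large
#' peaks recurring at `f_e` when \eqn{\varphi = 0}, a flatter outline
#' dominated by `2 f_e` when \eqn{\varphi = 90^\circ}.
#'
#' @param x a real-valued `time_series` of length at least 16.
#' @return A `time_series` of the same length, sample rate and units holding
#'   the envelope.
#' @export
hilbert_envelope <- function(x) {
  stopifnot(inherits(x, "time_series"))
  n <- length(x$samples)
  if (n < 16) stop("hilbert_envelope(): need at least 16 samples")
  X <- stats::fft(x$samples)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n
  out <- x
  out$samples <- Mod(z)
  out$meta$generator <- "hilbert_envelope"
  out
}

#' Envelope component amplitudes at f_e and 2 f_e
#'
#' Extracts the modulation amplitudes of the envelope at the envelope
#' frequency and its second harmonic. The envelope mean (DC) is removed first,
#' so the amplitudes measure pure envelope *variation*. To avoid
#' analytic-signal edge artifacts the first and last 5% of samples are
#' discarded, and the remaining window is truncated to a whole number of
#' `f_e` periods so both components are exact-bin under a rectangular window.
#'
#' @param x a `time_series` (the raw waveform; its envelope is computed
#'   internally). The sample rate must be an integer multiple of `f_e`.
#' @param f_e envelope frequency in Hz.
#' @param edge_frac fraction of samples discarded at each end (default 0.05).
#' @return A list of class `envelope_components` with `amp_fe`, `amp_2fe`,
#'   `dc` (envelope mean over the analysed window), and `normalization`
#'   (always `"none"` here; see [envelope_phase_sweep()]).
#' @export
envelope_component_amplitudes <- function(x, f_e, edge_frac = 0.05) {
  stopifnot(inherits(x, "time_series"))
  stop_if_not_scalar(f_e, "f_e", positive = TRUE)
  spp <- x$sample_rate / f_e
  if (abs(spp - round(spp)) > 1e-9) {
    stop("bin misalignment: sample_rate must be an integer multiple of f_e")
  }
  spp <- round(spp)
  env <- hilbert_envelope(x)$samples
  n <- length(env)
  k <- floor(edge_frac * n)
  env <- env[(k + 1):(n - k)]
  m <- floor(length(env) / spp) * spp
  if (m < spp) stop("envelope_component_amplitudes(): fewer than one f_e period")
  env <- env[seq_len(m)]
  dc <- mean(env)
  E <- stats::fft(env - dc)
  k_fe <- round(f_e * m / x$sample_rate)
  amp <- function(k) 2 * Mod(E[k + 1]) / m
  structure(
    list(amp_fe = amp(k_fe), amp_2fe = amp(2 * k_fe), dc = dc,
         normalization = "none"),
    class = "envelope_components"
  )
}

#' Quadratic-nonlinearity prediction for envelope components
#'
#' A memoryless nonlinearity applied to the three-tone complex produces, in
#' its quadratic Taylor term, low-frequency components with relative
#' coefficients \eqn{2|\cos\varphi|} at `f_e` and 1 at `2 f_e`. The `f_e`
#' component therefore vanishes at a centre-tone phase of 90 deg while the
#' `2 f_e` component is phase-independent.
#'
#' @param phi centre-tone phase in degrees (vectorized).
#' @return A data frame with columns `phi`, `c_fe` (`2 |cos phi|`) and
#'   `c_2fe` (1).
#' @examples
#' quadratic_prediction(c(0, 60, 90))  # c_fe = 2, 1, 0
#' @export
quadratic_prediction <- function(phi) {
  stopifnot(is.numeric(phi))
  data.frame(phi = phi, c_fe = 2 * abs(cos(deg2rad(phi))), c_2fe = 1)
}

#' Envelope component amplitudes across a centre-tone phase sweep
#'
#' Synthesizes the unramped three-tone complex at each phase, extracts the
#' envelope amplitudes at `f_e` and `2 f_e`, and optionally normalizes each
#' component trace by its own maximum over the sweep (the convention used for
#' relative-amplitude plots, giving a 0-1 range per component).
#'
#' @param params a [three_tone_params()]; its `phi` field is ignored.
#' @param phis phase grid in degrees.
#' @param sample_rate sampling rate in Hz.
#' @param normalization `"max-over-sweep"` or `"none"`.
#' @return A data frame with columns `phi_deg`, `amp_fe`, `amp_2fe`, `dc`,
#'   `normalization`.
#' @export
envelope_phase_sweep <- function(params, phis = seq(0, 180, by = 15),
                                 sample_rate = default_sample_rate(params),
                                 normalization = c("max-over-sweep", "none")) {
  stopifnot(inherits(params, "three_tone_params"))
  normalization <- match.arg(normalization)
  rows <- lapply(phis, function(p) {
    pp <- params
    pp$phi <- p
    pp$ramp <- 0
    x <- synthesize_three_tone(pp, sample_rate)
    ec <- envelope_component_amplitudes(x, params$f_e)
    data.frame(phi_deg = p, amp_fe = ec$amp_fe, amp_2fe = ec$amp_2fe,
               dc = ec$dc)
  })
  out <- do.call(rbind, rows)
  if (normalization == "max-over-sweep") {
    out$amp_fe <- out$amp_fe / max(out$amp_fe)
    out$amp_2fe <- out$amp_2fe / max(out$amp_2fe)
  }
  out$normalization <- normalization
  out
}

#' Write a phase sweep table to CSV
#'
#' @param sweep a data frame from [envelope_phase_sweep()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phase_sweep_csv <- function(sweep, path) {
  utils::write.csv(sweep, path, row.names = FALSE)
  invisible(path)
}
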