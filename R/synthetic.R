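#' Parametric recording-noise model
#'
#' Interferometric and electrical recordings have a broadband noise floor
#' that rises at low frequencies (breathing, body noise, 1/f electronics).
#' The model is white Gaussian noise shaped in the frequency domain: flat at
#' `floor` (amplitude density, units/sqrt(Hz)) above `lf_corner`, rising at
#' `lf_slope` dB per octave below it.
#'
#' @param floor broadband amplitude density in units/sqrt(Hz); non-negative.
#' @param lf_corner corner frequency in Hz below which noise rises; positive.
#' @param lf_slope low-frequency rise in dB/octave; non-negative.
#' @param seed RNG seed recorded in the output metadata; `NULL` draws from
#'   the current RNG stream.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(floor = 0.01, lf_corner = 1000, lf_slope = 6,
                        seed = NULL) {
  stop_if_not_scalar(floor, "floor")
  if (floor < 0) stop("noise_model(): 'floor' must be >= 0")
  stop_if_not_scalar(lf_corner, "lf_corner", positive = TRUE)
  stop_if_not_scalar(lf_slope, "lf_slope")
  if (lf_slope < 0) stop("noise_model(): 'lf_slope' must be >= 0")
  structure(list(floor = floor, lf_corner = lf_corner, lf_slope = lf_slope,
                 seed = seed),
            class = "noise_model")
}

# One realisation of shaped noise, as a bare sample vector.
shaped_noise <- function(n, sample_rate, noise, seed = noise$seed) {
  stopifnot(inherits(noise, "noise_model"))
  if (noise$floor == 0) return(numeric(n))
  w <- with_seed(seed, stats::rnorm(n, sd = noise$floor * sqrt(sample_rate / 2)))
  if (noise$lf_slope == 0) return(w)
  f <- abs(dft_freqs(n, sample_rate))
  f[1] <- sample_rate / n                      # shape DC like the first bin
  gain <- rep(1, n)
  low <- f < noise$lf_corner
  gain[low] <- (noise$lf_corner / f[low])^(noise$lf_slope / (20 * log10(2)))
  Re(stats::fft(stats::fft(w) * gain, inverse = TRUE)) / n
}

#' Synthetic basilar-membrane-like recording
#'
#' Emulates a vibrometry trace at the basilar membrane: strong responses at
#' the three primaries, optional high-frequency intermodulation distortion
#' products at stated levels, and shaped measurement noise — but, by
#' construction, exactly zero deterministic energy at `f_e` and `2 f_e`
#' (the defining negative result for this site).
#'
#' @param stim_params a [three_tone_params()]; the primaries are rendered at
#'   amplitude `A` each.
#' @param dp_levels_db named numeric vector of high-frequency distortion
#'   levels in dB re the `f1` component; names must come from the
#'   `hf_products` labels of [distortion_frequencies()]. Envelope-frequency
#'   components cannot be requested.
#' @param noise a [noise_model()].
#' @param sample_rate sampling rate in Hz.
#' @param units `"um/s"` (velocity, laser vibrometry) or `"nm"`
#'   (displacement, interferometry).
#' @param seed RNG seed for the noise (defaults to the model's).
#' @return A `time_series`; its `meta` records generator, parameters and seed.
#' @export
generate_bm_recording <- function(stim_params, dp_levels_db = numeric(),
                                  noise = noise_model(),
                                  sample_rate = default_sample_rate(stim_params),
                                  units = c("um/s", "nm"), seed = noise$seed) {
  stopifnot(inherits(stim_params, "three_tone_params"))
  units <- match.arg(units)
  dfreq <- distortion_frequencies(stim_params$f1, stim_params$f_e)
  if (length(dp_levels_db)) {
    bad <- setdiff(names(dp_levels_db), names(dfreq$hf_products))
    if (length(bad)) {
      stop("generate_bm_recording(): only high-frequency distortion products ",
           "may be requested; offending: ", paste(bad, collapse = ", "))
    }
  }
  sp <- stim_params
  sp$ramp <- 0
  x <- synthesize_three_tone(sp, sample_rate, units = units)
  t <- time_axis(x)
  for (lab in names(dp_levels_db)) {
    amp <- stim_params$A * 10^(dp_levels_db[[lab]] / 20)
    x$samples <- x$samples +
      amp * sin(2 * pi * dfreq$hf_products[[lab]] * t)
  }
  x$samples <- x$samples + shaped_noise(length(x$samples), sample_rate, noise,
                                        seed)
  x$meta <- list(generator = "generate_bm_recording",
                 params = unclass(stim_params),
                 dp_levels_db = as.list(dp_levels_db),
                 noise = unclass(noise), seed = seed)
  x
}

#' Synthetic organ-of-Corti-like electrical recording
#'
#' Emulates a microelectrode recording near the outer hair cells: the
#' displacement stimulus drives the memoryless Boltzmann MET nonlinearity,
#' the resulting current is low-pass filtered by the first-order electrode
#' model, and shaped noise is added. The trace is reported in nA with an
#' arbitrary electrode calibration.
#'
#' @param stim_params a [three_tone_params()] (displacement in nm).
#' @param met a [boltzmann_params()].
#' @param electrode_cutoff electrode filter cutoff in Hz; typical
#'   microelectrodes fall in 1-5 kHz, values in \[500, 20000\] (or `Inf` for
#'   no filtering) are accepted.
#' @param noise a [noise_model()].
#' @param sample_rate sampling rate in Hz.
#' @param seed RNG seed for the noise.
#' @return A `time_series` of filtered current; `meta` records all
#'   parameters and the seed.
#' @export
generate_ooc_recording <- function(stim_params, met = boltzmann_params(),
                                   electrode_cutoff = 3000,
                                   noise = noise_model(),
                                   sample_rate = default_sample_rate(stim_params),
                                   seed = noise$seed) {
  stopifnot(inherits(stim_params, "three_tone_params"),
            inherits(met, "boltzmann_params"))
  if (is.finite(electrode_cutoff) &&
      (electrode_cutoff < 500 || electrode_cutoff > 20000)) {
    stop("generate_ooc_recording(): electrode_cutoff must lie in [500, 20000] Hz (or Inf)")
  }
  sp <- stim_params
  sp$ramp <- 0
  stim <- synthesize_three_tone(sp, sample_rate, units = "nm")
  cur <- simulate_receptor_current(stim, met)
  cur <- apply_electrode_filter(cur, electrode_cutoff)
  cur$samples <- cur$samples + shaped_noise(length(cur$samples), sample_rate,
                                            noise, seed)
  cur$meta <- list(generator = "generate_ooc_recording",
                   params = unclass(stim_params), boltzmann = unclass(met),
                   electrode_cutoff = electrode_cutoff,
                   noise = unclass(noise), seed = seed)
  cur
}

#' Population configuration for round-window-like recordings
#'
#' @param n_cells number of hair cells contributing to the far-field sum.
#' @param x0_mean,x0_sd mean and s.d. of the per-cell operating point (nm).
#' @param gain_sd s.d. of the per-cell log-normal gain jitter (log scale).
#' @param neural_gain amplitude of the stereotyped envelope-locked neural
#'   waveform, relative to the `f_e` component of the hair-cell sum (the
#'   quantity a sodium-channel block removes from the envelope-tracking
#'   response).
#' @param ttx if `TRUE`, the neural component is zeroed (sodium-channel block
#'   emulation); the hair-cell contribution is untouched.
#' @param seed RNG seed for the per-cell draws.
#' @return An object of class `population_config`.
#' @export
population_config <- function(n_cells = 50, x0_mean = 5.5, x0_sd = 1,
                              gain_sd = 0.2, neural_gain = 0.05,
                              ttx = FALSE, seed = NULL) {
  if (!is.numeric(n_cells) || n_cells < 1) {
    stop("population_config(): 'n_cells' must be >= 1")
  }
  if (x0_sd < 0 || gain_sd < 0 || neural_gain < 0) {
    stop("population_config(): 'x0_sd', 'gain_sd', 'neural_gain' must be >= 0")
  }
  structure(list(n_cells = as.integer(n_cells), x0_mean = x0_mean,
                 x0_sd = x0_sd, gain_sd = gain_sd, neural_gain = neural_gain,
                 ttx = isTRUE(ttx), seed = seed),
            class = "population_config")
}

# Single-frequency discrete projection amplitude (internal).
projection_amp <- function(x, sample_rate, f) {
  n <- length(x)
  t <- (seq_len(n) - 1) / sample_rate
  2 * Mod(sum(x * exp(-2i * pi * f * t))) / n
}

# Stereotyped envelope-locked neural surrogate: half-wave-rectified,
# low-pass-filtered copy of the stimulus envelope. Exists solely so that the
# TTX flag has a component to remove; it is not a physiological model.
neural_waveform <- function(stim, cutoff = 1000) {
  env <- hilbert_envelope(stim)
  hw <- pmax(env$samples - mean(env$samples), 0)
  y <- apply_electrode_filter(time_series(hw, stim$sample_rate, stim$units),
                              cutoff)
  y$samples
}

#' Synthetic round-window-like recording
#'
#' Emulates a far-field electrode on the round window membrane: the sum of
#' MET currents from a population of hair cells with jittered operating
#' points and gains, plus a small stereotyped envelope-locked neural
#' component (removable via the `ttx` flag), plus shaped noise.
#'
#' @param stim_params a [three_tone_params()].
#' @param pop a [population_config()].
#' @param met_base a [boltzmann_params()]; per-cell `X0` values are drawn as
#'   `Normal(x0_mean, x0_sd)` around the population configuration.
#' @param noise a [noise_model()].
#' @param sample_rate sampling rate in Hz.
#' @param seed master seed; per-cell draws and noise use child seeds derived
#'   from it, so `ttx` toggling changes nothing except the neural term.
#' @return A `time_series` (population current sum, nA); `meta` records all
#'   parameters and seeds.
#' @export
generate_rw_recording <- function(stim_params, pop = population_config(),
                                  met_base = boltzmann_params(),
                                  noise = noise_model(),
                                  sample_rate = default_sample_rate(stim_params),
                                  seed = pop$seed) {
  stopifnot(inherits(stim_params, "three_tone_params"),
            inherits(pop, "population_config"),
            inherits(met_base, "boltzmann_params"))
  sp <- stim_params
  sp$ramp <- 0
  stim <- synthesize_three_tone(sp, sample_rate, units = "nm")
  draws <- with_seed(derive_seed(seed, "cells"), list(
    x0 = stats::rnorm(pop$n_cells, pop$x0_mean, pop$x0_sd),
    gain = stats::rlnorm(pop$n_cells, 0, pop$gain_sd)
  ))
  acc <- numeric(length(stim$samples))
  for (i in seq_len(pop$n_cells)) {
    p <- met_base
    p$X0 <- draws$x0[i]
    acc <- acc + draws$gain[i] * boltzmann_current(stim$samples, p)
  }
  if (!pop$ttx && pop$neural_gain > 0) {
    nw <- neural_waveform(stim)
    # neural_gain is defined relative to the envelope-locked (f_e) component
    # of the hair-cell sum: that is the quantity a sodium-channel block would
    # remove from the envelope-tracking response
    fe_hc <- projection_amp(acc, sample_rate, stim_params$f_e)
    fe_nw <- projection_amp(nw, sample_rate, stim_params$f_e)
    scale <- pop$neural_gain * fe_hc / max(fe_nw, .Machine$double.eps)
    acc <- acc + scale * nw
  }
  acc <- acc + shaped_noise(length(acc), sample_rate, noise,
                            derive_seed(seed, "noise"))
  time_series(acc, sample_rate, "nA",
              meta = list(generator = "generate_rw_recording",
                          params = unclass(stim_params),
                          population = unclass(pop),
                          boltzmann = unclass(met_base),
                          noise = unclass(noise), seed = seed))
}

#' A set of repeated stimulus presentations
#'
#' Bundles repeated sweeps (identical stimulus, independent noise) with
#' ground-truth artifact flags for testing the rejection logic.
#'
#' @param sweeps list of `time_series`, all sharing length and sample rate.
#' @param artifact_flags logical vector marking contaminated sweeps (ground
#'   truth; the averaging routine never reads it).
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(sweeps, artifact_flags = rep(FALSE, length(sweeps))) {
  stopifnot(is.list(sweeps), length(sweeps) >= 1,
            all(vapply(sweeps, inherits, TRUE, "time_series")))
  ns <- vapply(sweeps, function(s) length(s$samples), 1L)
  fss <- vapply(sweeps, function(s) s$sample_rate, 1)
  if (length(unique(ns)) != 1 || length(unique(fss)) != 1) {
    stop("sweep_set(): all sweeps must share length and sample rate")
  }
  stopifnot(is.logical(artifact_flags), length(artifact_flags) == length(sweeps))
  structure(list(sweeps = sweeps, artifact_flags = artifact_flags),
            class = "sweep_set")
}

#' Generate repeated noisy presentations of a signal
#'
#' Each sweep is `signal + noise`; optionally, some sweeps are contaminated
#' with a large slow drift (breathing-artifact emulation) and flagged in the
#' ground truth.
#'
#' @param signal a `time_series` (the deterministic response).
#' @param n_sweeps number of presentations (the in vivo protocol used 60 or
#'   120 depending on stimulus level).
#' @param noise a [noise_model()].
#' @param n_artifact number of sweeps to contaminate.
#' @param artifact_amp peak amplitude of the drift, in signal units.
#' @param artifact_freq drift frequency in Hz (breathing-rate scale).
#' @param seed master seed; sweep `i` uses a child seed derived from it.
#' @return A [sweep_set()].
#' @export
generate_sweep_set <- function(signal, n_sweeps = 60, noise = noise_model(),
                               n_artifact = 0, artifact_amp = 0,
                               artifact_freq = 2, seed = NULL) {
  stopifnot(inherits(signal, "time_series"), n_sweeps >= 1)
  flags <- rep(FALSE, n_sweeps)
  if (n_artifact > 0) {
    idx <- with_seed(derive_seed(seed, "which_artifact"),
                     sample.int(n_sweeps, n_artifact))
    flags[idx] <- TRUE
  }
  t <- time_axis(signal)
  sweeps <- lapply(seq_len(n_sweeps), function(i) {
    s <- signal
    s$samples <- s$samples +
      shaped_noise(length(t), signal$sample_rate, noise,
                   derive_seed(seed, paste0("sweep", i)))
    if (flags[i]) {
      ph <- with_seed(derive_seed(seed, paste0("artifact", i)),
                      stats::runif(1, 0, 2 * pi))
      s$samples <- s$samples + artifact_amp * sin(2 * pi * artifact_freq * t + ph)
    }
    s$meta$sweep_index <- i
    s
  })
  sweep_set(sweeps, flags)
}

#' Average repeated sweeps with low-frequency artifact rejection
#'
#' Emulates the acquisition-side rejection of records contaminated by
#' breathing movements: a sweep is rejected when its r.m.s. amplitude in the
#' low-frequency artifact band exceeds `reject_k` times the median across
#' sweeps; the survivors are averaged in the time domain.
#'
#' @param sweeps a [sweep_set()].
#' @param reject_k rejection factor (default 3).
#' @param band artifact frequency band in Hz (default 0-50 Hz, breathing
#'   scale; DC excluded).
#' @return A list with `average` (a `time_series`), `n_used`, `n_rejected`,
#'   and `rejected` (indices).
#' @export
average_with_artifact_rejection <- function(sweeps, reject_k = 3,
                                            band = c(0, 50)) {
  stopifnot(inherits(sweeps, "sweep_set"))
  if (length(sweeps$sweeps) < 2) {
    stop("average_with_artifact_rejection(): need at least 2 sweeps")
  }
  n <- length(sweeps$sweeps[[1]]$samples)
  fs <- sweeps$sweeps[[1]]$sample_rate
  df <- fs / n
  k_lo <- max(1L, ceiling(band[1] / df))
  k_hi <- floor(band[2] / df)
  if (k_hi < k_lo) stop("average_with_artifact_rejection(): artifact band is empty")
  band_rms <- vapply(sweeps$sweeps, function(s) {
    X <- stats::fft(s$samples)
    sqrt(sum(Mod(X[(k_lo:k_hi) + 1])^2) * 2) / n
  }, 1)
  med <- stats::median(band_rms)
  rej <- which(band_rms > reject_k * med)
  keep <- setdiff(seq_along(sweeps$sweeps), rej)
  if (!length(keep)) stop("average_with_artifact_rejection(): all sweeps rejected")
  acc <- Reduce(`+`, lapply(sweeps$sweeps[keep], function(s) s$samples))
  out <- sweeps$sweeps[[keep[1]]]
  out$samples <- acc / length(keep)
  out$meta$generator <- "average_with_artifact_rejection"
  out$meta$n_used <- length(keep)
  list(average = out, n_used = length(keep), n_rejected = length(rej),
       rejected = rej)
}
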