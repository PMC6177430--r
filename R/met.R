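#' Boltzmann activation parameters for MET channels
#'
#' Mechanoelectrical transduction (MET) channels in hair-cell stereocilia have
#' a sigmoidal (first-order Boltzmann) activation curve
#' \deqn{I(X) = \frac{I_{max}}{1 + e^{-Z (X - X_0) / (k_B T)}}}
#' where \eqn{X} is bundle displacement, \eqn{Z} the single-channel gating
#' force, \eqn{k_B} Boltzmann's constant, \eqn{T} absolute temperature and
#' \eqn{X_0} the horizontal offset that sets the resting open probability.
#' The model is memoryless: channels are treated as infinitely fast, so a
#' displacement waveform maps sample-by-sample to a current waveform.
#'
#' @param I_max saturating current in nA, positive.
#' @param X0 activation-curve offset in nm (any sign; the sign flips the
#'   resting asymmetry).
#' @param Z single-channel gating force in pN, positive.
#' @param temperature absolute temperature in K, positive.
#' @param k_b Boltzmann constant in J/K (fixed physical constant).
#' @return An object of class `boltzmann_params`.
#' @examples
#' p <- boltzmann_params(I_max = 2.5, X0 = 5.5, Z = 1.05)
#' resting_open_probability(p)  # about 0.21
#' @export
boltzmann_params <- function(I_max = 2.5, X0 = 5.5, Z = 1.05,
                             temperature = 310.15, k_b = 1.381e-23) {
  stop_if_not_scalar(I_max, "I_max", positive = TRUE)
  stop_if_not_scalar(X0, "X0")
  stop_if_not_scalar(Z, "Z", positive = TRUE)
  stop_if_not_scalar(temperature, "temperature", positive = TRUE)
  stop_if_not_scalar(k_b, "k_b", positive = TRUE)
  structure(
    list(I_max = I_max, X0 = X0, Z = Z, temperature = temperature, k_b = k_b),
    class = "boltzmann_params"
  )
}

#' @export
print.boltzmann_params <- function(x, ...) {
  cat(sprintf(
    "<boltzmann_params> I_max=%g nA, X0=%g nm, Z=%g pN, T=%g K (P_open(0)=%.3f)\n",
    x$I_max, x$X0, x$Z, x$temperature, resting_open_probability(x)))
  invisible(x)
}

#' MET receptor current for a given displacement
#'
#' Evaluates the Boltzmann activation curve. Unit bookkeeping: `Z` (pN) times
#' displacement (nm) gives energy in units of 1e-21 J, divided by
#' \eqn{k_B T} in J.
#'
#' @param X displacement in nm (vectorized); must be finite.
#' @param p a [boltzmann_params()].
#' @return current in nA, strictly inside `(0, I_max)` (overflow saturates to
#'   the limits).
#' @export
boltzmann_current <- function(X, p) {
  stopifnot(inherits(p, "boltzmann_params"), is.numeric(X))
  if (any(!is.finite(X))) stop("boltzmann_current(): displacement must be finite")
  u <- p$Z * (X - p$X0) * 1e-21 / (p$k_b * p$temperature)
  p$I_max / (1 + exp(-u))      # exp overflow yields 0 or I_max, as intended
}

#' Resting open probability of the MET channels
#'
#' The open probability at zero displacement,
#' \eqn{P_{open}(0) = 1 / (1 + e^{Z X_0 / (k_B T)})}. `X0 = 0` gives exactly
#' 0.5; the offset used throughout the receptor-current simulations,
#' `X0 = 5.5` nm with `Z = 1.05` pN at 310.15 K, gives about 0.2.
#'
#' @param p a [boltzmann_params()].
#' @return probability in (0, 1).
#' @export
resting_open_probability <- function(p) {
  stopifnot(inherits(p, "boltzmann_params"))
  boltzmann_current(0, p) / p$I_max
}

#' Simulate the receptor current for a displacement waveform
#'
#' Applies the Boltzmann nonlinearity sample-wise — no filtering, no state.
#' The asymmetric rectification this produces is what writes the stimulus
#' envelope into the current spectrum: for a peaked envelope (centre-tone
#' phase 0) a large component appears at `f_e`, absent from the stimulus
#' itself, which collapses towards the numerical floor as the phase moves
#' to 90 deg.
#'
#' @param stim a `time_series` of bundle displacement; units must be `"nm"`.
#' @param p a [boltzmann_params()].
#' @return A `time_series` of current in nA.
#' @export
simulate_receptor_current <- function(stim, p) {
  stopifnot(inherits(stim, "time_series"))
  if (!identical(stim$units, "nm")) {
    stop("unit mismatch: receptor-current simulation needs displacement in nm, got '",
         stim$units, "'")
  }
  out <- stim
  out$samples <- boltzmann_current(stim$samples, p)
  out$units <- "nA"
  out$meta$generator <- "simulate_receptor_current"
  out$meta$boltzmann <- unclass(p)
  out
}

# f_e / 2f_e amplitudes of the receptor current for one stimulus realisation
current_envelope_components <- function(stim, p) {
  cur <- simulate_receptor_current(stim, p)
  s <- amplitude_spectrum(cur)
  f_e <- stim$meta$params$f_e
  c(fe = component_amplitude(s, f_e), fe2 = component_amplitude(s, 2 * f_e))
}

#' Sweep the operating point X0 of the MET model
#'
#' Simulates the receptor current for each `X0` on a grid (all other
#' parameters fixed) and extracts the current amplitude at `f_e` and `2 f_e`.
#' At `X0 = 0` the activation curve is symmetric about rest and no envelope
#' component is generated; as `|X0|` grows the rectification asymmetry first
#' strengthens the `f_e` component and then, once the stimulus rides the flat
#' tail of the sigmoid, weakens it again.
#'
#' @param stim_params a [three_tone_params()] for the displacement stimulus
#'   (unramped plateau is analysed; the `ramp` field is ignored).
#' @param p_base a [boltzmann_params()]; its `X0` is replaced by each grid
#'   value.
#' @param grid strictly increasing X0 values in nm (default 0 to 20 nm in
#'   0.05-nm steps).
#' @param sample_rate sampling rate in Hz.
#' @return An object of class `x0_sweep` with `grid`, `amp_fe`, `amp_2fe`
#'   (nA) and `argmax_fe` (the grid point with the largest `f_e` amplitude;
#'   ties broken towards the smaller X0).
#' @export
sweep_operating_point <- function(stim_params, p_base = boltzmann_params(),
                                  grid = seq(0, 20, by = 0.05),
                                  sample_rate = default_sample_rate(stim_params)) {
  stopifnot(inherits(stim_params, "three_tone_params"),
            inherits(p_base, "boltzmann_params"))
  if (length(grid) < 1 || is.unsorted(grid, strictly = TRUE)) {
    stop("sweep_operating_point(): 'grid' must be non-empty and strictly increasing")
  }
  sp <- stim_params
  sp$ramp <- 0
  stim <- synthesize_three_tone(sp, sample_rate)
  n <- length(stim$samples)
  k_fe <- round(sp$f_e * n / sample_rate)
  amp_fe <- numeric(length(grid))
  amp_2fe <- numeric(length(grid))
  for (i in seq_along(grid)) {
    p <- p_base
    p$X0 <- grid[i]
    X <- stats::fft(boltzmann_current(stim$samples, p))
    amp_fe[i] <- 2 * Mod(X[k_fe + 1]) / n
    amp_2fe[i] <- 2 * Mod(X[2 * k_fe + 1]) / n
  }
  structure(
    list(grid = grid, amp_fe = amp_fe, amp_2fe = amp_2fe,
         argmax_fe = grid[which.max(amp_fe)]),
    class = "x0_sweep"
  )
}

#' @export
print.x0_sweep <- function(x, ...) {
  cat(sprintf("<x0_sweep> %d points on [%g, %g] nm; f_e max %.4g nA at X0 = %g nm\n",
              length(x$grid), min(x$grid), max(x$grid), max(x$amp_fe),
              x$argmax_fe))
  invisible(x)
}
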