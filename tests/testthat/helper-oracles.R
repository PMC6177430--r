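# Shared fixtures and independent oracles.

# Standard model-experiment stimulus: primaries 14.5/15/15.5 kHz, 1 nm each,
# 100-ms unramped record.
model_stim_params <- function(phi = 0, A = 1) {
  three_tone_params(A = A, f1 = 14500, f_e = 500, phi = phi,
                    duration = 0.1, ramp = 0)
}

model_met_params <- function(X0 = 5.5) {
  boltzmann_params(I_max = 2.5, X0 = X0, Z = 1.05, temperature = 310.15)
}

# Independent single-frequency discrete projection (Goertzel-style oracle):
# amplitude of the component at frequency f in samples x, without an FFT.
projection_amplitude <- function(x, sample_rate, f) {
  n <- length(x)
  t <- (seq_len(n) - 1) / sample_rate
  c_ <- sum(x * cos(2 * pi * f * t))
  s_ <- sum(x * sin(2 * pi * f * t))
  2 * sqrt(c_^2 + s_^2) / n
}

# Closed-form envelope of the three-tone complex (modulus of the analytic
# signal, derived by summing the three phasors):
#   |z(t)| = A * sqrt(3 + 4 cos(phi) cos(2 pi fe t) + 2 cos(4 pi fe t))
closed_form_envelope <- function(A, f_e, phi_deg, t) {
  phi <- phi_deg * pi / 180
  u <- 2 * pi * f_e * t
  A * sqrt(pmax(3 + 4 * cos(phi) * cos(u) + 2 * cos(2 * u), 0))
}

# dB of an amplitude ratio, for readable expectations
to_db <- function(r) 20 * log10(r)
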