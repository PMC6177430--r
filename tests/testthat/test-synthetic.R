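silent_noise <- function() noise_model(floor = 0, seed = 1)

test_that("BM generator renders primaries and requested distortion, never envelope energy", {
  p <- three_tone_params(A = 1, f1 = 17000, f_e = 500, duration = 0.02)
  # noise floor 0, no distortion: exactly the three primaries
  x <- generate_bm_recording(p, noise = silent_noise())
  s <- amplitude_spectrum(x)
  big <- which(s$amps > 1e-9)
  expect_equal(s$freqs[big], c(17000, 17500, 18000))
  # deterministic part has exactly zero energy at f_e and 2f_e
  expect_lt(component_amplitude(s, 500), 1e-12)
  expect_lt(component_amplitude(s, 1000), 1e-12)
  # requested 2f3-f2 at -13 dB re f1 is recovered at -13 +/- 0.1 dB
  y <- generate_bm_recording(p, dp_levels_db = c("2f3-f2" = -13),
                             noise = silent_noise())
  sy <- amplitude_spectrum(y)
  lvl <- db_ratio(component_amplitude(sy, 18500),
                  component_amplitude(sy, 17000))
  expect_equal(lvl, -13, tolerance = 0.1)
  # envelope-frequency components cannot be requested
  expect_error(generate_bm_recording(p, dp_levels_db = c("fe" = -20)),
               "high-frequency")
})

test_that("BM noise floor rises at low frequencies and buries f_e in noise", {
  p <- three_tone_params(A = 1, f1 = 17000, f_e = 500, duration = 0.02)
  nm <- noise_model(floor = 1e-3, lf_corner = 2000, lf_slope = 6, seed = 11)
  x <- generate_bm_recording(p, noise = nm)
  s <- amplitude_spectrum(x)
  # f_e sits at (not above) the local noise floor
  floor_est <- noise_floor_estimate(s, 500, exclude = c(500, 1000))
  expect_lt(component_amplitude(s, 500), 6 * floor_est)
  # low-frequency bins are noisier than mid-band bins on average
  lo <- s$amps[s$freqs >= 100 & s$freqs <= 500]
  mid <- s$amps[s$freqs >= 4000 & s$freqs <= 8000]
  expect_gt(mean(lo), 1.5 * mean(mid))
  # identical seed reproduces the recording bit-for-bit
  y <- generate_bm_recording(p, noise = nm)
  expect_identical(x$samples, y$samples)
})

test_that("OoC generator degenerates to the bare receptor current and corrects cleanly", {
  p <- three_tone_params(A = 1, f1 = 14500, f_e = 500, duration = 0.02)
  met <- model_met_params()
  # noise 0, cutoff Inf: identical to simulate_receptor_current output
  x <- generate_ooc_recording(p, met, electrode_cutoff = Inf,
                              noise = silent_noise())
  ref <- simulate_receptor_current(synthesize_three_tone(p), met)
  expect_equal(x$samples, ref$samples, tolerance = 1e-12)
  # phase 0: prominent f_e peak plus smaller 2f_e and 3f_e peaks
  filt <- generate_ooc_recording(p, met, electrode_cutoff = 3000,
                                 noise = silent_noise())
  s <- amplitude_spectrum(filt)
  a1 <- component_amplitude(s, 500)
  a2 <- component_amplitude(s, 1000)
  a3 <- component_amplitude(s, 1500)
  expect_gt(a1, a2)
  expect_gt(a2, a3)
  expect_gt(a3, 0)
  # electrode-corrected analysis matches the unfiltered current spectrum
  corrected <- correct_electrode_filter(filt, 3000)
  sref <- amplitude_spectrum(ref)
  sc <- amplitude_spectrum(corrected)
  for (f in c(500, 1000, 1500, 14500)) {
    expect_equal(component_amplitude(sc, f), component_amplitude(sref, f),
                 tolerance = 1e-3)
  }
  expect_error(generate_ooc_recording(p, met, electrode_cutoff = 100),
               "\\[500, 20000\\]")
})

test_that("RW population sum degenerates, is order-invariant, and tracks the envelope", {
  p <- three_tone_params(A = 1, f1 = 14500, f_e = 500, duration = 0.02)
  met <- model_met_params()
  # n_cells = 1, no jitter, no neural, no noise: a single unfiltered cell
  pop1 <- population_config(n_cells = 1, x0_sd = 0, gain_sd = 0,
                            neural_gain = 0, seed = 5)
  x <- generate_rw_recording(p, pop1, met, silent_noise())
  ref <- simulate_receptor_current(synthesize_three_tone(p), met)
  expect_equal(x$samples, ref$samples, tolerance = 1e-9)
  # population summation is order-invariant: shuffle cell order in a manual sum
  stim <- synthesize_three_tone(p)
  set.seed(31)
  x0s <- rnorm(20, 5.5, 1); gains <- rlnorm(20, 0, 0.2)
  total <- function(ord) {
    acc <- numeric(length(stim$samples))
    for (i in ord) {
      acc <- acc + gains[i] *
        boltzmann_current(stim$samples, model_met_params(X0 = x0s[i]))
    }
    projection_amplitude(acc, stim$sample_rate, 500)
  }
  expect_lt(abs(db_ratio(total(1:20), total(20:1))), 0.1)
  # phase sweep of the population signal is V-shaped with the minimum at 90
  pop <- population_config(n_cells = 20, seed = 5)
  nm <- noise_model(floor = 1e-4, seed = 5)
  fe_at <- function(phi) {
    pp <- p
    pp$phi <- phi
    r <- generate_rw_recording(pp, pop, met, nm, seed = 5)
    component_amplitude(amplitude_spectrum(r), 500)
  }
  lv <- vapply(c(0, 45, 90, 135, 180), fe_at, 0)
  expect_equal(which.min(lv), 3)
  expect_gt(db_ratio(lv[1], lv[3]), 20)
  expect_gt(db_ratio(lv[5], lv[3]), 20)
  # same seed reproduces bit-identically
  expect_identical(generate_rw_recording(p, pop, met, nm, seed = 9)$samples,
                   generate_rw_recording(p, pop, met, nm, seed = 9)$samples)
})

test_that("TTX flag removes only the neural component and spares tip-to-tail", {
  p <- three_tone_params(A = 1, f1 = 14500, f_e = 500, duration = 0.02)
  met <- model_met_params()
  nm <- noise_model(floor = 1e-5, seed = 3)
  sweep_for <- function(ttx) {
    pop <- population_config(n_cells = 20, neural_gain = 0.05, ttx = ttx,
                             seed = 7)
    lv <- vapply(c(0, 90, 180), function(phi) {
      pp <- p
      pp$phi <- phi
      r <- generate_rw_recording(pp, pop, met, nm, seed = 7)
      component_amplitude(amplitude_spectrum(r), 500)
    }, 0)
    phase_sweep_result(c(0, 90, 180), list(fe = lv), site = "RW")
  }
  ttr_ctrl <- tip_to_tail(sweep_for(FALSE))
  ttr_ttx <- tip_to_tail(sweep_for(TRUE))
  expect_gt(ttr_ctrl, 10)                      # envelope tracking is present
  expect_lt(abs(ttr_ctrl - ttr_ttx), 1)        # and survives the neural block
})

test_that("sweep averaging rejects drift-contaminated records and keeps clean ones", {
  fs <- 16000
  t <- (0:1599) / fs
  signal <- time_series(0.5 * sin(2 * pi * 500 * t), fs, "uV")
  # identical clean sweeps: average equals any sweep, nothing rejected
  clean <- sweep_set(rep(list(signal), 5))
  avg <- average_with_artifact_rejection(clean)
  expect_equal(avg$average$samples, signal$samples)
  expect_equal(avg$n_rejected, 0)
  expect_equal(avg$n_used, 5)
  # 60 clean + 5 drift-contaminated: exactly the flagged sweeps are rejected
  ss <- generate_sweep_set(signal, n_sweeps = 65,
                           noise = noise_model(floor = 1e-3, lf_slope = 0),
                           n_artifact = 5, artifact_amp = 3,
                           artifact_freq = 20, seed = 13)
  res <- average_with_artifact_rejection(ss, reject_k = 3)
  expect_setequal(res$rejected, which(ss$artifact_flags))
  expect_equal(res$n_used, 60)
  expect_error(average_with_artifact_rejection(sweep_set(list(signal))),
               "at least 2")
})

test_that("averaging N sweeps shrinks the noise by about sqrt(N)", {
  fs <- 16000
  t <- (0:799) / fs
  signal <- time_series(rep(0, length(t)), fs, "uV")
  N <- 25
  ratios <- vapply(1:20, function(rep_i) {
    ss <- generate_sweep_set(signal, n_sweeps = N,
                             noise = noise_model(floor = 1e-3, lf_slope = 0),
                             seed = 100 + rep_i)
    res <- average_with_artifact_rejection(ss, reject_k = 100)  # keep all
    rms1 <- mean(vapply(ss$sweeps, function(s) sqrt(mean(s$samples^2)), 0))
    rms1 / sqrt(mean(res$average$samples^2))
  }, 0)
  expect_equal(mean(ratios), sqrt(N), tolerance = 0.1)
})
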