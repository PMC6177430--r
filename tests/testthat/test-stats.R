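test_that("permutation test separates shifted signals and respects its support", {
  set.seed(1)
  noise <- rnorm(10)
  signal <- noise + 100                      # maximal separation
  r <- permutation_test_vs_noise(signal, noise, n_perm = 199, seed = 2)
  expect_equal(r$p_value, 1 / 200)
  expect_equal(r$observed_stat, 100, tolerance = 1e-9)
  # p-value always within its attainable range
  r2 <- permutation_test_vs_noise(rnorm(6), rnorm(6), n_perm = 99, seed = 3)
  expect_gte(r2$p_value, 1 / 100)
  expect_lte(r2$p_value, 1)
  expect_error(permutation_test_vs_noise(numeric(), 1:3), "non-empty")
  expect_error(permutation_test_vs_noise(1:3, 1:3, n_perm = 10), ">= 99")
})

test_that("permutation p is invariant to input order and common rescaling", {
  set.seed(4)
  s <- rnorm(8, mean = 1)
  n <- rnorm(8)
  base <- permutation_test_vs_noise(s, n, n_perm = 199, seed = 5)
  shuffled <- permutation_test_vs_noise(rev(s), sample(n), n_perm = 199, seed = 5)
  expect_identical(base$p_value, shuffled$p_value)
  scaled <- permutation_test_vs_noise(3.7 * s, 3.7 * n, n_perm = 199, seed = 5)
  expect_identical(base$p_value, scaled$p_value)
})

test_that("permutation test holds its nominal size under the null", {
  # moderate calibration run; the acceptance suite repeats this at 2000 draws
  set.seed(6)
  rejections <- 0L
  n_rep <- 400
  for (i in seq_len(n_rep)) {
    r <- permutation_test_vs_noise(rnorm(8), rnorm(8), n_perm = 99,
                                   seed = 1000 + i)
    if (r$p_value <= 0.05) rejections <- rejections + 1L
  }
  expect_gt(rejections / n_rep, 0.02)
  expect_lt(rejections / n_rep, 0.09)
})

test_that("phase-effect regression recovers a noiseless slope exactly", {
  phis <- c(0, 30, 60, 90, 120, 150, 180)
  mk_prep <- function(id, intercept, slope) {
    lv <- exp(intercept + slope * abs(cos(phis * pi / 180)))
    phase_sweep_result(phis, list(fe = lv), prep_id = id)
  }
  fit <- fit_phase_effect(list(mk_prep("a", 1.0, 2.3), mk_prep("b", -0.5, 2.3)),
                          n_perm = 99, seed = 1)
  expect_equal(fit$slope, 2.3, tolerance = 1e-6)
  expect_equal(unname(fit$intercepts[c("a", "b")]), c(1.0, -0.5),
               tolerance = 1e-6)
  expect_lt(fit$p_slope, 0.05)
  # per-preparation gain is absorbed by the intercepts: slope and p unchanged
  gained <- mk_prep("b", -0.5, 2.3)
  gained$levels$fe <- 10 * gained$levels$fe
  fit2 <- fit_phase_effect(list(mk_prep("a", 1.0, 2.3), gained),
                           n_perm = 99, seed = 1)
  expect_equal(fit2$slope, fit$slope, tolerance = 1e-9)
  expect_identical(fit2$p_slope, fit$p_slope)
  # degenerate design: |cos(phi)| constant
  flat <- phase_sweep_result(c(45, 135), list(fe = c(1, 2)))
  expect_error(fit_phase_effect(flat), "degenerate design")
})

test_that("phase-effect permutation p holds its size on slope-free data", {
  set.seed(8)
  phis <- c(0, 45, 90, 135, 180)
  n_rep <- 150
  rej <- 0L
  for (i in seq_len(n_rep)) {
    preps <- lapply(c("a", "b"), function(id) {
      phase_sweep_result(phis, list(fe = exp(rnorm(5, sd = 0.5))), prep_id = id)
    })
    f <- fit_phase_effect(preps, n_perm = 99, seed = 2000 + i)
    if (f$p_slope <= 0.05) rej <- rej + 1L
  }
  expect_lt(rej / n_rep, 0.11)
})

test_that("model-generated phase sweeps yield a significantly positive slope", {
  p <- three_tone_params(A = 1, f1 = 14500, f_e = 500, duration = 0.02)
  met <- model_met_params()
  phis <- c(0, 30, 60, 90, 120, 150, 180)
  preps <- lapply(1:2, function(k) {
    nm <- noise_model(floor = 1e-5, seed = k)
    lv <- vapply(phis, function(phi) {
      pp <- p
      pp$phi <- phi
      r <- generate_ooc_recording(pp, met, electrode_cutoff = 3000,
                                  noise = nm, seed = 50 + k)
      component_amplitude(amplitude_spectrum(r), 500)
    }, 0)
    phase_sweep_result(phis, list(fe = lv), prep_id = paste0("prep", k),
                       site = "OoC")
  })
  fit <- fit_phase_effect(preps, n_perm = 199, seed = 9)
  expect_gt(fit$slope, 0)
  expect_lt(fit$p_slope, 0.01)
})

test_that("the receptor-current experiment runner reports the model quantities deterministically", {
  cfg <- list(x0_grid = seq(4, 7, by = 0.5))   # small grid for speed
  rep1 <- run_receptor_current_experiment(cfg)
  expect_gt(rep1$fe_drop_db, 60)
  expect_equal(rep1$fe_level_db_re_f1, -17, tolerance = 1.5)
  expect_lt(rep1$fe2_change_db, 0.2)
  expect_equal(rep1$resting_open_probability, 0.206, tolerance = 0.01)
  expect_identical(rep1$resting_open_probability_at_zero, 0.5)
  # end-to-end determinism: bit-identical on a rerun
  rep2 <- run_receptor_current_experiment(cfg)
  expect_identical(rep1[setdiff(names(rep1), "config")],
                   rep2[setdiff(names(rep2), "config")])
  # report round-trips through the JSON writer
  path <- withr::local_tempfile(fileext = ".json")
  write_experiment_report(rep1, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$fe_level_db_re_f1, rep1$fe_level_db_re_f1,
               tolerance = 1e-9)
  expect_equal(back$schema_version, "1.0")
})

test_that("the envelope sweep experiment reports the phase-sweep shape", {
  rep <- run_envelope_sweep_experiment(list(duration = 0.02))
  expect_lt(rep$amp_fe_at_90_normalized, 1e-9)
  expect_lt(rep$amp_2fe_max_min_ratio, 1.3)
  expect_equal(rep$sweep$amp_fe[1], 1)         # maximum at phase 0
  expect_true(all(diff(rep$sweep$amp_fe[1:7]) < 0))  # monotone to 90 deg
})
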