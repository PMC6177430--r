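#' Phase-sweep result container
#'
#' Component levels measured (or simulated) as a function of centre-tone
#' phase for one preparation/site.
#'
#' @param phases phase grid in degrees, sorted ascending within \[0, 180\].
#' @param levels named list of non-negative per-phase amplitude vectors,
#'   keyed by component label (e.g. `"fe"`, `"2fe"`, `"2f3-f2"`).
#' @param prep_id preparation/site identifier.
#' @param stimulus_level free-form stimulus level tag (e.g. `"47 dB SPL"`).
#' @param site one of `"BM"`, `"OoC"`, `"RW"`, `"model"`.
#' @return An object of class `phase_sweep_result`.
#' @export
phase_sweep_result <- function(phases, levels, prep_id = "prep1",
                               stimulus_level = "", site = c("model", "BM", "OoC", "RW")) {
  site <- match.arg(site)
  stopifnot(is.numeric(phases), is.list(levels), length(levels) >= 1,
            !is.null(names(levels)))
  if (is.unsorted(phases) || any(phases < 0) || any(phases > 180)) {
    stop("phase_sweep_result(): phases must be ascending within [0, 180] deg")
  }
  for (lab in names(levels)) {
    lv <- levels[[lab]]
    if (!is.numeric(lv) || length(lv) != length(phases) || any(lv < 0)) {
      stop("phase_sweep_result(): levels[['", lab,
           "']] must be non-negative and match the phase grid")
    }
  }
  structure(list(phases = phases, levels = levels, prep_id = prep_id,
                 stimulus_level = stimulus_level, site = site),
            class = "phase_sweep_result")
}

#' Permutation test of signal amplitudes against a noise floor
#'
#' Tests whether a set of response amplitudes exceeds a set of noise-floor
#' amplitudes. The statistic is the difference of group means; the null
#' distribution is built by randomly reassigning the pooled values to the two
#' groups. The p-value is one-sided (signal exceeds noise) with the add-one
#' convention `p = (1 + #\{permuted >= observed\}) / (n_perm + 1)`, so its
#' smallest attainable value is `1 / (n_perm + 1)`.
#'
#' @param signal_amps numeric vector of response amplitudes.
#' @param noise_amps numeric vector of noise-floor amplitudes.
#' @param n_perm number of permutations (at least 99).
#' @param seed RNG seed for the permutation draws.
#' @return An object of class `perm_test` with `observed_stat`, `p_value`,
#'   `n_perm` and `seed`.
#' @export
permutation_test_vs_noise <- function(signal_amps, noise_amps, n_perm = 999,
                                      seed = NULL) {
  if (!length(signal_amps) || !length(noise_amps)) {
    stop("permutation_test_vs_noise(): both input sets must be non-empty")
  }
  if (n_perm < 99) stop("permutation_test_vs_noise(): n_perm must be >= 99")
  obs <- mean(signal_amps) - mean(noise_amps)
  # canonical pool order (sorted within group): the p-value then depends only
  # on the two sets of values, not on the order they were supplied in
  pool <- c(sort(signal_amps), sort(noise_amps))
  ns <- length(signal_amps)
  exceed <- with_seed(seed, {
    count <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(length(pool), ns)
      stat <- mean(pool[idx]) - mean(pool[-idx])
      if (stat >= obs) count <- count + 1L
    }
    count
  })
  structure(list(observed_stat = obs,
                 p_value = (1 + exceed) / (n_perm + 1),
                 n_perm = n_perm, seed = seed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> mean difference %.4g, p = %.4g (%d permutations)\n",
              x$observed_stat, x$p_value, x$n_perm))
  invisible(x)
}

#' Phase-effect regression with the |cos(phi)| predictor
#'
#' Fits the V-shaped dependence of component level on centre-tone phase:
#' `log(level) = intercept[prep] + slope * |cos(phi)|`, with a separate
#' fixed intercept per preparation so that preparation-specific gains are
#' absorbed. Inference on the slope uses a permutation of phase labels within
#' each preparation (one-sided: slope positive).
#'
#' @param results a `phase_sweep_result` or list of them (one per
#'   preparation).
#' @param component component label to analyse.
#' @param n_perm permutations for the slope p-value.
#' @param seed RNG seed.
#' @return A list with `slope`, `intercepts` (named per preparation),
#'   `p_slope`, `n_perm`, `seed` and the model `data`.
#' @export
fit_phase_effect <- function(results, component = "fe", n_perm = 999,
                             seed = NULL) {
  if (inherits(results, "phase_sweep_result")) results <- list(results)
  stopifnot(all(vapply(results, inherits, TRUE, "phase_sweep_result")))
  df <- do.call(rbind, lapply(results, function(r) {
    lv <- r$levels[[component]]
    if (is.null(lv)) stop("fit_phase_effect(): no component '", component,
                          "' in preparation ", r$prep_id)
    if (length(r$phases) < 2) {
      stop("fit_phase_effect(): need at least 2 phases per preparation")
    }
    if (any(lv <= 0)) {
      stop("fit_phase_effect(): levels must be > 0 (log transform)")
    }
    data.frame(prep = r$prep_id, phi = r$phases, level = lv)
  }))
  df$abscos <- abs(cos(deg2rad(df$phi)))
  if (diff(range(df$abscos)) < 1e-12) {
    stop("degenerate design: |cos(phi)| is constant across the data")
  }
  df$prep <- factor(df$prep)
  fit <- stats::lm(log(level) ~ 0 + prep + abscos, data = df)
  slope <- unname(stats::coef(fit)["abscos"])
  intercepts <- stats::coef(fit)[grep("^prep", names(stats::coef(fit)))]
  names(intercepts) <- sub("^prep", "", names(intercepts))
  slope_of <- function(d) {
    unname(stats::coef(stats::lm(log(level) ~ 0 + prep + abscos, data = d))["abscos"])
  }
  exceed <- with_seed(seed, {
    count <- 0L
    for (b in seq_len(n_perm)) {
      d <- df
      for (p in levels(df$prep)) {
        i <- which(d$prep == p)
        d$abscos[i] <- d$abscos[sample(i)]
      }
      if (slope_of(d) >= slope) count <- count + 1L
    }
    count
  })
  list(slope = slope, intercepts = intercepts,
       p_slope = (1 + exceed) / (n_perm + 1),
       n_perm = n_perm, seed = seed, data = df)
}

#' End-to-end receptor-current model experiment
#'
#' Runs the full MET-model computation on the standard displacement stimulus:
#' simulates the Boltzmann receptor current at centre-tone phases 0 and
#' 90 deg, measures the `f_e` and `2 f_e` spectral components and the level
#' of the `f1` primary, computes the `f_e` drop between phases and the
#' `f_e` level re `f1`, the resting open probability, and sweeps the
#' operating point `X0` for the `f_e` maximum.
#'
#' Defaults: `I_max` 2.5 nA, `X0` 5.5 nm, `Z` 1.05 pN, `T` 310.15 K,
#' primaries 14.5/15/15.5 kHz (`f1` 14500 Hz, `f_e` 500 Hz), amplitude 1 nm
#' per component, 100-ms unramped record at 16x the highest primary.
#'
#' @param config optional named list overriding any of `A`, `f1`, `f_e`,
#'   `duration`, `I_max`, `X0`, `Z`, `temperature`, `sample_rate`,
#'   `x0_grid`.
#' @return A report list (schema-versioned) with entries `fe_level_db_re_f1`,
#'   `fe_drop_db`, `fe2_change_db`, `resting_open_probability`,
#'   `resting_open_probability_at_zero`, `x0_argmax_fe_nm`, the component
#'   amplitudes at both phases, and the configuration used.
#' @export
run_receptor_current_experiment <- function(config = list()) {
  cfg <- utils::modifyList(list(
    A = 1, f1 = 14500, f_e = 500, duration = 0.1,
    I_max = 2.5, X0 = 5.5, Z = 1.05, temperature = 310.15,
    sample_rate = NULL, x0_grid = seq(0, 20, by = 0.05)
  ), config)
  sp <- three_tone_params(A = cfg$A, f1 = cfg$f1, f_e = cfg$f_e,
                          duration = cfg$duration, ramp = 0)
  sr <- if (is.null(cfg$sample_rate)) default_sample_rate(sp) else cfg$sample_rate
  met <- boltzmann_params(I_max = cfg$I_max, X0 = cfg$X0, Z = cfg$Z,
                          temperature = cfg$temperature)
  comp_at <- function(phi) {
    spp <- sp
    spp$phi <- phi
    stim <- synthesize_three_tone(spp, sr)
    s <- amplitude_spectrum(simulate_receptor_current(stim, met))
    c(fe = component_amplitude(s, cfg$f_e),
      fe2 = component_amplitude(s, 2 * cfg$f_e),
      f1 = component_amplitude(s, cfg$f1))
  }
  a0 <- comp_at(0)
  a90 <- comp_at(90)
  floor_amp <- 1e-12 * met$I_max     # numerical floor: keeps dB finite
  sweep <- sweep_operating_point(sp, met, grid = cfg$x0_grid, sample_rate = sr)
  list(
    schema_version = "1.0",
    config = cfg,
    amplitudes_phi0 = as.list(a0),
    amplitudes_phi90 = as.list(a90),
    fe_level_db_re_f1 = db_ratio(a0[["fe"]], a0[["f1"]]),
    fe_drop_db = db_ratio(max(a0[["fe"]], floor_amp),
                          max(a90[["fe"]], floor_amp)),
    fe2_change_db = abs(db_ratio(a0[["fe2"]], a90[["fe2"]])),
    resting_open_probability = resting_open_probability(met),
    resting_open_probability_at_zero =
      resting_open_probability(boltzmann_params(I_max = met$I_max, X0 = 0,
                                                Z = met$Z,
                                                temperature = met$temperature)),
    x0_argmax_fe_nm = sweep$argmax_fe,
    x0_sweep = list(grid = sweep$grid, amp_fe = sweep$amp_fe,
                    amp_2fe = sweep$amp_2fe)
  )
}

#' End-to-end envelope phase-sweep experiment
#'
#' Computes the Hilbert-envelope component amplitudes of the three-tone
#' stimulus across a centre-tone phase sweep, normalizes each component by
#' its maximum over the sweep, and compares the normalized `f_e` trace with
#' the quadratic-nonlinearity prediction `2 |cos(phi)|` (also normalized).
#'
#' Defaults: primaries 16/16.5/17 kHz, amplitude 1, 100-ms unramped record,
#' phases 0 to 180 deg in 15-deg steps.
#'
#' @param config optional named list overriding `A`, `f1`, `f_e`,
#'   `duration`, `phis`, `sample_rate`.
#' @return A report list with the sweep table (`sweep`), the prediction
#'   column, `max_abs_deviation` (normalized `amp_fe` vs normalized
#'   prediction), `amp_2fe_max_min_ratio`, and `amp_fe_at_90_normalized`.
#' @export
run_envelope_sweep_experiment <- function(config = list()) {
  cfg <- utils::modifyList(list(
    A = 1, f1 = 16000, f_e = 500, duration = 0.1,
    phis = seq(0, 180, by = 15), sample_rate = NULL
  ), config)
  sp <- three_tone_params(A = cfg$A, f1 = cfg$f1, f_e = cfg$f_e,
                          duration = cfg$duration, ramp = 0)
  sr <- if (is.null(cfg$sample_rate)) default_sample_rate(sp) else cfg$sample_rate
  sweep <- envelope_phase_sweep(sp, phis = cfg$phis, sample_rate = sr,
                                normalization = "max-over-sweep")
  pred <- quadratic_prediction(cfg$phis)
  pred_norm <- pred$c_fe / max(pred$c_fe)
  sweep$prediction_fe <- pred_norm
  list(
    schema_version = "1.0",
    config = cfg,
    sweep = sweep,
    max_abs_deviation = max(abs(sweep$amp_fe - pred_norm)),
    amp_2fe_max_min_ratio = max(sweep$amp_2fe) / min(sweep$amp_2fe),
    amp_fe_at_90_normalized = sweep$amp_fe[which.min(abs(cfg$phis - 90))]
  )
}

#' Write an experiment report as JSON
#'
#' @param report a report list from one of the experiment runners.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_experiment_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
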