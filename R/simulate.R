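# Pulse kernel: one cardiac pulse in normalized phase u in [0, 1),
# w(u) = u^2 (1 - u)^4 scaled to peak amplitude 1 (fast systolic upstroke,
# peak at u = 1/3, slow diastolic decay). Only the foot timing, the
# foot-to-peak amplitude and the baseline are contractual; the shape is a
# free modelling choice.
PULSE_KERNEL_PEAK <- (1 / 3)^2 * (2 / 3)^4        # max of u^2 (1-u)^4
PULSE_KERNEL_MEAN <- (1 / 105) / PULSE_KERNEL_PEAK # Beta(3,5) integral / peak

pulse_kernel <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u^2 * (1 - u)^4 / PULSE_KERNEL_PEAK
}

#' Simulate a PPG waveform with known beat-level ground truth
#'
#' Generates a pulsatile photoplethysmogram: an asymmetric pulse kernel per
#' beat (fast upstroke, slow decay, foot at the beat onset) riding on a
#' baseline (DC) level, with optional Gaussian noise and transient motion
#' artifacts. Each beat is centred so that the within-beat mean of the
#' clean signal equals the DC profile and the foot-to-peak excursion equals
#' the AC profile, so the extracted AC/DC features of [beat_features()]
#' recover the generating values up to discretization and noise.
#'
#' @param duration_s Signal duration, seconds.
#' @param sampling_rate Sampling rate, Hz (60 emulates a smartphone camera,
#'   1000 a laboratory photoplethysmograph).
#' @param hr_bpm Heart rate profile: a constant (bpm) or a function of time
#'   `f(t)` returning bpm (use for ramps or steps).
#' @param ac,dc Pulse (AC) amplitude and baseline (DC) level: constants or
#'   functions of time, in signal units. `dc` must stay positive.
#' @param noise_sd Standard deviation of additive Gaussian noise, signal
#'   units.
#' @param artifacts Optional tibble/data frame with columns `time_s` and
#'   `amplitude`: each row adds a 20-ms Gaussian transient spike.
#' @param first_onset_s Time of the first pulse foot, seconds.
#' @param invert If `TRUE` the output is negated, emulating transmittance
#'   devices where more blood means less light (pair with
#'   `invert = TRUE` in [detect_beats()]).
#' @param seed Integer seed; identical specs and seeds give bitwise
#'   identical output. The global RNG state is left untouched.
#'
#' @return A [ppg_record()] whose ground-truth annotations (one row per
#'   complete beat) are available through [pulse_truth()].
#' @examples
#' rec <- simulate_ppg(duration_s = 30, hr_bpm = 75, seed = 1)
#' head(pulse_truth(rec))
#' @export
simulate_ppg <- function(duration_s = 60, sampling_rate = 60, hr_bpm = 75,
                         ac = 0.5, dc = 20, noise_sd = 0, artifacts = NULL,
                         first_onset_s = 0.2, invert = FALSE, seed = 1L) {
  check_number(duration_s, "duration_s", positive = TRUE)
  check_number(sampling_rate, "sampling_rate", positive = TRUE)
  check_number(noise_sd, "noise_sd")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  check_number(first_onset_s, "first_onset_s")
  if (first_onset_s < 0 || first_onset_s >= duration_s) {
    abort("`first_onset_s` must lie within the signal")
  }
  hr_f <- as_profile(hr_bpm, "hr_bpm")
  ac_f <- as_profile(ac, "ac")
  dc_f <- as_profile(dc, "dc")

  # beat onsets from the (possibly time-varying) heart-rate profile;
  # IBIs are kept exactly as generated (not re-differenced) so the
  # ground-truth HR = 60000 / IBI identities hold to the last bit
  ibis <- numeric(0)
  onsets <- first_onset_s
  repeat {
    t_cur <- onsets[length(onsets)]
    hr_cur <- hr_f(t_cur)[1]
    if (!is.finite(hr_cur) || hr_cur <= 0) abort("infeasible profile")
    ibi <- 60 / hr_cur
    if (ibi < 0.25) abort("infeasible profile")
    ibis <- c(ibis, ibi)
    t_next <- t_cur + ibi
    onsets <- c(onsets, t_next)
    if (t_next >= duration_s) break
  }

  n <- floor(duration_s * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate
  value <- dc_f(t)
  if (any(value <= 0)) abort("`dc` profile must stay positive")

  n_beats <- length(onsets) - 1L
  ac_beat <- ac_f(onsets[seq_len(n_beats)])
  if (any(ac_beat < 0)) abort("`ac` profile must be non-negative")
  dc_truth <- numeric(n_beats)
  for (k in seq_len(n_beats)) {
    in_beat <- t >= onsets[k] & t < onsets[k + 1]
    u <- (t[in_beat] - onsets[k]) / (onsets[k + 1] - onsets[k])
    value[in_beat] <- value[in_beat] +
      ac_beat[k] * (pulse_kernel(u) - PULSE_KERNEL_MEAN)
    dc_truth[k] <- mean(dc_f(t[in_beat]))
  }
  # flat (foot-level) signal before the first and after the last onset so
  # there is no step at the record edges
  pre <- t < onsets[1]
  value[pre] <- value[pre] - ac_beat[1] * PULSE_KERNEL_MEAN
  post <- t >= onsets[length(onsets)]
  value[post] <- value[post] - ac_beat[n_beats] * PULSE_KERNEL_MEAN

  if (!is.null(artifacts) && nrow(artifacts) > 0) {
    check_columns(artifacts, c("time_s", "amplitude"), "artifacts")
    for (k in seq_len(nrow(artifacts))) {
      value <- value + artifacts$amplitude[k] *
        exp(-((t - artifacts$time_s[k]) / 0.02)^2)
    }
  }
  if (noise_sd > 0) {
    value <- value +
      withr::with_seed(as.integer(seed), rnorm(n, sd = noise_sd))
  }
  if (invert) value <- -value

  ibi_ms <- ibis * 1000
  truth <- tibble::tibble(
    onset_s = onsets[seq_len(n_beats)],
    ibi_ms = ibi_ms,
    hr_bpm = 60000 / ibi_ms,
    ac = ac_beat,
    dc = dc_truth,
    mnpv = ac_beat / dc_truth,
    ln_mnpv = log(ac_beat / dc_truth)
  )
  rec <- ppg_record(value, sampling_rate = sampling_rate,
                    channel = "synthetic")
  attr(rec, "truth") <- truth
  rec
}

#' Simulate a calibration cohort from the log-linear blood-pressure model
#'
#' Draws block-averaged (HR, ln mNPV) observations per subject, condition
#' and measurement block, then generates reference systolic and diastolic
#' pressures from the log-linear model
#' \eqn{\ln BP = a \ln HR + b \ln mNPV + c} with homoscedastic Gaussian
#' residuals on the ln scale (the systolic and diastolic residuals are
#' positively correlated, r = 0.7, since both arise from one cuff reading,
#' and the rare draw that would cross SBP below DBP is redrawn); mean
#' arterial pressure is derived with the
#' one-third formula [map_from_sbp_dbp()] (set `map_mode = "model"` to
#' generate MAP from its own coefficients instead, which makes the MAP fit
#' exactly identifiable). Defaults emulate a rest ("BL") versus mental
#' stress ("MA") protocol: 13 subjects, two conditions, two 45-s blocks per
#' condition, typical HR 75 and 92 bpm and ln mNPV -3.63 and -4.37.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param conditions Tibble with columns `condition`, `hr_bpm`
#'   (typical heart rate, interpreted on the log scale) and `ln_mnpv`
#'   (mean ln mNPV) — one row per experimental condition.
#' @param blocks_per_condition Measurement blocks per subject and condition
#'   (the two cuff readings per 3-min period in the emulated protocol).
#' @param coefficients Named list of `c(a, b, c)` generating vectors for
#'   `map`, `sbp`, `dbp` (ln-scale model). Defaults are of realistic
#'   magnitude for this model class.
#' @param hr_subject_sd,hr_block_sd Between-subject and between-block SDs
#'   of ln HR (dimensionless, log scale).
#' @param mnpv_subject_sd,mnpv_block_sd Same for ln mNPV.
#' @param residual_sd SD of the Gaussian residual added to ln SBP / ln DBP
#'   (and ln MAP when `map_mode = "model"`). The default 0.09 yields a
#'   multiple correlation near 0.7 at the default predictor spread (see
#'   [calibrate_residual_sd()]).
#' @param map_mode `"derived"` (default): MAP = DBP + (SBP - DBP)/3;
#'   `"model"`: MAP generated from `coefficients$map` with its own
#'   residual.
#' @param seed Integer seed; reproducible, global RNG untouched.
#'
#' @return A tibble with columns `subject_id`, `condition`, `block`,
#'   `hr_bpm`, `ln_mnpv`, `sbp_mmHg`, `dbp_mmHg`, `map_mmHg`. The
#'   generating truth (coefficients, residual SD, map mode) is attached as
#'   attribute `"truth"`.
#' @examples
#' calib <- simulate_cohort(seed = 7)
#' fit <- bp_calibrate(calib)
#' glance(fit)
#' @export
simulate_cohort <- function(n_subjects = 13,
                            conditions = default_conditions(),
                            blocks_per_condition = 2,
                            coefficients = default_coefficients(),
                            hr_subject_sd = 0.16, hr_block_sd = 0.10,
                            mnpv_subject_sd = 0.30, mnpv_block_sd = 0.18,
                            residual_sd = 0.09,
                            map_mode = c("derived", "model"),
                            seed = 1L) {
  map_mode <- match.arg(map_mode)
  if (!is.numeric(n_subjects) || n_subjects < 2) {
    abort("`n_subjects` must be >= 2")
  }
  check_columns(conditions, c("condition", "hr_bpm", "ln_mnpv"),
                "conditions")
  for (nm in c("hr_subject_sd", "hr_block_sd", "mnpv_subject_sd",
               "mnpv_block_sd", "residual_sd")) {
    v <- get(nm)
    check_number(v, nm)
    if (v < 0) abort(sprintf("`%s` must be >= 0", nm))
  }
  for (nm in c("map", "sbp", "dbp")) {
    if (!nm %in% names(coefficients) || length(coefficients[[nm]]) != 3) {
      abort("`coefficients` must hold c(a, b, c) for map, sbp and dbp")
    }
  }

  grid <- tidyr::expand_grid(
    subject_id = sprintf("S%02d", seq_len(n_subjects)),
    condition = conditions$condition,
    block = seq_len(blocks_per_condition)
  )
  grid <- dplyr::left_join(grid, conditions, by = "condition")

  n <- nrow(grid)
  draws <- withr::with_seed(as.integer(seed), {
    u_hr <- rnorm(n_subjects, sd = hr_subject_sd)
    u_mnpv <- rnorm(n_subjects, sd = mnpv_subject_sd)
    names(u_hr) <- names(u_mnpv) <- sprintf("S%02d", seq_len(n_subjects))

    ln_hr <- log(grid$hr_bpm) + u_hr[grid$subject_id] +
      rnorm(n, sd = hr_block_sd)
    ln_mnpv <- grid$ln_mnpv + u_mnpv[grid$subject_id] +
      rnorm(n, sd = mnpv_block_sd)

    # SBP and DBP residuals come from the same cuff reading, so they are
    # drawn with positive correlation; the rare draw that would cross
    # SBP below DBP is redrawn. Parameters whose mean structure itself
    # crosses (> 5% of rows, or rows that never resolve) are rejected.
    rho <- 0.7
    draw_pair <- function(m) {
      z1 <- rnorm(m, sd = residual_sd)
      z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(m, sd = residual_sd)
      cbind(z1, z2)
    }
    eps <- draw_pair(n)
    sbp <- exp(cf_apply(coefficients$sbp, ln_hr, ln_mnpv, eps[, 1]))
    dbp <- exp(cf_apply(coefficients$dbp, ln_hr, ln_mnpv, eps[, 2]))
    bad <- which(sbp <= dbp)
    if (length(bad) > 0.05 * n) abort("incoherent generating model")
    tries <- 0
    while (length(bad) > 0) {
      tries <- tries + 1
      if (tries > 100) abort("incoherent generating model")
      eps_new <- draw_pair(length(bad))
      sbp[bad] <- exp(cf_apply(coefficients$sbp, ln_hr[bad],
                               ln_mnpv[bad], eps_new[, 1]))
      dbp[bad] <- exp(cf_apply(coefficients$dbp, ln_hr[bad],
                               ln_mnpv[bad], eps_new[, 2]))
      bad <- bad[sbp[bad] <= dbp[bad]]
    }
    map <- if (map_mode == "model") {
      exp(cf_apply(coefficients$map, ln_hr, ln_mnpv,
                   rnorm(n, sd = residual_sd)))
    } else {
      map_from_sbp_dbp(sbp, dbp)
    }
    list(ln_hr = ln_hr, ln_mnpv = ln_mnpv, sbp = sbp, dbp = dbp,
         map = map)
  })

  out <- tibble::tibble(
    subject_id = grid$subject_id,
    condition = grid$condition,
    block = grid$block,
    hr_bpm = exp(draws$ln_hr),
    ln_mnpv = draws$ln_mnpv,
    sbp_mmHg = draws$sbp,
    dbp_mmHg = draws$dbp,
    map_mmHg = draws$map
  )
  attr(out, "truth") <- list(
    coefficients = coefficients, residual_sd = residual_sd,
    map_mode = map_mode, conditions = conditions
  )
  out
}

#' @rdname simulate_cohort
#' @export
default_conditions <- function() {
  tibble::tibble(
    condition = c("BL", "MA"),
    hr_bpm = c(75, 92),
    ln_mnpv = c(-3.63, -4.37)
  )
}

#' @rdname simulate_cohort
#' @export
default_coefficients <- function() {
  list(
    map = c(0.305, -0.084, 2.905),
    sbp = c(0.418, -0.029, 2.874),
    dbp = c(0.220, -0.126, 2.959)
  )
}

cf_apply <- function(cf, ln_hr, ln_mnpv, eps) {
  cf[1] * ln_hr + cf[2] * ln_mnpv + cf[3] + eps
}

#' Residual SD needed for a target multiple correlation
#'
#' Computes, for a given cohort specification, the ln-scale residual SD at
#' which the pooled log-linear fit of the chosen index attains a target
#' multiple correlation R. The variance of the noiseless linear predictor
#' is measured on one large simulated cohort and the residual variance is
#' solved from \eqn{R^2 = V / (V + \sigma^2)}.
#'
#' @param target_r Target multiple correlation, in (0, 1).
#' @param index Which blood-pressure index to calibrate for.
#' @param n_subjects Cohort size used to measure the predictor variance.
#' @param seed Integer seed.
#' @inheritParams simulate_cohort
#' @return The residual SD (ln scale) as a single number.
#' @export
calibrate_residual_sd <- function(target_r, index = c("map", "sbp", "dbp"),
                                  n_subjects = 4000,
                                  conditions = default_conditions(),
                                  coefficients = default_coefficients(),
                                  hr_subject_sd = 0.16, hr_block_sd = 0.10,
                                  mnpv_subject_sd = 0.30,
                                  mnpv_block_sd = 0.18, seed = 1L) {
  index <- match.arg(index)
  check_number(target_r, "target_r", positive = TRUE)
  if (target_r >= 1) abort("`target_r` must be in (0, 1)")
  big <- simulate_cohort(
    n_subjects = n_subjects, conditions = conditions,
    blocks_per_condition = 1, coefficients = coefficients,
    hr_subject_sd = hr_subject_sd, hr_block_sd = hr_block_sd,
    mnpv_subject_sd = mnpv_subject_sd, mnpv_block_sd = mnpv_block_sd,
    residual_sd = 0, map_mode = "model", seed = seed
  )
  cf <- coefficients[[index]]
  pred <- cf[1] * log(big$hr_bpm) + cf[2] * big$ln_mnpv
  v <- stats::var(pred)
  sqrt(v * (1 - target_r^2) / target_r^2)
}
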