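#' Mean arterial pressure from systolic and diastolic pressure
#'
#' The standard one-third approximation
#' \eqn{MAP = DBP + (SBP - DBP)/3}: diastolic pressure plus one third of
#' the pulse pressure. Vectorized; because the formula is linear, the MAP
#' of group means equals the mean of per-reading MAPs.
#'
#' @param sbp,dbp Systolic and diastolic pressure, mmHg; `sbp > dbp > 0`
#'   elementwise.
#' @return Mean arterial pressure, mmHg.
#' @examples
#' map_from_sbp_dbp(117.1, 76.9) # 90.3
#' @export
map_from_sbp_dbp <- function(sbp, dbp) {
  if (length(sbp) != length(dbp)) abort("invalid reading")
  if (any(!is.finite(sbp)) || any(!is.finite(dbp))) abort("invalid reading")
  if (any(dbp <= 0) || any(sbp <= dbp)) abort("invalid reading")
  dbp + (sbp - dbp) / 3
}

bp_indices <- c("map", "sbp", "dbp")

#' Calibrate the log-linear blood-pressure model
#'
#' Fits, for each requested blood-pressure index, the pooled ordinary
#' least-squares regression
#' \deqn{\ln BP = a \, \ln HR + b \, \ln mNPV + c}
#' of the log reference pressure on log heart rate and ln mNPV, with no
#' per-subject terms (the model is calibration-free across subjects by
#' design). Reports for each index the coefficients `(a, b, c)`, the
#' multiple correlation R, standardized coefficients
#' (\eqn{\beta \cdot SD(x) / SD(y)}) and two-sided coefficient p-values.
#'
#' @param data Calibration rows: a data frame with columns `hr_bpm` and
#'   `ln_mnpv` plus reference pressures `sbp_mmHg` and `dbp_mmHg`
#'   (`map_mmHg` is derived with [map_from_sbp_dbp()] when absent). At
#'   least 4 complete rows are required.
#' @param indices Which indices to fit, a subset of
#'   `c("map", "sbp", "dbp")`.
#' @return An object of class `bp_model`; see [tidy.bp_model()],
#'   [glance.bp_model()], [predict.bp_model()], [bp_evaluate()].
#' @examples
#' calib <- simulate_cohort(seed = 3)
#' fit <- bp_calibrate(calib)
#' tidy(fit)
#' @export
bp_calibrate <- function(data, indices = bp_indices) {
  indices <- match.arg(indices, bp_indices, several.ok = TRUE)
  check_columns(data, c("hr_bpm", "ln_mnpv"), "data")
  if (!"map_mmHg" %in% names(data) || "map" %in% indices) {
    if (all(c("sbp_mmHg", "dbp_mmHg") %in% names(data)) &&
        !"map_mmHg" %in% names(data)) {
      data$map_mmHg <- map_from_sbp_dbp(data$sbp_mmHg, data$dbp_mmHg)
    }
  }
  ref_cols <- paste0(indices, "_mmHg")
  check_columns(data, ref_cols, "data")
  keep <- complete.cases(data[c("hr_bpm", "ln_mnpv", ref_cols)])
  data <- data[keep, , drop = FALSE]
  if (nrow(data) < 4) abort("insufficient data")
  if (any(data$hr_bpm <= 0)) abort("`hr_bpm` must be > 0")
  if (any(data[ref_cols] <= 0)) abort("reference pressures must be > 0")
  if (sd(data$hr_bpm) == 0 || sd(data$ln_mnpv) == 0) {
    abort("degenerate design")
  }

  ln_hr <- log(data$hr_bpm)
  ln_mnpv <- data$ln_mnpv
  fits <- purrr::map(rlang::set_names(indices), function(ix) {
    y <- log(data[[paste0(ix, "_mmHg")]])
    fit <- lm(y ~ ln_hr + ln_mnpv)
    if (any(is.na(coef(fit)))) abort("degenerate design")
    fit
  })
  coefficients <- purrr::map_dfr(indices, function(ix) {
    fit <- fits[[ix]]
    # summary.lm warns on an exactly interpolating fit; that case is
    # legitimate here (noiseless calibration data)
    sm <- suppressWarnings(summary(fit))
    cf <- coef(fit)
    y <- fit$model[[1]]
    tibble::tibble(
      index = ix,
      a = unname(cf["ln_hr"]),
      b = unname(cf["ln_mnpv"]),
      c = unname(cf["(Intercept)"]),
      r = sqrt(sm$r.squared),
      std_beta_a = unname(cf["ln_hr"]) * sd(ln_hr) / sd(y),
      std_beta_b = unname(cf["ln_mnpv"]) * sd(ln_mnpv) / sd(y),
      p_a = sm$coefficients["ln_hr", 4],
      p_b = sm$coefficients["ln_mnpv", 4],
      p_c = sm$coefficients["(Intercept)", 4],
      n = nrow(data)
    )
  })
  structure(
    list(coefficients = coefficients, fits = fits, data = data,
         indices = indices),
    class = "bp_model"
  )
}

#' Build a blood-pressure model from known coefficients
#'
#' Wraps externally supplied `(a, b, c)` triples (for example from a
#' published calibration) in a `bp_model` so [predict.bp_model()] can be
#' used without refitting. No fit diagnostics are attached.
#'
#' @param coefficients Named list of numeric `c(a, b, c)` vectors, names
#'   among `c("map", "sbp", "dbp")`.
#' @return A `bp_model`.
#' @examples
#' m <- bp_model(list(map = c(0.305, -0.084, 2.905)))
#' predict(m, tibble::tibble(hr_bpm = 75, ln_mnpv = -3.63))
#' @export
bp_model <- function(coefficients) {
  indices <- intersect(bp_indices, names(coefficients))
  if (length(indices) == 0) {
    abort("`coefficients` must name at least one of map, sbp, dbp")
  }
  coefficients <- purrr::map_dfr(indices, function(ix) {
    v <- coefficients[[ix]]
    if (length(v) != 3 || !all(is.finite(v))) {
      abort("each coefficient entry must be a finite c(a, b, c)")
    }
    tibble::tibble(index = ix, a = v[1], b = v[2], c = v[3], r = NA_real_,
                   std_beta_a = NA_real_, std_beta_b = NA_real_,
                   p_a = NA_real_, p_b = NA_real_, p_c = NA_real_,
                   n = NA_integer_)
  })
  structure(
    list(coefficients = coefficients, fits = NULL, data = NULL,
         indices = indices),
    class = "bp_model"
  )
}

#' @export
print.bp_model <- function(x, ...) {
  cat("Log-linear blood-pressure model: ln BP = a ln HR + b ln mNPV + c\n")
  print(x$coefficients, ...)
  invisible(x)
}

#' Tidy and summarize a fitted blood-pressure model
#'
#' `tidy()` returns one row per index and term with the estimate,
#' standardized estimate and p-value; `glance()` returns one row per index
#' with the multiple correlation `r`, `r_squared`, ln-scale residual
#' `sigma` and `n`.
#'
#' @param x A `bp_model` from [bp_calibrate()] or [bp_model()].
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.bp_model <- function(x, ...) {
  cf <- x$coefficients
  purrr::map_dfr(seq_len(nrow(cf)), function(i) {
    tibble::tibble(
      index = cf$index[i],
      term = c("ln_hr", "ln_mnpv", "(Intercept)"),
      estimate = c(cf$a[i], cf$b[i], cf$c[i]),
      std_estimate = c(cf$std_beta_a[i], cf$std_beta_b[i], NA_real_),
      p_value = c(cf$p_a[i], cf$p_b[i], cf$p_c[i])
    )
  })
}

#' @rdname tidy.bp_model
#' @exportS3Method generics::glance
glance.bp_model <- function(x, ...) {
  cf <- x$coefficients
  sigma <- if (is.null(x$fits)) rep(NA_real_, nrow(cf)) else
    purrr::map_dbl(cf$index,
                   ~ suppressWarnings(summary(x$fits[[.x]]))$sigma)
  tibble::tibble(
    index = cf$index, r = cf$r, r_squared = cf$r^2,
    sigma = sigma, n = cf$n
  )
}

#' Predict blood pressure from heart rate and ln mNPV
#'
#' Applies the exponential back-transform of the calibrated model:
#' \eqn{\widehat{BP} = \exp(a \ln HR + b \ln mNPV + c)} for each fitted
#' index. Estimates are strictly positive for any finite inputs.
#'
#' @param object A `bp_model`.
#' @param newdata Data frame with columns `hr_bpm` (> 0) and `ln_mnpv`.
#' @param ... Unused.
#' @return `newdata` with one added estimate column per index:
#'   `est_map_mmHg`, `est_sbp_mmHg`, `est_dbp_mmHg`.
#' @export
predict.bp_model <- function(object, newdata, ...) {
  check_columns(newdata, c("hr_bpm", "ln_mnpv"), "newdata")
  if (any(newdata$hr_bpm <= 0, na.rm = TRUE)) abort("invalid HR")
  out <- tibble::as_tibble(newdata)
  cf <- object$coefficients
  for (i in seq_len(nrow(cf))) {
    out[[paste0("est_", cf$index[i], "_mmHg")]] <-
      exp(cf$a[i] * log(newdata$hr_bpm) + cf$b[i] * newdata$ln_mnpv +
            cf$c[i])
  }
  out
}

#' Residual diagnostics of a calibrated model
#'
#' Computes, per index, mmHg-scale residuals (reference minus estimate) on
#' the calibration rows, the correlation of estimates with residuals, and a
#' Shapiro-Wilk normality check of the residuals (delegated to
#' [stats::shapiro.test()]). With (near-)zero residual variance the
#' correlation and normality test are undefined and reported as `NA`.
#'
#' @param object A fitted `bp_model`.
#' @param data Calibration rows; defaults to the rows the model was fitted
#'   on.
#' @return A list with `residuals` (long tibble: `index`, `reference`,
#'   `estimate`, `residual`) and `summary` (per index: `r_est_resid`,
#'   `shapiro_p`, `normality_ok`, `n`).
#' @export
bp_evaluate <- function(object, data = object$data) {
  if (is.null(data)) abort("no calibration data available")
  est <- predict(object, data)
  residuals <- purrr::map_dfr(object$coefficients$index, function(ix) {
    ref_col <- paste0(ix, "_mmHg")
    check_columns(data, ref_col, "data")
    tibble::tibble(
      index = ix,
      reference = data[[ref_col]],
      estimate = est[[paste0("est_", ix, "_mmHg")]],
      residual = data[[ref_col]] - est[[paste0("est_", ix, "_mmHg")]]
    )
  })
  summary <- residuals |>
    dplyr::group_by(.data$index) |>
    dplyr::summarise(
      r_est_resid = if (dplyr::n() < 3 || sd(.data$residual) < 1e-12 ||
                          sd(.data$estimate) < 1e-12) NA_real_ else
        cor(.data$estimate, .data$residual),
      shapiro_p = if (dplyr::n() < 3 || sd(.data$residual) < 1e-12)
        NA_real_ else shapiro.test(.data$residual)$p.value,
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(normality_ok = is.na(.data$shapiro_p) |
                    .data$shapiro_p > 0.05)
  list(residuals = residuals, summary = summary)
}

#' Serialize a blood-pressure model to a plain-text file
#'
#' `write_bp_model()` writes one CSV line per index (`index,a,b,c,r`);
#' `read_bp_model()` reads it back into a `bp_model` usable with
#' [predict.bp_model()] without refitting.
#'
#' @param object A `bp_model`.
#' @param path File path.
#' @return `write_bp_model()` returns `path` invisibly; `read_bp_model()`
#'   a `bp_model`.
#' @export
write_bp_model <- function(object, path) {
  cf <- object$coefficients[c("index", "a", "b", "c", "r")]
  readr::write_csv(cf, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_bp_model
#' @export
read_bp_model <- function(path) {
  cf <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(cf, c("index", "a", "b", "c"), "model file")
  m <- bp_model(purrr::map(
    rlang::set_names(cf$index),
    function(ix) unlist(cf[cf$index == ix, c("a", "b", "c")])
  ))
  if ("r" %in% names(cf)) m$coefficients$r <- cf$r
  m
}
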