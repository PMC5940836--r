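#' Run the full cuffless blood-pressure pipeline
#'
#' Composes the stages end to end: beat detection
#' ([detect_beats()]), feature extraction ([beat_features()]),
#' sliding-window outlier flagging ([flag_outliers()]), block averaging
#' ([block_average()]) on the blocks carrying reference cuff readings,
#' log-linear calibration ([bp_calibrate()]), prediction
#' ([predict.bp_model()]) and agreement analytics ([gm_regression()],
#' [bland_altman()]) of estimated versus reference pressures per index.
#' The result equals running the stages individually on the same inputs,
#' and is deterministic for fixed inputs.
#'
#' @param record A [ppg_record()].
#' @param reference Tibble of cuff readings with columns `block_start_s`,
#'   `sbp_mmHg`, `dbp_mmHg` (one row per measured block; `map_mmHg`
#'   derived internally).
#' @param block_len_s Averaging block length, seconds.
#' @param detect Named list of arguments forwarded to [detect_beats()].
#' @param filter Named list of arguments forwarded to [flag_outliers()].
#' @param indices Blood-pressure indices to calibrate.
#' @param limit_multiplier Bland-Altman band half-width in SD units.
#' @param invert Passed to both detection and feature extraction.
#'
#' @return A list of class `bp_pipeline`: `beats` (flagged beat table),
#'   `blocks` (block summaries), `calibration` (valid blocks joined with
#'   reference readings), `model` (a `bp_model`), `estimates` (calibration
#'   rows with `est_*_mmHg` columns), `agreement` (per-index tibble of GMR
#'   slope/intercept/r and Bland-Altman bias/limits), and `evaluation`
#'   (residual diagnostics from [bp_evaluate()]).
#' @export
bp_pipeline <- function(record, reference, block_len_s = 45,
                        detect = list(), filter = list(),
                        indices = bp_indices, limit_multiplier = 1,
                        invert = FALSE) {
  check_columns(reference, c("block_start_s", "sbp_mmHg", "dbp_mmHg"),
                "reference")
  onsets <- do.call(detect_beats,
                    c(list(record = record, invert = invert), detect))
  beats <- beat_features(record, onsets, invert = invert)
  beats <- do.call(flag_outliers, c(list(beats = beats), filter))
  blocks <- block_average(beats, reference$block_start_s,
                          block_len_s = block_len_s)

  calibration <- dplyr::bind_cols(
    blocks[c("block_start_s", "mean_hr", "mean_ln_mnpv", "status")],
    reference[c("sbp_mmHg", "dbp_mmHg")]
  ) |>
    dplyr::filter(.data$status == "valid") |>
    dplyr::rename(hr_bpm = "mean_hr", ln_mnpv = "mean_ln_mnpv") |>
    dplyr::mutate(map_mmHg = map_from_sbp_dbp(.data$sbp_mmHg,
                                              .data$dbp_mmHg))

  model <- bp_calibrate(calibration, indices = indices)
  estimates <- predict(model, calibration)

  agreement <- purrr::map_dfr(indices, function(ix) {
    est <- estimates[[paste0("est_", ix, "_mmHg")]]
    ref <- estimates[[paste0(ix, "_mmHg")]]
    g <- gm_regression(est, ref)
    ba <- bland_altman(est, ref, limit_multiplier = limit_multiplier)
    dplyr::bind_cols(tibble::tibble(index = ix),
                     tidy(g)[c("slope", "intercept", "r")],
                     tidy(ba)[c("bias", "sd_diff", "lower", "upper")],
                     tibble::tibble(n = g$n))
  })

  structure(
    list(beats = beats, blocks = blocks, calibration = calibration,
         model = model, estimates = estimates, agreement = agreement,
         evaluation = bp_evaluate(model, calibration)),
    class = "bp_pipeline"
  )
}

#' @export
print.bp_pipeline <- function(x, ...) {
  cat(sprintf(
    "Cuffless BP pipeline: %d beats (%d outliers), %d/%d valid blocks\n",
    nrow(x$beats), sum(x$beats$outlier),
    sum(x$blocks$status == "valid"), nrow(x$blocks)
  ))
  print(x$agreement, ...)
  invisible(x)
}
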