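#' Flag outlying beats with the sliding-window SD rule
#'
#' Walks the beat series in time order and flags a beat as an outlier when
#' it is what pushes the standard deviation of the preceding window above
#' the acceptance limit: with `w` the accepted (non-flagged) beats whose
#' onsets lie in the `window_s` seconds before the candidate, the candidate
#' is flagged if `sd(c(w, candidate)) > limit` while `sd(w) <= limit`, for
#' either the heart-rate series (limit `hr_sd_limit`, bpm) or the ln mNPV
#' series (limit `lnmnpv_sd_limit`, a.u.). Flagged beats are excluded from
#' all subsequent windows so one artifact cannot poison later decisions.
#' Beats with fewer than two accepted predecessors in the window (the
#' warm-up region) are never flagged. Sample SDs use the n-1 denominator.
#' The rule is causal: flags depend only on beats at or before the
#' candidate.
#'
#' @param beats Beat tibble from [beat_features()] (columns `onset_s`,
#'   `hr_bpm`, `ln_mnpv` required), in time order.
#' @param window_s Length of the preceding reference window, seconds.
#' @param hr_sd_limit Maximum acceptable window SD of heart rate, bpm.
#' @param lnmnpv_sd_limit Maximum acceptable window SD of ln mNPV, a.u.
#' @return `beats` with the logical `outlier` column set. Empty input is
#'   returned unchanged.
#' @export
flag_outliers <- function(beats, window_s = 10, hr_sd_limit = 8.0,
                          lnmnpv_sd_limit = 0.25) {
  check_number(window_s, "window_s", positive = TRUE)
  check_number(hr_sd_limit, "hr_sd_limit", positive = TRUE)
  check_number(lnmnpv_sd_limit, "lnmnpv_sd_limit", positive = TRUE)
  if (nrow(beats) == 0) {
    beats$outlier <- logical(0)
    return(beats)
  }
  check_columns(beats, c("onset_s", "hr_bpm", "ln_mnpv"), "beats")
  if (is.unsorted(beats$onset_s)) abort("`beats` must be time-ordered")

  t <- beats$onset_s
  hr <- beats$hr_bpm
  ln_mnpv <- beats$ln_mnpv
  n <- nrow(beats)
  flag <- logical(n)
  for (i in seq_len(n)) {
    w <- which(!flag[seq_len(i - 1)] & t[seq_len(i - 1)] >= t[i] - window_s &
                 t[seq_len(i - 1)] < t[i])
    if (length(w) < 2) next
    flag[i] <- exceeds_with_candidate(hr[w], hr[i], hr_sd_limit) ||
      exceeds_with_candidate(ln_mnpv[w], ln_mnpv[i], lnmnpv_sd_limit)
  }
  beats$outlier <- flag
  beats
}

# candidate pushes the window SD over the limit: SD(window + candidate)
# exceeds it while SD(window) alone does not; NA values never trigger
exceeds_with_candidate <- function(window_vals, candidate, limit) {
  vals <- window_vals[!is.na(window_vals)]
  if (length(vals) < 2 || is.na(candidate)) return(FALSE)
  sd(c(vals, candidate)) > limit && sd(vals) <= limit
}

#' Average beats over fixed-length blocks with the missing-value rule
#'
#' Computes, for each requested block, the arithmetic means of heart rate
#' and ln mNPV over the non-outlier beats whose onset lies in
#' `[start, start + block_len_s)`. A block is `"missing"` when it contains
#' no beats or when strictly more than 20% of its beats are flagged
#' outliers (a block with exactly 20% outliers is still valid); otherwise
#' it is `"valid"`.
#'
#' @param beats Flagged beat tibble (see [flag_outliers()]).
#' @param block_starts Numeric vector of block start times, seconds.
#' @param block_len_s Block length, seconds (default 45, one quarter of a
#'   3-minute condition period).
#' @param max_outlier_frac Outlier fraction strictly above which a block is
#'   treated as missing.
#' @return A tibble with one row per block: `block_start_s`, `block_len_s`,
#'   `mean_hr`, `mean_ln_mnpv`, `n_beats`, `n_outliers`, `status`
#'   (`"valid"` or `"missing"`). Means are `NA` for missing blocks.
#' @export
block_average <- function(beats, block_starts, block_len_s = 45,
                          max_outlier_frac = 0.20) {
  check_number(block_len_s, "block_len_s", positive = TRUE)
  check_columns(beats, c("onset_s", "hr_bpm", "ln_mnpv", "outlier"),
                "beats")
  purrr::map_dfr(block_starts, function(start) {
    inb <- beats$onset_s >= start & beats$onset_s < start + block_len_s
    n_beats <- sum(inb)
    n_out <- sum(beats$outlier[inb])
    missing <- n_beats == 0 || n_out / n_beats > max_outlier_frac
    good <- inb & !beats$outlier
    tibble::tibble(
      block_start_s = start,
      block_len_s = block_len_s,
      mean_hr = if (missing || !any(good)) NA_real_ else
        mean(beats$hr_bpm[good]),
      mean_ln_mnpv = if (missing || !any(good)) NA_real_ else
        mean(beats$ln_mnpv[good], na.rm = TRUE),
      n_beats = n_beats,
      n_outliers = n_out,
      status = if (missing) "missing" else "valid"
    )
  })
}
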