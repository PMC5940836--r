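#' Construct a PPG record
#'
#' A `ppg_record` is a tibble with columns `time` (seconds) and `value`
#' (signal amplitude, arbitrary units or mV) holding a uniformly sampled
#' photoplethysmogram, with the sampling rate and a channel label stored as
#' attributes. It is the input type of [detect_beats()] and
#' [beat_features()].
#'
#' @param value Numeric vector of signal samples; all values must be finite
#'   and at least two samples are required.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param start_time Time of the first sample, seconds. Default 0.
#' @param channel Free-text channel label, e.g. `"transmittance-IR"` or
#'   `"reflectance-green"`.
#'
#' @return A tibble of class `ppg_record` with columns `time` and `value`.
#' @examples
#' rec <- ppg_record(sin(seq(0, 10, by = 1 / 60)) + 10, sampling_rate = 60)
#' sampling_rate(rec)
#' @export
ppg_record <- function(value, sampling_rate, start_time = 0,
                       channel = "ppg") {
  check_number(sampling_rate, "sampling_rate", positive = TRUE)
  check_number(start_time, "start_time")
  if (!is.numeric(value) || length(value) < 2L) {
    abort("`value` must be a numeric vector with at least 2 samples")
  }
  if (!all(is.finite(value))) abort("`value` must contain only finite samples")
  out <- tibble::tibble(
    time = start_time + (seq_along(value) - 1) / sampling_rate,
    value = as.numeric(value)
  )
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "channel") <- channel
  class(out) <- c("ppg_record", class(out))
  out
}

#' @rdname ppg_record
#' @param x A `ppg_record`.
#' @export
sampling_rate <- function(x) {
  rate <- attr(x, "sampling_rate")
  if (is.null(rate)) abort("`x` has no sampling_rate attribute")
  rate
}

#' Ground-truth beat annotations of a simulated record
#'
#' Returns the per-beat ground truth attached by [simulate_ppg()]: onset
#' time, inter-beat interval, heart rate, AC amplitude, DC level and mNPV of
#' every complete simulated beat.
#'
#' @param x A `ppg_record` produced by [simulate_ppg()].
#' @return A tibble with columns `onset_s`, `ibi_ms`, `hr_bpm`, `ac`, `dc`,
#'   `mnpv`, `ln_mnpv`.
#' @export
pulse_truth <- function(x) {
  truth <- attr(x, "truth")
  if (is.null(truth)) abort("`x` carries no ground-truth annotations")
  truth
}

#' Read and write PPG and beat tables
#'
#' `read_ppg_csv()` reads a single-channel PPG from a CSV file with either a
#' `time_s,value` header (rate inferred from the time column unless given)
#' or a bare `value` column (rate required). `write_beats_csv()` /
#' `read_beats_csv()` round-trip the beat table produced by
#' [beat_features()].
#'
#' @param path File path.
#' @param rate Sampling rate in Hz; required when the file has no `time_s`
#'   column, otherwise overrides the inferred rate.
#' @param channel Channel label stored on the record.
#' @return `read_ppg_csv()` returns a [ppg_record()]; `read_beats_csv()`
#'   returns a beat tibble; `write_beats_csv()` returns `path` invisibly.
#' @export
read_ppg_csv <- function(path, rate = NULL, channel = "ppg") {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"value" %in% names(dat)) abort("PPG CSV must have a `value` column")
  start <- 0
  if ("time_s" %in% names(dat)) {
    dt <- diff(dat$time_s)
    if (any(dt <= 0)) abort("`time_s` must be strictly increasing")
    if (is.null(rate)) rate <- 1 / median(dt)
    start <- dat$time_s[1]
  } else if (is.null(rate)) {
    abort("no `time_s` column: a sampling `rate` is required")
  }
  ppg_record(dat$value, sampling_rate = rate, start_time = start,
             channel = channel)
}

#' @rdname read_ppg_csv
#' @param beats A beat tibble (see [beat_features()]).
#' @export
write_beats_csv <- function(beats, path) {
  check_columns(beats, beat_cols(), "beats")
  readr::write_csv(beats[beat_cols()], path, progress = FALSE)
  invisible(path)
}

#' @rdname read_ppg_csv
#' @export
read_beats_csv <- function(path) {
  beats <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(beats, setdiff(beat_cols(), "outlier"), "beats")
  if (!"outlier" %in% names(beats)) beats$outlier <- FALSE
  beats$outlier <- as.logical(beats$outlier)
  beats
}

beat_cols <- function() {
  c("onset_s", "ibi_ms", "hr_bpm", "ac", "dc", "mnpv", "ln_mnpv", "outlier")
}
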