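#' Band-limit a PPG record for onset detection
#'
#' Returns a zero-phase band-passed copy of the signal (2nd-order
#' Butterworth forward-backward filter). The conditioned copy is used only
#' to locate pulse feet; AC/DC feature extraction always reads the raw
#' signal so the DC level is preserved.
#'
#' @param record A [ppg_record()].
#' @param band Pass band in Hz, `c(low, high)`. The high cutoff is the
#'   default 8 Hz or, if lower, 90% of the Nyquist frequency; both cutoffs
#'   must lie below Nyquist.
#' @return A `ppg_record` of the conditioned signal.
#' @export
condition_ppg <- function(record, band = c(0.5, 8)) {
  rate <- sampling_rate(record)
  nyq <- rate / 2
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1]) {
    abort("invalid filter configuration")
  }
  if (band[1] >= nyq) abort("invalid filter configuration")
  band[2] <- min(band[2], 0.9 * nyq)
  if (band[2] >= nyq || band[2] <= band[1]) {
    abort("invalid filter configuration")
  }
  x <- record$value
  n <- length(x)
  # reflect-pad so filtfilt start-up transients stay outside the record
  pad <- min(n - 1L, as.integer(ceiling(3 * rate / band[1])))
  xp <- c(rev(x[seq_len(pad) + 1L]), x, rev(x[n - seq_len(pad)]))
  bf <- signal::butter(2, band / nyq, type = "pass")
  yp <- signal::filtfilt(bf, xp)
  y <- yp[pad + seq_len(n)]
  out <- ppg_record(y, sampling_rate = rate,
                    start_time = record$time[1],
                    channel = paste0(attr(record, "channel"), "-bandpassed"))
  out
}

#' Detect pulse feet (beat onsets) in a PPG record
#'
#' Locates one onset per cardiac pulse at the pulse foot: the local minimum
#' preceding the systolic upstroke. Systolic peaks are first found on a
#' band-passed copy of the signal (see [condition_ppg()]) as local maxima
#' exceeding a prominence fraction of the running signal amplitude, with a
#' refractory period enforced by keeping the higher of two competing peaks;
#' the foot is the conditioned-signal minimum between consecutive peaks,
#' refined on the raw signal and interpolated to sub-sample precision.
#'
#' @param record A [ppg_record()], oriented so a pulse is a positive
#'   deflection (use `invert` otherwise).
#' @param refractory_s Minimum spacing between onsets, seconds. The default
#'   0.25 s caps detectable heart rate at 240 bpm.
#' @param prominence Minimum peak height as a fraction of the running
#'   (2-s rolling maximum) amplitude of the conditioned signal.
#' @param band Detection pass band in Hz, handed to [condition_ppg()].
#' @param condition If `FALSE`, peaks and feet are searched on the raw
#'   signal (useful for already-filtered input).
#' @param invert Negate the signal before detection (transmittance devices
#'   where more blood means less light).
#'
#' @return A tibble with one row per detected beat: `onset` (sample index
#'   into `record`) and `onset_s` (sub-sample interpolated onset time,
#'   seconds), strictly increasing.
#' @export
detect_beats <- function(record, refractory_s = 0.25, prominence = 0.3,
                         band = c(0.5, 8), condition = TRUE,
                         invert = FALSE) {
  rate <- sampling_rate(record)
  x_raw <- if (invert) -record$value else record$value
  n <- length(x_raw)
  if (n / rate < 2 * refractory_s) abort("signal too short")
  if (diff(range(x_raw)) == 0) abort("no beats found")

  rec_work <- ppg_record(x_raw, sampling_rate = rate,
                         start_time = record$time[1])
  x <- if (condition) condition_ppg(rec_work, band = band)$value else x_raw

  peaks <- find_systolic_peaks(x, rate, refractory_s, prominence)
  if (length(peaks) == 0) abort("no beats found")

  feet <- integer(length(peaks))
  lookback <- if (length(peaks) >= 2) {
    as.integer(round(stats::median(diff(peaks))))
  } else {
    as.integer(round(0.6 * rate))
  }
  for (k in seq_along(peaks)) {
    lo <- if (k == 1) max(1L, peaks[1] - lookback) else peaks[k - 1] + 1L
    feet[k] <- foot_before_peak(x, peaks[k], lo)
  }
  # refine on the raw signal near the conditioned-signal foot; band
  # limiting smears the foot corner, so allow up to 30 ms (>= 1 sample)
  # and break flat-plateau ties towards the upstroke
  r <- max(1L, as.integer(round(0.03 * rate)))
  onset_t <- numeric(length(feet))
  for (k in seq_along(feet)) {
    seg <- max(1L, feet[k] - r):min(n, feet[k] + r)
    mins <- seg[x_raw[seg] == min(x_raw[seg])]
    feet[k] <- mins[length(mins)]
    onset_t[k] <- record$time[1] +
      (feet[k] - 1 + subsample_min_offset(x_raw, feet[k])) / rate
  }
  keep <- !duplicated(feet)
  tibble::tibble(onset = feet[keep], onset_s = onset_t[keep])
}

# local maxima of the conditioned signal above a running-amplitude
# prominence threshold, thinned to one peak per refractory period (higher
# peak wins)
find_systolic_peaks <- function(x, rate, refractory_s, prominence) {
  n <- length(x)
  if (n < 3) return(integer(0))
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(idx) == 0) return(integer(0))
  # running amplitude: rolling max of |x| over ~2 s, evaluated on a coarse
  # grid and linearly interpolated
  win <- max(3L, as.integer(round(2 * rate)))
  step <- max(1L, as.integer(round(rate / 10)))
  grid <- unique(c(seq(1L, n, by = step), n))
  amp_grid <- vapply(grid, function(i) {
    max(abs(x[max(1L, i - win %/% 2):min(n, i + win %/% 2)]))
  }, numeric(1))
  amp <- approx(grid, amp_grid, xout = seq_len(n), rule = 2)$y
  floor_abs <- 1e-12 * max(abs(x))
  idx <- idx[x[idx] > pmax(prominence * amp[idx], floor_abs) & x[idx] > 0]
  if (length(idx) == 0) return(integer(0))
  refr <- as.integer(round(refractory_s * rate))
  acc <- integer(0)
  for (i in idx[order(x[idx], decreasing = TRUE)]) {
    if (length(acc) == 0 || all(abs(i - acc) >= refr)) acc <- c(acc, i)
  }
  sort(acc)
}

# nearest local minimum of x strictly before index `peak`, bounded below
# by `lo`; falls back to the interval minimum when the signal is monotone
# down to `lo`
foot_before_peak <- function(x, peak, lo) {
  i <- peak - 1L
  while (i > lo) {
    if (x[i] <= x[i - 1] && x[i] < x[i + 1]) return(i)
    i <- i - 1L
  }
  seg <- lo:peak
  seg[which.min(x[seg])]
}

# parabolic interpolation of a sampled minimum; returns a fractional
# offset in (-0.5, 0.5] samples, 0 at record edges or degenerate curvature
subsample_min_offset <- function(x, i) {
  n <- length(x)
  if (i <= 1L || i >= n) return(0)
  denom <- x[i - 1] - 2 * x[i] + x[i + 1]
  if (denom <= 0) return(0)
  off <- 0.5 * (x[i - 1] - x[i + 1]) / denom
  max(min(off, 0.5), -0.5)
}

#' Extract beat-by-beat heart rate and mNPV features
#'
#' Converts consecutive onset pairs into one feature row per beat. For the
#' beat spanning onsets \eqn{[o_k, o_{k+1})}: the inter-beat interval (IBI)
#' is the onset-to-onset time in ms, heart rate HR = 60000 / IBI bpm, the
#' AC amplitude is the within-beat signal maximum minus the value at the
#' onset (foot), the DC level is the within-beat mean of the raw signal,
#' and the modified normalized pulse volume mNPV = AC / DC with
#' `ln_mnpv = log(mnpv)` (`NA` for a zero-amplitude beat). Features are
#' always read from the raw (unconditioned) signal.
#'
#' @param record A [ppg_record()].
#' @param onsets Output of [detect_beats()] (or an integer vector of onset
#'   sample indices).
#' @param invert Negate the signal before feature extraction; must match
#'   the `invert` used in detection.
#' @return A tibble with one row per beat and columns `onset_s`, `ibi_ms`,
#'   `hr_bpm`, `ac`, `dc`, `mnpv`, `ln_mnpv`, `outlier` (initialized
#'   `FALSE`; set by [flag_outliers()]).
#' @export
beat_features <- function(record, onsets, invert = FALSE) {
  x <- if (invert) -record$value else record$value
  rate <- sampling_rate(record)
  if (is.data.frame(onsets)) {
    check_columns(onsets, "onset", "onsets")
    idx <- onsets$onset
    t_on <- if ("onset_s" %in% names(onsets)) onsets$onset_s else
      record$time[idx]
  } else {
    idx <- as.integer(onsets)
    t_on <- record$time[idx]
  }
  if (length(idx) < 2) abort("at least 2 onsets are required")
  if (any(diff(idx) <= 0)) abort("`onsets` must be strictly increasing")

  n_beats <- length(idx) - 1L
  ac <- dc <- numeric(n_beats)
  for (k in seq_len(n_beats)) {
    seg <- idx[k]:(idx[k + 1] - 1L)
    ac[k] <- max(x[seg]) - x[idx[k]]
    dc[k] <- mean(x[seg])
  }
  if (any(dc <= 0)) abort("non-positive DC level")
  ibi_ms <- diff(t_on) * 1000
  mnpv <- ac / dc
  tibble::tibble(
    onset_s = t_on[seq_len(n_beats)],
    ibi_ms = ibi_ms,
    hr_bpm = 60000 / ibi_ms,
    ac = ac,
    dc = dc,
    mnpv = mnpv,
    ln_mnpv = ifelse(mnpv > 0, log(mnpv), NA_real_),
    outlier = FALSE
  )
}
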