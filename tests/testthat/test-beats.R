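test_that("a noiseless 75-bpm train is detected beat-perfectly", {
  for (fs in c(60, 1000)) {
    rec <- simulate_ppg(duration_s = 30, sampling_rate = fs, hr_bpm = 75,
                        seed = 1)
    onsets <- detect_beats(rec)
    expect_true(all(diff(onsets$onset) > 0))
    # ~37.5 beat periods in 30 s
    expect_lte(abs(nrow(onsets) - 1 - 37), 1)
    beats <- beat_features(rec, onsets)
    expect_equal(beats$hr_bpm, rep(75, nrow(beats)), tolerance = 1e-6)
    # detected feet match generator ground truth within one sample
    tr <- pulse_truth(rec)
    k <- min(nrow(onsets), nrow(tr))
    expect_lt(max(abs(onsets$onset_s[1:k] - tr$onset_s[1:k])), 1 / fs)
  }
})

test_that("per-beat features recover generator ground truth", {
  rec <- simulate_ppg(duration_s = 30, sampling_rate = 60, hr_bpm = 75,
                      ac = 0.53, dc = 20, seed = 1)
  beats <- beat_features(rec, detect_beats(rec))
  tr <- pulse_truth(rec)[seq_len(nrow(beats)), ]
  expect_lt(max(abs(beats$ibi_ms - tr$ibi_ms)), 1000 / 60) # 1 sample
  expect_lt(max(abs(beats$ac / tr$ac - 1)), 0.01)
  expect_lt(max(abs(beats$dc / tr$dc - 1)), 0.01)
})

test_that("a flat signal has no beats and a short one is rejected", {
  flat <- ppg_record(rep(10, 600), sampling_rate = 60)
  expect_error(detect_beats(flat), "no beats found")
  short <- ppg_record(c(1, 2, 3), sampling_rate = 60)
  expect_error(detect_beats(short), "signal too short")
})

test_that("doubling one beat's amplitude does not move detected feet", {
  fs <- 60
  base <- simulate_ppg(duration_s = 30, sampling_rate = fs, hr_bpm = 60,
                       ac = 0.5, dc = 20, seed = 1)
  bumped <- simulate_ppg(duration_s = 30, sampling_rate = fs, hr_bpm = 60,
                         ac = function(t) ifelse(t >= 14 & t < 15, 1.0, 0.5),
                         dc = 20, seed = 1)
  on_a <- detect_beats(base)
  on_b <- detect_beats(bumped)
  expect_equal(nrow(on_a), nrow(on_b))
  # the amplitude step allows at most ~1 sample of local wobble
  expect_lt(max(abs(on_a$onset_s - on_b$onset_s)), 1.5 / fs)
})

test_that("band-pass conditioning rejects mains interference", {
  fs <- 1000
  clean <- simulate_ppg(duration_s = 20, sampling_rate = fs, hr_bpm = 75,
                        seed = 1)
  noisy <- clean
  noisy$value <- noisy$value + 0.2 * sin(2 * pi * 50 * noisy$time)
  attr(noisy, "truth") <- NULL
  on_clean <- detect_beats(clean)
  on_noisy <- detect_beats(noisy)
  expect_equal(nrow(on_clean), nrow(on_noisy))
  # feet within 5 ms despite 50-Hz ripple on the raw trace
  expect_lt(max(abs(on_clean$onset_s - on_noisy$onset_s)), 0.005)
  hr_clean <- beat_features(clean, on_clean)$hr_bpm
  hr_noisy <- beat_features(noisy, on_noisy)$hr_bpm
  expect_lt(max(abs(hr_noisy - 75)), 1)
  expect_lt(max(abs(hr_clean - 75)), 0.1)
})

test_that("conditioning is a no-op for detection on a clean signal", {
  rec <- simulate_ppg(duration_s = 30, sampling_rate = 60, hr_bpm = 75,
                      seed = 1)
  on_c <- detect_beats(rec, condition = TRUE)
  on_r <- detect_beats(rec, condition = FALSE)
  # a truncated final beat may be seen by one path only
  k <- min(nrow(on_c), nrow(on_r))
  expect_lte(abs(nrow(on_c) - nrow(on_r)), 1)
  expect_lt(max(abs(on_c$onset_s[1:k] - on_r$onset_s[1:k])), 1 / 60)
})

test_that("inverted (transmittance) signals detect identically", {
  rec <- simulate_ppg(duration_s = 20, sampling_rate = 60, hr_bpm = 80,
                      seed = 2)
  inv <- rec
  inv$value <- -inv$value
  on <- detect_beats(rec)
  on_inv <- detect_beats(inv, invert = TRUE)
  expect_equal(on$onset, on_inv$onset)
})

test_that("feature arithmetic follows the AC/DC definitions", {
  # one beat: onset value 9, max 11, mean 10 -> ac 2, dc 10, mnpv 0.2
  x <- c(9, 11, 10, 10, 9, 11, 10, 10)
  rec <- ppg_record(x, sampling_rate = 5) # 4 samples = 800 ms per beat
  beats <- beat_features(rec, onsets = c(1L, 5L))
  expect_equal(beats$ac, 2)
  expect_equal(beats$dc, 10)
  expect_equal(beats$mnpv, 0.2)
  expect_equal(beats$ln_mnpv, log(0.2))
  expect_equal(beats$ibi_ms, 800)
  expect_equal(beats$hr_bpm, 75)
})

test_that("a DC offset moves dc but not ac; inverted input errors", {
  rec <- simulate_ppg(duration_s = 20, sampling_rate = 60, hr_bpm = 75,
                      seed = 1)
  onsets <- detect_beats(rec)
  base <- beat_features(rec, onsets)
  shifted <- rec
  shifted$value <- shifted$value + 100
  up <- beat_features(shifted, onsets)
  expect_equal(up$ac, base$ac)
  expect_equal(up$dc, base$dc + 100)

  neg <- rec
  neg$value <- neg$value - 100 # dc becomes negative
  expect_error(beat_features(neg, onsets), "non-positive DC level")
})

test_that("mNPV is invariant under positive gain", {
  for (seed in 1:5) {
    rec <- simulate_ppg(duration_s = 20, sampling_rate = 60,
                        hr_bpm = 70 + 5 * seed, noise_sd = 0.01,
                        seed = seed)
    onsets <- detect_beats(rec)
    b1 <- beat_features(rec, onsets)
    k <- stats::runif(1, 0.5, 20)
    scaled <- rec
    scaled$value <- scaled$value * k
    expect_identical(detect_beats(scaled)$onset, onsets$onset)
    b2 <- beat_features(scaled, onsets)
    expect_equal(b2$mnpv, b1$mnpv, tolerance = 1e-12)
    expect_equal(b2$ac, b1$ac * k, tolerance = 1e-12)
    expect_equal(b2$dc, b1$dc * k, tolerance = 1e-12)
  }
})

test_that("hr x ibi = 60000 exactly and HR rises when IBIs shrink", {
  rec <- simulate_ppg(duration_s = 25, sampling_rate = 60, hr_bpm = 68,
                      noise_sd = 0.02, seed = 9)
  beats <- beat_features(rec, detect_beats(rec))
  expect_equal(beats$hr_bpm * beats$ibi_ms, rep(60000, nrow(beats)))

  fast <- simulate_ppg(duration_s = 25, sampling_rate = 60, hr_bpm = 85,
                       seed = 9)
  slow_hr <- beat_features(rec, detect_beats(rec))$hr_bpm
  fast_hr <- beat_features(fast, detect_beats(fast))$hr_bpm
  expect_gt(min(fast_hr), max(slow_hr))
})

test_that("a typical smartphone-level mNPV is recovered on the ln scale", {
  dc <- 20
  rec <- simulate_ppg(duration_s = 60, sampling_rate = 60, hr_bpm = 75,
                      ac = dc * exp(-3.63), dc = dc, seed = 1)
  beats <- beat_features(rec, detect_beats(rec))
  expect_equal(mean(beats$ln_mnpv), -3.63, tolerance = 0.02)
})

test_that("filter configurations at or above Nyquist are rejected", {
  rec <- simulate_ppg(duration_s = 10, sampling_rate = 60, seed = 1)
  expect_error(condition_ppg(rec, band = c(30, 40)),
               "invalid filter configuration")
  expect_error(condition_ppg(rec, band = c(-1, 8)),
               "invalid filter configuration")
  expect_error(condition_ppg(rec, band = c(8, 2)),
               "invalid filter configuration")
})

test_that("conditioning preserves detection but zeroes the baseline", {
  rec <- simulate_ppg(duration_s = 20, sampling_rate = 60, dc = 50,
                      seed = 4)
  cond <- condition_ppg(rec)
  expect_lt(abs(mean(cond$value)), 0.05)
  expect_equal(sampling_rate(cond), 60)
})

test_that("zero-amplitude beats are emitted with mnpv 0 and flagged ln", {
  x <- c(9, 11, 10, 10, rep(10, 4), 9, 11, 10, 10)
  rec <- ppg_record(x, sampling_rate = 5)
  beats <- beat_features(rec, onsets = c(1L, 5L, 9L))
  expect_equal(beats$mnpv[2], 0)
  expect_true(is.na(beats$ln_mnpv[2]))
})
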