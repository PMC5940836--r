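# Independent brute-force oracles used to cross-check the implementation.

# O(n^2) re-derivation of the sliding-window outlier rule straight from its
# definition: for each beat, collect the accepted beats of the preceding
# window, test whether the candidate pushes the window SD over the limit
# for either series.
oracle_flag_outliers <- function(onset_s, hr, ln_mnpv, window_s = 10,
                                 hr_lim = 8.0, lnm_lim = 0.25) {
  n <- length(onset_s)
  flag <- rep(FALSE, n)
  pushes_over <- function(vals, cand, lim) {
    vals <- vals[!is.na(vals)]
    length(vals) >= 2 && !is.na(cand) &&
      stats::sd(c(vals, cand)) > lim && stats::sd(vals) <= lim
  }
  for (i in seq_len(n)) {
    prev <- which(seq_len(n) < i & !flag &
                    onset_s >= onset_s[i] - window_s & onset_s < onset_s[i])
    flag[i] <- pushes_over(hr[prev], hr[i], hr_lim) ||
      pushes_over(ln_mnpv[prev], ln_mnpv[i], lnm_lim)
  }
  flag
}

# closed-form geometric-mean-regression slope from explicit two-pass sums
oracle_gmr <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  vx <- sum((x - mx)^2) / (n - 1)
  vy <- sum((y - my)^2) / (n - 1)
  cxy <- sum((x - mx) * (y - my)) / (n - 1)
  r <- cxy / sqrt(vx * vy)
  slope <- (if (r < 0) -1 else 1) * sqrt(vy / vx)
  list(slope = slope, intercept = my - slope * mx, r = r)
}

# OLS coefficients by explicitly solving the normal equations
oracle_ols <- function(y, x1, x2) {
  X <- cbind(1, x1, x2)
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# random beat series with occasional large excursions, for oracle
# equivalence tests
random_beat_series <- function(n = 45, jump_prob = 0.1, hr_sd = 3,
                               lnm_sd = 0.1) {
  hr <- 75 + rnorm(n, sd = hr_sd)
  ln_mnpv <- -3.6 + rnorm(n, sd = lnm_sd)
  jumps <- runif(n) < jump_prob
  hr[jumps] <- hr[jumps] + sample(c(-1, 1), sum(jumps), TRUE) *
    runif(sum(jumps), 10, 40)
  jumps2 <- runif(n) < jump_prob
  ln_mnpv[jumps2] <- ln_mnpv[jumps2] + sample(c(-1, 1), sum(jumps2), TRUE) *
    runif(sum(jumps2), 0.4, 1.5)
  tibble::tibble(
    onset_s = cumsum(60 / hr) - 60 / hr[1],
    hr_bpm = hr,
    ln_mnpv = ln_mnpv,
    outlier = FALSE
  )
}

# step-profile waveform paired with model-generated cuff readings, for
# closed-loop pipeline tests
closed_loop_inputs <- function(n_blocks = 12, block_len = 45, fs = 60,
                               noise_sd = 0.02, ln_resid_sd = 0.005,
                               seed = 1) {
  withr::local_seed(seed)
  hr_vals <- runif(n_blocks, 62, 105)
  lnm_vals <- runif(n_blocks, -4.4, -3.3)
  step <- function(vals) {
    force(vals)
    function(t) vals[pmin(floor(t / block_len) + 1, length(vals))]
  }
  dc <- 20
  rec <- simulate_ppg(
    duration_s = n_blocks * block_len, sampling_rate = fs,
    hr_bpm = step(hr_vals), ac = step(dc * exp(lnm_vals)), dc = dc,
    noise_sd = noise_sd, seed = seed
  )
  cf <- default_coefficients()
  ln_bp <- function(cfv, eps) {
    exp(cfv[1] * log(hr_vals) + cfv[2] * lnm_vals + cfv[3] + eps)
  }
  reference <- tibble::tibble(
    block_start_s = (seq_len(n_blocks) - 1) * block_len,
    sbp_mmHg = ln_bp(cf$sbp, rnorm(n_blocks, sd = ln_resid_sd)),
    dbp_mmHg = ln_bp(cf$dbp, rnorm(n_blocks, sd = ln_resid_sd))
  )
  list(record = rec, reference = reference, hr = hr_vals, lnm = lnm_vals)
}
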