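test_that("the one-third MAP formula reproduces cuff summary values", {
  expect_equal(round(map_from_sbp_dbp(117.1, 76.9), 1), 90.3)
  expect_equal(round(map_from_sbp_dbp(134.6, 91.8), 1), 106.1)
  expect_error(map_from_sbp_dbp(100, 100), "invalid reading")
  expect_error(map_from_sbp_dbp(90, 110), "invalid reading")
  expect_error(map_from_sbp_dbp(100, -5), "invalid reading")
})

test_that("MAP is linear: MAP of means equals mean of MAPs", {
  withr::local_seed(5)
  sbp <- stats::runif(20, 100, 150)
  dbp <- stats::runif(20, 60, 95)
  expect_equal(mean(map_from_sbp_dbp(sbp, dbp)),
               map_from_sbp_dbp(mean(sbp), mean(dbp)))
})

test_that("fitting noiseless model data recovers coefficients exactly", {
  truth <- default_coefficients()
  calib <- simulate_cohort(residual_sd = 0, map_mode = "model", seed = 2)
  fit <- bp_calibrate(calib)
  cf <- fit$coefficients
  for (ix in c("map", "sbp", "dbp")) {
    got <- unlist(cf[cf$index == ix, c("a", "b", "c")])
    expect_equal(got, truth[[ix]], tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  expect_equal(glance(fit)$r, rep(1, 3), tolerance = 1e-9)
})

test_that("fitted coefficients match a normal-equations oracle", {
  withr::local_seed(8)
  calib <- simulate_cohort(seed = 8)
  fit <- bp_calibrate(calib, indices = "sbp")
  want <- oracle_ols(log(calib$sbp_mmHg), log(calib$hr_bpm),
                     calib$ln_mnpv)
  cf <- fit$coefficients
  expect_equal(cf$c, unname(want[1]), tolerance = 1e-10)
  expect_equal(cf$a, unname(want[2]), tolerance = 1e-10)
  expect_equal(cf$b, unname(want[3]), tolerance = 1e-10)
  # standardized coefficients follow beta * sd(x) / sd(y)
  expect_equal(cf$std_beta_a,
               cf$a * sd(log(calib$hr_bpm)) / sd(log(calib$sbp_mmHg)))
})

test_that("a pure-noise response gives R near zero and calibrated p-values", {
  withr::local_seed(21)
  n_reps <- 300
  p_a <- numeric(n_reps)
  r <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    dat <- tibble::tibble(
      hr_bpm = exp(rnorm(30, log(80), 0.2)),
      ln_mnpv = rnorm(30, -3.8, 0.4),
      sbp_mmHg = exp(rnorm(30, log(120), 0.1))
    )
    dat$dbp_mmHg <- dat$sbp_mmHg * 0.65
    fit <- bp_calibrate(dat, indices = "sbp")
    p_a[i] <- fit$coefficients$p_a
    r[i] <- fit$coefficients$r
  }
  expect_lt(mean(r), 0.35)
  # p-values approximately uniform under the null
  expect_lt(abs(mean(p_a < 0.05) - 0.05), 0.04)
  expect_lt(abs(mean(p_a) - 0.5), 0.06)
})

test_that("degenerate designs and tiny samples are rejected", {
  dat <- tibble::tibble(hr_bpm = rep(75, 10), ln_mnpv = rnorm(10, -3.6),
                        sbp_mmHg = stats::runif(10, 110, 130))
  dat$dbp_mmHg <- dat$sbp_mmHg * 0.65
  expect_error(bp_calibrate(dat, indices = "sbp"), "degenerate design")
  small <- simulate_cohort(seed = 1)[1:3, ]
  expect_error(bp_calibrate(small), "insufficient data")
})

test_that("prediction is the exponential back-transform", {
  ident <- bp_model(list(map = c(1, 0, 0)))
  got <- predict(ident, tibble::tibble(hr_bpm = 72, ln_mnpv = -3.5))
  expect_equal(got$est_map_mmHg, 72)

  pub <- bp_model(list(map = c(0.305, -0.084, 2.905)))
  est <- predict(pub, tibble::tibble(hr_bpm = 75, ln_mnpv = -3.63))
  # independent scalar computation of exp(a ln HR + b ln mNPV + c)
  expect_equal(est$est_map_mmHg,
               exp(0.305 * log(75) - 0.084 * (-3.63) + 2.905))
  expect_equal(est$est_map_mmHg, 92.4579, tolerance = 1e-4)

  expect_error(predict(pub, tibble::tibble(hr_bpm = -5, ln_mnpv = -3)),
               "invalid HR")
})

test_that("noiseless fit and predict round-trip to machine precision", {
  calib <- simulate_cohort(residual_sd = 0, map_mode = "model", seed = 4)
  fit <- bp_calibrate(calib)
  est <- predict(fit, calib)
  for (ix in c("map", "sbp", "dbp")) {
    expect_equal(est[[paste0("est_", ix, "_mmHg")]],
                 calib[[paste0(ix, "_mmHg")]], tolerance = 1e-8)
  }
})

test_that("predictions are positive and coherent under ln mNPV shifts", {
  fit <- bp_calibrate(simulate_cohort(seed = 6))
  newdata <- tibble::tibble(hr_bpm = c(40, 75, 200),
                            ln_mnpv = c(-8, -3.6, 2))
  est <- predict(fit, newdata)
  expect_true(all(est$est_map_mmHg > 0 & est$est_sbp_mmHg > 0 &
                    est$est_dbp_mmHg > 0))
  delta <- 0.3
  shifted <- predict(fit, dplyr::mutate(newdata,
                                        ln_mnpv = ln_mnpv + delta))
  b <- fit$coefficients$b[fit$coefficients$index == "map"]
  expect_equal(log(shifted$est_map_mmHg) - log(est$est_map_mmHg),
               rep(b * delta, 3))
})

test_that("residual diagnostics behave like OLS requires", {
  calib <- simulate_cohort(seed = 10)
  fit <- bp_calibrate(calib)
  # ln-scale residuals are orthogonal to fitted values by construction
  for (ix in c("map", "sbp", "dbp")) {
    m <- fit$fits[[ix]]
    expect_lt(abs(cor(fitted(m), resid(m))), 1e-10)
  }
  ev <- bp_evaluate(fit)
  expect_identical(nrow(ev$summary), 3L)
  expect_true(all(is.finite(ev$summary$r_est_resid)))

  # noiseless data: residuals are 0 and diagnostics not applicable
  ev0 <- bp_evaluate(bp_calibrate(
    simulate_cohort(residual_sd = 0, map_mode = "model", seed = 2)
  ))
  expect_true(all(is.na(ev0$summary$r_est_resid)))
})

test_that("mmHg-scale estimate-residual correlation is small at realistic noise", {
  rs <- vapply(1:200, function(i) {
    calib <- simulate_cohort(seed = 400 + i)
    ev <- bp_evaluate(bp_calibrate(calib, indices = "sbp"))
    ev$summary$r_est_resid
  }, numeric(1))
  expect_lt(mean(abs(rs)), 0.1)
})

test_that("models serialize to plain text and predict without refitting", {
  fit <- bp_calibrate(simulate_cohort(seed = 12))
  path <- withr::local_tempfile(fileext = ".txt")
  write_bp_model(fit, path)
  back <- read_bp_model(path)
  newdata <- tibble::tibble(hr_bpm = c(70, 95), ln_mnpv = c(-3.5, -4.2))
  expect_equal(predict(back, newdata), predict(fit, newdata),
               tolerance = 1e-12)
  expect_equal(back$coefficients$r, fit$coefficients$r, tolerance = 1e-12)
})

test_that("tidy and glance expose the fit in standard broom shapes", {
  fit <- bp_calibrate(simulate_cohort(seed = 13))
  td <- tidy(fit)
  expect_identical(nrow(td), 9L)
  expect_named(td, c("index", "term", "estimate", "std_estimate",
                     "p_value"))
  gl <- glance(fit)
  expect_identical(nrow(gl), 3L)
  expect_true(all(gl$r >= 0 & gl$r <= 1))
  expect_equal(gl$r_squared, gl$r^2)
})
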