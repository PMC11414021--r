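# ThT sigmoid feature extraction and TIRF elongation rates.

test_that("the lag identity t1/2 - 2*tau holds exactly on a noiseless Boltzmann", {
  tr <- gen_tht(lag = 15, rate = 100, plateau = 1000, duration = 40)
  # generator parameterization: tau = amp/(4 rate) = 2.5 h, thalf = 20 h
  f <- fit_sigmoid(tr)
  expect_true(f$aggregating)
  expect_equal(f$t_half, 20, tolerance = 1e-6)
  expect_equal(f$tau_g, 2.5, tolerance = 1e-6)
  expect_equal(f$lag_time, 15, tolerance = 1e-5)
  expect_equal(f$growth_rate, 100, tolerance = 1e-5)
  expect_equal(f$plateau, 1000, tolerance = 1e-4)
})

test_that("flat and decreasing traces are flagged non-aggregating", {
  withr::local_seed(3)
  t <- seq(0, 50, by = 1 / 6)
  flat <- tht_trace(t, 100 + rnorm(length(t), 0, 2))
  f <- fit_sigmoid(flat)
  expect_false(f$aggregating)
  expect_true(is.na(f$lag_time))
  dec <- tht_trace(t, 1000 * exp(-0.05 * t))
  expect_false(fit_sigmoid(dec)$aggregating)
})

test_that("30 h vs 40 h lag scenarios are recovered within 1 h and ordered", {
  # the TM/QM surfactant scenario: lag phases of 30 and 40 h
  lags <- c(tm = 30, qm = 40)
  est <- vapply(names(lags), function(v) {
    tr <- gen_tht(lag = lags[[v]], rate = 80, plateau = 800,
                  duration = 80,
                  noise = noise_spec("additive", 8,
                                     seed = derive_seed(101, v)))
    fit_sigmoid(tr)$lag_time
  }, numeric(1))
  expect_lt(abs(est[["tm"]] - 30), 1)
  expect_lt(abs(est[["qm"]] - 40), 1)
  expect_lt(est[["tm"]], est[["qm"]])
})

test_that("fit_sigmoid is affine-invariant in fluorescence", {
  tr <- gen_tht(lag = 12, rate = 50, plateau = 600, duration = 40,
                noise = noise_spec("additive", 5, seed = 9))
  f1 <- fit_sigmoid(tr)
  tr2 <- tht_trace(tr$time_h, 3 * tr$fluorescence + 250)
  f2 <- fit_sigmoid(tr2)
  expect_equal(f2$lag_time, f1$lag_time, tolerance = 1e-4)
  expect_equal(f2$t_half, f1$t_half, tolerance = 1e-4)
  expect_equal(f2$growth_rate, 3 * f1$growth_rate, tolerance = 1e-4)
})

test_that("tht_trace validates its invariants", {
  expect_error(tht_trace(1:5, 1:5), ">= 10 points")
  expect_error(tht_trace(c(1:9, 9), rep(1, 10)), "strictly increasing")
})

test_that("growth_rate_tirf divides net elongation by elapsed time", {
  # 20.088 um over 3 h is the wt average of 1.86 nm/s
  s <- fibril_length_series(c(0, 10800), c(0, 20.088))
  expect_equal(growth_rate_tirf(s)$rate_nm_s, 1.86)
  const <- fibril_length_series(c(0, 30, 60), c(5, 5, 5))
  g <- growth_rate_tirf(const)
  expect_identical(g$rate_nm_s, 0)
  expect_false(g$shrinkage)
  shr <- fibril_length_series(c(0, 100), c(5, 4))
  expect_true(growth_rate_tirf(shr)$shrinkage)
  expect_error(growth_rate_tirf(
    fibril_length_series(c(0, 1), c(0, 1))[c(1, 1), ]), "zero elapsed")
})

test_that("growth_rate_tirf is invariant to time origin and length offset", {
  s1 <- gen_fibril_growth(1.2, duration = 3600)
  s2 <- fibril_length_series(s1$time_s + 500, s1$length_um + 3)
  expect_equal(growth_rate_tirf(s1)$rate_nm_s,
               growth_rate_tirf(s2)$rate_nm_s)
})

test_that("ensemble mean of seeded fibril growth recovers the DM rate", {
  # 20 fibrils at a true rate of 0.39 nm/s with measurement noise
  rates <- vapply(1:20, function(i) {
    s <- gen_fibril_growth(0.39, duration = 10800, frame_interval = 30,
                           noise = noise_spec("additive", 0.3,
                                              seed = derive_seed(7, i)))
    growth_rate_tirf(s)$rate_nm_s
  }, numeric(1))
  sem <- stats::sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 0.39), max(2 * sem, 0.02))
})
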