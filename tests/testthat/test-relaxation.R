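# Mono-exponential decay / inversion-recovery fitting and the delta-R2
# association-rate estimator.

cpmg_delays <- seq(0, 0.25, length.out = 8)

test_that("noiseless decays are recovered exactly and match the log-linear oracle", {
  for (r2 in c(9.1, 13.4)) {
    s <- decay_series(cpmg_delays, exp(-r2 * cpmg_delays))
    fit <- fit_monoexponential_decay(s)
    expect_equal(fit$rate, r2, tolerance = 1e-9)
    expect_equal(fit$amplitude, 1, tolerance = 1e-9)
    # independent oracle: slope of ln I vs tau
    oracle <- -unname(coef(lm(log(s$intensity) ~ s$delay_s))[2])
    expect_lt(abs(fit$rate - oracle) / oracle, 1e-6)
  }
})

test_that("decay fit is scale-equivariant and unit-consistent", {
  s <- decay_series(cpmg_delays, 5 * exp(-9.1 * cpmg_delays))
  f1 <- fit_monoexponential_decay(s)
  f2 <- fit_monoexponential_decay(decay_series(s$delay_s,
                                               3 * s$intensity))
  expect_equal(f2$rate, f1$rate, tolerance = 1e-10)
  expect_equal(f2$amplitude, 3 * f1$amplitude, tolerance = 1e-10)
  # delays in ms instead of s multiply the rate by 10^3 exactly
  f3 <- fit_monoexponential_decay(decay_series(s$delay_s / 1000,
                                               s$intensity))
  expect_equal(f3$rate, 1000 * f1$rate, tolerance = 1e-6)
})

test_that("95% intervals cover the generating R2 in >= 90% of replicates", {
  # constant 1% relative noise -> inverse-variance weights 1/I^2 and a
  # t-based 95% interval (6 residual degrees of freedom at 8 delays)
  n_rep <- 200
  covered <- vapply(seq_len(n_rep), function(i) {
    s <- gen_decay(9.1, i0 = 1, delays = cpmg_delays,
                   noise = noise_spec("multiplicative", 0.01, seed = i))
    fit <- fit_monoexponential_decay(s, weights = 1 / s$intensity^2)
    q <- stats::qt(0.975, fit$df)
    ci <- fit$rate + c(-q, q) * fit$se
    ci[1] <= 9.1 && 9.1 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("degenerate and increasing series are handled", {
  expect_error(fit_monoexponential_decay(
    decay_series(cpmg_delays, rep(1, 8))), "degenerate")
  expect_warning(fit_monoexponential_decay(
    decay_series(cpmg_delays, exp(0.5 * cpmg_delays))), "increase")
})

test_that("inversion recovery recovers R1 = 3 exactly and crosses zero at ln2/R1", {
  t <- seq(0, 2, length.out = 12)
  s <- recovery_series(t, 1 - 2 * exp(-3 * t))
  fit <- fit_inversion_recovery(s)
  expect_equal(fit$rate, 3, tolerance = 1e-8)
  expect_equal(fit$efficiency, 1, tolerance = 1e-8)
  # analytic zero crossing of the fitted curve at a = 1
  t0 <- log(2 * fit$efficiency) / fit$rate
  expect_equal(t0, log(2) / 3, tolerance = 1e-8)
  model_at_t0 <- fit$amplitude *
    (1 - 2 * fit$efficiency * exp(-fit$rate * t0))
  expect_equal(model_at_t0, 0, tolerance = 1e-8)
})

test_that("inversion recovery tolerates noise and imperfect inversion", {
  s <- gen_recovery(3, iinf = 2, a = 0.92,
                    delays = seq(0, 2, length.out = 12),
                    noise = noise_spec("additive", 0.02, seed = 5))
  fit <- fit_inversion_recovery(s)
  expect_lt(abs(fit$rate - 3) / 3, 0.10)
  expect_lt(abs(fit$efficiency - 0.92), 0.1)
})

test_that("estimate_kon_app subtracts rates and flags no exchange", {
  est <- estimate_kon_app(13.4, 9.1)
  expect_equal(est$kon_app, 4.3)
  expect_false(est$no_exchange_detected)
  est0 <- estimate_kon_app(9.1, 9.1)
  expect_identical(est0$kon_app, 0)
  expect_true(est0$no_exchange_detected)
  neg <- estimate_kon_app(8.0, 9.1)
  expect_equal(neg$kon_app, -1.1)
  expect_true(neg$no_exchange_detected)
  # antisymmetry
  expect_equal(estimate_kon_app(12, 9)$kon_app,
               -estimate_kon_app(9, 12)$kon_app)
  expect_error(estimate_kon_app(Inf, 9.1), "r2_with_fibrils")
})
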