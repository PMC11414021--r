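# Forward Bloch-McConnell model: generator structure, propagation,
# limiting behaviour and the dual-route (expm vs adaptive ODE) oracle.

test_that("generator conserves Mz under pure exchange and decouples at kon = 0", {
  p <- wt_params()
  # zero all relaxation: exchange alone must conserve Mz_A + Mz_B
  p0 <- p
  p0$r1_free <- p0$r2_free <- p0$r1_dark <- p0$r2_dark <- 0
  G <- build_generator(p0, offset = 1000, rf_field = 0)
  iz <- c("MzA", "MzB")
  expect_equal(unname(colSums(G[iz, iz])), c(0, 0))
  # kon_app = 0: Mz_A dynamics independent of Mz_B
  pA <- wt_params(kon_app = 0)
  G <- build_generator(pA, offset = 1000, rf_field = 350)
  expect_identical(G["MzA", "MzB"] + G["MxA", "MxB"] + G["MyA", "MyB"],
                   p$koff * 3)  # back-exchange entries remain koff
  expect_identical(G["MzB", "MzA"], 0)
  expect_identical(G["MxB", "MxA"], 0)
})

test_that("generator rejects non-finite inputs naming the field", {
  p <- wt_params()
  expect_error(build_generator(p, offset = Inf, rf_field = 350), "offset")
  expect_error(build_generator(p, offset = 0, rf_field = -1), "rf_field")
})

test_that("all non-trivial eigenvalues have non-positive real part", {
  # stability of the dissipative generator over a grid of physical sets,
  # including the wt regime
  withr::local_seed(11)
  sets <- c(list(wt_params()), replicate(20, random_params(),
                                         simplify = FALSE))
  for (p in sets) {
    G <- build_generator(p, offset = stats::runif(1, -35000, 35000),
                         rf_field = sample(c(180, 350), 1))
    ev <- eigen(G[2:7, 2:7], only.values = TRUE)$values
    expect_true(all(Re(ev) <= 1e-9))
  }
})

test_that("attenuation is 1 with the RF off and far off-resonance", {
  p <- wt_params()
  expect_identical(simulate_attenuation(p, 5000, 0), 1)
  expect_equal(simulate_attenuation(p, 1e9, 350), 1, tolerance = 1e-3)
})

test_that("matrix-exponential and adaptive-ODE propagation agree", {
  # independent-oracle check on a randomized physical grid; the full
  # 50-set sweep runs in the acceptance suite
  withr::local_seed(7)
  for (i in 1:12) {
    p <- random_params()
    off <- stats::runif(1, -35000, 35000)
    rf <- sample(c(180, 350), 1)
    a_expm <- simulate_attenuation(p, off, rf, 0.7)
    a_ode <- simulate_attenuation(p, off, rf, 0.7, propagator = "ode")
    expect_lt(abs(a_expm - a_ode), 1e-6)
  }
  # cross-check against a third, external matrix exponential
  p <- wt_params()
  G <- build_generator(p, 5000, 350)
  M0 <- c(1, 0, 0, p$p_free, 0, 0, p$p_bound)
  m1 <- as.numeric(fibrildyn:::propagate_expm_cpp(G, M0, 0.7))
  m2 <- as.numeric(Matrix::expm(Matrix::Matrix(G * 0.7)) %*% M0)
  expect_equal(m1, m2, tolerance = 1e-8)
})

test_that("attenuation stays within [0, 1] across physical profiles", {
  withr::local_seed(23)
  for (i in 1:8) {
    prof <- simulate_profile(random_params(), small_scheme())
    expect_true(all(prof$attenuation >= -1e-8 &
                      prof$attenuation <= 1 + 1e-8))
  }
})

test_that("profiles are symmetric when both states sit on the carrier", {
  p <- wt_params(delta_free = 0, delta_dark = 0)
  s <- saturation_scheme(offsets = c(-20000, -5000, -1000,
                                     1000, 5000, 20000))
  prof <- simulate_profile(p, s)
  for (rf in s$rf_fields) {
    pr <- prof[prof$rf_field_hz == rf, ]
    plus <- pr$attenuation[match(c(1000, 5000, 20000), pr$offset_hz)]
    minus <- pr$attenuation[match(-c(1000, 5000, 20000), pr$offset_hz)]
    expect_lt(max(abs(plus - minus)), 1e-10)
  }
})

test_that("raising p_B * r2_dark broadens the saturation wing monotonically", {
  # halving koff at fixed kon_app raises p_B: attenuation must be
  # pointwise non-increasing at every off-resonance point
  s <- small_scheme()
  ladder <- c(3600, 1800, 900, 450)
  profs <- lapply(ladder, function(k) simulate_profile(wt_params(koff = k), s))
  for (i in seq_len(length(ladder) - 1)) {
    expect_true(all(profs[[i + 1]]$attenuation <=
                      profs[[i]]$attenuation + 1e-12))
  }
})

test_that("the no-exchange limit matches the closed-form CW steady state", {
  # p_B = 0, sat_time >= 10/R1: Mz_ss/M0 = R1(R2^2 + dw^2) /
  # (R1(R2^2 + dw^2) + w1^2 R2)
  p <- wt_params(kon_app = 0, delta_free = 0, delta_dark = 0)
  for (off in c(500, 2000, 10000)) {
    for (rf in c(180, 350)) {
      att <- simulate_attenuation(p, off, rf, sat_time = 10 / p$r1_free)
      dw <- 2 * pi * off
      w1 <- 2 * pi * rf
      ss <- p$r1_free * (p$r2_free^2 + dw^2) /
        (p$r1_free * (p$r2_free^2 + dw^2) + w1^2 * p$r2_free)
      expect_equal(att, ss, tolerance = 0.01)
    }
  }
})
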