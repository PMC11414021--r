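# Seeded synthetic-data generators: exactness at sigma = 0, determinism,
# noise calibration and lossless round trips through the CSV readers.

test_that("sigma = 0 reproduces the deterministic models exactly", {
  p <- wt_params()
  s <- small_scheme()
  expect_equal(gen_dest_dataset(p, s, noise_spec("additive", 0))$attenuation,
               simulate_profile(p, s)$attenuation)
  d <- gen_decay(13.4)
  expect_equal(d$intensity, exp(-13.4 * d$delay_s))
  expect_equal(fit_monoexponential_decay(d)$rate, 13.4,
               tolerance = 1e-9)
  g <- gen_fibril_growth(1.86, duration = 3600)
  expect_equal(growth_rate_tirf(g)$rate_nm_s, 1.86)
})

test_that("identical seeds give byte-identical CSV files", {
  p <- wt_params()
  s <- small_scheme()
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_dest_csv(gen_dest_dataset(p, s, noise_spec("additive", 0.01,
                                                   seed = 77)), f1)
  write_dest_csv(gen_dest_dataset(p, s, noise_spec("additive", 0.01,
                                                   seed = 77)), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # and a different seed differs
  write_dest_csv(gen_dest_dataset(p, s, noise_spec("additive", 0.01,
                                                   seed = 78)), f2)
  expect_false(identical(readLines(f1), readLines(f2)))
})

test_that("noise calibration: residual SD matches sigma within 5%", {
  # 10^4 draws against the noiseless model
  tr <- gen_tht(lag = 10, rate = 50, plateau = 500,
                duration = 10000 / 6, step = 1 / 6,
                noise = noise_spec("additive", 3, seed = 13))
  clean <- gen_tht(lag = 10, rate = 50, plateau = 500,
                   duration = 10000 / 6, step = 1 / 6)
  res <- tr$fluorescence - clean$fluorescence
  expect_gt(length(res), 1e4)
  expect_lt(abs(stats::sd(res) - 3) / 3, 0.05)
})

test_that("generated datasets round-trip losslessly through the readers", {
  tmp <- tempfile(fileext = ".csv")
  p <- wt_params()
  d <- gen_dest_dataset(p, small_scheme(),
                        noise_spec("additive", 0.01, seed = 4))
  write_dest_csv(d, tmp)
  expect_equal(as.data.frame(read_dest_csv(tmp)), as.data.frame(d))
  dec <- gen_decay(9.1, noise = noise_spec("multiplicative", 0.01,
                                           seed = 2))
  write_relaxation_csv(dec, tmp)
  expect_equal(as.data.frame(read_relaxation_csv(tmp, "decay")),
               as.data.frame(dec))
  dis <- gen_dissolution(60, -0.8,
                         noise = noise_spec("multiplicative", 0.03,
                                            seed = 3))
  write_dissolution_csv(dis, tmp)
  rd <- read_dissolution_csv(tmp)
  expect_equal(rd$intensity, dis$intensity)
  tht <- gen_tht(20, 50, 500, noise = noise_spec("additive", 5,
                                                 seed = 6))
  write_tht_csv(tht, tmp)
  expect_equal(as.data.frame(read_tht_csv(tmp)), as.data.frame(tht))
  g <- gen_fibril_growth(0.39, noise = noise_spec("additive", 0.05,
                                                  seed = 8))
  write_tirf_csv(g, tmp)
  expect_equal(as.data.frame(read_tirf_csv(tmp)), as.data.frame(g))
})

test_that("seed fan-out is deterministic and label-sensitive", {
  expect_identical(derive_seed(1, "dest wt"), derive_seed(1, "dest wt"))
  expect_false(derive_seed(1, "dest wt") == derive_seed(1, "dest dm"))
  expect_false(derive_seed(1, "x") == derive_seed(2, "x"))
  expect_true(derive_seed(2147483646, "long label works") >= 1)
})

test_that("gen_dissolution always contains the reference lane", {
  s <- gen_dissolution(60, -0.8, lanes = c(0, 50, 60, 70))
  expect_true(any(s$fa_percent == 98))
  n <- normalize_to_reference(s)
  expect_identical(n$y_diss[n$fa_percent == 98], 100)
})
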