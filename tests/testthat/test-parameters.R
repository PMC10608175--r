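test_that("unit conversions round-trip and match the fixed kBT", {
  expect_equal(sigma_to_kBT_per_nm2(0.1), 0.1e-21 / 4.141e-21)
  expect_equal(sigma_to_mN_per_m(sigma_to_kBT_per_nm2(0.1)), 0.1,
               tolerance = 1e-12)
  # 0.1 mN/m is about 0.024 kBT/nm^2
  expect_equal(sigma_to_kBT_per_nm2(0.1), 0.02415, tolerance = 1e-3)
})

test_that("higher moduli derivation and homogeneity in h", {
  m <- derive_higher_moduli(kt = 12, h = 1.3)
  expect_equal(m$kc, -12 * 1.3^2 / 6)
  expect_equal(m$kgr, 12 * 1.3^4 / 20)
  expect_equal(m$B, -12 * 1.3 / 2)
  expect_equal(m$C, 12 * 1.3^3 / 8)
  m2 <- derive_higher_moduli(kt = 12, h = 2.6)
  expect_equal(m2$kc, m$kc * 4)
  expect_equal(m2$kgr, m$kgr * 16)
  expect_equal(m2$B, m$B * 2)
  expect_equal(m2$C, m$C * 8)
  m0 <- derive_higher_moduli(kt = 12, h = 0)
  expect_true(all(unlist(m0) == 0))
  expect_error(derive_higher_moduli(kt = -1, h = 1), "kt")
})

test_that("spontaneous stretching alpha0 = sigma / kA", {
  expect_equal(spontaneous_stretching(0.1, 30, unit = "mN/m"),
               sigma_to_kBT_per_nm2(0.1) / 30)
  expect_equal(spontaneous_stretching(0.1, 30, unit = "mN/m"), 8.05e-4,
               tolerance = 1e-3)
  expect_equal(spontaneous_stretching(0.0242, 30, unit = "kBT/nm2"),
               0.0242 / 30)
})

test_that("phase parameter constructor fills derived moduli", {
  p <- phase_parameters("ordered", h = 1.8, km = 20, kt = 12, kA = 30)
  expect_s3_class(p, "phase_params")
  expect_equal(p$kc, -12 * 1.8^2 / 6)
  expect_equal(p$kgr, 12 * 1.8^4 / 20)
  # explicit overrides win
  p2 <- phase_parameters("ordered", h = 1.8, km = 20, kt = 12, kA = 30,
                         kgr = 99)
  expect_equal(p2$kgr, 99)
})

test_that("default parameter set matches the documented values", {
  p <- default_parameter_set()
  expect_equal(p$ordered$h, 1.8)
  expect_equal(p$disordered$h, 1.3)
  expect_equal(p$ordered$km, 20)
  expect_equal(p$disordered$km, 10)
  expect_equal(p$ordered$kt, 12)
  expect_equal(p$ordered$kA, 30)
  expect_equal(p$system$sigma, sigma_to_kBT_per_nm2(0.1))
  expect_equal(p$system$misregistration_density, 0.016)
  expect_equal(p$peptide$delta_L, 1.3)
  expect_equal(p$peptide$Lp, 3.5)
})
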