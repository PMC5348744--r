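test_that("default campaign design enumerates 250 records deterministically", {
  geom <- beam_geometry()
  m <- truth_machine()
  a <- generate_campaign(m, geom, seed = 11)
  expect_equal(nrow(a$records), 250)
  expect_equal(length(unique(a$records$energy_MeV)), 10)
  expect_equal(length(unique(a$records$plane_z_mm)), 5)
  expect_false(10 %in% a$records$field_size_cm)
  expect_equal(nrow(a$truth), 50)

  b <- generate_campaign(m, geom, seed = 11)
  expect_identical(a$records, b$records)
  c <- generate_campaign(m, geom, seed = 12)
  expect_false(identical(a$records$fsf, c$records$fsf))
  expect_error(generate_campaign(m, geom), "seed")
})

test_that("noise-free records equal the truth-model FSFs exactly", {
  geom <- beam_geometry()
  m <- truth_machine(noise_sd = 0)
  camp <- generate_campaign(m, geom, seed = 3)
  want <- mapply(function(e, z, fs) {
    fsf(truth_params(m, e, z), geom, z, fs)
  }, camp$records$energy_MeV, camp$records$plane_z_mm,
     camp$records$field_size_cm)
  expect_equal(camp$records$fsf, as.numeric(want), tolerance = 1e-14)
})

test_that("a held-out validation campaign yields 50 isocenter records", {
  geom <- beam_geometry()
  m <- truth_machine()
  val <- generate_campaign(m, geom, energies = seq(85, 170, length.out = 10),
                           planes = 0, seed = 5)
  expect_equal(nrow(val$records), 50)
  expect_true(all(val$records$plane_z_mm == 0))
})

test_that("truth parameters follow the configured energy and plane trends", {
  m <- truth_machine()
  p_low <- truth_params(m, 80.3, 0)
  p_high <- truth_params(m, 175.9, 0)
  expect_equal(p_low$sigma1_mm, 9)
  expect_equal(p_high$sigma1_mm, 4.5)
  expect_equal(p_low$w2, 0.12)
  expect_equal(p_high$w2, 0.04)
  # spots grow downstream, 8% per 100 mm
  expect_equal(truth_params(m, 121, 100)$sigma1_mm,
               1.08 * truth_params(m, 121, 0)$sigma1_mm)
  expect_equal(p_low$sigma2_mm / p_low$sigma1_mm, 3.5)
})

test_that("the Lorentzian tail profile is normalized and guarded", {
  total <- stats::integrate(function(r) 2 * pi * r * lorentz_profile(40, r, 0),
                            0, Inf, rel.tol = 1e-10)$value
  expect_equal(total, 1, tolerance = 1e-6)

  p <- spot_params(7, 20, 0.1)
  expect_error(inject_mismatch(p, 0.03, width_mm = 15), "exceed sigma2")
  expect_error(inject_mismatch(p, 0.5), "fraction")

  geom <- beam_geometry()
  plain <- inject_mismatch(p, 0)
  expect_identical(plain(geom, 0, 4), central_fluence(p, geom, 0, 4))
  mixed <- inject_mismatch(p, 0.03, 40)
  expect_false(isTRUE(all.equal(mixed(geom, 0, 4),
                                central_fluence(p, geom, 0, 4))))
})

test_that("fit residuals match the injected noise level", {
  geom <- beam_geometry()
  m <- truth_machine()  # 0.2% multiplicative noise
  camp <- generate_campaign(m, geom, energies = c(100, 140), seed = 7)
  fits <- fit_campaign(camp$records, geom)
  resid <- unlist(lapply(fits, function(f) f$residuals$rel_diff))
  expect_length(resid, 50)
  expect_gt(stats::sd(resid), 0.001)
  expect_lt(stats::sd(resid), 0.004)
})

test_that("non-Gaussian tail mismatch inflates the fit residuals", {
  geom <- beam_geometry()
  clean <- generate_campaign(truth_machine(noise_sd = 0), geom,
                             energies = 121, planes = c(-100, 0, 100),
                             seed = 9)
  tail <- generate_campaign(truth_machine(noise_sd = 0,
                                          mismatch_fraction = 0.03,
                                          mismatch_width_mm = 40),
                            geom, energies = 121, planes = c(-100, 0, 100),
                            seed = 9)
  fit_clean <- fit_energy(clean$records, geom)
  fit_tail <- fit_energy(tail$records, geom)
  expect_gt(max(abs(fit_tail$residuals$rel_diff)),
            max(abs(fit_clean$residuals$rel_diff)))
})

test_that("charge-mode noise enters through the cumulative readings", {
  geom <- beam_geometry()
  m <- truth_machine(noise_sd = 0)
  direct <- generate_campaign(m, geom, energies = 121, planes = 0, seed = 2)
  charge <- generate_campaign(m, geom, energies = 121, planes = 0, seed = 2,
                              mode = "charge")
  # without noise the two modes coincide
  expect_equal(direct$records$fsf, charge$records$fsf, tolerance = 1e-12)
  noisy <- generate_campaign(truth_machine(), geom, energies = 121,
                             planes = 0, seed = 2, mode = "charge")
  expect_false(identical(noisy$records$fsf, charge$records$fsf))
  expect_equal(nrow(noisy$records), 5)
})
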