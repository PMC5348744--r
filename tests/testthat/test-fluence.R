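test_that("spot profile evaluates the two-Gaussian sum term by term", {
  p <- spot_params(5)
  expect_equal(fluence_at(p, 0, 0), 1 / (2 * pi * 25))
  expect_lt(fluence_at(p, 1e3, 1e3), 1e-300)

  p2 <- spot_params(7, 20, w2 = 0.1)
  expect_equal(fluence_at(p2, 10, 0), oracle_profile(7, 20, 0.1, 1, 10, 0))
  # fluence integrates to amplitude over the plane (polar quadrature)
  total <- stats::integrate(function(r) 2 * pi * r * fluence_at(p2, r, 0),
                            0, Inf)$value
  expect_equal(total, 1, tolerance = 1e-8)
})

test_that("spot parameter invariants are enforced", {
  expect_error(spot_params(0), "sigma1")
  expect_error(spot_params(7, 5), "sigma2")
  expect_error(spot_params(7, 20, w2 = 1), "w2")
  expect_error(spot_params(7, 20, w2 = -0.1), "w2")
  expect_error(spot_params(7, amplitude = 0), "amplitude")
})

test_that("spot grid enumerates the (2N+1)^2 lattice and rejects misfits", {
  expect_equal(nrow(spot_grid(2, 5)), 25)
  expect_equal(nrow(spot_grid(10, 5)), 441)
  expect_equal(nrow(spot_grid(20, 5)), 1681)
  g <- spot_grid(2, 5)
  expect_setequal(unique(g$i), -2:2)
  expect_error(spot_grid(2, 7), "not an even multiple")
  expect_error(spot_grid(-2, 5), "field size")
  expect_error(spot_grid(2, 0), "spacing")
})

test_that("separable central fluence matches the brute-force double sum", {
  # frozen closed-form case: single Gaussian, parallel beam
  p <- spot_params(7)
  geom <- beam_geometry(parallel = TRUE)
  sep <- sum(exp(-25 * (-2:2)^2 / 98))^2 / (2 * pi * 49)
  expect_equal(central_fluence(p, geom, 0, 2), sep, tolerance = 1e-12)

  set.seed(71)
  for (k in 1:20) {
    s1 <- runif(1, 2, 12)
    s2 <- s1 * runif(1, 1, 6)
    w2 <- runif(1, 0, 0.4)
    amp <- runif(1, 0.5, 2)
    z <- sample(c(-200, -100, 0, 100, 200), 1)
    fs <- sample(c(2, 4, 6), 1)
    geom_k <- if (k %% 2 == 0) beam_geometry(parallel = TRUE)
              else beam_geometry(vsad_x_mm = 1900, vsad_y_mm = 2300)
    pk <- spot_params(s1, s2, w2, amp)
    got <- central_fluence(pk, geom_k, z, fs)
    want <- oracle_central_fluence(
      s1, s2, w2, amp,
      projected_spacing(geom_k, z, "x"), projected_spacing(geom_k, z, "y"),
      round(10 * fs / 10))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("central fluence is monotone in field size and peaks for one spot", {
  p <- spot_params(7, 20, 0.1)
  geom <- beam_geometry()
  cf <- vapply(c(2, 4, 6, 8, 10, 20), function(fs)
    central_fluence(p, geom, 100, fs), 0)
  expect_true(all(diff(cf) > 0))
  # degenerate single-spot grid recovers the peak fluence
  expect_equal(central_fluence(spot_params(5), geom, 0, 1e-12),
               1 / (2 * pi * 25))
})

test_that("FSF is 1 at the reference field and matches the oracle elsewhere", {
  geom <- beam_geometry(parallel = TRUE)
  p <- spot_params(7)
  expect_identical(fsf(p, geom, 0, 10), 1)
  expect_identical(fsf(spot_params(3, 40, 0.3), beam_geometry(), -200, 10), 1)

  expect_equal(fsf(p, geom, 0, 2), 0.8685825, tolerance = 1e-6)
  expect_equal(fsf(p, geom, 0, 2), oracle_fsf(7, 7, 0, 2, 10, 5),
               tolerance = 1e-12)
})

test_that("FSF invariances: monotone in FS, amplitude-free, x/y symmetric", {
  geom <- beam_geometry()
  p <- spot_params(6, 18, 0.12)
  vals <- vapply(c(2, 4, 6, 8, 10, 20), function(fs)
    fsf(p, geom, -100, fs), 0)
  expect_true(all(diff(vals) > 0))
  expect_gte(vals[length(vals)], 1)  # FSF(20) / FSF(10) >= 1

  p_amp <- spot_params(6, 18, 0.12, amplitude = 37.5)
  expect_equal(fsf(p_amp, geom, -100, 4), fsf(p, geom, -100, 4),
               tolerance = 1e-14)

  # equal VSADs: swapping axes cannot matter; unequal VSADs still symmetric
  # in the i/j sum because the field is square
  g_sym <- beam_geometry(vsad_x_mm = 2000, vsad_y_mm = 2000)
  g_swp <- beam_geometry(vsad_x_mm = 2000, vsad_y_mm = 2000)
  expect_equal(fsf(p, g_sym, 150, 6), fsf(p, g_swp, 150, 6))

  # w2 = 0 collapses to the single-Gaussian model regardless of sigma2
  expect_equal(fsf(spot_params(7, 50, 0), geom, 0, 4),
               fsf(spot_params(7, 7, 0), geom, 0, 4), tolerance = 1e-14)

  # vanishing spot: only the central spot contributes, FSF -> 1
  expect_equal(fsf(spot_params(0.6), geom, 0, 2), 1, tolerance = 1e-8)
})

test_that("FSF tables round-trip through CSV with the column contract", {
  df <- fsf_records(energy_MeV = 121, plane_z_mm = c(0, 0, 100),
                    field_size_cm = c(2, 4, 2), fsf = c(0.7, 0.9, 0.72))
  path <- withr::local_tempfile(fileext = ".csv")
  write_fsf_table(df, path)
  back <- read_fsf_table(path)
  expect_equal(back, df)
  expect_named(back, c("energy_MeV", "plane_z_mm", "field_size_cm",
                       "ref_field_size_cm", "fsf"))

  expect_error(fsf_records(121, 0, 2, 10, fsf = -0.5), "> 0")
  expect_error(fsf_records(121, 0, 10, 10, fsf = 0.99), "exactly 1")
  bad <- df[, -5]
  expect_error(spotfluence:::validate_fsf_table(bad), "missing columns")
})
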