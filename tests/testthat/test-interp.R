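test_that("layer lists span the energy range with the requested count", {
  layers <- build_layer_list(80.3, 175.6, 68)
  expect_length(layers, 68)
  expect_equal(layers[1], 80.3)
  expect_equal(layers[68], 175.6)
  expect_equal(build_layer_list(100, 101, 2), c(100, 101))
  expect_error(build_layer_list(100, 90, 5))
})

make_linear_fits <- function(energies, planes = c(-100, 0, 100)) {
  lapply(energies, function(e) {
    s1 <- (10 - 0.03 * e) * (1 + 0.05 * planes / 100)
    stub_fit(e, planes, s1, 3 * s1, w2 = 0.2 - 5e-4 * e)
  })
}

test_that("interpolation passes exactly through the fitted energies", {
  fits <- make_linear_fits(c(90, 110, 130, 150))
  layers <- c(90, 100, 110, 120, 130, 150)
  tab <- interpolate_table(fits, layers)
  expect_s3_class(tab, "fluence_model_table")
  for (f in fits) {
    sub <- tab[tab$energy_MeV == f$energy_MeV, ]
    expect_equal(sub$sigma1_mm, f$per_plane$sigma1_mm)
    expect_equal(sub$sigma2_mm, f$per_plane$sigma2_mm)
    expect_equal(unique(sub$w2), f$w2)
    expect_true(all(sub$provenance == "fitted"))
  }
  expect_true(all(tab$provenance[tab$energy_MeV %in% c(100, 120)] ==
                    "interpolated"))
  # 68-layer bookkeeping: 10 fitted layers leave 58 interpolated
  layers68 <- build_layer_list(80.3, 175.6, 68)
  fits10 <- make_linear_fits(layers68[round(seq(1, 68, length.out = 10))])
  tab68 <- interpolate_table(fits10, layers68)
  prov <- tab68[tab68$plane_z_mm == 0, "provenance"]
  expect_equal(sum(prov == "fitted"), 10)
  expect_equal(sum(prov == "interpolated"), 58)
})

test_that("smooth truth is recovered at unfitted layers without overshoot", {
  energies <- seq(80.3, 175.6, length.out = 10)
  fits <- make_linear_fits(energies)
  layers <- build_layer_list(80.3, 175.6, 68)
  tab <- interpolate_table(fits, layers)
  for (z in c(-100, 0, 100)) {
    sub <- tab[tab$plane_z_mm == z, ]
    truth <- (10 - 0.03 * sub$energy_MeV) * (1 + 0.05 * z / 100)
    expect_true(all(abs(sub$sigma1_mm / truth - 1) < 0.005))
    # monotone fitted sequence stays monotone after interpolation
    expect_true(all(diff(sub$sigma1_mm) < 0))
    # no overshoot: every value within the bracketing fitted values
    expect_true(all(sub$sigma1_mm <= max(truth) + 1e-9 &
                      sub$sigma1_mm >= min(truth) - 1e-9))
  }
  expect_true(all(tab$w2 >= 0 & tab$w2 <= 0.5))
  expect_true(all(tab$sigma2_mm >= tab$sigma1_mm))
})

test_that("interpolation preconditions and extrapolation behave as stated", {
  fits <- make_linear_fits(120)
  expect_error(interpolate_table(fits, c(110, 130)), "at least 2")
  fits2 <- make_linear_fits(c(100, 120, 140))
  expect_message(tab <- interpolate_table(fits2, c(90, 110, 150)),
                 "extrapolating")
  expect_true(all(tab$sigma1_mm > 0))
  # clamped-linear beyond the fitted range: continues the boundary slope
  sub <- tab[tab$plane_z_mm == 0, ]
  inner <- interpolate_table(fits2, c(100, 120, 140))
  inner0 <- inner[inner$plane_z_mm == 0, ]
  slope <- (inner0$sigma1_mm[2] - inner0$sigma1_mm[1]) / 20
  expect_equal(sub$sigma1_mm[sub$energy_MeV == 90],
               inner0$sigma1_mm[1] - 10 * slope, tolerance = 0.05)
})

test_that("model tables round-trip through the JSON schema", {
  fits <- make_linear_fits(c(100, 120, 140))
  tab <- interpolate_table(fits, c(100, 110, 120, 130, 140))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_table(tab, path)
  back <- read_model_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
  p <- model_params(back, 110, 0)
  expect_s3_class(p, "spot_params")
  expect_error(model_params(back, 115, 0), "no unique table entry")

  # schema violations are caught on read
  bad <- jsonlite::read_json(path)
  bad[[1]]$planes[[1]]$w2 <- 0.9
  bad_path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, bad_path, auto_unbox = TRUE)
  expect_error(read_model_table(bad_path), "bounds")
})
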