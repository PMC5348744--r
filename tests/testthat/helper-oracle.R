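# Independent brute-force oracles: the double-Gaussian profile and the
# central-fluence lattice sum are written out directly (full O((2N+1)^2)
# double summation over the spot grid), with no use of the package's
# separable fast path.

oracle_profile <- function(s1, s2, w2, amp, dx, dy) {
  r2 <- dx^2 + dy^2
  amp * ((1 - w2) / (2 * pi * s1^2) * exp(-r2 / (2 * s1^2)) +
           w2 / (2 * pi * s2^2) * exp(-r2 / (2 * s2^2)))
}

oracle_central_fluence <- function(s1, s2, w2, amp, ssx, ssy, n) {
  ij <- expand.grid(i = -n:n, j = -n:n)
  sum(oracle_profile(s1, s2, w2, amp, ij$i * ssx, ij$j * ssy))
}

# field sizes in cm, spacing in mm; plain (SS * (VSAD + z) / VSAD) projection
oracle_fsf <- function(s1, s2, w2, field_size_cm, ref_field_size_cm,
                       spacing_mm, vsad_x = Inf, vsad_y = Inf, z = 0) {
  ssx <- if (is.finite(vsad_x)) spacing_mm * (vsad_x + z) / vsad_x else spacing_mm
  ssy <- if (is.finite(vsad_y)) spacing_mm * (vsad_y + z) / vsad_y else spacing_mm
  n1 <- round(10 * field_size_cm / (2 * spacing_mm))
  n2 <- round(10 * ref_field_size_cm / (2 * spacing_mm))
  oracle_central_fluence(s1, s2, w2, 1, ssx, ssy, n1) /
    oracle_central_fluence(s1, s2, w2, 1, ssx, ssy, n2)
}

# minimal fit-result stub for summary/interpolation tests that do not need
# a real optimization run
stub_fit <- function(energy, planes, sigma1, sigma2, w2,
                     residuals = NULL) {
  structure(list(
    energy_MeV = energy,
    per_plane = data.frame(plane_z_mm = planes, sigma1_mm = sigma1,
                           sigma2_mm = sigma2),
    w2 = w2,
    residuals = residuals,
    objective_value = 0,
    grid_objective_value = 0,
    converged = TRUE), class = "fsf_fit")
}

# noise-free FSF records computed from given truth parameters
records_from_truth <- function(params_by_plane, geom, energy,
                               field_sizes = c(2, 4, 6, 8, 20), ref = 10) {
  do.call(rbind, lapply(names(params_by_plane), function(zname) {
    z <- as.numeric(zname)
    p <- params_by_plane[[zname]]
    fsf_records(energy_MeV = energy, plane_z_mm = z,
                field_size_cm = field_sizes, ref_field_size_cm = ref,
                fsf = vapply(field_sizes, function(fs)
                  fsf(p, geom, z, fs, ref), 0))
  }))
}
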