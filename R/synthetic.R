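#' Synthetic truth machine for FSF campaign simulation
#'
#' Defines a ground-truth beam model with smooth energy dependence, used to
#' generate synthetic "measured" FSF campaigns against which fitting and
#' interpolation can be verified end to end. Defaults emulate a
#' range-shifter machine: large spots that shrink with energy
#' (`sigma1` 9 mm at the lowest to 4.5 mm at the highest energy at
#' isocenter), grow downstream of the nozzle (8% per 100 mm), a halo
#' 3.5 times wider than the core, and a halo weight falling from 0.12 to
#' 0.04 with energy. Measurement noise is multiplicative Gaussian with
#' 0.2% standard deviation, the day-to-day reproducibility of charge-ratio
#' measurements. An optional Lorentzian tail fraction makes the generated
#' fluence deviate from the double-Gaussian family, emulating real spot
#' profiles whose far tails are not Gaussian.
#'
#' @param e_min_MeV,e_max_MeV Energy range of the campaign, MeV.
#' @param sigma1_iso_mm Primary width at isocenter at `(e_min, e_max)`, mm.
#' @param growth_per_100mm Relative growth of both widths per 100 mm
#'   downstream (positive z).
#' @param sigma2_ratio `sigma2 / sigma1`, constant.
#' @param w2_range Halo weight at `(e_min, e_max)`.
#' @param noise_sd Relative standard deviation of multiplicative
#'   measurement noise.
#' @param mismatch_fraction Fraction of the generated fluence carried by a
#'   Lorentzian tail instead of the double Gaussian, in `[0, 0.1]`.
#' @param mismatch_width_mm Lorentzian half-width scale, mm (must exceed
#'   `sigma2` everywhere when the fraction is positive).
#' @return An object of class `truth_machine`.
#' @export
truth_machine <- function(e_min_MeV = 80.3, e_max_MeV = 175.9,
                          sigma1_iso_mm = c(9, 4.5),
                          growth_per_100mm = 0.08,
                          sigma2_ratio = 3.5,
                          w2_range = c(0.12, 0.04),
                          noise_sd = 0.002,
                          mismatch_fraction = 0,
                          mismatch_width_mm = 40) {
  stopifnot(e_min_MeV < e_max_MeV, noise_sd >= 0)
  if (mismatch_fraction < 0 || mismatch_fraction > 0.1) {
    stop("mismatch_fraction must lie in [0, 0.1]")
  }
  structure(list(e_min_MeV = e_min_MeV, e_max_MeV = e_max_MeV,
                 sigma1_iso_mm = sigma1_iso_mm,
                 growth_per_100mm = growth_per_100mm,
                 sigma2_ratio = sigma2_ratio, w2_range = w2_range,
                 noise_sd = noise_sd,
                 mismatch_fraction = mismatch_fraction,
                 mismatch_width_mm = mismatch_width_mm),
            class = "truth_machine")
}

#' Ground-truth spot parameters of a truth machine
#'
#' @param machine A [truth_machine()].
#' @param energy_MeV Nominal energy, MeV.
#' @param z_mm Plane offset from isocenter, mm.
#' @return A [spot_params()] object.
#' @export
truth_params <- function(machine, energy_MeV, z_mm) {
  stopifnot(inherits(machine, "truth_machine"))
  t <- (energy_MeV - machine$e_min_MeV) /
    (machine$e_max_MeV - machine$e_min_MeV)
  s1_iso <- machine$sigma1_iso_mm[1L] +
    t * (machine$sigma1_iso_mm[2L] - machine$sigma1_iso_mm[1L])
  s1 <- s1_iso * (1 + machine$growth_per_100mm * z_mm / 100)
  w2 <- machine$w2_range[1L] + t * (machine$w2_range[2L] - machine$w2_range[1L])
  spot_params(s1, machine$sigma2_ratio * s1, w2)
}

#' Areal Lorentzian tail profile
#'
#' Rotationally symmetric heavy-tailed profile
#' `L(r) = (1 / 2 pi) * width / (r^2 + width^2)^(3/2)`, normalized to unit
#' integral over the plane. Used only by the synthetic generator to emulate
#' spot tails that the double-Gaussian family cannot represent.
#'
#' @param width_mm Half-width scale, mm.
#' @param dx_mm,dy_mm Offsets from the spot center, mm. Vectorized.
#' @return Fluence density per mm^2.
#' @export
lorentz_profile <- function(width_mm, dx_mm, dy_mm) {
  stopifnot(width_mm > 0)
  r2 <- dx_mm^2 + dy_mm^2
  width_mm / (2 * pi) / (r2 + width_mm^2)^1.5
}

#' Central-fluence evaluator with an injected non-Gaussian tail
#'
#' Returns a function `(geom, z_mm, field_size_cm) -> central fluence`
#' evaluating `(1 - fraction)` times the double-Gaussian lattice sum plus
#' `fraction` times the Lorentzian-tail lattice sum. With `fraction = 0`
#' it reproduces [central_fluence()] exactly. The fitted model stays
#' double-Gaussian, so a positive fraction turns into structured fit
#' residuals — the synthetic analogue of real-profile mismatch.
#'
#' @param params A [spot_params()] (the double-Gaussian part).
#' @param fraction Tail fraction, in `[0, 0.1]`.
#' @param width_mm Lorentzian width, mm; must exceed `params$sigma2_mm`.
#' @return A function `(geom, z_mm, field_size_cm)`.
#' @export
inject_mismatch <- function(params, fraction, width_mm = 40) {
  stopifnot(inherits(params, "spot_params"))
  if (fraction < 0 || fraction > 0.1) stop("fraction must lie in [0, 0.1]")
  if (fraction == 0) {
    return(function(geom, z_mm, field_size_cm)
      central_fluence(params, geom, z_mm, field_size_cm))
  }
  if (width_mm <= params$sigma2_mm) {
    stop("mismatch width must exceed sigma2")
  }
  function(geom, z_mm, field_size_cm) {
    n <- half_index(field_size_cm, geom$spot_spacing_mm)
    ssx <- projected_spacing(geom, z_mm, "x")
    ssy <- projected_spacing(geom, z_mm, "y")
    idx <- -n:n
    r2 <- outer((idx * ssx)^2, (idx * ssy)^2, "+")
    lor <- sum(width_mm / (2 * pi) / (r2 + width_mm^2)^1.5)
    (1 - fraction) * central_fluence(params, geom, z_mm, field_size_cm) +
      fraction * params$amplitude * lor
  }
}

#' Generate a synthetic FSF measurement campaign
#'
#' Simulates the full in-air campaign: for every (energy, plane), FSFs of
#' all non-reference field sizes with multiplicative Gaussian measurement
#' noise. The default design — 10 energies, 5 planes, field sizes 2 to
#' 20 cm normalized to 10 cm — yields 250 records. Two noise modes are
#' provided: `"direct"` applies noise to each FSF after normalization;
#' `"charge"` simulates the spiral-delivery readout, applying independent
#' noise to each cumulative charge reading (including the reference) before
#' normalization via [cumulative_fsf_from_charges()].
#'
#' @param machine A [truth_machine()].
#' @param geom A [beam_geometry()].
#' @param energies Nominal energies, MeV; default 10 equally spaced over
#'   the machine range.
#' @param planes Plane offsets, mm; default the geometry's plane set.
#' @param field_sizes_cm Field sizes including the reference.
#' @param seed Integer seed; identical seeds give identical campaigns.
#' @param ref_field_size_cm Reference field size, cm.
#' @param mode `"direct"` or `"charge"` (see above).
#' @return A list of class `fsf_campaign`: `records` (FSF table,
#'   reference rows excluded) and `truth` (data frame of true `sigma1_mm`,
#'   `sigma2_mm`, `w2` per energy and plane).
#' @examples
#' camp <- generate_campaign(truth_machine(), beam_geometry(), seed = 1)
#' nrow(camp$records)  # 250
#' @export
generate_campaign <- function(machine, geom,
                              energies = NULL, planes = NULL,
                              field_sizes_cm = c(2, 4, 6, 8, 10, 20),
                              seed, ref_field_size_cm = 10,
                              mode = c("direct", "charge")) {
  stopifnot(inherits(machine, "truth_machine"), inherits(geom, "beam_geometry"))
  mode <- match.arg(mode)
  if (is.null(energies)) {
    energies <- seq(machine$e_min_MeV, machine$e_max_MeV, length.out = 10)
  }
  if (is.null(planes)) planes <- geom$plane_offsets_mm
  if (!ref_field_size_cm %in% field_sizes_cm) {
    stop("field_sizes_cm must include the reference field size")
  }
  if (missing(seed)) stop("a seed is required for reproducibility")
  set.seed(as.integer(seed))
  fs_sorted <- sort(field_sizes_cm)
  rec_list <- list()
  truth_list <- list()
  for (e in energies) {
    for (z in planes) {
      p <- truth_params(machine, e, z)
      cf_eval <- inject_mismatch(p, machine$mismatch_fraction,
                                 machine$mismatch_width_mm)
      cf <- vapply(fs_sorted, function(fs) cf_eval(geom, z, fs), 0)
      if (mode == "direct") {
        truth_fsf <- cf / cf[fs_sorted == ref_field_size_cm]
        keep <- fs_sorted != ref_field_size_cm
        eps <- stats::rnorm(sum(keep), 0, machine$noise_sd)
        rec <- fsf_records(energy_MeV = e, plane_z_mm = z,
                           field_size_cm = fs_sorted[keep],
                           ref_field_size_cm = ref_field_size_cm,
                           fsf = truth_fsf[keep] * (1 + eps))
      } else {
        charges <- cf * (1 + stats::rnorm(length(cf), 0, machine$noise_sd))
        n_fs <- length(fs_sorted)
        rec <- cumulative_fsf_from_charges(
          charges, pause_field_sizes_cm = fs_sorted[-n_fs],
          max_field_size_cm = fs_sorted[n_fs],
          ref_field_size_cm = ref_field_size_cm,
          energy_MeV = e, plane_z_mm = z)
      }
      rec_list[[length(rec_list) + 1L]] <- rec
      truth_list[[length(truth_list) + 1L]] <- data.frame(
        energy_MeV = e, plane_z_mm = z, sigma1_mm = p$sigma1_mm,
        sigma2_mm = p$sigma2_mm, w2 = p$w2)
    }
  }
  structure(list(records = do.call(rbind, rec_list),
                 truth = do.call(rbind, truth_list)),
            class = "fsf_campaign")
}

#' @export
print.fsf_campaign <- function(x, ...) {
  cat(sprintf("<fsf_campaign> %d FSF records, %d energies, %d planes\n",
              nrow(x$records), length(unique(x$records$energy_MeV)),
              length(unique(x$records$plane_z_mm))))
  invisible(x)
}
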