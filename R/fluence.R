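#' Double-Gaussian single-spot fluence parameters
#'
#' The lateral fluence of one pencil-beam spot in air is modeled as the sum
#' of a narrow primary Gaussian (width `sigma1`) carrying weight `1 - w2`
#' and a wide secondary Gaussian (width `sigma2`, weight `w2`) that
#' represents the low-dose halo produced mainly by scattering in the range
#' shifter. Both Gaussians are normalized so the fluence integrates to
#' `amplitude` over the plane; `amplitude` cancels in every field size
#' factor and defaults to 1.
#'
#' @param sigma1_mm Primary Gaussian standard deviation, mm (> 0).
#' @param sigma2_mm Secondary Gaussian standard deviation, mm
#'   (>= `sigma1_mm`).
#' @param w2 Weight of the secondary Gaussian, in `[0, 1)`.
#' @param amplitude Per-spot fluence normalization (> 0).
#' @return An object of class `spot_params`.
#' @examples
#' p <- spot_params(7, 20, w2 = 0.1)
#' fluence_at(p, 0, 0)
#' @export
spot_params <- function(sigma1_mm, sigma2_mm = sigma1_mm, w2 = 0,
                        amplitude = 1) {
  stopifnot(is.numeric(sigma1_mm), is.numeric(sigma2_mm), is.numeric(w2),
            is.numeric(amplitude))
  if (sigma1_mm <= 0) stop("sigma1_mm must be > 0")
  if (sigma2_mm < sigma1_mm) stop("sigma2_mm must be >= sigma1_mm")
  if (w2 < 0 || w2 >= 1) stop("w2 must lie in [0, 1)")
  if (amplitude <= 0) stop("amplitude must be > 0")
  structure(list(sigma1_mm = sigma1_mm, sigma2_mm = sigma2_mm,
                 w2 = w2, amplitude = amplitude),
            class = "spot_params")
}

#' @export
print.spot_params <- function(x, ...) {
  cat(sprintf("<spot_params> sigma1 = %g mm, sigma2 = %g mm, w2 = %g, amplitude = %g\n",
              x$sigma1_mm, x$sigma2_mm, x$w2, x$amplitude))
  invisible(x)
}

#' Evaluate the double-Gaussian spot fluence at an offset from the spot
#'
#' @param params A [spot_params()].
#' @param dx_mm,dy_mm Offsets from the spot center, mm. Vectorized.
#' @return Fluence density per mm^2.
#' @export
fluence_at <- function(params, dx_mm, dy_mm) {
  stopifnot(inherits(params, "spot_params"))
  r2 <- dx_mm^2 + dy_mm^2
  s1 <- params$sigma1_mm
  s2 <- params$sigma2_mm
  w2 <- params$w2
  params$amplitude *
    ((1 - w2) / (2 * pi * s1^2) * exp(-r2 / (2 * s1^2)) +
       w2 / (2 * pi * s2^2) * exp(-r2 / (2 * s2^2)))
}

# Half-width of the spot lattice in index units: N = 0.5 * FS / SS.
# The field size must be an even multiple of the spacing; rounding silently
# would change FSFs at the 0.1% level, so non-integral N is an error.
half_index <- function(field_size_cm, spacing_mm) {
  if (!is.numeric(field_size_cm) || field_size_cm <= 0) {
    stop("field size must be > 0")
  }
  if (!is.numeric(spacing_mm) || spacing_mm <= 0) {
    stop("spot spacing must be > 0")
  }
  n <- (10 * field_size_cm) / (2 * spacing_mm)
  if (abs(n - round(n)) > 1e-9) {
    stop(sprintf(
      "field size %g cm is not an even multiple of the %g mm spot spacing",
      field_size_cm, spacing_mm))
  }
  as.integer(round(n))
}

#' Spot index grid of a uniform square field
#'
#' A square field of side `FS` delivered with spot spacing `SS` consists of
#' the `(2N + 1)^2` lattice points `(i, j)` with `|i|, |j| <= N` and
#' `N = 0.5 * FS / SS` (field size measured center-to-center of the edge
#' spots).
#'
#' @param field_size_cm Square field side, cm.
#' @param spacing_mm Spot spacing at the isocenter plane, mm.
#' @return A data frame with integer columns `i`, `j`, one row per spot.
#' @examples
#' nrow(spot_grid(2, 5))   # 25
#' nrow(spot_grid(20, 5))  # 1681
#' @export
spot_grid <- function(field_size_cm, spacing_mm) {
  n <- half_index(field_size_cm, spacing_mm)
  expand.grid(i = -n:n, j = -n:n, KEEP.OUT.ATTRS = FALSE)
}

# 1-D lattice Gaussian sum: sum_{i=-N..N} exp(-(i * spacing)^2 / (2 sigma^2)).
# The 2-D lattice sum of an isotropic Gaussian factorizes into the product
# of the x and y line sums; this is what makes central_fluence O(N).
gauss_line_sum <- function(sigma_mm, spacing_mm, n) {
  i <- -n:n
  sum(exp(-(i * spacing_mm)^2 / (2 * sigma_mm^2)))
}

#' Central fluence of a uniform square spot field
#'
#' Sums the double-Gaussian spot fluence over the full lattice of a square
#' field, evaluated at the field center, with the lattice spacing projected
#' onto the plane at `z_mm` through the virtual-source divergence. All spots
#' carry equal weight. The isotropic Gaussian lattice sum factorizes into
#' separable x and y line sums, so the cost is linear in `N` rather than
#' quadratic.
#'
#' @inheritParams fluence_at
#' @param geom A [beam_geometry()].
#' @param z_mm Plane offset from isocenter, mm.
#' @param field_size_cm Square field side, cm (even multiple of spacing).
#' @return Central fluence density per mm^2.
#' @export
central_fluence <- function(params, geom, z_mm, field_size_cm) {
  stopifnot(inherits(params, "spot_params"), inherits(geom, "beam_geometry"))
  n <- half_index(field_size_cm, geom$spot_spacing_mm)
  ssx <- projected_spacing(geom, z_mm, "x")
  ssy <- projected_spacing(geom, z_mm, "y")
  s1 <- params$sigma1_mm
  s2 <- params$sigma2_mm
  w2 <- params$w2
  term1 <- (1 - w2) / (2 * pi * s1^2) *
    gauss_line_sum(s1, ssx, n) * gauss_line_sum(s1, ssy, n)
  term2 <- if (w2 > 0) {
    w2 / (2 * pi * s2^2) *
      gauss_line_sum(s2, ssx, n) * gauss_line_sum(s2, ssy, n)
  } else 0
  params$amplitude * (term1 + term2)
}

#' Field size factor predicted by the double-Gaussian model
#'
#' Ratio of the central fluence of a square field to that of the reference
#' field (10 cm by default), both evaluated at the same energy and plane.
#' The per-spot amplitude cancels exactly. Equals 1 exactly at the reference
#' field size.
#'
#' @inheritParams central_fluence
#' @param ref_field_size_cm Reference field side, cm.
#' @return Dimensionless field size factor.
#' @examples
#' geom <- beam_geometry(parallel = TRUE)
#' fsf(spot_params(7), geom, 0, 2)   # ~0.869
#' @export
fsf <- function(params, geom, z_mm, field_size_cm, ref_field_size_cm = 10) {
  if (field_size_cm == ref_field_size_cm) {
    half_index(field_size_cm, geom$spot_spacing_mm)  # still validate
    return(1)
  }
  num <- central_fluence(params, geom, z_mm, field_size_cm)
  den <- central_fluence(params, geom, z_mm, ref_field_size_cm)
  stopifnot(den > 0)
  num / den
}

fsf_table_cols <- c("energy_MeV", "plane_z_mm", "field_size_cm",
                    "ref_field_size_cm", "fsf")

#' Assemble a table of field size factor records
#'
#' @param energy_MeV,plane_z_mm,field_size_cm,ref_field_size_cm,fsf
#'   Record coordinates and values; recycled to a common length.
#' @return A data frame with the FSF-table column contract
#'   (`energy_MeV`, `plane_z_mm`, `field_size_cm`, `ref_field_size_cm`,
#'   `fsf`).
#' @export
fsf_records <- function(energy_MeV, plane_z_mm, field_size_cm,
                        ref_field_size_cm = 10, fsf) {
  out <- data.frame(energy_MeV = energy_MeV, plane_z_mm = plane_z_mm,
                    field_size_cm = field_size_cm,
                    ref_field_size_cm = ref_field_size_cm, fsf = fsf)
  validate_fsf_table(out)
}

validate_fsf_table <- function(df) {
  missing <- setdiff(fsf_table_cols, names(df))
  if (length(missing)) {
    stop("FSF table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (any(df$fsf <= 0)) stop("FSF values must be > 0")
  at_ref <- df$field_size_cm == df$ref_field_size_cm
  if (any(at_ref & df$fsf != 1)) {
    stop("FSF at the reference field size must be exactly 1")
  }
  df[fsf_table_cols]
}

#' Read / write FSF tables as CSV
#'
#' The on-disk contract is a plain CSV with header `energy_MeV,
#' plane_z_mm, field_size_cm, ref_field_size_cm, fsf`.
#'
#' @param path File path.
#' @return `read_fsf_table` returns the validated data frame;
#'   `write_fsf_table` returns `path` invisibly.
#' @export
read_fsf_table <- function(path) {
  validate_fsf_table(utils::read.csv(path))
}

#' @rdname read_fsf_table
#' @param df An FSF table data frame.
#' @export
write_fsf_table <- function(df, path) {
  utils::write.csv(validate_fsf_table(df), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
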