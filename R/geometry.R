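#' Beamline geometry for a scanned proton beam
#'
#' Bundles the virtual source-to-axis distances (VSADs), the nominal spot
#' spacing at the isocenter plane, and the measurement-plane offsets used
#' throughout an FSF campaign. The scanning magnets act as a virtual point
#' source per axis; off the isocenter plane the spot lattice is magnified by
#' `(VSAD + z) / VSAD`, with `z` the signed offset from isocenter (positive
#' downstream, away from the nozzle).
#'
#' @param vsad_x_mm,vsad_y_mm Virtual SAD in mm for the x and y scanning
#'   axes. Ignored when `parallel = TRUE`.
#' @param spot_spacing_mm Spot spacing at the isocenter plane, mm.
#' @param plane_offsets_mm Signed plane offsets from isocenter, mm. The
#'   default is the five-plane design used for in-air FSF measurements.
#' @param parallel If `TRUE`, treat the beam as non-divergent (infinite
#'   VSAD on both axes); spot spacing is then identical on every plane.
#' @return An object of class `beam_geometry`.
#' @examples
#' geom <- beam_geometry()
#' projected_spacing(geom, z_mm = 200, axis = "x")
#' @export
beam_geometry <- function(vsad_x_mm = 2000, vsad_y_mm = 2000,
                          spot_spacing_mm = 5,
                          plane_offsets_mm = c(-200, -100, 0, 100, 200),
                          parallel = FALSE) {
  stopifnot(is.numeric(spot_spacing_mm), length(spot_spacing_mm) == 1L)
  if (spot_spacing_mm <= 0) stop("spot_spacing_mm must be > 0")
  if (!parallel) {
    if (!is.numeric(vsad_x_mm) || !is.numeric(vsad_y_mm) ||
        vsad_x_mm <= 0 || vsad_y_mm <= 0) {
      stop("vsad_x_mm and vsad_y_mm must be > 0 (or set parallel = TRUE)")
    }
    for (z in plane_offsets_mm) {
      if (vsad_x_mm + z <= 0 || vsad_y_mm + z <= 0) {
        stop(sprintf("plane offset %g mm lies behind the virtual source", z))
      }
    }
  }
  structure(
    list(vsad_x_mm = if (parallel) Inf else vsad_x_mm,
         vsad_y_mm = if (parallel) Inf else vsad_y_mm,
         spot_spacing_mm = spot_spacing_mm,
         plane_offsets_mm = as.numeric(plane_offsets_mm),
         parallel = isTRUE(parallel)),
    class = "beam_geometry"
  )
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat("<beam_geometry>\n")
  if (x$parallel) {
    cat("  parallel beam (infinite VSAD)\n")
  } else {
    cat(sprintf("  VSAD x/y: %g / %g mm\n", x$vsad_x_mm, x$vsad_y_mm))
  }
  cat(sprintf("  spot spacing: %g mm at isocenter\n", x$spot_spacing_mm))
  cat(sprintf("  planes (z from isocenter): %s mm\n",
              paste(x$plane_offsets_mm, collapse = ", ")))
  invisible(x)
}

#' Spot spacing projected onto a measurement plane
#'
#' Divergence magnifies the isocenter spot spacing `SS` to
#' `SS * (VSAD + z) / VSAD` on a plane at signed offset `z` from isocenter.
#' A parallel geometry returns the spacing unchanged.
#'
#' @param geom A [beam_geometry()].
#' @param z_mm Signed plane offset from isocenter, mm (positive downstream).
#' @param axis Scanning axis, `"x"` or `"y"`.
#' @return Projected spot spacing in mm.
#' @export
projected_spacing <- function(geom, z_mm, axis = c("x", "y")) {
  stopifnot(inherits(geom, "beam_geometry"), is.numeric(z_mm),
            length(z_mm) == 1L, is.finite(z_mm))
  axis <- match.arg(axis)
  if (geom$parallel) return(geom$spot_spacing_mm)
  vsad <- if (axis == "x") geom$vsad_x_mm else geom$vsad_y_mm
  if (vsad + z_mm <= 0) {
    stop(sprintf("plane at z = %g mm lies behind the virtual source (VSAD %g mm)",
                 z_mm, vsad))
  }
  geom$spot_spacing_mm * (vsad + z_mm) / vsad
}
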