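#' Spiral spot-delivery pattern with control points
#'
#' Generates the measurement-efficient delivery pattern: all spots of the
#' maximum square field, delivered center-outward ring by ring (rings in the
#' Chebyshev metric `max(|i|, |j|)`), with control points inserted after the
#' nested square sub-fields listed in `pause_field_sizes_cm`. Because every
#' completed ring closes a nested square field, the spot sequence delivered
#' up to control point `k` is exactly the spot grid of field size `k` —
#' pausing the beam there and reading the cumulative chamber charge yields
#' the FSFs of all nested field sizes from one delivery.
#'
#' Within a ring, spots are ordered counter-clockwise by angle from the +x
#' axis starting at `(ring, 0)`; only the prefix property matters for FSFs.
#'
#' @param geom A [beam_geometry()]; supplies the spot spacing.
#' @param max_field_size_cm Side of the full delivered square field, cm.
#' @param pause_field_sizes_cm Nested field sizes (cm) after which a control
#'   point pauses delivery; each must be smaller than the maximum and an
#'   even multiple of the spacing.
#' @param energy_MeV Optional nominal energy tag for the pattern.
#' @return An object of class `spot_pattern`: a list with `energy_MeV`,
#'   `spots` (data frame `order`, `i`, `j`, `x_mm`, `y_mm`, `weight`) and
#'   `control_points` (data frame `after_index`, `field_size_cm`).
#' @examples
#' p <- spiral_pattern(beam_geometry(), 20, c(2, 4, 6, 8, 10))
#' p$control_points$after_index  # 25 81 169 289 441
#' @export
spiral_pattern <- function(geom, max_field_size_cm = 20,
                           pause_field_sizes_cm = c(2, 4, 6, 8, 10),
                           energy_MeV = NA_real_) {
  stopifnot(inherits(geom, "beam_geometry"))
  ss <- geom$spot_spacing_mm
  n_max <- half_index(max_field_size_cm, ss)
  pause_n <- integer(0)
  for (fs in pause_field_sizes_cm) {
    n <- tryCatch(half_index(fs, ss), error = function(e) NA_integer_)
    if (is.na(n) || fs >= max_field_size_cm) {
      stop(sprintf("pause field size %g cm is not a nested sub-field of the %g cm field",
                   fs, max_field_size_cm))
    }
    pause_n <- c(pause_n, n)
  }

  rings <- vector("list", n_max + 1L)
  rings[[1L]] <- data.frame(i = 0L, j = 0L)
  for (r in seq_len(n_max)) {
    # perimeter of the Chebyshev ring of radius r
    i <- c(r:(-r), rep(-r, 2L * r - 1L), (-r):r, rep(r, 2L * r - 1L))
    j <- c(rep(r, 2L * r + 1L), (r - 1L):(-r + 1L), rep(-r, 2L * r + 1L),
           (-r + 1L):(r - 1L))
    ang <- atan2(j, i) %% (2 * pi)
    o <- order(ang, i, j)
    rings[[r + 1L]] <- data.frame(i = i[o], j = j[o])
  }
  ij <- do.call(rbind, rings)
  spots <- data.frame(order = seq_len(nrow(ij)), i = ij$i, j = ij$j,
                      x_mm = ij$i * ss, y_mm = ij$j * ss, weight = 1)
  cp <- data.frame(after_index = (2L * pause_n + 1L)^2,
                   field_size_cm = as.numeric(pause_field_sizes_cm))
  cp <- cp[order(cp$after_index), , drop = FALSE]
  rownames(cp) <- NULL
  structure(list(energy_MeV = energy_MeV, spots = spots, control_points = cp),
            class = "spot_pattern")
}

#' @export
print.spot_pattern <- function(x, ...) {
  cat(sprintf("<spot_pattern> %d spots, %d control points",
              nrow(x$spots), nrow(x$control_points)))
  if (!is.na(x$energy_MeV)) cat(sprintf(", energy %g MeV", x$energy_MeV))
  cat("\n")
  invisible(x)
}

#' Write a spot pattern as CSV
#'
#' Columns: `order`, `x_mm`, `y_mm`, `weight`, `control_point_after` (0/1,
#' set on the last spot before each pause). No vendor machine-file dialect
#' is attempted.
#'
#' @param pattern A [spiral_pattern()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spot_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "spot_pattern"))
  df <- pattern$spots[c("order", "x_mm", "y_mm", "weight")]
  df$control_point_after <-
    as.integer(df$order %in% pattern$control_points$after_index)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Field size factors from cumulative charge readings
#'
#' Converts the chamber readings of one spiral delivery — one cumulative
#' charge per control point plus a final reading for the full field — into
#' FSF records by normalizing each reading to the reading at the reference
#' field size. The reference field itself is not emitted (its FSF is 1 by
#' definition).
#'
#' @param charges Cumulative charge readings, one per control point plus one
#'   final full-field reading, in delivery order. Must be non-decreasing.
#' @param pause_field_sizes_cm Field sizes at the control points, in
#'   delivery order.
#' @param max_field_size_cm Field size of the final reading, cm.
#' @param ref_field_size_cm Reference field size; must be one of the pause
#'   field sizes (or the maximum).
#' @param energy_MeV,plane_z_mm Coordinates stamped onto the records.
#' @return An FSF table data frame (see [fsf_records()]), one row per
#'   non-reference field size.
#' @export
cumulative_fsf_from_charges <- function(charges,
                                        pause_field_sizes_cm = c(2, 4, 6, 8, 10),
                                        max_field_size_cm = 20,
                                        ref_field_size_cm = 10,
                                        energy_MeV = NA_real_,
                                        plane_z_mm = NA_real_) {
  fs <- c(pause_field_sizes_cm, max_field_size_cm)
  if (length(charges) != length(fs)) {
    stop(sprintf("expected %d readings (%d control points + final), got %d",
                 length(fs), length(pause_field_sizes_cm), length(charges)))
  }
  if (any(diff(charges) < 0)) {
    stop("cumulative charges must be non-decreasing")
  }
  ref_idx <- which(fs == ref_field_size_cm)
  if (length(ref_idx) != 1L) {
    stop(sprintf("reference field size %g cm is not among the recorded field sizes",
                 ref_field_size_cm))
  }
  keep <- seq_along(fs)[-ref_idx]
  fsf_records(energy_MeV = energy_MeV, plane_z_mm = plane_z_mm,
              field_size_cm = fs[keep],
              ref_field_size_cm = ref_field_size_cm,
              fsf = charges[keep] / charges[ref_idx])
}
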