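#' Build a machine energy-layer list
#'
#' Uniformly spaced nominal energies including both endpoints. Real
#' machines use non-uniform layer lists; arbitrary lists can be supplied to
#' [interpolate_table()] directly, this helper only covers the uniform
#' default.
#'
#' @param e_min_MeV,e_max_MeV Endpoint nominal energies, MeV.
#' @param n_layers Number of layers (>= 2).
#' @return Sorted numeric vector of energies.
#' @examples
#' length(build_layer_list(80.3, 175.6, 68))  # 68
#' @export
build_layer_list <- function(e_min_MeV, e_max_MeV, n_layers) {
  stopifnot(n_layers >= 2L, e_min_MeV < e_max_MeV)
  seq(e_min_MeV, e_max_MeV, length.out = n_layers)
}

# Shape-preserving interpolant in energy with clamped-linear extrapolation.
# monoH.FC guarantees no overshoot between knots, which keeps sigma > 0 and
# w2 inside [0, 0.5] without clipping; outside the fitted range the curve
# continues linearly with the boundary slope, then values are clamped to
# the stated bounds.
interp_fun <- function(e_fit, y_fit, lower = -Inf, upper = Inf) {
  sf <- stats::splinefun(e_fit, y_fit, method = "monoH.FC")
  e1 <- min(e_fit); e2 <- max(e_fit)
  d1 <- sf(e1, deriv = 1L); d2 <- sf(e2, deriv = 1L)
  function(e) {
    y <- ifelse(e < e1, y_fit[which.min(e_fit)] + d1 * (e - e1),
                ifelse(e > e2, y_fit[which.max(e_fit)] + d2 * (e - e2),
                       sf(e)))
    pmin(pmax(y, lower), upper)
  }
}

#' Interpolate fitted fluence parameters over the full layer list
#'
#' Fitting is done at a handful of measured energies; the machine delivers
#' many more layers. This interpolates `sigma1` and `sigma2` per plane and
#' the shared `w2` across energy with a shape-preserving monotone piecewise
#' cubic (Fritsch-Carlson Hermite), which passes exactly through the fitted
#' values and never overshoots the bracketing fitted values — so positivity
#' of the widths and the `[0, 0.5]` weight range are preserved without
#' clipping. Layers outside the fitted energy range are extrapolated
#' linearly with the boundary slope (clamped to the parameter bounds) and
#' reported with a message.
#'
#' @param fits List of [fit_energy()] results at >= 2 distinct energies,
#'   all sharing the same plane set.
#' @param layer_list Energies (MeV) of the full machine layer list.
#' @return An object of class `fluence_model_table`: a data frame with one
#'   row per (energy, plane) and columns `energy_MeV`, `plane_z_mm`,
#'   `sigma1_mm`, `sigma2_mm`, `w2`, `provenance` ("fitted" or
#'   "interpolated").
#' @export
interpolate_table <- function(fits, layer_list) {
  if (inherits(fits, "fsf_fit")) fits <- list(fits)
  stopifnot(all(vapply(fits, inherits, TRUE, "fsf_fit")))
  e_fit <- vapply(fits, function(f) f$energy_MeV, 0)
  if (length(unique(e_fit)) < 2L) {
    stop("at least 2 fitted energies are required for interpolation")
  }
  o <- order(e_fit)
  fits <- fits[o]; e_fit <- e_fit[o]
  planes <- fits[[1L]]$per_plane$plane_z_mm
  for (f in fits) {
    if (!identical(f$per_plane$plane_z_mm, planes)) {
      stop("all fits must share the same plane set")
    }
  }
  layer_list <- sort(as.numeric(layer_list))
  if (any(layer_list < min(e_fit)) || any(layer_list > max(e_fit))) {
    message(sprintf("extrapolating outside the fitted range [%g, %g] MeV (clamped linear)",
                    min(e_fit), max(e_fit)))
  }
  # a layer "is" a fitted energy when it matches to within numerical noise
  fit_idx <- vapply(layer_list, function(e) {
    k <- which(abs(e_fit - e) < 1e-9)
    if (length(k)) k[1L] else NA_integer_
  }, 0L)

  w2_fun <- interp_fun(e_fit, vapply(fits, function(f) f$w2, 0), 0, 0.5)
  rows <- vector("list", length(planes))
  for (k in seq_along(planes)) {
    s1_fit <- vapply(fits, function(f) f$per_plane$sigma1_mm[k], 0)
    s2_fit <- vapply(fits, function(f) f$per_plane$sigma2_mm[k], 0)
    s1_fun <- interp_fun(e_fit, s1_fit, lower = 1e-3)
    s2_fun <- interp_fun(e_fit, s2_fit, lower = 1e-3)
    s1 <- s1_fun(layer_list); s2 <- s2_fun(layer_list)
    w2 <- w2_fun(layer_list)
    # exact pass-through at fitted energies
    hit <- !is.na(fit_idx)
    s1[hit] <- s1_fit[fit_idx[hit]]
    s2[hit] <- s2_fit[fit_idx[hit]]
    w2[hit] <- vapply(fits[fit_idx[hit]], function(f) f$w2, 0)
    rows[[k]] <- data.frame(
      energy_MeV = layer_list, plane_z_mm = planes[k],
      sigma1_mm = s1, sigma2_mm = pmax(s2, s1), w2 = w2,
      provenance = ifelse(hit, "fitted", "interpolated"))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$energy_MeV, out$plane_z_mm), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fluence_model_table", "data.frame")
  out
}

#' Look up spot parameters in a fluence model table
#'
#' @param table A [interpolate_table()] result.
#' @param energy_MeV,plane_z_mm Coordinates of the requested entry (must
#'   match a table row exactly).
#' @return A [spot_params()] object.
#' @export
model_params <- function(table, energy_MeV, plane_z_mm) {
  k <- which(abs(table$energy_MeV - energy_MeV) < 1e-9 &
               table$plane_z_mm == plane_z_mm)
  if (length(k) != 1L) {
    stop(sprintf("no unique table entry for %g MeV at z = %g mm",
                 energy_MeV, plane_z_mm))
  }
  spot_params(table$sigma1_mm[k], table$sigma2_mm[k], table$w2[k])
}

#' Read / write the fluence model table as JSON
#'
#' Schema: an object keyed by energy, each holding a `provenance` flag and
#' a `planes` object keyed by plane offset with `sigma1_mm`, `sigma2_mm`,
#' `w2` fields.
#'
#' @param table A `fluence_model_table`.
#' @param path File path.
#' @return `write_model_table` returns `path` invisibly;
#'   `read_model_table` returns the `fluence_model_table`.
#' @export
write_model_table <- function(table, path) {
  stopifnot(inherits(table, "fluence_model_table"))
  energies <- unique(table$energy_MeV)
  obj <- lapply(energies, function(e) {
    sub <- table[table$energy_MeV == e, , drop = FALSE]
    planes <- lapply(seq_len(nrow(sub)), function(i) {
      list(sigma1_mm = sub$sigma1_mm[i], sigma2_mm = sub$sigma2_mm[i],
           w2 = sub$w2[i])
    })
    names(planes) <- format(sub$plane_z_mm, trim = TRUE)
    list(provenance = sub$provenance[1L], planes = planes)
  })
  names(obj) <- format(energies, digits = 12, trim = TRUE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_table
#' @export
read_model_table <- function(path) {
  obj <- jsonlite::read_json(path)
  rows <- list()
  for (e_name in names(obj)) {
    entry <- obj[[e_name]]
    if (is.null(entry$planes) || is.null(entry$provenance)) {
      stop("model table JSON is missing 'planes' or 'provenance' at energy ",
           e_name)
    }
    for (z_name in names(entry$planes)) {
      p <- entry$planes[[z_name]]
      if (!all(c("sigma1_mm", "sigma2_mm", "w2") %in% names(p))) {
        stop("model table entry lacks sigma1_mm/sigma2_mm/w2 at energy ",
             e_name, ", plane ", z_name)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        energy_MeV = as.numeric(e_name), plane_z_mm = as.numeric(z_name),
        sigma1_mm = p$sigma1_mm, sigma2_mm = p$sigma2_mm, w2 = p$w2,
        provenance = entry$provenance)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$energy_MeV, out$plane_z_mm), , drop = FALSE]
  rownames(out) <- NULL
  if (any(out$sigma1_mm <= 0) || any(out$sigma2_mm < out$sigma1_mm) ||
      any(out$w2 < 0 | out$w2 > 0.5)) {
    stop("model table violates parameter bounds")
  }
  class(out) <- c("fluence_model_table", "data.frame")
  out
}
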