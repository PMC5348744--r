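#' Read a beamline / fit configuration file
#'
#' YAML with two optional blocks. `geometry`: `vsad_x_mm`, `vsad_y_mm` (or
#' `parallel: true`), `spot_spacing_mm`, `plane_offsets_mm`; lengths may
#' also be given in cm via keys ending in `_cm`. `fit`: any argument of
#' [fit_settings()]. Missing blocks fall back to package defaults.
#'
#' @param path Path to the YAML file.
#' @return A list with elements `geometry` (a [beam_geometry()]) and
#'   `fit` (a [fit_settings()]).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  g <- cfg$geometry
  to_mm <- function(block, key) {
    if (!is.null(block[[paste0(key, "_mm")]])) return(block[[paste0(key, "_mm")]])
    if (!is.null(block[[paste0(key, "_cm")]])) return(10 * block[[paste0(key, "_cm")]])
    NULL
  }
  geom_args <- list()
  if (!is.null(g)) {
    for (key in c("vsad_x", "vsad_y", "spot_spacing", "plane_offsets")) {
      v <- to_mm(g, key)
      if (!is.null(v)) geom_args[[paste0(key, "_mm")]] <- unlist(v)
    }
    if (isTRUE(g$parallel)) geom_args$parallel <- TRUE
  }
  geometry <- do.call(beam_geometry, geom_args)
  fit_args <- cfg$fit
  if (!is.null(fit_args)) {
    bad <- setdiff(names(fit_args), names(formals(fit_settings)))
    if (length(bad)) stop("unknown fit settings: ", paste(bad, collapse = ", "))
    fit_args <- lapply(fit_args, unlist)
  }
  fit <- do.call(fit_settings, as.list(fit_args))
  list(geometry = geometry, fit = fit)
}
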