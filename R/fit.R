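#' Settings for the FSF parameter fit
#'
#' The fit proceeds in two stages: a deterministic coarse grid search over
#' candidate `(sigma1, sigma2/sigma1, w2)` triples, then derivative-free
#' (Nelder-Mead) local refinement of the per-plane widths nested inside a
#' golden-section refinement of the shared halo weight. The grid defaults
#' bracket the range-shifter-broadened spot regime: spots of a few mm to a
#' couple of cm, halos several times wider.
#'
#' @param sigma1_grid_mm Coarse-grid candidates for the primary width, mm.
#' @param ratio_grid Candidates for `sigma2 / sigma1` (>= 1).
#' @param w2_grid Candidates for the shared secondary-Gaussian weight.
#' @param sigma1_bounds_mm,sigma2_max_mm,w2_bounds Hard parameter bounds.
#' @param refine If `FALSE`, return the best coarse-grid candidate (pure
#'   grid search).
#' @param reltol Relative convergence tolerance on the refinement objective.
#' @param maxit Maximum Nelder-Mead iterations per plane refinement.
#' @return A list of class `fit_settings`.
#' @export
fit_settings <- function(sigma1_grid_mm = exp(seq(log(1), log(20), length.out = 20)),
                         ratio_grid = exp(seq(log(1.5), log(10), length.out = 10)),
                         w2_grid = seq(0, 0.3, length.out = 11),
                         sigma1_bounds_mm = c(0.5, 30),
                         sigma2_max_mm = 150,
                         w2_bounds = c(0, 0.5),
                         refine = TRUE,
                         reltol = 1e-10,
                         maxit = 400) {
  structure(list(sigma1_grid_mm = sigma1_grid_mm, ratio_grid = ratio_grid,
                 w2_grid = w2_grid, sigma1_bounds_mm = sigma1_bounds_mm,
                 sigma2_max_mm = sigma2_max_mm, w2_bounds = w2_bounds,
                 refine = isTRUE(refine), reltol = reltol, maxit = maxit),
            class = "fit_settings")
}

# Per-plane sum of squared relative FSF differences for one (s1, s2, w2).
# Squared lattice offsets per field size are precomputed once; the 2-D
# Gaussian lattice sum factorizes into x and y line sums, and the 2*pi
# normalization cancels in the FSF ratio.
plane_objective_fn <- function(recs, geom) {
  z <- recs$plane_z_mm[1L]
  ref <- recs$ref_field_size_cm[1L]
  fs_all <- unique(c(recs$field_size_cm, ref))
  idx <- match(recs$field_size_cm, fs_all)
  ref_idx <- match(ref, fs_all)
  ssx <- projected_spacing(geom, z, "x")
  ssy <- projected_spacing(geom, z, "y")
  d2x <- lapply(fs_all, function(fs) {
    n <- half_index(fs, geom$spot_spacing_mm)
    ((-n:n) * ssx)^2
  })
  d2y <- lapply(fs_all, function(fs) {
    n <- half_index(fs, geom$spot_spacing_mm)
    ((-n:n) * ssy)^2
  })
  meas <- recs$fsf
  function(s1, s2, w2) {
    a1 <- 1 / (2 * s1^2)
    a2 <- 1 / (2 * s2^2)
    cf <- vapply(seq_along(fs_all), function(k) {
      v <- (1 - w2) * 2 * a1 * sum(exp(-d2x[[k]] * a1)) * sum(exp(-d2y[[k]] * a1))
      if (w2 > 0) {
        v <- v + w2 * 2 * a2 * sum(exp(-d2x[[k]] * a2)) * sum(exp(-d2y[[k]] * a2))
      }
      v
    }, 0)
    model <- cf[idx] / cf[ref_idx]
    sum(((model - meas) / meas)^2)
  }
}

# Coarse grid: for a fixed shared w2 the joint objective separates by plane,
# so the exact grid minimum is the sum of per-plane minima. Ties broken
# toward smaller sigma1, then smaller w2 (grids iterated in ascending order
# with strict improvement). Returns the per-w2 candidates so refinement can
# start from each.
grid_search <- function(obj_fns, settings) {
  n_ratio <- length(settings$ratio_grid)
  per_w2 <- lapply(sort(settings$w2_grid), function(w2) {
    tot <- 0
    per_plane <- vector("list", length(obj_fns))
    for (k in seq_along(obj_fns)) {
      # best candidate per sigma2/sigma1 ratio: the objective can have a
      # second basin where a very wide sigma2 mimics a flat pedestal, so
      # refinement later starts from several distinct-ratio candidates
      by_ratio <- vector("list", n_ratio)
      for (s1 in sort(settings$sigma1_grid_mm)) {
        for (ri in seq_len(n_ratio)) {
          s2 <- s1 * settings$ratio_grid[ri]
          if (s2 > settings$sigma2_max_mm) next
          v <- obj_fns[[k]](s1, s2, w2)
          if (is.null(by_ratio[[ri]]) || v < by_ratio[[ri]]$value) {
            by_ratio[[ri]] <- list(s1 = s1, s2 = s2, value = v)
          }
        }
      }
      by_ratio <- by_ratio[!vapply(by_ratio, is.null, TRUE)]
      ord <- order(vapply(by_ratio, function(c) c$value, 0))
      pb <- by_ratio[[ord[1L]]]
      pb$starts <- by_ratio[ord[seq_len(min(4L, length(ord)))]]
      tot <- tot + pb$value
      per_plane[[k]] <- pb
    }
    list(w2 = w2, per_plane = per_plane, value = tot)
  })
  vals <- vapply(per_w2, function(c) c$value, 0)
  best <- per_w2[[which.min(vals)]]
  best$per_w2 <- per_w2
  best
}

# Nelder-Mead refinement of (sigma1, sigma2) for one plane at fixed w2.
# Parameters are log-transformed (sigma2 = sigma1 * (1 + exp(q))) so the
# ordering constraint holds by construction; hard bounds enter as a smooth
# quadratic penalty.
refine_plane <- function(obj, s1_start, s2_start, w2, settings) {
  lo <- settings$sigma1_bounds_mm[1L]
  hi <- settings$sigma1_bounds_mm[2L]
  s2max <- settings$sigma2_max_mm
  par0 <- c(log(s1_start), log(max(s2_start / s1_start - 1, 1e-6)))
  fn <- function(p) {
    s1 <- exp(p[1L])
    s2 <- s1 * (1 + exp(p[2L]))
    pen <- 0
    if (s1 < lo) pen <- pen + 1e4 * (lo - s1)^2
    if (s1 > hi) pen <- pen + 1e4 * (s1 - hi)^2
    if (s2 > s2max) pen <- pen + 1e4 * ((s2 - s2max) / s2max)^2
    obj(min(max(s1, lo), hi), min(s2, s2max), w2) + pen
  }
  res <- stats::optim(par0, fn, method = "Nelder-Mead",
                      control = list(reltol = settings$reltol,
                                     maxit = settings$maxit))
  s1 <- min(max(exp(res$par[1L]), lo), hi)
  s2 <- min(s1 * (1 + exp(res$par[2L])), s2max)
  list(s1 = s1, s2 = s2, value = res$value, converged = res$convergence == 0L)
}

#' Fit double-Gaussian fluence parameters for one energy
#'
#' Estimates a primary width `sigma1` and secondary width `sigma2` per
#' measurement plane, plus a single secondary-Gaussian weight `w2` shared
#' across planes (the halo weight depends on energy, not on the plane), by
#' minimizing the sum over all records of squared relative differences
#' between modeled and measured FSFs. A deterministic coarse grid search
#' supplies the starting point; derivative-free refinement then polishes the
#' widths per plane inside a 1-D search over `w2`. The returned objective is
#' never worse than the best coarse-grid candidate.
#'
#' @param records FSF table rows for a single energy (>= 3 distinct field
#'   sizes per plane, identifiability requirement).
#' @param geom A [beam_geometry()].
#' @param settings A [fit_settings()].
#' @return An object of class `fsf_fit`: list with `energy_MeV`,
#'   `per_plane` (data frame `plane_z_mm`, `sigma1_mm`, `sigma2_mm`), `w2`,
#'   `residuals` (the input records plus `model_fsf` and `rel_diff`
#'   columns), `objective_value`, `converged`.
#' @export
fit_energy <- function(records, geom, settings = fit_settings()) {
  records <- validate_fsf_table(records)
  stopifnot(inherits(geom, "beam_geometry"))
  if (length(unique(records$energy_MeV)) != 1L) {
    stop("fit_energy expects records of a single energy")
  }
  planes <- sort(unique(records$plane_z_mm))
  by_plane <- lapply(planes, function(z)
    records[records$plane_z_mm == z, , drop = FALSE])
  for (k in seq_along(planes)) {
    nfs <- length(unique(by_plane[[k]]$field_size_cm))
    if (nfs < 3L) {
      stop(sprintf("plane z = %g mm has only %d distinct field sizes; >= 3 needed to identify (sigma1, sigma2)",
                   planes[k], nfs))
    }
  }
  obj_fns <- lapply(by_plane, plane_objective_fn, geom = geom)

  g <- grid_search(obj_fns, settings)
  best <- g
  converged <- TRUE

  if (settings$refine) {
    # polish the per-plane widths at a given w2 from a list of starting
    # points per plane; the per-plane problems are independent given w2
    grid_w2 <- vapply(g$per_w2, function(c) c$w2, 0)
    refine_at_w2 <- function(w2, starts) {
      pp <- vector("list", length(obj_fns))
      tot <- 0
      ok <- TRUE
      for (k in seq_along(obj_fns)) {
        rb <- NULL
        for (st in starts[[k]]) {
          r <- refine_plane(obj_fns[[k]], st$s1, st$s2, w2, settings)
          if (is.null(rb) || r$value < rb$value) rb <- r
        }
        pp[[k]] <- rb
        tot <- tot + rb$value
        ok <- ok && rb$converged
      }
      list(w2 = w2, per_plane = pp, value = tot, converged = ok)
    }
    # refined objective profile over the w2 grid: the coarse sigma grid can
    # alias the w2 minimum, polishing per plane before comparing removes it
    profile <- lapply(seq_along(grid_w2), function(i) {
      refine_at_w2(grid_w2[i],
                   lapply(g$per_w2[[i]]$per_plane, function(p) p$starts))
    })
    pvals <- vapply(profile, function(c) c$value, 0)
    kbest <- which.min(pvals)
    cand <- profile[[kbest]]
    # golden-section polish of w2 between the neighbouring grid points,
    # restarting each plane from the profile optimum
    cand_starts <- lapply(cand$per_plane, function(p) list(p))
    lo <- grid_w2[max(kbest - 1L, 1L)]
    hi <- grid_w2[min(kbest + 1L, length(grid_w2))]
    lo <- max(settings$w2_bounds[1L], lo)
    hi <- min(settings$w2_bounds[2L], hi)
    if (hi > lo) {
      opt <- stats::optimize(function(w2) refine_at_w2(w2, cand_starts)$value,
                             interval = c(lo, hi), tol = 1e-5)
      cand2 <- refine_at_w2(opt$minimum, cand_starts)
      if (cand2$value < cand$value) cand <- cand2
    }
    if (cand$value < best$value) {
      best <- cand
      converged <- cand$converged
    }
  }

  per_plane <- data.frame(
    plane_z_mm = planes,
    sigma1_mm = vapply(best$per_plane, function(p) p$s1, 0),
    sigma2_mm = vapply(best$per_plane, function(p) p$s2, 0))
  params_of <- function(z) {
    k <- match(z, planes)
    spot_params(per_plane$sigma1_mm[k], per_plane$sigma2_mm[k], best$w2)
  }
  model <- mapply(function(z, fs, ref) {
    fsf(params_of(z), geom, z, fs, ref)
  }, records$plane_z_mm, records$field_size_cm, records$ref_field_size_cm)
  residuals <- records
  residuals$model_fsf <- as.numeric(model)
  residuals$rel_diff <- (residuals$model_fsf - residuals$fsf) / residuals$fsf

  structure(list(energy_MeV = records$energy_MeV[1L],
                 per_plane = per_plane, w2 = best$w2,
                 residuals = residuals,
                 objective_value = best$value,
                 grid_objective_value = g$value,
                 converged = converged),
            class = "fsf_fit")
}

#' @export
print.fsf_fit <- function(x, ...) {
  cat(sprintf("<fsf_fit> energy %g MeV, w2 = %.4f, objective = %.3g%s\n",
              x$energy_MeV, x$w2, x$objective_value,
              if (x$converged) "" else " (not converged)"))
  print(x$per_plane, row.names = FALSE)
  invisible(x)
}

#' Fit every energy of an FSF campaign
#'
#' @param records A full FSF table (multiple energies).
#' @inheritParams fit_energy
#' @return A list of [fit_energy()] results, ordered by energy.
#' @export
fit_campaign <- function(records, geom, settings = fit_settings()) {
  records <- validate_fsf_table(records)
  energies <- sort(unique(records$energy_MeV))
  lapply(energies, function(e) {
    fit_energy(records[records$energy_MeV == e, , drop = FALSE],
               geom, settings)
  })
}

box_stats <- function(x_pct) {
  q <- stats::quantile(x_pct, c(0.25, 0.5, 0.75), names = FALSE)
  data.frame(n = length(x_pct), min_pct = min(x_pct), q1_pct = q[1L],
             median_pct = q[2L], q3_pct = q[3L], max_pct = max(x_pct))
}

#' Fit-quality summary over a fitted campaign
#'
#' Box-plot statistics (min, quartiles, median, max) of the relative
#' model-minus-measurement FSF differences, in percent, grouped by field
#' size and by plane, plus the overall maximum absolute difference and the
#' fraction of records within 2%.
#'
#' @param results A single [fit_energy()] result or a list of them.
#' @return A list of class `fsf_fit_summary` with data frames
#'   `by_field_size` and `by_plane` and a list `overall`
#'   (`n`, `max_abs_pct`, `within_2pct_pct`).
#' @export
fit_quality_summary <- function(results) {
  if (inherits(results, "fsf_fit")) results <- list(results)
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, TRUE, "fsf_fit")))
  res <- do.call(rbind, lapply(results, function(f) f$residuals))
  pct <- 100 * res$rel_diff
  by_fs <- do.call(rbind, lapply(split(pct, res$field_size_cm), box_stats))
  by_fs <- cbind(data.frame(field_size_cm = as.numeric(rownames(by_fs))), by_fs)
  rownames(by_fs) <- NULL
  by_pl <- do.call(rbind, lapply(split(pct, res$plane_z_mm), box_stats))
  by_pl <- cbind(data.frame(plane_z_mm = as.numeric(rownames(by_pl))), by_pl)
  rownames(by_pl) <- NULL
  structure(list(
    by_field_size = by_fs,
    by_plane = by_pl,
    overall = list(n = length(pct),
                   max_abs_pct = max(abs(pct)),
                   within_2pct_pct = 100 * mean(abs(pct) <= 2))),
    class = "fsf_fit_summary")
}

#' @export
print.fsf_fit_summary <- function(x, ...) {
  cat(sprintf("<fsf_fit_summary> %d records, max |diff| = %.3f%%, %.1f%% within 2%%\n",
              x$overall$n, x$overall$max_abs_pct, x$overall$within_2pct_pct))
  cat("by field size:\n"); print(x$by_field_size, row.names = FALSE, digits = 3)
  cat("by plane:\n"); print(x$by_plane, row.names = FALSE, digits = 3)
  invisible(x)
}
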