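#' Fluence-rate field from a Monte Carlo score
#'
#' Two estimators. The absorption estimator divides the absorbed power
#' density by `mu_a`: `Phi_i = P A_i / (mu_a_i V_i)` with `A_i` the absorbed
#' fraction of emitted energy; it is undefined (`NA`) where `mu_a = 0`. The
#' track-length estimator uses the weighted path length:
#' `Phi_i = P L_i / V_i`; it is defined everywhere, including transparent
#' regions. Internally mm-based; results are converted to mW cm^-2.
#'
#' @param score a [run_mc()] result.
#' @param mesh the mesh simulated.
#' @param materials the materials used.
#' @param total_power total source power in mW (defaults to the power
#'   recorded in the score).
#' @param estimator `"absorption"` or `"track_length"`.
#' @return object of class `fluence_field`: `phi` (per-tet fluence rate,
#'   mW cm^-2), `estimator`, `total_power`.
#' @export
fluence_from_score <- function(score, mesh, materials,
                               total_power = score$total_power,
                               estimator = c("track_length", "absorption")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(score, "raw_score"), inherits(mesh, "tetra_mesh"))
  emitted <- score$ledger$emitted
  if (estimator == "absorption") {
    mt <- .material_table(mesh, materials)
    mu_a <- unname(mt$mat[mt$rows + 1L, 1L])
    phi_mm <- total_power * (score$absorbed / emitted) / (mu_a * mesh$volume)
    if (any(mu_a == 0)) {
      phi_mm[mu_a == 0] <- NA_real_
      warning("absorption estimator undefined in mu_a = 0 region(s); ",
              "entries flagged NA (use the track_length estimator)")
    }
  } else {
    phi_mm <- total_power * (score$tracklen / emitted) / mesh$volume
  }
  structure(list(phi = phi_mm * 100,  # mW mm^-2 -> mW cm^-2
                 estimator = estimator, total_power = total_power),
            class = "fluence_field")
}

#' Per-boundary-face exitance
#'
#' @param score a [run_mc()] result.
#' @param mesh the mesh simulated.
#' @param total_power total source power, mW.
#' @return tibble with `tet`, `face`, `area_mm2`, `exitance` (mW cm^-2).
#' @export
surface_exitance <- function(score, mesh, total_power = score$total_power) {
  bf <- mesh$boundary_faces
  w <- score$exited[bf]
  areas <- face_areas(mesh, bf)
  tibble::tibble(tet = bf[, 1L], face = bf[, 2L], area_mm2 = areas,
                 exitance = 100 * total_power * (w / score$ledger$emitted) / areas)
}

.phi_of <- function(field) {
  if (inherits(field, "fluence_field")) field$phi else as.numeric(field)
}

.threshold_per_tet <- function(thresholds, mesh, regions = NULL) {
  stopifnot(is.numeric(thresholds), !is.null(names(thresholds)))
  if (is.null(regions)) regions <- unique(mesh$region)
  missing <- setdiff(as.character(regions), names(thresholds))
  if (length(missing) > 0L)
    stop("no threshold for region(s): ", paste(missing, collapse = ", "))
  unname(thresholds[as.character(mesh$region)])
}

#' Dose-volume histogram
#'
#' Volume-weighted survival curve per region: the x axis is the dose as a
#' percentage of that region's threshold, the y axis the percentage of the
#' region's volume receiving at least that dose. `y(0) = 100` and the curve
#' is nonincreasing. Doses are piecewise-constant per tet.
#'
#' @param field a [fluence_from_score()] result (or a plain per-tet numeric
#'   dose vector).
#' @param thresholds named numeric vector of per-region threshold doses
#'   (names = region labels), same units as the field.
#' @param mesh the mesh.
#' @param regions regions to include (default: all regions with thresholds
#'   present among mesh regions).
#' @param bins number of uniform dose bins (default 1000).
#' @return tibble of class `dvh_curve` with columns `region`, `dose_pct`,
#'   `volume_pct`.
#' @export
compute_dvh <- function(field, thresholds, mesh, regions = NULL, bins = 1000L) {
  phi <- .phi_of(field)
  if (is.null(regions))
    regions <- intersect(as.character(unique(mesh$region)), names(thresholds))
  if (length(regions) == 0L) stop("no region to plot")
  tt <- .threshold_per_tet(thresholds, mesh, regions)
  ratio <- 100 * phi / tt
  xmax <- max(ratio[mesh$region %in% as.integer(regions)], 0, na.rm = TRUE)
  xs <- seq(0, max(xmax, 100), length.out = bins)
  out <- lapply(regions, function(r) {
    idx <- mesh$region == as.integer(r)
    v <- mesh$volume[idx]
    rr <- ratio[idx]
    y <- vapply(xs, function(x) 100 * sum(v[rr >= x]) / sum(v), numeric(1L))
    tibble::tibble(region = as.integer(r), dose_pct = xs, volume_pct = y)
  })
  res <- do.call(rbind, out)
  class(res) <- c("dvh_curve", class(res))
  res
}

#' Tumor/region coverage fraction
#'
#' Fraction of the region's volume at or above its threshold dose.
#'
#' @inheritParams compute_dvh
#' @param region single region label.
#' @return volume fraction in `[0, 1]`.
#' @export
coverage <- function(field, thresholds, mesh, region) {
  phi <- .phi_of(field)
  idx <- mesh$region == as.integer(region)
  if (!any(idx)) stop("region ", region, " is empty")
  tr <- thresholds[as.character(region)]
  if (is.na(tr)) stop("no threshold for region ", region)
  sum(mesh$volume[idx][phi[idx] >= tr]) / sum(mesh$volume[idx])
}

#' Threshold-model necrosis mask
#'
#' Photodynamic threshold model: a tet is necrosed iff its dose meets or
#' exceeds its region's threshold.
#'
#' @inheritParams compute_dvh
#' @return list with `necrotic` (per-tet logical; `NA` where the region has
#'   no threshold) and `volume_by_region` (named mm^3 of necrosed tissue).
#' @export
necrosis_mask <- function(field, thresholds, mesh) {
  phi <- .phi_of(field)
  tt <- rep(NA_real_, length(mesh$region))
  have <- as.character(mesh$region) %in% names(thresholds)
  tt[have] <- unname(thresholds[as.character(mesh$region[have])])
  nec <- phi >= tt
  regs <- sort(unique(mesh$region[have]))
  vol <- vapply(regs, function(r) {
    idx <- mesh$region == r & !is.na(nec) & nec
    sum(mesh$volume[idx])
  }, numeric(1L))
  list(necrotic = nec, volume_by_region = setNames(vol, as.character(regs)))
}

#' Diffusion-theory point-source fluence rate
#'
#' Closed-form fluence rate of an isotropic point source in an infinite
#' homogeneous medium, `Phi(r) = P exp(-mu_eff r) / (4 pi D r)`, the
#' reference used to validate the Monte Carlo engine.
#'
#' @param r distance(s) from the source, mm (> 0).
#' @param P source power, mW.
#' @param mu_a absorption coefficient, mm^-1 (> 0).
#' @param mu_s_prime reduced scattering coefficient, mm^-1.
#' @return fluence rate(s) in mW cm^-2.
#' @export
analytic_point_fluence <- function(r, P, mu_a, mu_s_prime) {
  if (any(r <= 0)) stop("r must be > 0 (the solution is singular at r = 0)")
  if (mu_a <= 0) stop("mu_a must be > 0")
  D <- 1 / (3 * (mu_a + mu_s_prime))
  mu_eff <- sqrt(3 * mu_a * (mu_a + mu_s_prime))
  100 * P * exp(-mu_eff * r) / (4 * pi * D * r)  # mW mm^-2 -> mW cm^-2
}

#' Sample a field along a line segment
#'
#' Piecewise-constant per-tet readout at `n_samples` equally spaced points.
#' Points outside the mesh get `NA`.
#'
#' @param field a fluence field or per-tet numeric vector.
#' @param mesh the mesh.
#' @param from,to segment endpoints, mm.
#' @param n_samples number of points.
#' @return tibble with `distance` (mm from `from`), `x`, `y`, `z`, `phi`.
#' @export
line_probe <- function(field, mesh, from, to, n_samples = 100L) {
  phi <- .phi_of(field)
  s <- if (n_samples == 1L) 0.5 else seq(0, 1, length.out = n_samples)
  pts <- outer(1 - s, as.numeric(from)) + outer(s, as.numeric(to))
  tet <- locate_tetra(mesh, pts)
  tibble::tibble(distance = s * sqrt(sum((to - from)^2)),
                 x = pts[, 1L], y = pts[, 2L], z = pts[, 3L],
                 phi = ifelse(is.na(tet), NA_real_, phi[tet]))
}

#' Plot a dose-volume histogram
#' @param object a [compute_dvh()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.dvh_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$dose_pct, y = .data$volume_pct,
                               colour = factor(.data$region))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "dose (% of region threshold)",
                  y = "volume receiving at least dose (%)",
                  colour = "region") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.dvh_curve
#' @param dvh a [compute_dvh()] result.
#' @export
plot_dvh <- function(dvh) autoplot.dvh_curve(dvh)

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
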