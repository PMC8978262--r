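#' Optical-property sweep specification
#'
#' Defines a lookup-table sweep: for every `(mu_a, mu_s_prime)` pair the
#' target region's material is overridden and a fresh simulation is run; the
#' fluence rate at each detector position is tabulated.
#'
#' @param mesh the phantom mesh.
#' @param materials baseline [material_set()].
#' @param target_region region whose optical properties are swept.
#' @param mu_a_values,mu_s_prime_values coefficient grids, mm^-1 (nonempty).
#' @param g,n fixed anisotropy and refractive index for the target region.
#' @param source the light source.
#' @param detectors matrix of detector positions (one per row, mm), inside
#'   the mesh.
#' @param packets packets per grid run.
#' @param seed base seed; run `k` (row-major over the grid) uses `seed + k`.
#' @return object of class `sweep_spec`.
#' @export
sweep_spec <- function(mesh, materials, target_region, mu_a_values,
                       mu_s_prime_values, g = 0, n = 1.37, source,
                       detectors, packets = 1e4, seed = 1L) {
  if (length(mu_a_values) == 0L || length(mu_s_prime_values) == 0L)
    stop("coefficient grids must be nonempty")
  detectors <- matrix(as.numeric(detectors), ncol = 3L)
  det_tet <- locate_tetra(mesh, detectors)
  if (anyNA(det_tet)) stop("detector position(s) outside the mesh")
  structure(list(mesh = mesh, materials = materials,
                 target_region = as.integer(target_region),
                 mu_a_values = as.numeric(mu_a_values),
                 mu_s_prime_values = as.numeric(mu_s_prime_values),
                 g = g, n = n, source = source, detectors = detectors,
                 det_tet = det_tet, packets = packets,
                 seed = as.integer(seed)),
            class = "sweep_spec")
}

#' Run an optical-property lookup-table sweep
#'
#' One simulation per grid pair (exactly
#' `length(mu_a_values) * length(mu_s_prime_values)` runs), deterministic
#' sub-seeds. Detector readout is the containing tet's fluence rate
#' (piecewise constant).
#'
#' @param spec a [sweep_spec()].
#' @return tibble of class `lookup_table` with columns `mu_a`, `mu_s_prime`,
#'   `detector`, `fluence_rate` (mW cm^-2 at the source's actual power);
#'   attributes `packets`, `seed`, `n_runs`, `power`.
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- expand.grid(mu_a = spec$mu_a_values,
                      mu_s_prime = spec$mu_s_prime_values)
  n_det <- nrow(spec$detectors)
  rows <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    mats <- spec$materials
    mats[[as.character(spec$target_region)]] <-
      material(region = spec$target_region, mu_a = grid$mu_a[k],
               mu_s_prime = grid$mu_s_prime[k], g = spec$g, n = spec$n)
    cfg <- sim_config(n_packets = spec$packets, seed = spec$seed + k)
    sc <- tryCatch(run_mc(spec$mesh, mats, spec$source, cfg),
                   error = function(e)
                     stop("sweep run failed at grid point (mu_a=",
                          grid$mu_a[k], ", mu_s_prime=", grid$mu_s_prime[k],
                          "): ", conditionMessage(e)))
    field <- fluence_from_score(sc, spec$mesh, mats)
    rows[[k]] <- tibble::tibble(mu_a = grid$mu_a[k],
                                mu_s_prime = grid$mu_s_prime[k],
                                detector = seq_len(n_det),
                                fluence_rate = field$phi[spec$det_tet])
  }
  out <- do.call(rbind, rows)
  attr(out, "packets") <- spec$packets
  attr(out, "seed") <- spec$seed
  attr(out, "n_runs") <- nrow(grid)
  attr(out, "power") <- total_power(spec$source)
  class(out) <- c("lookup_table", class(out))
  out
}

#' Invert a lookup table to estimate optical properties
#'
#' Returns the grid point minimizing the sum over detectors of squared
#' log-ratios between measured and tabulated signals. With a single
#' detector the inversion can be degenerate; candidates within `tol` of the
#' best misfit are counted and reported as `ambiguous`.
#'
#' @param table a [run_sweep()] result.
#' @param measured per-detector measured signals (positive; same order and
#'   units as the table's detectors).
#' @param tol relative misfit band within which alternative grid points are
#'   considered indistinguishable.
#' @return list with `mu_a`, `mu_s_prime`, `misfit`, `ambiguous` (logical),
#'   `n_candidates`.
#' @export
invert_lookup <- function(table, measured, tol = 1e-6) {
  stopifnot(inherits(table, "lookup_table"))
  if (any(measured <= 0)) stop("measured signals must be positive")
  n_det <- length(unique(table$detector))
  if (length(measured) != n_det)
    stop("expected ", n_det, " detector signal(s)")
  key <- paste(table$mu_a, table$mu_s_prime)
  split_idx <- split(seq_len(nrow(table)), key)
  mis <- vapply(split_idx, function(ii) {
    tab <- table$fluence_rate[ii][order(table$detector[ii])]
    if (any(tab <= 0)) return(Inf)
    sum((log(measured) - log(tab))^2)
  }, numeric(1L))
  best <- which.min(mis)
  ii <- split_idx[[best]][1L]
  n_cand <- sum(mis <= mis[best] + tol * max(1, abs(mis[best])))
  list(mu_a = table$mu_a[ii], mu_s_prime = table$mu_s_prime[ii],
       misfit = unname(mis[best]),
       ambiguous = n_det < 2L && n_cand > 1L,
       n_candidates = n_cand)
}

#' Diffuser dose-escalation workflow
#'
#' Seats cylindrical diffusers in a vessel lumen, simulates each at unit
#' power, scales the powers so the maximum fluence rate on the intima (wall
#' tets in contact with the lumen) stays below `limit`, and reports the
#' maximum permissible powers, the fluence profile between diffuser
#' midpoints, the peak-to-midpoint attenuation factor, and per-region
#' necrotic volumes under the photodynamic threshold model.
#'
#' @param mesh vessel phantom mesh.
#' @param materials a [material_set()].
#' @param diffusers list of [source_cyl_diffuser()] sources (initial powers
#'   are the pre-escalation request).
#' @param lumen_region,wall_region region labels of the vessel lumen and
#'   wall; the intima surface is the set of wall tets adjacent to the lumen.
#' @param limit intima fluence-rate cap, mW cm^-2 (default 300).
#' @param thresholds optional named per-region threshold doses for the
#'   necrosis report.
#' @param packets packets per diffuser run.
#' @param seed base seed.
#' @return list with `powers` (scaled, mW), `scale`, `intima_max`
#'   (mW cm^-2, after scaling), `profile` (tibble along the inter-diffuser
#'   line, or along the diffuser axis if only one), `attenuation_factor`
#'   (peak / midpoint fluence rate), `necrotic_volume`, `dose_matrix`.
#' @export
dose_escalation <- function(mesh, materials, diffusers, lumen_region,
                            wall_region, limit = 300, thresholds = NULL,
                            packets = 1e5, seed = 1L) {
  if (inherits(diffusers, "light_source")) diffusers <- list(diffusers)
  stopifnot(all(vapply(diffusers, function(d) d$type == "cyl_diffuser",
                       logical(1L))))
  dm <- build_dose_matrix(mesh, materials, diffusers, packets = packets,
                          seed = seed)
  p0 <- vapply(diffusers, function(d) d$power, numeric(1L))
  intima <- interface_tets(mesh, region = wall_region, touching = lumen_region)
  if (length(intima) == 0L) stop("no wall tets adjacent to the lumen")
  surf <- as.numeric(dm$phi[intima, , drop = FALSE] %*% p0)
  plan <- structure(list(powers = p0, sources = diffusers,
                         tumor_region = NA_integer_),
                    class = "pdt_plan")
  plan <- enforce_surface_limit(plan, surf, limit)

  field <- as.numeric(dm$phi %*% plan$powers)
  centers <- t(vapply(diffusers, function(d) d$center, numeric(3L)))
  if (length(diffusers) >= 2L) {
    from <- centers[1L, ]; to <- centers[2L, ]
  } else {
    d <- diffusers[[1L]]
    from <- d$center - d$axis * d$length
    to <- d$center + d$axis * d$length
  }
  profile <- line_probe(field, mesh, from, to, n_samples = 101L)
  peak <- max(profile$phi, na.rm = TRUE)
  midpoint <- profile$phi[ceiling(nrow(profile) / 2)]
  nec <- if (!is.null(thresholds))
    necrosis_mask(field, thresholds, mesh)$volume_by_region else NULL

  list(powers = plan$powers, scale = plan$surface_scale,
       intima_max = plan$surface_max, limit = limit,
       intima_tets = intima, profile = profile,
       attenuation_factor = peak / midpoint,
       necrotic_volume = nec, dose_matrix = dm)
}
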