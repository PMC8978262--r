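# Fixtures are built in code; nothing is read from disk.

# unit right tetrahedron: vertices at the origin and the three unit axes
unit_tet_mesh <- function() {
  tetra_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
             matrix(1:4, 1L), region = 0L)
}

# homogeneous box mesh, region 0
box_mesh <- function(extents = c(40, 40, 40), cells = c(6L, 6L, 6L)) {
  generate_phantom(phantom_spec("box", extents = extents, cells = cells))
}

uniform_materials <- function(regions = 0L, mu_a = 0.02, mu_s = 1, g = 0,
                              n = 1.37, mu_s_prime = NULL) {
  material_set(lapply(regions, function(r)
    material(r, mu_a = mu_a, mu_s = if (is.null(mu_s_prime)) mu_s else NULL,
             g = g, n = n, mu_s_prime = mu_s_prime)))
}

# dose_matrix built directly from a phi matrix (for optimizer unit tests)
fake_dose_matrix <- function(phi, volume, region) {
  structure(list(phi = phi, volume = volume, region = as.integer(region),
                 sources = replicate(ncol(phi), source_point(c(0, 0, 0), 1),
                                     simplify = FALSE),
                 seeds = seq_len(ncol(phi)), packets = 0,
                 scores = vector("list", ncol(phi))),
            class = "dose_matrix")
}

# hinge-LP objective at tumor weight w_t (reference implementation for tests)
hinge_objective <- function(phi, volume, region, thresholds, tumor_region,
                            w_t, p) {
  dose <- as.numeric(phi %*% p)
  tum <- region == tumor_region
  oar_regions <- setdiff(intersect(as.character(unique(region)),
                                   names(thresholds)),
                         as.character(tumor_region))
  v <- 0
  for (r in oar_regions) {
    idx <- region == as.integer(r)
    v <- v + sum(volume[idx] * pmax(0, dose[idx] - thresholds[r]))
  }
  t_t <- thresholds[as.character(tumor_region)]
  v + w_t * sum(volume[tum] * pmax(0, t_t - dose[tum]))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# multi-stage grid search over the power box (coarse scan + local refinement;
# valid because the hinge objective is convex, so there is a single basin)
grid_search_powers <- function(f, p_hi, n_coarse = 13L, n_refine = 6L,
                               shrink = 4) {
  J <- length(p_hi)
  lo <- rep(0, J)
  hi <- p_hi
  best <- NULL
  best_v <- Inf
  for (stage in seq_len(n_refine)) {
    grids <- lapply(seq_len(J), function(j) seq(lo[j], hi[j],
                                                length.out = n_coarse))
    pts <- as.matrix(expand.grid(grids))
    vals <- apply(pts, 1L, f)
    k <- which.min(vals)
    if (vals[k] < best_v) {
      best_v <- vals[k]
      best <- pts[k, ]
    }
    span <- (hi - lo) / shrink
    lo <- pmax(0, best - span / 2)
    hi <- best + span / 2
  }
  list(p = best, value = best_v)
}
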