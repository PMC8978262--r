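#' Phantom specification
#'
#' Describes a synthetic test geometry: a box of hexahedral cells, each split
#' into 6 tetrahedra (Freudenthal/Kuhn decomposition, conforming across
#' cells), with optional features assigned by tet-centroid membership:
#' a sphere, an axis-aligned or oblique cylindrical vessel, or a stack of
#' slabs along z. Background is region 0.
#'
#' @param kind one of `"box"`, `"slab_stack"`, `"sphere_in_box"`,
#'   `"vessel_in_box"`.
#' @param extents box side lengths (x, y, z) in mm; the box spans
#'   `[0, extents]`.
#' @param cells hexahedral subdivision counts (nx, ny, nz); the mesh has
#'   `6 * nx * ny * nz` tets.
#' @param sphere_center,sphere_radius sphere feature (mm), for
#'   `sphere_in_box`.
#' @param vessel_point,vessel_axis,vessel_radius infinite-cylinder feature
#'   (point on axis, axis direction, radius, mm), for `vessel_in_box`.
#'   `vessel_radius` may be an increasing vector of radii describing nested
#'   shells (for example lumen + wall), one label each.
#' @param layer_boundaries increasing z values (mm) splitting the box into
#'   slabs, for `slab_stack`.
#' @param labels region labels: single label for sphere/vessel (default 1);
#'   for `slab_stack`, one label per layer.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("box", "slab_stack", "sphere_in_box",
                                  "vessel_in_box"),
                         extents = c(60, 60, 60), cells = c(6L, 6L, 6L),
                         sphere_center = NULL, sphere_radius = NULL,
                         vessel_point = NULL, vessel_axis = NULL,
                         vessel_radius = NULL,
                         layer_boundaries = NULL, labels = NULL) {
  kind <- match.arg(kind)
  extents <- as.numeric(extents)
  cells <- as.integer(cells)
  if (any(extents <= 0)) stop("extents must be positive")
  if (any(cells < 1L)) stop("cells must be >= 1")
  spec <- structure(list(kind = kind, extents = extents, cells = cells,
                         sphere_center = sphere_center,
                         sphere_radius = sphere_radius,
                         vessel_point = vessel_point,
                         vessel_axis = vessel_axis,
                         vessel_radius = vessel_radius,
                         layer_boundaries = layer_boundaries,
                         labels = labels),
                    class = "phantom_spec")
  if (kind == "sphere_in_box") {
    if (is.null(sphere_center) || is.null(sphere_radius))
      stop("sphere_in_box needs sphere_center and sphere_radius")
    if (sphere_radius < 0) stop("sphere_radius must be >= 0")
    if (any(sphere_center - sphere_radius < 0) ||
        any(sphere_center + sphere_radius > extents))
      stop("sphere does not fit inside the box")
    if (is.null(labels)) spec$labels <- 1L
  }
  if (kind == "vessel_in_box") {
    if (is.null(vessel_point) || is.null(vessel_axis) || is.null(vessel_radius))
      stop("vessel_in_box needs vessel_point, vessel_axis, vessel_radius")
    if (any(vessel_radius < 0)) stop("vessel_radius must be >= 0")
    if (length(vessel_radius) > 1L && is.unsorted(vessel_radius, strictly = TRUE))
      stop("nested vessel_radius values must be strictly increasing")
    if (is.null(labels)) spec$labels <- seq_along(vessel_radius)
    if (length(spec$labels) != length(vessel_radius))
      stop("one label per vessel radius required")
  }
  if (kind == "slab_stack") {
    if (is.null(layer_boundaries)) stop("slab_stack needs layer_boundaries")
    lb <- as.numeric(layer_boundaries)
    if (is.unsorted(lb, strictly = TRUE) || any(lb <= 0) || any(lb >= extents[3L]))
      stop("layer_boundaries must be strictly increasing inside (0, z extent)")
    if (is.null(labels)) spec$labels <- seq_len(length(lb) + 1L) - 1L
    if (length(spec$labels) != length(lb) + 1L)
      stop("slab_stack needs one label per layer (boundaries + 1)")
  }
  spec
}

# Freudenthal 6-tet decomposition of the unit cube: path permutations from
# corner 0 to corner 7; conforming across translated copies.
.hex6 <- local({
  corners <- function(ix, iy, iz) c(ix, iy, iz)
  perms <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  lapply(perms, function(p) {
    steps <- diag(3L)[p, , drop = FALSE]
    v <- matrix(0L, 4L, 3L)
    v[2L, ] <- steps[1L, ]
    v[3L, ] <- steps[1L, ] + steps[2L, ]
    v[4L, ] <- c(1L, 1L, 1L)
    v
  })
})

#' Generate a phantom mesh
#'
#' Deterministic for a fixed spec: same spec, same mesh.
#'
#' @param spec a [phantom_spec()].
#' @return a [tetra_mesh()] with regions assigned by feature membership of
#'   tet centroids (background = 0).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$cells[1L]; ny <- spec$cells[2L]; nz <- spec$cells[3L]
  hx <- spec$extents[1L] / nx; hy <- spec$extents[2L] / ny
  hz <- spec$extents[3L] / nz

  # vertex grid
  xs <- seq(0, spec$extents[1L], length.out = nx + 1L)
  ys <- seq(0, spec$extents[2L], length.out = ny + 1L)
  zs <- seq(0, spec$extents[3L], length.out = nz + 1L)
  vid <- function(ix, iy, iz) 1L + ix + (nx + 1L) * (iy + (ny + 1L) * iz)
  grid <- expand.grid(ix = 0:nx, iy = 0:ny, iz = 0:nz)
  verts <- cbind(xs[grid$ix + 1L], ys[grid$iy + 1L], zs[grid$iz + 1L])

  cellsg <- expand.grid(ix = 0:(nx - 1L), iy = 0:(ny - 1L), iz = 0:(nz - 1L))
  n_hex <- nrow(cellsg)
  tets <- matrix(0L, 6L * n_hex, 4L)
  row <- 1L
  for (h in seq_len(n_hex)) {
    ix <- cellsg$ix[h]; iy <- cellsg$iy[h]; iz <- cellsg$iz[h]
    for (k in 1:6) {
      off <- .hex6[[k]]
      tets[row, ] <- vid(ix + off[, 1L], iy + off[, 2L], iz + off[, 3L])
      row <- row + 1L
    }
  }

  region <- integer(nrow(tets))
  mesh0 <- tetra_mesh(verts, tets, region)
  cen <- tet_centroids(mesh0)
  region <- .assign_regions(spec, cen)
  tetra_mesh(verts, mesh0$tets, region)
}

.assign_regions <- function(spec, cen) {
  region <- integer(nrow(cen))
  if (spec$kind == "sphere_in_box" && spec$sphere_radius > 0) {
    d2 <- rowSums(sweep(cen, 2L, spec$sphere_center)^2)
    region[d2 <= spec$sphere_radius^2] <- as.integer(spec$labels[1L])
  } else if (spec$kind == "vessel_in_box" && any(spec$vessel_radius > 0)) {
    ax <- spec$vessel_axis / sqrt(sum(spec$vessel_axis^2))
    rel <- sweep(cen, 2L, spec$vessel_point)
    along <- as.numeric(rel %*% ax)
    perp2 <- rowSums(rel^2) - along^2
    # outermost shell first so inner labels overwrite
    for (k in rev(seq_along(spec$vessel_radius)))
      region[perp2 <= spec$vessel_radius[k]^2] <- as.integer(spec$labels[k])
  } else if (spec$kind == "slab_stack") {
    lb <- c(spec$layer_boundaries, Inf)
    layer <- findInterval(cen[, 3L], c(-Inf, spec$layer_boundaries))
    region <- as.integer(spec$labels[layer])
  }
  region
}

#' Tumor + organ-at-risk phantom
#'
#' A spherical tumor (region 1) wrapped in a concentric organ-at-risk shell
#' (region 2) inside a background box (region 0): the test bed for
#' power-allocation planning.
#'
#' @param tumor_radius tumor sphere radius, mm.
#' @param oar_shell_thickness shell thickness, mm (0 gives no region-2 tets).
#' @param extents,cells as in [phantom_spec()].
#' @return a [tetra_mesh()] with regions 0/1/2.
#' @export
generate_tumor_oar_phantom <- function(tumor_radius, oar_shell_thickness,
                                       extents = c(60, 60, 60),
                                       cells = c(15L, 15L, 15L)) {
  extents <- as.numeric(extents)
  if (tumor_radius < 0 || oar_shell_thickness < 0)
    stop("radii must be >= 0")
  ctr <- extents / 2
  r_out <- tumor_radius + oar_shell_thickness
  if (any(ctr - r_out < 0) || any(ctr + r_out > extents))
    stop("tumor + shell do not fit inside the box")
  spec <- phantom_spec("box", extents = extents, cells = cells)
  mesh0 <- generate_phantom(spec)
  cen <- tet_centroids(mesh0)
  d <- sqrt(rowSums(sweep(cen, 2L, ctr)^2))
  region <- integer(nrow(cen))
  region[d <= r_out] <- 2L
  region[d <= tumor_radius] <- 1L
  tetra_mesh(mesh0$vertices, mesh0$tets, region)
}
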