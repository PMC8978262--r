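#' Tetrahedral mesh container
#'
#' Builds the mesh object used throughout the package: vertex coordinates
#' (mm), tetrahedra as 1-based vertex index quadruples, a per-tet integer
#' region label, derived per-tet volumes, and face adjacency. Tetrahedra are
#' reoriented to positive signed volume; face `f` of a tet is the face
#' opposite its `f`-th vertex.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param tets integer matrix, one row per tetrahedron, four 1-based vertex
#'   indices.
#' @param region integer vector of per-tet region labels (>= 0).
#' @param degenerate_tol tets with volume below this (mm^3) are rejected.
#' @return An object of class `tetra_mesh` with elements `vertices`, `tets`,
#'   `region`, `volume` (mm^3), `adjacency` (per-tet, per-face neighbor index
#'   or `NA` on the boundary) and `boundary_faces` (matrix of tet/face pairs).
#' @export
tetra_mesh <- function(vertices, tets, region, degenerate_tol = 1e-12) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  region <- as.integer(region)
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(tets) != 4L) stop("tets must have 4 columns")
  if (length(region) != nrow(tets)) stop("one region label per tet required")
  if (any(region < 0L)) stop("region labels must be >= 0")
  if (min(tets) < 1L || max(tets) > nrow(vertices))
    stop("tet vertex index out of range")

  vol <- cpp_tet_volumes(vertices, tets - 1L)
  flip <- vol < 0
  if (any(flip)) {
    tets[flip, c(1L, 2L)] <- tets[flip, c(2L, 1L)]
    vol <- abs(vol)
  }
  degenerate <- which(vol < degenerate_tol)
  if (length(degenerate) > 0L)
    stop("degenerate tetrahedra (|volume| < ", degenerate_tol, " mm^3) at: ",
         paste(head(degenerate, 10L), collapse = ", "))

  adj <- cpp_build_adjacency(tets - 1L) + 1L  # 0 -> boundary marker
  adj[adj == 0L] <- NA_integer_
  bnd <- which(is.na(adj), arr.ind = TRUE)
  colnames(bnd) <- c("tet", "face")

  structure(
    list(vertices = vertices, tets = tets, region = region,
         volume = as.numeric(vol), adjacency = adj,
         boundary_faces = bnd[order(bnd[, 1L], bnd[, 2L]), , drop = FALSE]),
    class = "tetra_mesh")
}

#' @export
print.tetra_mesh <- function(x, ...) {
  d <- mesh_diagnostics(x)
  cat(sprintf(
    "tetra_mesh: n_tets=%d n_vertices=%d n_regions=%d n_boundary_faces=%d\n",
    d$n_tets, d$n_vertices, d$n_regions, d$n_boundary_faces))
  invisible(x)
}

#' Mesh diagnostics
#'
#' Summary counts plus a degeneracy check, printed by the CLI in a fixed
#' `key=value` layout.
#'
#' @param mesh a [tetra_mesh()].
#' @param unit_declared unit the source file declared (`"mm"` or `"cm"`);
#'   coordinates are always stored in mm.
#' @param degenerate_tol volume threshold (mm^3) below which a tet is
#'   reported degenerate.
#' @return list with `n_tets`, `n_vertices`, `n_regions`, `n_boundary_faces`,
#'   `degenerate_tets`, `unit_declared`.
#' @export
mesh_diagnostics <- function(mesh, unit_declared = "mm", degenerate_tol = 1e-12) {
  stopifnot(inherits(mesh, "tetra_mesh"))
  list(n_tets = nrow(mesh$tets),
       n_vertices = nrow(mesh$vertices),
       n_regions = length(unique(mesh$region)),
       n_boundary_faces = nrow(mesh$boundary_faces),
       degenerate_tets = which(mesh$volume < degenerate_tol),
       unit_declared = unit_declared)
}

#' Format mesh diagnostics as key=value lines
#' @param d result of [mesh_diagnostics()].
#' @return character vector of `key=value` lines.
#' @export
format_diagnostics <- function(d) {
  c(sprintf("n_tets=%d", d$n_tets),
    sprintf("n_vertices=%d", d$n_vertices),
    sprintf("n_regions=%d", d$n_regions),
    sprintf("n_boundary_faces=%d", d$n_boundary_faces),
    sprintf("degenerate_tets=%d", length(d$degenerate_tets)),
    sprintf("unit_declared=%s", d$unit_declared))
}

#' Locate the tetrahedron containing a point
#'
#' Closed-barycentric containment: points on shared faces may belong to
#' either incident tet; one of them is returned. Points outside every tet
#' give `NA`.
#'
#' @param mesh a [tetra_mesh()].
#' @param points numeric vector of length 3, or a matrix with one point per
#'   row (mm).
#' @param hint 1-based tet index to start the walking search from.
#' @return integer vector of 1-based tet indices (`NA` if outside).
#' @export
locate_tetra <- function(mesh, points, hint = 1L) {
  stopifnot(inherits(mesh, "tetra_mesh"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L, byrow = TRUE)
  storage.mode(points) <- "double"
  adj0 <- mesh$adjacency
  adj0[is.na(adj0)] <- 0L
  idx <- cpp_locate(mesh$vertices, mesh$tets - 1L, adj0 - 1L, points,
                    as.integer(hint) - 1L)
  idx[idx < 0L] <- NA_integer_
  idx + 1L
}

#' First face crossed by a ray inside a tetrahedron
#'
#' @param mesh a [tetra_mesh()].
#' @param tet 1-based tet index containing `position`.
#' @param position point inside (or on the boundary of) the tet, mm.
#' @param direction unit vector.
#' @return list with `face` (local id 1..4, face `f` opposite vertex `f`) and
#'   `distance` (mm, >= 0).
#' @export
exit_face <- function(mesh, tet, position, direction) {
  stopifnot(inherits(mesh, "tetra_mesh"))
  nd <- sqrt(sum(direction^2))
  if (abs(nd - 1) > 1e-6) stop("direction must be a unit vector")
  res <- cpp_exit_face(mesh$vertices, mesh$tets - 1L, as.integer(tet) - 1L,
                       as.numeric(position), as.numeric(direction))
  if (res$face < 0L)
    stop("no forward face intersection: position/tet pair is inconsistent")
  list(face = res$face + 1L, distance = res$distance)
}

#' Tetrahedron centroids
#' @param mesh a [tetra_mesh()].
#' @return matrix of per-tet centroid coordinates (mm).
#' @export
tet_centroids <- function(mesh) {
  v <- mesh$vertices
  (v[mesh$tets[, 1L], , drop = FALSE] + v[mesh$tets[, 2L], , drop = FALSE] +
     v[mesh$tets[, 3L], , drop = FALSE] + v[mesh$tets[, 4L], , drop = FALSE]) / 4
}

# local face f (opposite vertex f) -> the three vertex rows of that face
.face_vertex_ids <- function(mesh, tet, face) {
  mesh$tets[tet, setdiff(1:4, face)]
}

#' Areas of given tet faces
#' @param mesh a [tetra_mesh()].
#' @param faces matrix with columns `tet`, `face` (local 1..4).
#' @return numeric vector of face areas (mm^2).
#' @export
face_areas <- function(mesh, faces) {
  apply(faces, 1L, function(r) {
    ids <- .face_vertex_ids(mesh, r[[1L]], r[[2L]])
    a <- mesh$vertices[ids[1L], ]
    b <- mesh$vertices[ids[2L], ]
    c_ <- mesh$vertices[ids[3L], ]
    v1 <- b - a
    v2 <- c_ - a
    cr <- c(v1[2L] * v2[3L] - v1[3L] * v2[2L],
            v1[3L] * v2[1L] - v1[1L] * v2[3L],
            v1[1L] * v2[2L] - v1[2L] * v2[1L])
    0.5 * sqrt(sum(cr^2))
  })
}

#' Tets of one region that touch another region across a face
#'
#' Used to define interface surfaces such as the vessel intima (wall tets in
#' contact with the lumen).
#'
#' @param mesh a [tetra_mesh()].
#' @param region region label of the tets to return.
#' @param touching region label that must lie across at least one face.
#' @return integer vector of tet indices.
#' @export
interface_tets <- function(mesh, region, touching) {
  cand <- which(mesh$region == region)
  nb <- mesh$adjacency[cand, , drop = FALSE]
  hit <- matrix(FALSE, nrow(nb), 4L)
  ok <- !is.na(nb)
  hit[ok] <- mesh$region[nb[ok]] == touching
  cand[rowSums(hit) > 0L]
}
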