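#' Light source specifications
#'
#' Six emitter models, each a tagged record with a power in mW. Interstitial
#' sources must lie inside the mesh at simulation time.
#'
#' @param position,center 3-vectors, mm.
#' @param direction,axis unit 3-vectors (normalized internally).
#' @param power total emitted power, mW (>= 0).
#' @param half_angle cone half-angle, radians, in `[0, pi]`.
#' @param radius,length diffuser/ball geometry, mm.
#' @param linear_density alternative to `power` for diffusers, mW per cm of
#'   diffuser length (the conventional "100 mW/cm" prescription style).
#' @param segment_weights optional nonnegative per-segment relative emission
#'   along the diffuser (uniform when omitted).
#' @param emission angular law for diffuser/surface emission:
#'   `"cosine"` (Lambertian, default) or `"isotropic"` (hemisphere /
#'   isotropic shell).
#' @param faces for [source_surface()]: matrix with columns `tet`, `face`
#'   (local 1..4) of boundary faces to emit from.
#' @param region for [source_volume()]: region label that emits diffusely.
#' @return object of class `light_source`.
#' @name light_sources
NULL

.src <- function(type, power, fields) {
  if (power < 0) stop("power must be >= 0")
  structure(c(list(type = type, power = as.numeric(power)), fields),
            class = "light_source")
}

.unit3 <- function(v, what) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop(what, " must be a nonzero vector")
  v / nv
}

#' @rdname light_sources
#' @export
source_point <- function(position, power) {
  .src("point", power, list(position = as.numeric(position)))
}

#' @rdname light_sources
#' @export
source_pencil <- function(position, direction, power) {
  .src("pencil", power, list(position = as.numeric(position),
                             direction = .unit3(direction, "direction")))
}

#' @rdname light_sources
#' @export
source_cone_fiber <- function(position, direction, half_angle, power) {
  if (half_angle < 0 || half_angle > pi) stop("half_angle must be in [0, pi]")
  .src("cone", power, list(position = as.numeric(position),
                           direction = .unit3(direction, "direction"),
                           half_angle = as.numeric(half_angle)))
}

#' @rdname light_sources
#' @export
source_cyl_diffuser <- function(center, axis, radius, length,
                                power = NULL, linear_density = NULL,
                                segment_weights = NULL,
                                emission = c("cosine", "isotropic")) {
  emission <- match.arg(emission)
  if (radius <= 0 || length <= 0) stop("radius and length must be positive")
  if (is.null(power) == is.null(linear_density))
    stop("give exactly one of power or linear_density")
  if (is.null(power)) power <- linear_density * (length / 10)  # mW/cm * cm
  if (!is.null(segment_weights)) {
    if (any(segment_weights < 0) || sum(segment_weights) <= 0)
      stop("segment_weights must be nonnegative and not all zero")
  }
  .src("cyl_diffuser", power,
       list(center = as.numeric(center), axis = .unit3(axis, "axis"),
            radius = as.numeric(radius), length = as.numeric(length),
            segment_weights = segment_weights, emission = emission))
}

#' @rdname light_sources
#' @export
source_ball <- function(center, radius, power) {
  if (radius <= 0) stop("radius must be positive")
  .src("ball", power, list(center = as.numeric(center),
                           radius = as.numeric(radius)))
}

#' @rdname light_sources
#' @export
source_surface <- function(faces, power,
                           emission = c("cosine", "isotropic")) {
  emission <- match.arg(emission)
  faces <- as.matrix(faces)
  if (ncol(faces) != 2L) stop("faces must have columns tet, face")
  .src("surface", power, list(faces = faces, emission = emission))
}

#' @rdname light_sources
#' @export
source_volume <- function(region, power) {
  .src("volume", power, list(region = as.integer(region)))
}

#' Total power of a source list
#'
#' @param sources list of [light_sources].
#' @return total power in mW (linear-density diffusers contribute
#'   density x length).
#' @export
total_power <- function(sources) {
  if (inherits(sources, "light_source")) sources <- list(sources)
  if (length(sources) == 0L) return(0)
  sum(vapply(sources, function(s) s$power, numeric(1L)))
}

#' Split a cylindrical diffuser into segments
#'
#' Cuts the diffuser into `k` contiguous equal-length segments, each an
#' independent diffuser source; the power share of segment `j` is
#' proportional to its `segment_weights` entry (uniform by default), so the
#' union of segments emits identically to the parent.
#'
#' @param d a [source_cyl_diffuser()].
#' @param k segment count, >= 1.
#' @return list of `k` diffuser sources.
#' @export
discretize_diffuser <- function(d, k) {
  stopifnot(inherits(d, "light_source"), d$type == "cyl_diffuser")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  w <- d$segment_weights
  if (is.null(w)) w <- rep(1, k)
  if (length(w) != k)
    stop("segment_weights length (", length(w), ") must equal k (", k, ")")
  w <- w / sum(w)
  seg_len <- d$length / k
  lapply(seq_len(k), function(j) {
    mid <- d$center + d$axis * ((j - 0.5) * seg_len - d$length / 2)
    source_cyl_diffuser(center = mid, axis = d$axis, radius = d$radius,
                        length = seg_len, power = d$power * w[j],
                        emission = d$emission)
  })
}

.iso_dirs <- function(n) {
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# orthonormal frame completing unit vector a
.frame <- function(a) {
  ref <- if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * a) * a
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(a[2L] * e1[3L] - a[3L] * e1[2L],
          a[3L] * e1[1L] - a[1L] * e1[3L],
          a[1L] * e1[2L] - a[2L] * e1[1L])
  list(e1 = e1, e2 = e2)
}

# cosine-weighted (Lambertian) directions about per-row outward normals
.cosine_about <- function(normals) {
  n <- nrow(normals)
  u1 <- runif(n); u2 <- runif(n)
  st <- sqrt(u1)           # sin of polar angle: cosine-weighted
  ct <- sqrt(1 - u1)
  phi <- 2 * pi * u2
  t(vapply(seq_len(n), function(i) {
    fr <- .frame(normals[i, ])
    ct[i] * normals[i, ] + st[i] * (cos(phi[i]) * fr$e1 + sin(phi[i]) * fr$e2)
  }, numeric(3L)))
}

.hemi_about <- function(normals) {
  n <- nrow(normals)
  d <- .iso_dirs(n)
  flip <- rowSums(d * normals) < 0
  d[flip, ] <- -d[flip, , drop = FALSE]
  d
}

#' Sample initial photon packets from a source
#'
#' Emission laws: point/ball/volume emit isotropically; pencil along its
#' axis; cone fiber uniformly in solid angle within the half-angle;
#' cylindrical diffusers from their lateral surface, axially proportional to
#' `segment_weights`, with cosine-weighted (default) or isotropic-shell
#' directions; surface sources area-weighted over their faces with
#' Lambertian or hemispherical emission into the domain.
#'
#' Uses R's RNG; seed with `set.seed()` for reproducibility.
#'
#' @param source a [light_sources] object.
#' @param n number of packets.
#' @param mesh required for `volume` and `surface` sources.
#' @return list with `positions` (n x 3), `directions` (n x 3), and for
#'   volume/surface sources `tets` (containing tet per packet, else `NULL`).
#' @export
emit_packets <- function(source, n, mesh = NULL) {
  stopifnot(inherits(source, "light_source"))
  n <- as.integer(n)
  tets <- NULL
  switch(source$type,
    point = {
      pos <- matrix(source$position, n, 3L, byrow = TRUE)
      dir <- .iso_dirs(n)
    },
    pencil = {
      pos <- matrix(source$position, n, 3L, byrow = TRUE)
      dir <- matrix(source$direction, n, 3L, byrow = TRUE)
    },
    cone = {
      pos <- matrix(source$position, n, 3L, byrow = TRUE)
      ct_min <- cos(source$half_angle)
      ct <- runif(n, ct_min, 1)
      st <- sqrt(pmax(0, 1 - ct^2))
      phi <- runif(n, 0, 2 * pi)
      fr <- .frame(source$direction)
      dir <- outer(ct, source$direction) +
        outer(st * cos(phi), fr$e1) + outer(st * sin(phi), fr$e2)
    },
    cyl_diffuser = {
      w <- source$segment_weights
      if (is.null(w)) {
        z <- runif(n, 0, source$length)
      } else {
        k <- length(w)
        seg <- sample.int(k, n, replace = TRUE, prob = w / sum(w))
        z <- (seg - 1 + runif(n)) * (source$length / k)
      }
      psi <- runif(n, 0, 2 * pi)
      fr <- .frame(source$axis)
      radial <- outer(cos(psi), fr$e1) + outer(sin(psi), fr$e2)
      pos <- matrix(source$center, n, 3L, byrow = TRUE) +
        outer(z - source$length / 2, source$axis) + source$radius * radial
      dir <- if (source$emission == "cosine") .cosine_about(radial)
             else .hemi_about(radial)
    },
    ball = {
      r <- source$radius * runif(n)^(1 / 3)
      pos <- matrix(source$center, n, 3L, byrow = TRUE) + r * .iso_dirs(n)
      dir <- .iso_dirs(n)
    },
    volume = {
      if (is.null(mesh)) stop("volume source needs a mesh")
      idx <- which(mesh$region == source$region)
      if (length(idx) == 0L)
        stop("volume source region ", source$region, " has no tets")
      pick <- idx[sample.int(length(idx), n, replace = TRUE,
                             prob = mesh$volume[idx])]
      pos <- .uniform_in_tets(mesh, pick)
      dir <- .iso_dirs(n)
      tets <- pick
    },
    surface = {
      if (is.null(mesh)) stop("surface source needs a mesh")
      areas <- face_areas(mesh, source$faces)
      pick <- sample.int(nrow(source$faces), n, replace = TRUE, prob = areas)
      pos <- matrix(0, n, 3L)
      nrm <- matrix(0, n, 3L)
      for (i in seq_len(n)) {
        tf <- source$faces[pick[i], ]
        ids <- .face_vertex_ids(mesh, tf[[1L]], tf[[2L]])
        a <- mesh$vertices[ids[1L], ]; b <- mesh$vertices[ids[2L], ]
        c_ <- mesh$vertices[ids[3L], ]
        u <- runif(1); v <- runif(1)
        if (u + v > 1) { u <- 1 - u; v <- 1 - v }
        pos[i, ] <- a + u * (b - a) + v * (c_ - a)
        fn <- .outward_face_normal(mesh, tf[[1L]], tf[[2L]])
        nrm[i, ] <- -fn  # inward: emit into the domain
      }
      dir <- if (source$emission == "cosine") .cosine_about(nrm)
             else .hemi_about(nrm)
      tets <- source$faces[pick, 1L]
    },
    stop("unknown source type: ", source$type))
  list(positions = pos, directions = dir, tets = tets)
}

.uniform_in_tets <- function(mesh, tet_idx) {
  n <- length(tet_idx)
  # uniform barycentric via sorted uniforms
  u <- matrix(runif(3L * n), n, 3L)
  u <- t(apply(u, 1L, sort))
  b <- cbind(u[, 1L], u[, 2L] - u[, 1L], u[, 3L] - u[, 2L], 1 - u[, 3L])
  v <- mesh$vertices
  t1 <- v[mesh$tets[tet_idx, 1L], , drop = FALSE]
  t2 <- v[mesh$tets[tet_idx, 2L], , drop = FALSE]
  t3 <- v[mesh$tets[tet_idx, 3L], , drop = FALSE]
  t4 <- v[mesh$tets[tet_idx, 4L], , drop = FALSE]
  b[, 1L] * t1 + b[, 2L] * t2 + b[, 3L] * t3 + b[, 4L] * t4
}

.outward_face_normal <- function(mesh, tet, face) {
  ids <- .face_vertex_ids(mesh, tet, face)
  a <- mesh$vertices[ids[1L], ]; b <- mesh$vertices[ids[2L], ]
  c_ <- mesh$vertices[ids[3L], ]
  nrm <- c((b - a)[2L] * (c_ - a)[3L] - (b - a)[3L] * (c_ - a)[2L],
           (b - a)[3L] * (c_ - a)[1L] - (b - a)[1L] * (c_ - a)[3L],
           (b - a)[1L] * (c_ - a)[2L] - (b - a)[2L] * (c_ - a)[1L])
  nrm <- nrm / sqrt(sum(nrm^2))
  opp <- mesh$vertices[mesh$tets[tet, face], ]
  if (sum(nrm * (opp - a)) > 0) nrm <- -nrm
  nrm
}
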