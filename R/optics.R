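#' Optical material
#'
#' Per-region optical properties. Units: absorption and scattering
#' coefficients in mm^-1; anisotropy `g` is the mean scattering cosine;
#' refractive index `n` must be at least 1 (validator rule shared with the
#' mesh-unit check).
#'
#' @param region integer region label the material applies to.
#' @param mu_a absorption coefficient, mm^-1, >= 0.
#' @param mu_s scattering coefficient, mm^-1, >= 0. Give either `mu_s` or
#'   `mu_s_prime`.
#' @param g anisotropy, in (-1, 1).
#' @param n refractive index, >= 1.
#' @param name optional tissue name.
#' @param mu_s_prime reduced scattering coefficient mm^-1; converted to
#'   `mu_s = mu_s_prime / (1 - g)` when supplied.
#' @return object of class `material`.
#' @export
material <- function(region, mu_a, mu_s = NULL, g = 0, n = 1.37,
                     name = "", mu_s_prime = NULL) {
  if (is.null(mu_s) == is.null(mu_s_prime))
    stop("give exactly one of mu_s or mu_s_prime")
  if (g <= -1 || g >= 1) stop("anisotropy g must be in (-1, 1)")
  if (is.null(mu_s)) mu_s <- mu_s_prime / (1 - g)
  if (mu_a < 0) stop("mu_a must be >= 0")
  if (mu_s < 0) stop("mu_s must be >= 0")
  if (n < 1) stop("refractive index must be at least 1 (got ", n, ")")
  structure(list(region = as.integer(region), name = name,
                 mu_a = as.numeric(mu_a), mu_s = as.numeric(mu_s),
                 g = as.numeric(g), n = as.numeric(n)),
            class = "material")
}

#' A list of materials keyed by region
#'
#' @param ... [material()] objects.
#' @return object of class `material_set` (list keyed by region label).
#' @export
material_set <- function(...) {
  mats <- list(...)
  if (length(mats) == 1L && is.list(mats[[1L]]) && !inherits(mats[[1L]], "material"))
    mats <- mats[[1L]]
  if (!all(vapply(mats, inherits, logical(1L), "material")))
    stop("all entries must be material objects")
  regs <- vapply(mats, function(m) m$region, integer(1L))
  if (anyDuplicated(regs)) stop("duplicate region labels in material set")
  names(mats) <- as.character(regs)
  structure(mats, class = "material_set")
}

#' Read a materials table
#'
#' CSV/TSV with columns `region`, `name`, `mu_a`, `g`, `n` and either `mu_s`
#' or `mu_s_prime` (all coefficients mm^-1). Lines starting with `#` are
#' comments (conventionally used to declare the unit).
#'
#' @param path file path.
#' @param sep field separator (default `,`).
#' @return a [material_set()].
#' @export
read_materials <- function(path, sep = ",") {
  df <- read.csv(path, sep = sep, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("region", "mu_a", "g", "n")
  if (!all(need %in% names(df)))
    stop("materials table must have columns: ", paste(need, collapse = ", "),
         " and mu_s or mu_s_prime")
  has_mus <- "mu_s" %in% names(df)
  has_musp <- "mu_s_prime" %in% names(df)
  if (!has_mus && !has_musp) stop("materials table needs mu_s or mu_s_prime")
  mats <- lapply(seq_len(nrow(df)), function(i) {
    material(region = df$region[i], mu_a = df$mu_a[i],
             mu_s = if (has_mus) df$mu_s[i] else NULL,
             mu_s_prime = if (!has_mus) df$mu_s_prime[i] else NULL,
             g = df$g[i], n = df$n[i],
             name = if ("name" %in% names(df)) df$name[i] else "")
  })
  material_set(mats)
}

#' Derived transport quantities
#'
#' From a [material()]: total attenuation `mu_t = mu_a + mu_s`, single-
#' scattering albedo `mu_s/mu_t`, reduced scattering
#' `mu_s_prime = mu_s (1 - g)`, effective attenuation
#' `mu_eff = sqrt(3 mu_a (mu_a + mu_s_prime))` and diffusion constant
#' `D = 1 / (3 (mu_a + mu_s_prime))` (mm). For a transparent material
#' (`mu_t = 0`) the albedo is `NA`.
#'
#' @param m a [material()].
#' @return list with `mu_t`, `albedo`, `mu_s_prime`, `mu_eff`, `D`.
#' @export
derive_optics <- function(m) {
  stopifnot(inherits(m, "material"))
  mu_t <- m$mu_a + m$mu_s
  mu_s_prime <- m$mu_s * (1 - m$g)
  list(mu_t = mu_t,
       albedo = if (mu_t > 0) m$mu_s / mu_t else NA_real_,
       mu_s_prime = mu_s_prime,
       mu_eff = sqrt(3 * m$mu_a * (m$mu_a + mu_s_prime)),
       D = 1 / (3 * (m$mu_a + mu_s_prime)))
}

#' Sample a Henyey-Greenstein scattering cosine
#'
#' Inverse-CDF sampling of the HG phase function. `u = 0` maps to -1 and
#' `u = 1` to +1; `|g| < 1e-6` uses the isotropic branch `2u - 1` to avoid
#' cancellation. Vectorized over `u`.
#'
#' @param g anisotropy in (-1, 1).
#' @param u uniform(0,1) deviates.
#' @return scattering cosines in `[-1, 1]`.
#' @export
sample_hg_cos <- function(g, u) {
  if (g <= -1 || g >= 1) stop("g must be in (-1, 1)")
  if (abs(g) < 1e-6) return(2 * u - 1)
  frac <- (1 - g^2) / (1 - g + 2 * g * u)
  out <- pmin(1, pmax(-1, (1 + g^2 - frac^2) / (2 * g)))
  # endpoints are analytically forced: (1-g^2)/(1-g) = 1+g gives -1 at u=0
  out[u == 0] <- -1
  out[u == 1] <- 1
  out
}

#' Rotate a direction by a scattering angle
#'
#' Deflects `direction` by `acos(cos_theta)` with azimuth `phi` about it,
#' using the standard local-frame rotation with an explicit branch for
#' directions within 1e-5 of the z axis.
#'
#' @param direction unit 3-vector.
#' @param cos_theta scattering cosine.
#' @param phi azimuth in `[0, 2*pi)`.
#' @return unit 3-vector with `dot(in, out) = cos_theta`.
#' @export
scatter_direction <- function(direction, cos_theta, phi) {
  u <- direction
  st <- sqrt(max(0, 1 - cos_theta^2))
  cp <- cos(phi); sp <- sin(phi)
  if (abs(u[3L]) > 0.99999) {
    out <- c(st * cp, st * sp, cos_theta * sign(u[3L]))
  } else {
    den <- sqrt(1 - u[3L]^2)
    out <- c(st * (u[1L] * u[3L] * cp - u[2L] * sp) / den + u[1L] * cos_theta,
             st * (u[2L] * u[3L] * cp + u[1L] * sp) / den + u[2L] * cos_theta,
             -st * cp * den + u[3L] * cos_theta)
  }
  out / sqrt(sum(out^2))
}

#' Unpolarized Fresnel reflectance
#'
#' Average of the s- and p-polarized reflectances at a planar interface;
#' returns 1 beyond the critical angle when going from dense to rare.
#'
#' @param n1,n2 refractive indices (incident, transmitted), >= 1.
#' @param cos_incident cosine of the incidence angle, in (0, 1].
#' @return reflectance in `[0, 1]`.
#' @export
fresnel_reflectance <- function(n1, n2, cos_incident) {
  if (cos_incident <= 0 || cos_incident > 1)
    stop("cos_incident must be in (0, 1]")
  cpp_fresnel_R(n1, n2, cos_incident)
}

#' Refract a direction at a planar interface
#'
#' Snell's law with the convention that `normal` points into the incident
#' medium (`dot(direction, normal) < 0`). On total internal reflection the
#' specularly reflected direction is returned with attribute `tir = TRUE`.
#'
#' @param direction,normal unit 3-vectors.
#' @param n1,n2 refractive indices (incident, transmitted).
#' @return unit 3-vector (transmitted, or reflected with `attr(, "tir")`).
#' @export
refract_direction <- function(direction, normal, n1, n2) {
  d <- direction; nr <- normal
  ci <- -sum(d * nr)
  if (ci <= 0) stop("convention violated: need dot(direction, normal) < 0")
  eta <- n1 / n2
  st2 <- eta^2 * (1 - ci^2)
  if (st2 > 1) {
    out <- d + 2 * ci * nr
    out <- out / sqrt(sum(out^2))
    attr(out, "tir") <- TRUE
    return(out)
  }
  ct <- sqrt(1 - st2)
  out <- eta * d + (eta * ci - ct) * nr
  out <- out / sqrt(sum(out^2))
  attr(out, "tir") <- FALSE
  out
}

#' Analytic Henyey-Greenstein density
#'
#' Density of the scattering cosine, `p(c) = 0.5 (1-g^2) / (1 + g^2 - 2gc)^{3/2}`.
#' Used as the reference in distributional tests.
#'
#' @param g anisotropy in (-1, 1).
#' @param cos_theta scattering cosines.
#' @return density values.
#' @export
hg_density <- function(g, cos_theta) {
  if (abs(g) < 1e-6) return(rep(0.5, length(cos_theta)))
  0.5 * (1 - g^2) / (1 + g^2 - 2 * g * cos_theta)^1.5
}
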