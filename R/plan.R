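#' Per-source unit-power dose matrix
#'
#' One Monte Carlo run per source at unit power (deterministic sub-seeds
#' derived from `seed`); column `j` is the standalone fluence-rate field of
#' source `j` per mW, so the field of a plan with powers `p` is the matrix
#' product `phi %*% p` (Monte Carlo linearity).
#'
#' @param mesh a [tetra_mesh()].
#' @param materials a [material_set()].
#' @param sources list of [light_sources].
#' @param packets packets per source run.
#' @param seed base seed; source `j` uses `seed + j`.
#' @param estimator fluence estimator, see [fluence_from_score()].
#' @return object of class `dose_matrix`: `phi` (n_tet x n_source,
#'   mW cm^-2 per mW), `volume`, `region`, `sources`, `seeds`, `packets`,
#'   plus the per-source raw scores in `scores`.
#' @export
build_dose_matrix <- function(mesh, materials, sources, packets = 1e5,
                              seed = 1L, estimator = "track_length") {
  if (inherits(sources, "light_source")) sources <- list(sources)
  J <- length(sources)
  if (J < 1L) stop("need at least one source")
  phi <- matrix(0, nrow(mesh$tets), J)
  seeds <- as.integer(seed) + seq_len(J)
  scores <- vector("list", J)
  for (j in seq_len(J)) {
    sj <- sources[[j]]
    sj$power <- 1  # unit power
    cfg <- sim_config(n_packets = packets, seed = seeds[j])
    sc <- run_mc(mesh, materials, sj, cfg)
    scores[[j]] <- sc
    phi[, j] <- fluence_from_score(sc, mesh, materials, total_power = 1,
                                   estimator = estimator)$phi
  }
  structure(list(phi = phi, volume = mesh$volume, region = mesh$region,
                 sources = sources, seeds = seeds, packets = packets,
                 scores = scores),
            class = "dose_matrix")
}

#' Plan-optimization configuration
#'
#' @param coverage_target minimum tumor volume fraction at or above
#'   threshold (default 0.98).
#' @param tumor_weight initial tumor underdose weight in the objective;
#'   doubled until the coverage target is met.
#' @param oar_weights named per-region overdose weights (default 1 for every
#'   thresholded non-tumor region).
#' @param tumor_region region label of the tumor (default 1).
#' @param pruning_normalization multiplicative factor applied to all
#'   thresholds before optimizing (default 1).
#' @param max_weight_iters cap on tumor-weight doublings (default 20).
#' @param bisection_iters refinement steps on the tumor weight after the
#'   geometric search brackets the target (default 6).
#' @param power_max per-source upper power bound, mW.
#' @return object of class `plan_config`.
#' @export
plan_config <- function(coverage_target = 0.98, tumor_weight = 1,
                        oar_weights = NULL, tumor_region = 1L,
                        pruning_normalization = 1,
                        max_weight_iters = 20L, bisection_iters = 6L,
                        power_max = 1e7) {
  if (coverage_target <= 0 || coverage_target > 1)
    stop("coverage_target must be in (0, 1]")
  if (tumor_weight <= 0) stop("tumor_weight must be > 0")
  structure(list(coverage_target = coverage_target,
                 tumor_weight = tumor_weight, oar_weights = oar_weights,
                 tumor_region = as.integer(tumor_region),
                 pruning_normalization = pruning_normalization,
                 max_weight_iters = as.integer(max_weight_iters),
                 bisection_iters = as.integer(bisection_iters),
                 power_max = power_max),
            class = "plan_config")
}

# min a.x s.t. Ale x <= ble, Age x >= bge, x >= 0.
# boot::simplex requires nonnegative right-hand sides, so rows with a
# negative rhs are sign-flipped into the opposite constraint family.
.lp_solve <- function(a, Ale = NULL, ble = NULL, Age = NULL, bge = NULL) {
  A1 <- NULL; b1 <- NULL; A2 <- NULL; b2 <- NULL
  add <- function(M, v, flip) {
    if (is.null(M) || nrow(M) == 0L) return()
    neg <- v < 0
    if (any(!neg)) {
      A_keep <- M[!neg, , drop = FALSE]; b_keep <- v[!neg]
      if (flip == "le") { A1 <<- rbind(A1, A_keep); b1 <<- c(b1, b_keep) }
      else { A2 <<- rbind(A2, A_keep); b2 <<- c(b2, b_keep) }
    }
    if (any(neg)) {
      A_fl <- -M[neg, , drop = FALSE]; b_fl <- -v[neg]
      if (flip == "le") { A2 <<- rbind(A2, A_fl); b2 <<- c(b2, b_fl) }
      else { A1 <<- rbind(A1, A_fl); b1 <<- c(b1, b_fl) }
    }
  }
  add(Ale, ble, "le")
  add(Age, bge, "ge")
  n_con <- length(b1) + length(b2)
  boot::simplex(a = a, A1 = A1, b1 = b1, A2 = A2, b2 = b2, maxi = FALSE,
                n.iter = 50L * (length(a) + n_con), eps = 1e-10)
}

# Hinge objective: sum_i c_over[i] max(0, a[i,].p - b[i]) +
#                  sum_k c_under[k] max(0, d[k] - e[k,].p)
# Exact minimization over p in [0, pmax]^J by Kelley cutting planes; the
# master LPs (variables p and epigraph t) are solved with boot::simplex.
# A second phase finds the minimum-total-power point among minimizers.
.hinge_lp <- function(A_over, b_over, c_over, A_under, b_under, c_under,
                      p_max, tol = 1e-9, max_cuts = 400L) {
  J <- if (!is.null(A_over) && nrow(A_over) > 0) ncol(A_over) else ncol(A_under)

  # normalize scales so the master LPs work on O(1) numbers: powers are
  # measured in units of the median power that lifts a tumor element to its
  # threshold, and the objective in units of f(0)
  p_ref <- 1
  if (length(b_under) > 0) {
    rmax <- apply(A_under, 1L, max)
    need <- b_under[rmax > 0] / rmax[rmax > 0]
    if (length(need) > 0) p_ref <- stats::median(need)
  }
  if (!is.finite(p_ref) || p_ref <= 0) p_ref <- 1
  f0 <- sum(c_under * pmax(0, b_under))
  c_scale <- if (f0 > 0) f0 else max(1, sum(c_over))
  if (length(c_over) > 0) {
    A_over <- A_over * p_ref
    c_over <- c_over / c_scale
  }
  if (length(c_under) > 0) {
    A_under <- A_under * p_ref
    c_under <- c_under / c_scale
  }
  p_max <- p_max / p_ref
  f_val <- function(p) {
    v <- 0
    if (length(c_over) > 0)
      v <- v + sum(c_over * pmax(0, as.numeric(A_over %*% p) - b_over))
    if (length(c_under) > 0)
      v <- v + sum(c_under * pmax(0, b_under - as.numeric(A_under %*% p)))
    v
  }
  f_grad <- function(p) {
    g <- numeric(J)
    if (length(c_over) > 0) {
      act <- as.numeric(A_over %*% p) - b_over > 0
      if (any(act)) g <- g + colSums(c_over[act] * A_over[act, , drop = FALSE])
    }
    if (length(c_under) > 0) {
      act <- b_under - as.numeric(A_under %*% p) > 0
      if (any(act)) g <- g - colSums(c_under[act] * A_under[act, , drop = FALSE])
    }
    g
  }
  # cuts: t >= f(p_k) + g_k . (p - p_k)  <=>  -g_k . p + t >= f(p_k) - g_k.p_k
  cuts_a <- matrix(0, 0L, J)
  cuts_b <- numeric(0)
  p <- rep(0, J)
  best_p <- p
  best_f <- f_val(p)
  scale <- max(1, abs(best_f))
  for (it in seq_len(max_cuts)) {
    fv <- f_val(p)
    if (fv < best_f) {
      best_f <- fv
      best_p <- p
    }
    g <- f_grad(p)
    cuts_a <- rbind(cuts_a, -g)
    cuts_b <- c(cuts_b, fv - sum(g * p))
    # master: min t  s.t.  -g_k.p + t >= b_k, 0 <= p <= pmax, t >= 0
    sol <- .lp_solve(a = c(rep(0, J), 1),
                     Ale = cbind(diag(J), 0), ble = rep(p_max, J),
                     Age = cbind(cuts_a, 1), bge = cuts_b)
    if (sol$solved < 0) break
    p_new <- unname(sol$soln[seq_len(J)])
    lb <- sol$value
    if (best_f - lb <= tol * max(1, abs(best_f))) {
      p <- p_new
      fv <- f_val(p)
      if (fv < best_f) {
        best_f <- fv
        best_p <- p
      }
      break
    }
    p <- p_new
  }
  # phase 2: minimum total power among (near-)minimizers
  f_star <- best_f
  slack <- tol * max(1, abs(f_star))
  p <- best_p
  for (it in seq_len(max_cuts)) {
    sol <- .lp_solve(a = rep(1, J),
                     Ale = rbind(diag(J), -cuts_a),
                     ble = c(rep(p_max, J), f_star + slack - cuts_b))
    if (sol$solved < 0) break
    p_new <- unname(sol$soln[seq_len(J)])
    fv <- f_val(p_new)
    if (fv <= f_star + 2 * slack) {
      if (sum(p_new) <= sum(p)) p <- p_new
      break
    }
    g <- f_grad(p_new)
    cuts_a <- rbind(cuts_a, -g)
    cuts_b <- c(cuts_b, fv - sum(g * p_new))
  }
  p <- pmax(p, 0)
  list(powers = p * p_ref, objective = f_val(p) * c_scale)
}

# phase-2 cut bookkeeping uses cuts as f lower bounds:
#   f(p) >= b_k + g_k.p  (stored as -g_k rows); constraint f<=f* becomes
#   -g_k.p <= f* - b_k  -> handled above via b1 = f* + slack - cuts_b.

#' Optimize source powers under a tumor-coverage constraint
#'
#' Solves the hinge-loss linear program: minimize the volume-weighted
#' organ-at-risk overdose plus `w_t` times the volume-weighted tumor
#' underdose, over nonnegative source powers. If the resulting tumor
#' coverage is below `coverage_target`, the tumor weight is doubled and the
#' LP re-solved (geometric search, then bisection on the weight). Thresholds
#' are pre-multiplied by `pruning_normalization`. Among power vectors of
#' equal objective the one with minimal total power is returned.
#'
#' @param dm a [build_dose_matrix()] result.
#' @param thresholds named per-region threshold doses (fluence rate,
#'   mW cm^-2, or fluence if the matrix is scaled by exposure time).
#' @param cfg a [plan_config()].
#' @return object of class `pdt_plan`: `powers` (mW), `objective`,
#'   `coverage`, `tumor_weight`, `overdose_volume` (named mm^3 per OAR
#'   region), `infeasible` flag.
#' @export
optimize_powers <- function(dm, thresholds, cfg = plan_config()) {
  stopifnot(inherits(dm, "dose_matrix"), inherits(cfg, "plan_config"))
  thr <- thresholds * cfg$pruning_normalization
  tum <- which(dm$region == cfg$tumor_region)
  if (length(tum) == 0L) stop("tumor region ", cfg$tumor_region, " is empty")
  t_t <- thr[as.character(cfg$tumor_region)]
  if (is.na(t_t)) stop("no threshold for tumor region")

  oar_regions <- setdiff(intersect(as.character(unique(dm$region)),
                                   names(thr)),
                         as.character(cfg$tumor_region))
  w_oar <- setNames(rep(1, length(oar_regions)), oar_regions)
  if (!is.null(cfg$oar_weights))
    w_oar[names(cfg$oar_weights)] <- cfg$oar_weights
  oar <- which(as.character(dm$region) %in% oar_regions[w_oar[oar_regions] > 0])

  A_under <- dm$phi[tum, , drop = FALSE]
  b_under <- rep(t_t, length(tum))
  A_over <- dm$phi[oar, , drop = FALSE]
  b_over <- unname(thr[as.character(dm$region[oar])])
  c_over <- unname(w_oar[as.character(dm$region[oar])]) * dm$volume[oar]

  cov_at <- function(p) {
    dose <- as.numeric(A_under %*% p)
    sum(dm$volume[tum][dose >= t_t]) / sum(dm$volume[tum])
  }
  solve_at <- function(w_t) {
    sol <- .hinge_lp(A_over, b_over, c_over, A_under, b_under,
                     w_t * dm$volume[tum], p_max = cfg$power_max)
    # the LP parks marginal elements exactly on their threshold; a relative
    # bump within the solver tolerance makes the >= comparison deterministic
    sol$powers <- sol$powers * (1 + 1e-7)
    sol
  }

  w_t <- cfg$tumor_weight
  sol <- solve_at(w_t)
  cov <- cov_at(sol$powers)
  it <- 0L
  w_lo <- NA_real_
  while (cov < cfg$coverage_target && it < cfg$max_weight_iters) {
    w_lo <- w_t
    w_t <- w_t * 2
    sol <- solve_at(w_t)
    cov <- cov_at(sol$powers)
    it <- it + 1L
  }
  infeasible <- cov < cfg$coverage_target
  if (!infeasible && !is.na(w_lo)) {
    # bisection: smallest weight (within 2^-k) still meeting the target
    w_hi <- w_t
    sol_hi <- sol
    for (k in seq_len(cfg$bisection_iters)) {
      w_mid <- sqrt(w_lo * w_hi)
      sol_mid <- solve_at(w_mid)
      if (cov_at(sol_mid$powers) >= cfg$coverage_target) {
        w_hi <- w_mid
        sol_hi <- sol_mid
      } else {
        w_lo <- w_mid
      }
    }
    sol <- sol_hi
    w_t <- w_hi
    cov <- cov_at(sol$powers)
  }
  if (infeasible)
    warning("coverage target ", cfg$coverage_target,
            " unreachable within power bounds (achieved ",
            signif(cov, 4), "); returning best-weight solution flagged infeasible")

  dose <- as.numeric(dm$phi %*% sol$powers)
  over_vol <- vapply(oar_regions, function(r) {
    idx <- dm$region == as.integer(r)
    sum(dm$volume[idx][dose[idx] > thr[r]])
  }, numeric(1L))

  structure(list(powers = sol$powers, objective = sol$objective,
                 coverage = cov, tumor_weight = w_t,
                 overdose_volume = over_vol, infeasible = infeasible,
                 sources = dm$sources, thresholds = thr,
                 tumor_region = cfg$tumor_region),
            class = "pdt_plan")
}

#' @export
print.pdt_plan <- function(x, ...) {
  cat(sprintf("pdt_plan: %d source(s), coverage=%.4f, objective=%.6g%s\n",
              length(x$powers), x$coverage, x$objective,
              if (x$infeasible) " [INFEASIBLE]" else ""))
  cat("powers (mW):", paste(signif(x$powers, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy summaries of a plan
#' @param x a [optimize_powers()] plan.
#' @param ... unused.
#' @return `tidy`: tibble with one row per source (type, power);
#'   `glance`: one-row tibble with coverage, objective, feasibility.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname tidy
#' @export
tidy.pdt_plan <- function(x, ...) {
  tibble::tibble(source = seq_along(x$powers),
                 type = vapply(x$sources, function(s) s$type, character(1L)),
                 power_mW = x$powers)
}

#' @rdname tidy
#' @export
glance.pdt_plan <- function(x, ...) {
  tibble::tibble(coverage = x$coverage, objective = x$objective,
                 tumor_weight = x$tumor_weight, infeasible = x$infeasible,
                 total_power_mW = sum(x$powers))
}

#' Scale a plan to respect a surface fluence-rate limit
#'
#' If the maximum of `surface_values` exceeds `limit`, all powers (and the
#' surface values) are scaled by `limit / max`; relative allocation is
#' preserved. Used to cap the vessel-wall (intima) fluence rate.
#'
#' @param plan a [optimize_powers()] plan (or any list with `powers`).
#' @param surface_values fluence rate on the constraint surface at the
#'   plan's current powers, mW cm^-2.
#' @param limit cap, mW cm^-2 (default 300, the vessel-wall thermal limit).
#' @return the plan with scaled `powers`, plus `surface_max` (after
#'   scaling) and `surface_scale`.
#' @export
enforce_surface_limit <- function(plan, surface_values, limit = 300) {
  mx <- if (length(surface_values) > 0) max(surface_values, na.rm = TRUE) else 0
  scale <- if (mx > limit) limit / mx else 1
  plan$powers <- plan$powers * scale
  plan$surface_scale <- scale
  plan$surface_max <- mx * scale
  plan$surface_limit <- limit
  plan
}

#' Simulated-annealing source repositioning
#'
#' Perturbs source positions (Gaussian jitter, clipped to the tumor region),
#' re-optimizes powers with a reduced-packet dose matrix for each proposal,
#' and accepts by the Metropolis rule on the LP objective with geometric
#' cooling. The best plan ever seen is returned; deterministic for a fixed
#' seed.
#'
#' @param mesh,materials,thresholds as in [build_dose_matrix()] /
#'   [optimize_powers()].
#' @param sources initial sources (the clinician's starting placement).
#' @param cfg a [plan_config()].
#' @param n_iter annealing iterations (0 returns the initial plan).
#' @param packets packets per proposal dose matrix (reduced count).
#' @param sigma positional jitter standard deviation, mm.
#' @param cooling geometric cooling factor per iteration.
#' @param seed RNG seed.
#' @return the best `pdt_plan` seen, with `positions` and an `objective_trace`.
#' @export
anneal_placement <- function(mesh, materials, sources, thresholds,
                             cfg = plan_config(), n_iter = 20L,
                             packets = 1e4, sigma = NULL, cooling = 0.95,
                             seed = 1L) {
  if (inherits(sources, "light_source")) sources <- list(sources)
  movable <- vapply(sources, function(s) !is.null(s$position) || !is.null(s$center),
                    logical(1L))
  if (!any(movable)) stop("no repositionable source (need position or center)")
  pos_of <- function(s) if (!is.null(s$position)) s$position else s$center
  set_pos <- function(s, p) {
    if (!is.null(s$position)) s$position <- p else s$center <- p
    s
  }
  if (is.null(sigma)) {
    # ~2 mesh cells
    bb <- apply(mesh$vertices, 2L, range)
    sigma <- 2 * mean((bb[2L, ] - bb[1L, ])) / (nrow(mesh$tets) / 6)^(1 / 3)
  }
  tum_idx <- which(mesh$region == cfg$tumor_region)

  eval_plan <- function(srcs, sub_seed) {
    dm <- build_dose_matrix(mesh, materials, srcs, packets = packets,
                            seed = sub_seed)
    optimize_powers(dm, thresholds, cfg)
  }

  set.seed(seed)
  cur_src <- sources
  cur <- eval_plan(cur_src, seed)
  best <- cur
  best_src <- cur_src
  trace <- cur$objective
  if (n_iter >= 1L) {
    temp0 <- max(abs(cur$objective), 1e-8)
    temp <- temp0
    for (it in seq_len(n_iter)) {
      prop_src <- cur_src
      j <- sample(which(movable), 1L)
      for (try in 1:20) {
        cand <- pos_of(cur_src[[j]]) + stats::rnorm(3, 0, sigma)
        tet <- locate_tetra(mesh, cand)
        if (!is.na(tet) && mesh$region[tet] == cfg$tumor_region) break
        cand <- NULL
      }
      if (is.null(cand)) {
        if (length(tum_idx) == 0L) stop("no valid perturbation inside the tumor")
        cand <- tet_centroids(mesh)[sample(tum_idx, 1L), ]
      }
      prop_src[[j]] <- set_pos(cur_src[[j]], cand)
      prop <- eval_plan(prop_src, seed + it)
      d_obj <- prop$objective - cur$objective
      if (d_obj <= 0 || runif(1) < exp(-d_obj / temp)) {
        cur <- prop
        cur_src <- prop_src
      }
      if (prop$objective < best$objective) {
        best <- prop
        best_src <- prop_src
      }
      trace <- c(trace, best$objective)
      temp <- temp * cooling
    }
  }
  best$sources <- best_src
  best$positions <- t(vapply(best_src, pos_of, numeric(3L)))
  best$objective_trace <- trace
  best
}

#' Evaluate a plan with a fresh high-packet simulation
#'
#' @param mesh,materials as elsewhere.
#' @param plan a `pdt_plan` (its `sources` and `powers` are used).
#' @param thresholds named per-region thresholds.
#' @param packets packets for the evaluation run.
#' @param seed RNG seed.
#' @return list with `coverage_report` (tumor coverage fraction, per-OAR
#'   overdose volume mm^3, necrotic volume per region), `dvh` (a
#'   [compute_dvh()] tibble) and the composed `field`.
#' @export
evaluate_plan <- function(mesh, materials, plan, thresholds, packets = 1e6,
                          seed = 1L) {
  srcs <- plan$sources
  for (j in seq_along(srcs)) srcs[[j]]$power <- plan$powers[j]
  active <- which(plan$powers > 0)
  if (length(active) == 0L) {
    phi <- rep(0, nrow(mesh$tets))
    field <- structure(list(phi = phi, estimator = "track_length",
                            total_power = 0), class = "fluence_field")
  } else {
    cfg <- sim_config(n_packets = packets, seed = seed)
    sc <- run_mc(mesh, materials, srcs[active], cfg)
    field <- fluence_from_score(sc, mesh, materials)
  }
  tum_r <- if (!is.null(plan$tumor_region)) plan$tumor_region else 1L
  cov <- coverage(field, thresholds, mesh, tum_r)
  nec <- necrosis_mask(field, thresholds, mesh)
  oar_regions <- setdiff(intersect(as.character(unique(mesh$region)),
                                   names(thresholds)), as.character(tum_r))
  over <- vapply(oar_regions, function(r) {
    idx <- mesh$region == as.integer(r)
    sum(mesh$volume[idx][field$phi[idx] > thresholds[r]])
  }, numeric(1L))
  dvh <- compute_dvh(field, thresholds, mesh)
  list(coverage_report = list(tumor_coverage = cov, overdose_volume = over,
                              necrotic_volume = nec$volume_by_region),
       dvh = dvh, field = field)
}
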