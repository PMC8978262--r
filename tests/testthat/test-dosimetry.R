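# a raw_score with prescribed absorbed fractions (for unit arithmetic tests)
fake_score <- function(absorbed, tracklen, n_tet, total_power = 1) {
  structure(list(absorbed = absorbed, tracklen = tracklen,
                 exited = matrix(0, n_tet, 4L),
                 ledger = list(emitted = 1, absorbed_total = sum(absorbed),
                               exited_total = 0, roulette_net = 0,
                               residual = 0),
                 total_power = total_power, n_packets = 1L, seed = 1L),
            class = "raw_score")
}

test_that("fluence estimators apply the documented unit arithmetic", {
  # one tet of volume 1000 mm^3 (1 cm^3), mu_a = 0.1/mm (1/cm), absorbed
  # fraction 0.2, power 100 mW -> 20 mW/cm^2
  v <- rbind(c(0, 0, 0), c(18.1712059, 0, 0), c(0, 18.1712059, 0),
             c(0, 0, 18.1712059))
  m <- tetra_mesh(v, matrix(1:4, 1), 0L)
  expect_equal(m$volume, 1000, tolerance = 1e-6)
  mats <- uniform_materials(0L, mu_a = 0.1, mu_s = 1)
  sc <- fake_score(absorbed = 0.2, tracklen = 0, n_tet = 1)
  f <- fluence_from_score(sc, m, mats, total_power = 100,
                          estimator = "absorption")
  expect_equal(f$phi, 20, tolerance = 1e-6)

  # zero absorbed -> zero field
  sc0 <- fake_score(absorbed = 0, tracklen = 0, n_tet = 1)
  expect_equal(fluence_from_score(sc0, m, mats, 100, "absorption")$phi, 0)

  # absorption estimator on a transparent region flags NA with a warning
  mats0 <- uniform_materials(0L, mu_a = 0, mu_s = 1)
  expect_warning(
    f0 <- fluence_from_score(sc0, m, mats0, 100, "absorption"),
    "mu_a = 0")
  expect_true(is.na(f0$phi))
})

test_that("track-length and absorption estimators agree on a phantom", {
  m <- box_mesh(extents = c(20, 20, 20), cells = c(4L, 4L, 4L))
  mats <- uniform_materials(0L, mu_a = 0.05, mu_s = 2, g = 0, n = 1.4)
  sc <- run_mc(m, mats, source_point(c(10.2, 9.9, 10.1), 1),
               sim_config(n_packets = 1e5, seed = 21))
  fa <- fluence_from_score(sc, m, mats, estimator = "absorption")
  ft <- fluence_from_score(sc, m, mats, estimator = "track_length")
  # compare on well-sampled tets (central region)
  cen <- tet_centroids(m)
  r <- sqrt(rowSums(sweep(cen, 2, c(10, 10, 10))^2))
  idx <- which(r < 8)
  rel <- abs(fa$phi[idx] - ft$phi[idx]) / ft$phi[idx]
  expect_lt(stats::median(rel), 0.1)
  expect_lt(mean(ft$phi[idx] == 0), 0.01)

  # field/ledger consistency: volume integral of mu_a * Phi equals the
  # absorbed power (absorption estimator: identity up to float error)
  mu_a <- 0.05
  absorbed_power <- sc$total_power * sc$ledger$absorbed_total /
    sc$ledger$emitted
  integral <- sum(fa$phi / 100 * mu_a * m$volume)  # back to mW/mm^2
  expect_equal(integral, absorbed_power, tolerance = 1e-6)
})

test_that("DVH has the survival-curve shape and matches brute-force counting", {
  m <- box_mesh(extents = c(10, 10, 10), cells = c(2L, 2L, 2L))
  n_tet <- nrow(m$tets)

  # uniform field exactly at threshold: y = 100 up to x = 100, then 0
  thr <- c("0" = 5)
  dvh_u <- compute_dvh(rep(5, n_tet), thr, m, bins = 200L)
  expect_true(all(dvh_u$volume_pct[dvh_u$dose_pct <= 100] == 100))
  expect_true(all(dvh_u$volume_pct[dvh_u$dose_pct > 100] == 0))

  # random instance against an exhaustive counting oracle at bin centers
  set.seed(51)
  phi <- runif(n_tet, 0, 12)
  dvh <- compute_dvh(phi, thr, m, bins = 173L)
  for (i in seq(1, nrow(dvh), by = 13)) {
    x <- dvh$dose_pct[i]
    expected <- 100 * sum(m$volume[100 * phi / 5 >= x]) / sum(m$volume)
    expect_identical(dvh$volume_pct[i], expected)
  }
  # monotone nonincreasing, y(0) = 100
  expect_true(all(diff(dvh$volume_pct) <= 0))
  expect_identical(dvh$volume_pct[1], 100)
  expect_error(compute_dvh(phi, c("3" = 1), m), "no region")
})

test_that("coverage and necrosis agree with direct counting", {
  m <- box_mesh(extents = c(10, 10, 10), cells = c(2L, 2L, 2L))
  n_tet <- nrow(m$tets)
  thr <- c("0" = 1)
  expect_equal(coverage(rep(2, n_tet), thr, m, 0), 1)
  phi <- rep(0.5, n_tet)
  phi[seq_len(n_tet / 2)] <- 2
  # equal-volume tets: half above
  expect_equal(coverage(phi, thr, m, 0), 0.5)
  set.seed(52)
  phi2 <- runif(n_tet, 0, 2)
  expect_equal(coverage(phi2, thr, m, 0),
               sum(m$volume[phi2 >= 1]) / sum(m$volume))
  nec <- necrosis_mask(phi2, thr, m)
  expect_identical(nec$necrotic, phi2 >= 1)
  expect_equal(unname(nec$volume_by_region["0"]), sum(m$volume[phi2 >= 1]))
  expect_error(coverage(phi2, thr, m, 9), "empty")

  # coverage ties out with the DVH at x = 100% within one bin
  dvh <- compute_dvh(phi2, thr, m, bins = 2001L)
  y_at_100 <- dvh$volume_pct[which.min(abs(dvh$dose_pct - 100))]
  expect_equal(coverage(phi2, thr, m, 0), y_at_100 / 100, tolerance = 0.01)
})

test_that("analytic point fluence has the diffusion-theory form", {
  # mu_a = 0.01, mu_s' = 1, P = 1, r = 10 mm -> 4.23e-3 mm^-2 before the
  # cm^-2 conversion
  phi10 <- analytic_point_fluence(10, 1, 0.01, 1)
  expect_equal(phi10 / 100, 4.23e-3, tolerance = 0.01)
  # monotone decay
  r <- seq(5, 50, by = 5)
  expect_true(all(diff(analytic_point_fluence(r, 1, 0.01, 1)) < 0))
  # functional-form identity for ratios
  mu_eff <- sqrt(3 * 0.01 * 1.01)
  ratio <- analytic_point_fluence(5, 1, 0.01, 1) /
    analytic_point_fluence(15, 1, 0.01, 1)
  expect_equal(ratio, (15 / 5) * exp(-mu_eff * (5 - 15)), tolerance = 1e-12)
  expect_error(analytic_point_fluence(0, 1, 0.01, 1), "singular")
})

test_that("line probes read the piecewise-constant field", {
  m <- box_mesh(extents = c(10, 10, 10), cells = c(2L, 2L, 2L))
  n_tet <- nrow(m$tets)
  # uniform field -> constant profile
  pr <- line_probe(rep(3, n_tet), m, c(1, 1, 1), c(9, 9, 9), 25L)
  expect_true(all(pr$phi == 3))
  # matches locate + lookup pointwise
  set.seed(53)
  phi <- runif(n_tet)
  pr2 <- line_probe(phi, m, c(0.5, 5, 5), c(9.5, 5, 5), 40L)
  tets <- locate_tetra(m, as.matrix(pr2[, c("x", "y", "z")]))
  expect_equal(pr2$phi, phi[tets])
  # points beyond the mesh flagged missing
  pr3 <- line_probe(phi, m, c(5, 5, 5), c(5, 5, 25), 11L)
  expect_true(anyNA(pr3$phi))
  # single-sample probe at a centroid reads that tet
  cen <- tet_centroids(m)
  pr4 <- line_probe(phi, m, cen[7, ], cen[7, ], 1L)
  expect_equal(pr4$phi, phi[7])
})

test_that("DVH plotting returns a ggplot object", {
  m <- box_mesh(extents = c(10, 10, 10), cells = c(2L, 2L, 2L))
  dvh <- compute_dvh(runif(nrow(m$tets)), c("0" = 0.5), m, bins = 50L)
  expect_s3_class(plot_dvh(dvh), "ggplot")
})
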