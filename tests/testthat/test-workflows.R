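# small shared sweep fixture: coarse tissue box with a short diffuser
sweep_fixture <- function(mu_a_values, mu_s_prime_values, packets = 500,
                          seed = 71) {
  mesh <- generate_phantom(phantom_spec("box", extents = c(40, 60, 40),
                                        cells = c(4L, 6L, 4L)))
  mats <- uniform_materials(0L, mu_a = 0.01, mu_s = 8, g = 0, n = 1.37)
  diff <- source_cyl_diffuser(center = c(20, 30, 20), axis = c(0, 1, 0),
                              radius = 1, length = 20, linear_density = 100)
  dets <- rbind(c(24.5, 30, 20), c(28, 30, 20))
  sweep_spec(mesh, mats, target_region = 0L, mu_a_values = mu_a_values,
             mu_s_prime_values = mu_s_prime_values, g = 0, n = 1.37,
             source = diff, detectors = dets, packets = packets, seed = seed)
}

test_that("sweeps run exactly one simulation per grid point", {
  tab1 <- run_sweep(sweep_fixture(0.01, 6, packets = 200))
  expect_equal(attr(tab1, "n_runs"), 1L)
  expect_equal(nrow(tab1), 2L)  # 1 grid point x 2 detectors

  tab4 <- run_sweep(sweep_fixture(c(0.005, 0.05), c(6, 9), packets = 200))
  expect_equal(attr(tab4, "n_runs"), 4L)
  expect_equal(nrow(tab4), 8L)
  expect_equal(nrow(unique(tab4[, c("mu_a", "mu_s_prime")])), 4L)
})

test_that("detected fluence falls with absorption at fixed scattering", {
  tab <- run_sweep(sweep_fixture(c(0.001, 0.02, 0.063), 7, packets = 3000))
  far <- tab[tab$detector == 2L, ]
  far <- far[order(far$mu_a), ]
  expect_true(all(diff(far$fluence_rate) < 0))
})

test_that("lookup inversion recovers the generating grid point", {
  tab <- run_sweep(sweep_fixture(c(0.005, 0.03, 0.063), c(6, 8.5, 11),
                                 packets = 3000))
  for (i in c(2, 4, 5)) {
    g <- unique(tab[, c("mu_a", "mu_s_prime")])[i, ]
    row <- tab[tab$mu_a == g$mu_a & tab$mu_s_prime == g$mu_s_prime, ]
    meas <- row$fluence_rate[order(row$detector)]
    est <- invert_lookup(tab, meas)
    expect_equal(est$mu_a, g$mu_a)
    expect_equal(est$mu_s_prime, g$mu_s_prime)
  }
  expect_error(invert_lookup(tab, c(-1, 2)), "positive")
  expect_error(invert_lookup(tab, 1), "detector")
})

test_that("single-detector inversions report degeneracy", {
  # two grid points engineered to give identical single-detector signals
  tab <- tibble::tibble(mu_a = c(0.01, 0.02), mu_s_prime = c(6, 8),
                        detector = c(1L, 1L), fluence_rate = c(5, 5))
  class(tab) <- c("lookup_table", class(tab))
  est <- invert_lookup(tab, 5)
  expect_true(est$ambiguous)
  expect_equal(est$n_candidates, 2L)
})

test_that("dose escalation caps the intima fluence rate", {
  mesh <- generate_phantom(phantom_spec(
    "vessel_in_box", extents = c(30, 30, 30), cells = c(10L, 10L, 10L),
    vessel_point = c(15, 15, 15), vessel_axis = c(0, 1, 0),
    vessel_radius = c(2.5, 4.5), labels = c(1L, 2L)))
  mats <- material_set(
    material(0, mu_a = 0.03, mu_s_prime = 1, g = 0.9, n = 1.4, name = "tissue"),
    material(1, mu_a = 0.002, mu_s_prime = 0.1, g = 0.9, n = 1.35, name = "blood/lumen"),
    material(2, mu_a = 0.05, mu_s_prime = 1.5, g = 0.9, n = 1.4, name = "wall"))
  d1 <- source_cyl_diffuser(center = c(15, 10, 15), axis = c(0, 1, 0),
                            radius = 1, length = 8, power = 500)
  d2 <- source_cyl_diffuser(center = c(15, 20, 15), axis = c(0, 1, 0),
                            radius = 1, length = 8, power = 500)
  rep_ <- dose_escalation(mesh, mats, list(d1, d2), lumen_region = 1L,
                          wall_region = 2L, limit = 300,
                          thresholds = c("0" = 20, "2" = 50),
                          packets = 5000, seed = 5)
  expect_lte(rep_$intima_max, 300 * (1 + 1e-12))
  expect_equal(rep_$powers, c(500, 500) * rep_$scale)
  # midpoint fluence strictly below the peak on a two-diffuser line
  expect_gt(rep_$attenuation_factor, 1)
  expect_true(all(names(rep_$necrotic_volume) %in% c("0", "2")))

  # an infinite limit leaves the requested powers unchanged
  rep_inf <- dose_escalation(mesh, mats, list(d1, d2), lumen_region = 1L,
                             wall_region = 2L, limit = Inf,
                             packets = 2000, seed = 5)
  expect_equal(rep_inf$powers, c(500, 500))
  expect_equal(rep_inf$scale, 1)
})

test_that("the CLI runs simulate and sweep end to end", {
  dir <- withr::local_tempdir()
  mesh_path <- file.path(dir, "mesh.vtk")
  mats_path <- file.path(dir, "materials.csv")
  srcs_path <- file.path(dir, "sources.yaml")
  out_vtk <- file.path(dir, "fluence.vtk")
  ledger_path <- file.path(dir, "ledger.json")

  mesh <- generate_phantom(phantom_spec("box", extents = c(20, 20, 20),
                                        cells = c(3L, 3L, 3L)))
  write_fluence_vtk(mesh, list(), mesh_path)
  writeLines(c("region,name,mu_a,mu_s,g,n", "0,tissue,0.02,1,0,1.37"),
             mats_path)
  writeLines(c("sources:",
               "  - type: point",
               "    position: [10.2, 9.9, 10.1]",
               "    power: 100"), srcs_path)

  code <- suppressMessages(cli_main(c(
    "simulate", "--mesh", mesh_path, "--materials", mats_path,
    "--sources", srcs_path, "--packets", "500", "--seed", "4",
    "--out-vtk", out_vtk, "--ledger-json", ledger_path)))
  expect_identical(code, 0L)
  expect_true(file.exists(out_vtk))
  led <- jsonlite::read_json(ledger_path)
  expect_equal(led$emitted, 500)
  m2 <- read_tetra_mesh_vtk(out_vtk)
  expect_length(attr(m2, "cell_arrays")$fluence, nrow(mesh$tets))

  # phantom subcommand
  ph_path <- file.path(dir, "ph.vtk")
  code2 <- suppressMessages(cli_main(c(
    "phantom", "--kind", "box", "--extents", "10,10,10",
    "--cells", "2,2,2", "--out", ph_path)))
  expect_identical(code2, 0L)
  expect_equal(nrow(read_tetra_mesh_vtk(ph_path)$tets), 48L)

  # sweep subcommand: 2x2 grid -> 4 result groups in the CSV
  sweep_csv <- file.path(dir, "lookup.csv")
  code3 <- suppressMessages(cli_main(c(
    "sweep", "--mesh", mesh_path, "--materials", mats_path,
    "--sources", srcs_path, "--target-region", "0",
    "--mu-a", "0.01,0.05", "--mu-s-prime", "1,2",
    "--detectors", "12,10,10;14,10,10", "--packets", "200", "--seed", "6",
    "--out", sweep_csv)))
  expect_identical(code3, 0L)
  tab <- read.csv(sweep_csv)
  expect_equal(nrow(unique(tab[, c("mu_a", "mu_s_prime")])), 4L)

  # dvh subcommand consumes the fluence VTK written by simulate
  thr_path <- file.path(dir, "thresholds.csv")
  dvh_path <- file.path(dir, "dvh.csv")
  writeLines(c("region,threshold", "0,1"), thr_path)
  code_dvh <- suppressMessages(cli_main(c(
    "dvh", "--fluence-vtk", out_vtk, "--thresholds", thr_path,
    "--bins", "100", "--out", dvh_path)))
  expect_identical(code_dvh, 0L)
  dvh_tab <- read.csv(dvh_path)
  expect_equal(nrow(dvh_tab), 100L)
  expect_equal(dvh_tab$volume_pct[1], 100)

  # invalid refractive index in the materials table names the rule
  writeLines(c("region,name,mu_a,mu_s,g,n", "0,tissue,0.02,1,0,0.9"),
             mats_path)
  msgs <- capture.output(
    code4 <- cli_main(c("simulate", "--mesh", mesh_path, "--materials",
                        mats_path, "--sources", srcs_path,
                        "--packets", "10")),
    type = "message")
  expect_identical(code4, 1L)
  expect_true(any(grepl("refractive index", msgs)))

  # unknown subcommand is a usage error
  msgs2 <- capture.output(code5 <- cli_main("frobnicate"), type = "message")
  expect_identical(code5, 1L)
})
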