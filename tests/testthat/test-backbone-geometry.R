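test_that("compute_dihedral follows the sign convention and handles wrap", {
  # ideal trans peptide built with omega = 180
  s <- build_backbone(tibble::tibble(resname = "ALA", phi = -57, psi = -47,
                                     omega = 180, .rows = 2), 50)
  g <- analyze_backbone(s)
  expect_angle_equal(g$omega[2], 180, tol = 1e-9)

  # mirror imaging negates any non-180 dihedral
  p <- list(c(1, 1, 0), c(0, 0, 0), c(0, 0, 1), c(1, -1, 1))
  d <- compute_dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
  dm <- compute_dihedral(-p[[1]], -p[[2]], -p[[3]], -p[[4]])
  expect_equal(dm, -d, tolerance = 1e-9)

  # degenerate (collinear) input is NA, not an error
  expect_true(is.na(compute_dihedral(c(0, 0, 0), c(1, 0, 0),
                                     c(2, 0, 0), c(3, 1, 0))))
})

test_that("build/analyze round-trip recovers dihedrals and overrides", {
  s <- build_backbone(tibble::tibble(resname = "ALA", phi = -75, psi = 150,
                                     omega = 180, .rows = 6), 40)
  g <- analyze_backbone(s)
  expect_angle_equal(g$phi[-1], rep(-75, 5))
  expect_angle_equal(g$psi[-6], rep(150, 5))

  ov <- data.frame(site = 4, parameter = "C-N-CA", value = 121.7 - 4 * 2.5)
  g2 <- analyze_backbone(build_backbone(
    tibble::tibble(resname = "ALA", phi = -57, psi = -47, omega = 180,
                   .rows = 8), 90, overrides = ov))
  expect_equal(g2$z_c_n_ca[4], -4, tolerance = 1e-9)
  expect_lt(max(abs(g2$z_c_n_ca[-c(1, 4)])), 1e-9)

  # a cis-range omega round-trips too
  spec <- tibble::tibble(resname = "ALA", phi = -60, psi = 140, omega = 180,
                         .rows = 5)
  spec$omega[3] <- 10
  g3 <- analyze_backbone(build_backbone(spec, 30))
  expect_angle_equal(g3$omega[3], 10)
})

test_that("random dihedral specs round-trip within 1e-6 degrees", {
  set.seed(421)
  for (rep in 1:25) {
    n <- sample(4:9, 1)
    spec <- tibble::tibble(
      resname = sample(c("ALA", "GLY", "PRO"), n, replace = TRUE),
      phi = stats::runif(n, -179, 179),
      psi = stats::runif(n, -179, 179),
      omega = stats::runif(n, -179, 179))
    ov <- data.frame(site = sample(2:n, 1), parameter = "C-N-CA",
                     value = stats::runif(1, 100, 140))
    g <- analyze_backbone(build_backbone(spec, 50, overrides = ov))
    expect_angle_equal(g$phi[-1], spec$phi[-1])
    expect_angle_equal(g$psi[-n], spec$psi[-n])
    expect_angle_equal(g$omega[-1], spec$omega[-1])
    expect_equal(g$z_c_n_ca[ov$site],
                 (ov$value - 121.7) / 2.5, tolerance = 1e-6)
  }
})

test_that("rigid motion leaves dihedrals, angles and z-scores unchanged", {
  s <- make_fixture("barbed_coil", length = 12, plddt = 30, seed = 3)
  g1 <- analyze_backbone(s)
  R <- barbedwire:::rotation_about(c(1, 2, 3), 73.2)
  s2 <- barbedwire:::transform_structure(s, R, t = c(11, -5, 42))
  g2 <- analyze_backbone(s2)
  for (col in c("phi", "psi", "omega", "z_n_ca", "z_ca_c", "z_n_ca_c",
                "z_c_n", "z_ca_c_n", "z_c_n_ca", "ca_angle", "mu_in",
                "mu_out")) {
    expect_equal(g2[[col]], g1[[col]], tolerance = 1e-9)
  }
})

test_that("unperturbed built geometry has zero z-scores", {
  g <- analyze_backbone(build_backbone(
    tibble::tibble(resname = "ALA", phi = -57, psi = -47, omega = 180,
                   .rows = 10), 90))
  zmat <- as.matrix(g[, c("z_n_ca", "z_ca_c", "z_n_ca_c", "z_ca_c_o",
                          "z_c_n", "z_ca_c_n", "z_c_n_ca")])
  expect_lt(max(abs(zmat), na.rm = TRUE), 1e-9)
  expect_angle_equal(g$omega[-1], rep(180, 9), tol = 1e-9)
})

test_that("a spatial gap splits the chain and truncates dihedrals", {
  s <- build_backbone(tibble::tibble(resname = "ALA", phi = -57, psi = -47,
                                     omega = 180, .rows = 6), 50)
  post <- s$resno >= 4
  s$x[post] <- s$x[post] + 10   # 10 A shift between residues 3 and 4
  g <- analyze_backbone(s)
  expect_true(g$chain_break_before[4])
  expect_true(g$chain_break_after[3])
  expect_true(is.na(g$phi[4]))
  expect_true(is.na(g$omega[4]))
  expect_true(is.na(g$psi[3]))
  expect_true(is.na(g$z_c_n[4]))
})

test_that("impossible overrides are rejected", {
  expect_error(build_backbone(
    tibble::tibble(resname = "ALA", phi = -57, psi = -47, omega = 180,
                   .rows = 3), 50,
    overrides = data.frame(site = 2, parameter = "C-N", value = -1)),
    "positive")
})
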