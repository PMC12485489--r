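test_that("omega classification splits cis/twisted/trans correctly", {
  expect_equal(classify_omega(180, FALSE), "trans")
  expect_equal(classify_omega(5, TRUE), "cis_pro")
  expect_equal(classify_omega(5, FALSE), "cis_nonpro")
  expect_equal(classify_omega(90, FALSE), "twisted")
  expect_equal(classify_omega(-90, TRUE), "twisted")
  expect_equal(classify_omega(c(30, -30), FALSE),
               c("cis_nonpro", "cis_nonpro"))
  expect_equal(classify_omega(c(150, -150), FALSE), c("trans", "trans"))
  expect_equal(classify_omega(NA_real_, FALSE), "undefined")
})

test_that("Ramachandran flags honor the allowed map and signature boxes", {
  r <- classify_rama(-57, -47, "general")
  expect_false(r$rama_outlier)
  expect_false(r$high_psi_band)

  r2 <- classify_rama(100, 100, "general")
  expect_true(r2$rama_outlier)
  expect_true(r2$rama_upper_right)

  # PPII point: inside the band, not an outlier (general and proline class)
  for (cls in c("general", "pro")) {
    r3 <- classify_rama(-75, 150, cls)
    expect_false(r3$rama_outlier)
    expect_true(r3$high_psi_band)
    expect_false(r3$rama_upper_right)
  }

  # undefined dihedrals: unevaluated, all flags false
  r4 <- classify_rama(NA, 100, "general")
  expect_false(r4$rama_evaluated)
  expect_false(r4$rama_outlier)
})

test_that("upper-right box implies both the outlier call and the psi band", {
  set.seed(99)
  phi <- stats::runif(10000, -180, 180)
  psi <- stats::runif(10000, -180, 180)
  cls <- sample(c("general", "gly", "pro", "prepro"), 10000, replace = TRUE)
  r <- classify_rama(phi, psi, cls)
  expect_true(all(r$rama_outlier[r$rama_upper_right]))
  expect_true(all(r$high_psi_band[r$rama_upper_right]))
  # band bounds are exactly +60/+170
  expect_equal(r$high_psi_band, !is.na(psi) & psi > 60 & psi < 170)
})

test_that("CA-geometry flag accepts regular elements and catches kinks", {
  h <- make_fixture("lone_helix", length = 10, plddt = 90)
  g <- analyze_backbone(h)
  ca <- classify_ca_geometry(g$ca_angle, g$mu_in, g$mu_out)
  interior <- !is.na(g$mu_in) & !is.na(g$mu_out)
  expect_true(all(!ca$ca_geom_outlier[interior]))

  p <- make_fixture("ppii", length = 10, plddt = 40)
  gp <- analyze_backbone(p)
  cap <- classify_ca_geometry(gp$ca_angle, gp$mu_in, gp$mu_out)
  expect_true(all(!cap$ca_geom_outlier[!is.na(gp$mu_in) & !is.na(gp$mu_out)]))

  # pseudo-angle below the 70-degree floor is an outlier even in an
  # otherwise allowed pseudo-dihedral region
  expect_true(classify_ca_geometry(60, 50, 50)$ca_geom_outlier)
  expect_false(classify_ca_geometry(90, 50, 50)$ca_geom_outlier)
  # terminal residues: undefined geometry, unevaluated and unflagged
  term <- classify_ca_geometry(NA, NA, 50)
  expect_false(term$ca_evaluated)
  expect_false(term$ca_geom_outlier)
})

test_that("ideal helix interiors carry no validation flags at all", {
  h <- make_fixture("lone_helix", length = 10, plddt = 90)
  fl <- compute_validation_flags(assign_ss(h, analyze_backbone(h)))
  interior <- 3:8
  expect_true(all(!fl$rama_outlier[interior]))
  expect_true(all(!fl$ca_geom_outlier[interior]))
  expect_true(all(!fl$bond_geom_outlier[interior]))
  expect_true(all(!fl$cnca_outlier[interior]))
  expect_true(all(fl$omega_state[interior] == "trans"))
})

test_that("bond z-scores beyond the cutoff raise geometry flags", {
  ov <- data.frame(site = 5, parameter = "C-N-CA", value = 121.7 - 4.5 * 2.5)
  s <- build_backbone(tibble::tibble(resname = "ALA", phi = -57, psi = -47,
                                     omega = 180, .rows = 8), 30,
                      overrides = ov)
  fl <- compute_validation_flags(assign_ss(s, analyze_backbone(s)))
  expect_true(fl$cnca_outlier[5])
  expect_true(fl$bond_geom_outlier[5])
  expect_false(any(fl$cnca_outlier[-5]))
  # invariant: a C-N-CA outlier is always a covalent-geometry outlier
  expect_true(all(fl$bond_geom_outlier[fl$cnca_outlier]))
})

test_that("external validation results override internal flags", {
  h <- make_fixture("lone_helix", length = 6, plddt = 50)
  fl <- compute_validation_flags(assign_ss(h, analyze_backbone(h)))
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    data.frame(chain = "A", resno = 3, ca_geom_outlier = TRUE),
    f, auto_unbox = FALSE)
  fl2 <- apply_external_validation(fl, f)
  expect_true(fl2$ca_geom_outlier[3])
  expect_equal(fl2$ca_geom_outlier[-3], fl$ca_geom_outlier[-3])

  jsonlite::write_json(
    data.frame(chain = "Q", resno = 99, ca_geom_outlier = TRUE), f)
  expect_error(apply_external_validation(fl, f), "unknown residues")
})
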