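B <- "barbed_wire"; P <- "pseudostructure"; N <- "near_predictive"


test_that("the mode decision tree matches the published branches", {
  cases <- expand.grid(plddt = c(30, 69.9, 70, 90), packed = c(TRUE, FALSE),
                       outlier = c(TRUE, FALSE))
  got <- assign_mode(cases$plddt, cases$packed, cases$outlier, FALSE)
  want <- ifelse(cases$plddt >= 70,
                 ifelse(cases$packed, "predictive", "unpacked_high_plddt"),
                 ifelse(cases$packed,
                        ifelse(cases$outlier, "unphysical", N),
                        ifelse(cases$outlier, B, P)))
  expect_equal(got, want)
  # the boundary is inclusive: 70 is high confidence, 69.9 is not
  expect_equal(assign_mode(70, TRUE, FALSE, FALSE), "predictive")
  expect_equal(assign_mode(69.9, TRUE, FALSE, FALSE), N)
})

test_that("signature rule: upper-right Ramachandran always marks", {
  fl <- flags_row(1, rama_upper_right = TRUE)
  expect_true(signature_outlier(fl, low_plddt = FALSE, packed = TRUE))
})

test_that("signature rule: CA-geometry outliers are contextual", {
  fl <- flags_row(1, ca_geom_outlier = TRUE)
  # permitted in predictive (packed, high-pLDDT) regions
  expect_false(signature_outlier(fl, low_plddt = FALSE, packed = TRUE))
  expect_false(signature_outlier(fl, low_plddt = TRUE, packed = TRUE))
  expect_true(signature_outlier(fl, low_plddt = TRUE, packed = FALSE))
})

test_that("signature rule: bad peptide bonds mark both residues", {
  # residue 2 carries a twisted bond (the bond between residues 1 and 2)
  fl <- flags_row(3)
  fl$omega_state[2] <- "twisted"
  sig <- signature_outlier(fl, low_plddt = FALSE, packed = TRUE)
  expect_equal(sig, c(TRUE, TRUE, FALSE))

  fl$omega_state[2] <- "cis_nonpro"
  expect_equal(signature_outlier(fl, FALSE, TRUE), c(TRUE, TRUE, FALSE))

  fl2 <- flags_row(3, cnca_outlier = c(FALSE, FALSE, TRUE))
  expect_equal(signature_outlier(fl2, FALSE, TRUE), c(FALSE, TRUE, TRUE))

  # but not across a chain break: the bond does not exist
  fl$chain_break_before[2] <- TRUE
  expect_equal(signature_outlier(fl, FALSE, TRUE), c(FALSE, TRUE, FALSE))
})

test_that("signature rule: cis-Pro marks only in low-pLDDT unpacked regions", {
  fl <- flags_row(1, omega_state = "cis_pro")
  expect_false(signature_outlier(fl, low_plddt = FALSE, packed = TRUE))
  expect_false(signature_outlier(fl, low_plddt = TRUE, packed = TRUE))
  expect_true(signature_outlier(fl, low_plddt = TRUE, packed = FALSE))
})

test_that("high outlier density requires two of the four criteria", {
  # two twisted + two covalent outliers -> criteria 1 and 3
  fl <- flags_row(3, omega_state = c("twisted", "twisted", "trans"),
                  bond_geom_outlier = c(TRUE, TRUE, FALSE))
  expect_true(high_outlier_density(fl)[2])
  # only two twisted -> one criterion, not enough
  fl2 <- flags_row(3, omega_state = c("twisted", "twisted", "trans"))
  expect_false(high_outlier_density(fl2)[2])
  # all three in the psi band with one rama outlier + two CA outliers
  fl3 <- flags_row(3, high_psi_band = TRUE,
                   rama_outlier = c(TRUE, FALSE, FALSE),
                   ca_geom_outlier = c(TRUE, TRUE, FALSE))
  expect_true(high_outlier_density(fl3)[2])
  # truncated terminal window evaluates on available residues
  fl4 <- flags_row(2, omega_state = "twisted", bond_geom_outlier = TRUE)
  expect_true(high_outlier_density(fl4)[1])
})

test_that("two-pass smoothing matches the worked examples", {
  expect_equal(smooth_modes(c(B, B, P, B, B)), rep(B, 5))
  expect_equal(smooth_modes(c(N, P, P, N)), rep(N, 4))
  expect_equal(smooth_modes(c(P, B, B, P)), rep(P, 4))
  # chain-initial pseudostructure has no left flank: unsmoothed
  expect_equal(smooth_modes(c(P, B, B, B)), c(P, B, B, B))
  # mixed flanks are left alone
  expect_equal(smooth_modes(c(B, P, N)), c(B, P, N))
  # runs of three or more never smooth
  expect_equal(smooth_modes(c(B, P, P, P, B)), c(B, P, P, P, B))
  # chain breaks cut the neighborhood
  expect_equal(smooth_modes(c(B, B, P, B, B),
                            break_before = c(FALSE, FALSE, FALSE, TRUE, FALSE)),
               c(B, B, P, B, B))
  # other modes never change
  expect_equal(smooth_modes(c("predictive", "unphysical", P)),
               c("predictive", "unphysical", P))
})

test_that("smoothing equals the brute-force reference and is idempotent", {
  set.seed(7)
  for (k in 1:200) {
    m <- sample(c(B, P, N), sample(1:8, 1), replace = TRUE)
    sm <- smooth_modes(m)
    expect_equal(sm, oracle_smooth(m))
    expect_equal(smooth_modes(sm), sm)
  }
})

test_that("Lprocg labels compose positionally", {
  expect_equal(make_label(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE), "L-----")
  expect_equal(make_label(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), "Lp----")
  expect_equal(make_label(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE), "Lpro-g")
  expect_equal(make_label(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE), "Lprocg")
  expect_equal(make_label(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE), "------")
})

test_that("the pLDDT gate holds before and after smoothing", {
  fit <- bw_analyze(make_fixture("mixed", length = 10, seed = 4))
  hi <- fit$residues$plddt >= 70
  for (col in c("mode_raw", "mode")) {
    expect_equal(fit$residues[[col]] %in%
                   c("predictive", "unpacked_high_plddt"), hi)
  }
})
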