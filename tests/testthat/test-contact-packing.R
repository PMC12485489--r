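contacts_as_pairs <- function(ct) {
  if (nrow(ct) == 0) return(matrix(integer(0), ncol = 2))
  as.matrix(ct[order(ct$i, ct$j), c("i", "j")])
}

test_that("isolated elements yield no tertiary contacts", {
  # extended 10-mer: nothing within reach after the |di| <= 4 exclusion
  s <- make_fixture("lone_strand", length = 10, plddt = 40)
  ss <- assign_ss(s, analyze_backbone(s))
  expect_equal(nrow(enumerate_contacts(s, ss)), 0)

  # one ideal helix, one element: intra-element contacts all excluded
  h <- make_fixture("lone_helix", length = 12, plddt = 92)
  ssh <- assign_ss(h, analyze_backbone(h))
  expect_true(all(ssh$ss == "H"))
  expect_equal(nrow(enumerate_contacts(h, ssh)), 0)
})

test_that("bundle contacts match the naive all-pairs oracle", {
  s <- make_fixture("helix_bundle", length = 12, plddt = 90)
  ss <- assign_ss(s, analyze_backbone(s))
  ct <- enumerate_contacts(s, ss)
  expect_gt(nrow(ct), 0)
  expect_equal(contacts_as_pairs(ct), unname(oracle_contacts(s, ss)),
               ignore_attr = TRUE)
})

test_that("cell-list enumeration equals the oracle on varied fixtures", {
  cases <- list(
    make_fixture("helix_bundle", length = 8, plddt = 90),
    make_fixture("barbed_coil", length = 15, plddt = 30, seed = 5),
    make_fixture("mixed", length = 8, seed = 2))
  for (s in cases) {
    ss <- assign_ss(s, analyze_backbone(s))
    expect_equal(contacts_as_pairs(enumerate_contacts(s, ss)),
                 unname(oracle_contacts(s, ss)), ignore_attr = TRUE)
  }
})

test_that("contact sets are invariant under rigid motion", {
  s <- make_fixture("helix_bundle", length = 10, plddt = 90)
  ss <- assign_ss(s, analyze_backbone(s))
  p1 <- contacts_as_pairs(enumerate_contacts(s, ss))
  s2 <- barbedwire:::transform_structure(
    s, barbedwire:::rotation_about(c(2, -1, 1), 121), t = c(-8, 2, 30))
  p2 <- contacts_as_pairs(enumerate_contacts(s2, assign_ss(s2,
                                                           analyze_backbone(s2))))
  expect_equal(p1, p2)
})

test_that("adding a distant atom group changes no existing score", {
  s <- make_fixture("helix_bundle", length = 10, plddt = 90)
  ss <- assign_ss(s, analyze_backbone(s))
  base <- packing_score(s, enumerate_contacts(s, ss), ss)
  far <- make_fixture("lone_helix", length = 5, plddt = 90)
  far$chain <- "Z"
  far <- barbedwire:::transform_structure(far, t = c(500, 500, 500))
  s2 <- barbedwire:::new_bw_structure(dplyr::bind_rows(s, far))
  ss2 <- assign_ss(s2, analyze_backbone(s2))
  new <- packing_score(s2, enumerate_contacts(s2, ss2), ss2)
  expect_equal(new$score[new$chain %in% c("A", "B")], base$score)
})

test_that("packing scores and SS-dependent cutoffs follow the rules", {
  s <- make_fixture("lone_strand", length = 10, plddt = 40)
  ss <- assign_ss(s, analyze_backbone(s))
  ps <- packing_score(s, barbedwire:::empty_contacts(), ss)
  expect_true(all(ps$score == 0))
  expect_true(all(!ps$packed))

  # identical score 0.40: packed for a strand residue, not for coil
  res <- bw_residues(s)
  fake_ss <- ss
  fake_contacts <- tibble::tibble(
    i = 1L, j = 2L, chain_i = "A", resno_i = 5L, chain_j = "A",
    resno_j = 10L, res_i = 5L, res_j = 10L, gap = 0)
  fake_contacts <- fake_contacts[rep(1, 20), ]  # 20 pairs touching res 5
  heavy_win5 <- sum(res$n_heavy_atoms[3:7])     # 25 atoms -> score 0.8
  n_pairs <- round(0.40 * heavy_win5)           # score exactly 0.40
  fake_contacts <- fake_contacts[rep(1, n_pairs), ]
  fake_ss$ss <- "E"
  ps_e <- packing_score(s, fake_contacts, fake_ss)
  fake_ss$ss <- "C"
  ps_c <- packing_score(s, fake_contacts, fake_ss)
  expect_equal(ps_e$score[5], 0.40)
  expect_true(ps_e$packed[5])
  expect_false(ps_c$packed[5])
})

test_that("windows truncate at termini and chain breaks", {
  s <- make_fixture("lone_strand", length = 10, plddt = 40)
  ss <- assign_ss(s, analyze_backbone(s))
  ps <- packing_score(s, barbedwire:::empty_contacts(), ss)
  res <- bw_residues(s)
  expect_equal(ps$heavy_atoms[1], sum(res$n_heavy_atoms[1:3]))
  expect_equal(ps$heavy_atoms[5], sum(res$n_heavy_atoms[3:7]))
})
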