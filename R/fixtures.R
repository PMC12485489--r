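# Synthetic structure generator. Each kind emulates one conformational
# regime the classifier distinguishes: packed helix bundles, isolated
# (unpacked) helices and strands, polyproline-II ribbons, and barbed-wire
# coils with high-psi dihedrals, twisted/cis peptide bonds and systematically
# compressed C-N-CA angles. Deterministic under a seed.

with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  fn()
}

align_axis_z <- function(structure) {
  ca <- as.matrix(structure[structure$atom == "CA", c("x", "y", "z")])
  ctr <- colMeans(ca)
  v <- svd(sweep(ca, 2, ctr))$v[, 1]
  if (v[3] < 0) v <- -v
  axis <- c(v[2], -v[1], 0)                    # rotate v onto +z
  ang <- acos(min(1, max(-1, v[3]))) * 180 / pi
  R <- if (sqrt(sum(axis^2)) < 1e-9) diag(3) else rotation_about(axis, ang)
  transform_structure(structure, R, t = -as.numeric(R %*% ctr))
}

ideal_spec <- function(n, resname, phi, psi, omega = 180) {
  tibble::tibble(resname = resname, phi = phi, psi = psi, omega = omega,
                 .rows = n)
}

#' Generate a synthetic test structure
#'
#' @param kind One of `"helix_bundle"` (two antiparallel ideal helices,
#'   chains A and B, in tertiary contact), `"lone_helix"` (a single packed-
#'   geometry helix with no contact partner), `"lone_strand"` (an isolated
#'   unpaired extended strand), `"ppii"` (a polyproline-II ribbon at
#'   phi = -75, psi = +150), `"barbed_coil"` (random dihedrals in the
#'   high-psi / upper-right Ramachandran band with twisted and cis-nonPro
#'   peptide bonds and compressed C-N-CA angles injected at the distortion
#'   rates), or `"mixed"` (helix, PPII and barbed-coil segments concatenated
#'   on one chain across chain breaks).
#' @param length Residues per element (per helix for `helix_bundle`;
#'   per segment for `mixed`).
#' @param plddt Constant or per-residue pLDDT profile. Ignored by `"mixed"`,
#'   which uses a fixed per-segment profile (helix 85, PPII 40, coil 30).
#' @param seed Integer seed; identical spec and seed give identical output.
#' @param separation Axis separation of the bundle helices, Angstrom.
#' @param frac_omega Fraction of barbed-coil peptide bonds set to a twisted
#'   (omega = +/-130) or cis-nonPro (omega = +8) conformation.
#' @param frac_cnca Fraction of barbed-coil peptide bonds whose C-N-CA angle
#'   is compressed to 4.5 sigma below ideal.
#' @param overrides Optional extra (site, parameter, value) distortions
#'   passed to [build_backbone()] (single-chain kinds only).
#' @return A `bw_structure`.
#' @export
#' @examples
#' s <- make_fixture("barbed_coil", length = 20, plddt = 30, seed = 7)
#' bw_analyze(s)
make_fixture <- function(kind = c("helix_bundle", "lone_helix", "lone_strand",
                                  "ppii", "barbed_coil", "mixed"),
                         length = 12, plddt = 50, seed = 1,
                         separation = 6.2, frac_omega = 0.25,
                         frac_cnca = 0.25, overrides = NULL) {
  kind <- match.arg(kind)
  stopifnot(length >= 3)
  switch(kind,
    helix_bundle = fixture_helix_bundle(length, plddt, separation),
    lone_helix = align_axis_z(
      build_backbone(ideal_spec(length, "ALA", -57, -47), plddt,
                     overrides = overrides)),
    lone_strand = build_backbone(ideal_spec(length, "ALA", -120, 130), plddt,
                                 overrides = overrides),
    ppii = build_backbone(ideal_spec(length, "PRO", -75, 150), plddt,
                          overrides = overrides),
    barbed_coil = fixture_barbed_coil(length, plddt, seed, frac_omega,
                                      frac_cnca, overrides),
    mixed = fixture_mixed(length, plddt, seed, frac_omega, frac_cnca))
}

fixture_helix_bundle <- function(length, plddt, separation, phase = 30) {
  h1 <- align_axis_z(build_backbone(ideal_spec(length, "ALA", -57, -47),
                                    plddt, chain = "A"))
  h2 <- align_axis_z(build_backbone(ideal_spec(length, "ALA", -57, -47),
                                    plddt, chain = "B"))
  # interdigitate the interface, then flip antiparallel and translate
  h2 <- transform_structure(h2, rotation_about(c(0, 0, 1), phase))
  h2 <- transform_structure(h2, rotation_about(c(1, 0, 0), 180),
                            t = c(separation, 0, 0))
  new_bw_structure(dplyr::bind_rows(h1, h2), title = "helix bundle fixture")
}

fixture_barbed_coil <- function(length, plddt, seed, frac_omega, frac_cnca,
                                extra_overrides = NULL) {
  with_seed(seed, function() {
    n <- length
    # A slowly varying dihedral base produces the wide, rigid looping coils
    # characteristic of the mode; an independent per-residue draw collapses
    # into a compact self-packing tangle instead. Candidate coils (with the
    # omega and C-N-CA distortions already applied) whose chain still curls
    # back on itself -- any nonlocal CA pair closer than 8.5 A -- are
    # redrawn, keeping the generated regime unpacked by construction.
    tg <- targets_vec(load_geometry_targets())
    bonds <- seq(2, n)
    draw <- function() {
      phi0 <- stats::runif(1, -7, 162)
      psi0 <- stats::runif(1, 68, 162)
      spec <- tibble::tibble(
        resname = "ALA",
        phi = pmin(pmax(phi0 + stats::runif(n, -8, 8), -15), 170),
        psi = pmin(pmax(psi0 + stats::runif(n, -8, 8), 60), 170),
        omega = 180)
      n_om <- max(1L, round(frac_omega * base::length(bonds)))
      om_sites <- sample(bonds, min(n_om, base::length(bonds)))
      half <- seq_len(ceiling(base::length(om_sites) / 2))
      spec$omega[om_sites[half]] <-
        130 * sample(c(-1, 1), base::length(half), replace = TRUE)
      if (base::length(om_sites) > base::length(half)) {
        spec$omega[om_sites[-half]] <- 8      # cis on non-Pro residues
      }
      n_cn <- max(1L, round(frac_cnca * base::length(bonds)))
      cn_sites <- sample(bonds, min(n_cn, base::length(bonds)))
      ov <- tibble::tibble(site = cn_sites, parameter = "C-N-CA",
                           value = tg[["C-N-CA"]]$ideal -
                             4.5 * tg[["C-N-CA"]]$sigma)
      if (!is.null(extra_overrides)) {
        ov <- dplyr::bind_rows(ov, extra_overrides)
      }
      list(spec = spec, ov = ov)
    }
    nonlocal_min_ca <- function(cand) {
      s <- build_backbone(cand$spec, 50, overrides = cand$ov)
      ca <- as.matrix(s[s$atom == "CA", c("x", "y", "z")])
      d <- as.matrix(stats::dist(ca))
      sep <- abs(row(d) - col(d))
      if (!any(sep > 4)) Inf else min(d[sep > 4])
    }
    cand <- draw()
    best <- nonlocal_min_ca(cand)
    tries <- 1L
    while (best < 8.5 && tries < 400L) {
      nxt <- draw()
      dmin <- nonlocal_min_ca(nxt)
      if (dmin > best) { cand <- nxt; best <- dmin }
      tries <- tries + 1L
    }
    build_backbone(cand$spec, plddt, overrides = cand$ov)
  })
}

fixture_mixed <- function(length, plddt, seed, frac_omega, frac_cnca) {
  helix <- align_axis_z(build_backbone(ideal_spec(length, "ALA", -57, -47),
                                       85))
  ppii <- build_backbone(ideal_spec(length, "PRO", -75, 150), 40,
                         start_resno = length + 1L)
  coil <- fixture_barbed_coil(length, 30, seed, frac_omega, frac_cnca)
  coil$resno <- coil$resno + 2L * length
  ppii <- transform_structure(ppii, t = c(60, 0, 0))
  coil <- transform_structure(coil, t = c(120, 0, 0))
  new_bw_structure(dplyr::bind_rows(helix, ppii, coil),
                   title = "mixed fixture")
}
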