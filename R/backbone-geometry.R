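# Backbone internal coordinates: phi/psi/omega, covalent-geometry z-scores,
# CA virtual geometry, chain breaks, and the inverse (internal -> Cartesian)
# builder used by the fixture generator.
#
# Conventions: omega of residue i is the CA(i-1)-C(i-1)-N(i)-CA(i) dihedral,
# i.e. the peptide bond PRECEDING residue i; the inter-residue covalent terms
# (C-N, CA-C-N, C-N-CA) of that bond are likewise reported on residue i.

wrap180 <- function(x) {
  out <- x - 360 * round(x / 360)
  out[!is.na(out) & out <= -180] <- out[!is.na(out) & out <= -180] + 360
  out
}

vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

vnorm <- function(a) sqrt(rowSums(a * a))

as_pts <- function(p) {
  if (is.null(dim(p))) matrix(p, ncol = 3, byrow = FALSE) else as.matrix(p)
}

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention; the result lies in (-180, 180]. Vectorized: each
#' argument may be a single 3-vector or an n-by-3 matrix.
#'
#' @param p1,p2,p3,p4 3-vectors or n-by-3 coordinate matrices (Angstrom).
#' @return Dihedral(s) in degrees; `NA` where points are coincident or
#'   collinear.
#' @export
#' @examples
#' compute_dihedral(c(1, 1, 0), c(0, 0, 0), c(0, 0, 1), c(1, -1, 1))
compute_dihedral <- function(p1, p2, p3, p4) {
  p1 <- as_pts(p1); p2 <- as_pts(p2); p3 <- as_pts(p3); p4 <- as_pts(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  b2n <- vnorm(b2)
  x <- rowSums(n1 * n2)
  y <- rowSums(vcross(n1, n2) * b2) / b2n
  ang <- atan2(y, x) * 180 / pi
  bad <- !is.finite(ang) | vnorm(n1) < 1e-9 | vnorm(n2) < 1e-9 | b2n < 1e-9
  ang[bad] <- NA_real_
  # atan2 returns -180 for the planar-trans case; map to +180
  ang[!is.na(ang) & ang <= -180 + 1e-12] <- 180
  ang
}

#' Bond angle of three points, degrees
#' @param p1,p2,p3 3-vectors or n-by-3 matrices; the angle is at `p2`.
#' @return Angle(s) in degrees, `NA` for degenerate input.
#' @export
compute_angle <- function(p1, p2, p3) {
  p1 <- as_pts(p1); p2 <- as_pts(p2); p3 <- as_pts(p3)
  u <- p1 - p2; v <- p3 - p2
  cu <- vnorm(u); cv <- vnorm(v)
  cosang <- rowSums(u * v) / (cu * cv)
  out <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  out[cu < 1e-9 | cv < 1e-9] <- NA_real_
  out
}

targets_vec <- function(targets) {
  stats::setNames(Map(function(i, s) list(ideal = i, sigma = s),
                      targets$ideal, targets$sigma),
                  targets$name)
}

# matrix of one named backbone atom per residue, NA rows where missing
atom_matrix <- function(structure, res_key, atom_name) {
  sel <- structure[structure$atom == atom_name & !structure$is_hydrogen, ]
  idx <- match(res_key, paste(sel$chain, sel$resno, sel$icode))
  cbind(sel$x[idx], sel$y[idx], sel$z[idx])
}

#' Backbone geometry analysis
#'
#' Computes, for every residue, the phi/psi/omega dihedrals, z-scores of the
#' seven backbone covalent terms against the geometry targets, CA virtual
#' geometry (the CA(i-1)-CA(i)-CA(i+1) pseudo-angle and the incoming/outgoing
#' four-CA pseudo-dihedrals), and chain-break flags. A break is declared
#' between consecutive residues when the C(i-1)-N(i) distance exceeds
#' `chain_break_cn` or either atom is missing; no dihedral or z-score spans a
#' break. Missing atoms yield `NA` fields, never errors.
#'
#' @param structure A `bw_structure`.
#' @param targets Geometry-target tibble from [load_geometry_targets()].
#' @param chain_break_cn Chain-break cutoff on the C-N distance (Angstrom).
#' @return A tibble, one row per residue in structure order: residue keys,
#'   `phi`, `psi`, `omega`, z-score columns (`z_n_ca`, `z_ca_c`, `z_n_ca_c`,
#'   `z_ca_c_o` for intra-residue terms; `z_c_n`, `z_ca_c_n`, `z_c_n_ca` for
#'   the peptide bond preceding the residue), `ca_angle`, `mu_in`, `mu_out`,
#'   `chain_break_before`, `chain_break_after`.
#' @export
analyze_backbone <- function(structure, targets = load_geometry_targets(),
                             chain_break_cn = 2.5) {
  res <- bw_residues(structure)
  key <- paste(res$chain, res$resno, res$icode)
  N  <- atom_matrix(structure, key, "N")
  CA <- atom_matrix(structure, key, "CA")
  C  <- atom_matrix(structure, key, "C")
  O  <- atom_matrix(structure, key, "O")
  n <- nrow(res)
  tg <- targets_vec(targets)
  z <- function(obs, name) (obs - tg[[name]]$ideal) / tg[[name]]$sigma

  lagm <- function(m, k = 1) {
    if (abs(k) >= n) return(matrix(NA_real_, n, 3))
    if (k >= 0) rbind(matrix(NA_real_, k, 3), m[seq_len(n - k), , drop = FALSE])
    else rbind(m[(1 - k):n, , drop = FALSE], matrix(NA_real_, -k, 3))
  }
  same_chain_prev <- c(FALSE, res$chain[-1] == res$chain[-n])

  Cp <- lagm(C); Np <- lagm(N); CAp <- lagm(CA)
  Nn <- lagm(N, -1)

  d_cn_prev <- vnorm(N - Cp)            # C(i-1)-N(i)
  link_prev <- same_chain_prev & !is.na(d_cn_prev) & d_cn_prev <= chain_break_cn
  break_before <- same_chain_prev & !link_prev
  link_next <- c(link_prev[-1], FALSE)
  break_after <- c(break_before[-1], FALSE)

  phi <- compute_dihedral(Cp, N, CA, C);  phi[!link_prev] <- NA_real_
  omega <- compute_dihedral(CAp, Cp, N, CA); omega[!link_prev] <- NA_real_
  psi <- compute_dihedral(N, CA, C, Nn);  psi[!link_next] <- NA_real_

  out <- tibble::tibble(
    chain = res$chain, resno = res$resno, icode = res$icode,
    resname = res$resname, plddt = res$plddt,
    phi = phi, psi = psi, omega = omega,
    z_n_ca   = z(vnorm(CA - N), "N-CA"),
    z_ca_c   = z(vnorm(C - CA), "CA-C"),
    z_n_ca_c = z(compute_angle(N, CA, C), "N-CA-C"),
    z_ca_c_o = z(compute_angle(CA, C, O), "CA-C-O"),
    z_c_n    = ifelse(link_prev, z(d_cn_prev, "C-N"), NA_real_),
    z_ca_c_n = ifelse(link_prev, z(compute_angle(CAp, Cp, N), "CA-C-N"), NA_real_),
    z_c_n_ca = ifelse(link_prev, z(compute_angle(Cp, N, CA), "C-N-CA"), NA_real_),
    chain_break_before = break_before,
    chain_break_after = break_after)

  # CA virtual geometry, defined only over break-free stretches
  CAp2 <- lagm(CA, 2); CAn <- lagm(CA, -1); CAn2 <- lagm(CA, -2)
  ok1 <- link_prev & link_next                       # i-1, i, i+1 connected
  ok_in <- link_prev & link_next & c(FALSE, link_prev[-n])   # i-2..i+1
  ok_out <- link_prev & link_next & c(link_next[-1], FALSE)  # i-1..i+2
  ca_angle <- compute_angle(CAp, CA, CAn); ca_angle[!ok1] <- NA_real_
  mu_in <- compute_dihedral(CAp2, CAp, CA, CAn); mu_in[!ok_in] <- NA_real_
  mu_out <- compute_dihedral(CAp, CA, CAn, CAn2); mu_out[!ok_out] <- NA_real_
  out$ca_angle <- ca_angle
  out$mu_in <- mu_in
  out$mu_out <- mu_out
  out
}

# --- internal-coordinate builder (NeRF placement) ---------------------------

place_atom <- function(A, B, C, r, theta, chi) {
  # place D with |C-D| = r, angle(B,C,D) = theta, dihedral(A,B,C,D) = chi
  th <- theta * pi / 180; ch <- chi * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- r * c(-cos(th), sin(th) * cos(ch), sin(th) * sin(ch))
  C + d[1] * bc + d[2] * m + d[3] * n
}

builder_param <- function(overrides, i, name, default) {
  if (is.null(overrides)) return(default)
  hit <- overrides$site == i & overrides$parameter == name
  if (any(hit)) overrides$value[which(hit)[1]] else default
}

#' Build a polypeptide backbone from internal coordinates
#'
#' Sequentially places N/CA/C/O (plus CB for non-glycine) atoms from a table
#' of per-residue dihedrals using the ideal geometry targets, with optional
#' per-site overrides of any named bond length or angle. The inverse of
#' [analyze_backbone()]: re-analysis of the built structure recovers every
#' specified dihedral and override to numerical precision.
#'
#' @param spec A data frame with one row per residue and columns `resname`
#'   (3-letter code), `phi`, `psi`, `omega` (degrees; `omega` of row i is the
#'   peptide bond preceding residue i, ignored on the first row; `phi` of the
#'   first row and `psi` of the last row only orient terminal atoms).
#' @param plddt Per-residue pLDDT values, recycled to the spec length.
#' @param overrides Optional data frame with columns `site` (residue index),
#'   `parameter` (a geometry-target name, e.g. `"C-N-CA"`; inter-residue
#'   terms refer to the bond preceding the site) and `value`.
#' @param chain Chain identifier for the built chain.
#' @param start_resno First residue number.
#' @param targets Geometry targets, as in [analyze_backbone()].
#' @return A `bw_structure` tibble.
#' @export
#' @examples
#' helix <- tibble::tibble(resname = "ALA", phi = -57, psi = -47, omega = 180,
#'                         .rows = 8)
#' s <- build_backbone(helix, plddt = 90)
#' analyze_backbone(s)$phi[2:7]
build_backbone <- function(spec, plddt = 50, overrides = NULL, chain = "A",
                           start_resno = 1L,
                           targets = load_geometry_targets()) {
  spec <- as.data.frame(spec)
  stopifnot(nrow(spec) >= 1, all(c("resname", "phi", "psi") %in% names(spec)))
  if (is.null(spec$omega)) spec$omega <- 180
  n <- nrow(spec)
  plddt <- rep_len(plddt, n)
  tg <- targets_vec(targets)
  id <- function(nm) tg[[nm]]$ideal
  if (!is.null(overrides)) {
    overrides <- as.data.frame(overrides)
    stopifnot(all(c("site", "parameter", "value") %in% names(overrides)),
              all(overrides$parameter %in% names(tg)),
              all(overrides$site >= 1 & overrides$site <= n))
    lens <- overrides$parameter %in% c("N-CA", "CA-C", "C-N", "C-O")
    if (any(lens & overrides$value <= 0)) {
      stop("bond-length override must be positive")
    }
  }
  ov <- function(i, nm) builder_param(overrides, i, nm, id(nm))

  pos <- vector("list", n)
  for (i in seq_len(n)) {
    p <- list()
    if (i == 1) {
      p$N <- c(0, 0, 0)
      p$CA <- c(ov(1, "N-CA"), 0, 0)
      th <- ov(1, "N-CA-C") * pi / 180
      p$C <- p$CA + ov(1, "CA-C") * c(-cos(th), sin(th), 0)
    } else {
      q <- pos[[i - 1]]
      p$N  <- place_atom(q$N, q$CA, q$C, ov(i, "C-N"), ov(i, "CA-C-N"),
                         spec$psi[i - 1])
      p$CA <- place_atom(q$CA, q$C, p$N, ov(i, "N-CA"), ov(i, "C-N-CA"),
                         spec$omega[i])
      p$C  <- place_atom(q$C, p$N, p$CA, ov(i, "CA-C"), ov(i, "N-CA-C"),
                         spec$phi[i])
    }
    psi_i <- if (is.na(spec$psi[i])) 180 else spec$psi[i]
    p$O <- place_atom(p$N, p$CA, p$C, ov(i, "C-O"), ov(i, "CA-C-O"),
                      wrap180(psi_i + 180))
    if (spec$resname[i] != "GLY") {
      b <- p$CA - p$N; cc <- p$C - p$CA
      a <- c(b[2] * cc[3] - b[3] * cc[2],
             b[3] * cc[1] - b[1] * cc[3],
             b[1] * cc[2] - b[2] * cc[1])
      p$CB <- -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + p$CA
    }
    pos[[i]] <- p
  }

  rows <- purrr::imap_dfr(pos, function(p, i) {
    nm <- names(p)
    tibble::tibble(chain = chain, resno = start_resno + i - 1L, icode = "",
                   resname = spec$resname[i], atom = nm,
                   element = substr(nm, 1, 1), is_hydrogen = FALSE,
                   x = unname(purrr::map_dbl(p, 1)),
                   y = unname(purrr::map_dbl(p, 2)),
                   z = unname(purrr::map_dbl(p, 3)),
                   b = plddt[i], plddt = plddt[i])
  })
  new_bw_structure(rows, source_format = "pdb", title = "built backbone")
}

# rigid-motion helpers shared by the fixture generator
transform_structure <- function(structure, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(structure[, c("x", "y", "z")]) %*% t(R)
  structure$x <- xyz[, 1] + t[1]
  structure$y <- xyz[, 2] + t[2]
  structure$z <- xyz[, 3] + t[3]
  structure
}

rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2)); a <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}
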