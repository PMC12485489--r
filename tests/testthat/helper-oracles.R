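# Independent reference implementations used to cross-check the package's
# optimized code paths.

# Naive all-pairs contact enumeration: every unordered heavy-atom pair is
# tested directly against the gap cutoff and the exclusion rules.
oracle_contacts <- function(structure, ss = NULL, radii = load_vdw_radii(),
                            gap_max = 0.5, min_seq_sep = 4) {
  heavy <- which(!structure$is_hydrogen)
  at <- structure[heavy, ]
  res <- bw_residues(structure)
  res_key <- paste(res$chain, res$resno, res$icode)
  res_idx <- match(paste(at$chain, at$resno, at$icode), res_key)
  chain_pos <- stats::ave(seq_len(nrow(res)), res$chain, FUN = seq_along)
  elem <- if (is.null(ss)) rep(NA_integer_, nrow(res)) else
    ss$ss_element[match(res_key, paste(ss$chain, ss$resno, ss$icode))]
  rad <- barbedwire:::atom_radius(at$atom, at$element, radii)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  out <- list()
  n <- nrow(at)
  for (a in seq_len(n - 1)) {
    for (b in seq((a + 1), n)) {
      ra <- res_idx[a]; rb <- res_idx[b]
      if (ra == rb) next
      if (res$chain[ra] == res$chain[rb] &&
          abs(chain_pos[ra] - chain_pos[rb]) <= min_seq_sep) next
      if (!is.na(elem[ra]) && !is.na(elem[rb]) && elem[ra] == elem[rb]) next
      gap <- sqrt(sum((xyz[a, ] - xyz[b, ])^2)) - (rad[a] + rad[b])
      if (gap <= gap_max) {
        out[[length(out) + 1]] <- c(heavy[a], heavy[b])
      }
    }
  }
  if (length(out) == 0) return(matrix(integer(0), ncol = 2))
  do.call(rbind, out)
}

# Brute-force two-pass smoothing by explicit position scanning, written
# without run-length encoding.
oracle_smooth <- function(modes) {
  one_pass <- function(m, target, flanks, to_flank) {
    out <- m
    n <- length(m)
    i <- 1
    while (i <= n) {
      j <- i
      while (j <= n && m[j] == m[i]) j <- j + 1
      len <- j - i
      if (m[i] == target && len <= 2 && i > 1 && j <= n &&
          m[i - 1] == m[j] && m[i - 1] %in% flanks) {
        out[i:(j - 1)] <- if (to_flank) m[i - 1] else "pseudostructure"
      }
      i <- j
    }
    out
  }
  m1 <- one_pass(modes, "pseudostructure",
                 c("barbed_wire", "near_predictive"), TRUE)
  one_pass(m1, "barbed_wire", "pseudostructure", FALSE)
}

# Tolerant angular comparison (wrap at +/-180).
expect_angle_equal <- function(actual, expected, tol = 1e-6) {
  d <- (actual - expected) %% 360
  d <- pmin(d, 360 - d)
  expect_true(all(is.na(d) == (is.na(actual) | is.na(expected))))
  expect_lt(max(d, na.rm = TRUE), tol)
}

# Minimal hand-rolled PDB text for io tests (independent of the writer).
pdb_text_3res <- function(b = c(90, 45, 30)) {
  fmt <- paste0("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                "           %s")
  atoms <- list(
    list("N", "N", 0.0, 0.0, 0.0), list("CA", "C", 1.46, 0.0, 0.0),
    list("C", "C", 2.0, 1.4, 0.0), list("O", "O", 1.4, 2.4, 0.2))
  lines <- character(0)
  k <- 0
  for (i in 1:3) {
    for (a in atoms) {
      k <- k + 1
      lines <- c(lines, sprintf(fmt, k, a[[1]], "ALA", "A", i,
                                a[[3]] + 4 * (i - 1), a[[4]], a[[5]],
                                1.00, b[i], a[[2]]))
    }
  }
  c(lines, "END")
}

# The same three-residue content as a minimal mmCIF atom_site loop.
cif_text_3res <- function(b = c(90, 45, 30)) {
  head <- c("data_fixture",
            "loop_",
            "_atom_site.group_PDB", "_atom_site.id",
            "_atom_site.type_symbol", "_atom_site.label_atom_id",
            "_atom_site.label_alt_id", "_atom_site.label_comp_id",
            "_atom_site.label_asym_id", "_atom_site.label_entity_id",
            "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
            "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
            "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
            "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
            "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
            "_atom_site.pdbx_PDB_model_num")
  atoms <- list(
    list("N", "N", 0.0, 0.0, 0.0), list("CA", "C", 1.46, 0.0, 0.0),
    list("C", "C", 2.0, 1.4, 0.0), list("O", "O", 1.4, 2.4, 0.2))
  rows <- character(0)
  k <- 0
  for (i in 1:3) {
    for (a in atoms) {
      k <- k + 1
      rows <- c(rows, sprintf(
        "ATOM %d %s %s . ALA A 1 %d ? %.3f %.3f %.3f 1.00 %.2f %d ALA A %s 1",
        k, a[[2]], a[[1]], i, a[[3]] + 4 * (i - 1), a[[4]], a[[5]], b[i],
        i, a[[1]]))
    }
  }
  c(head, rows)
}

# Shared synthetic flag/residue tables for classifier tests.
B <- "barbed_wire"; P <- "pseudostructure"; N <- "near_predictive"

flags_row <- function(n = 1, ...) {
  base <- tibble::tibble(
    chain = "A", chain_break_before = FALSE,
    rama_upper_right = FALSE, ca_geom_outlier = FALSE,
    cnca_outlier = FALSE, omega_state = "trans",
    bond_geom_outlier = FALSE, high_psi_band = FALSE, rama_outlier = FALSE,
    .rows = n)
  over <- list(...)
  for (k in names(over)) base[[k]] <- over[[k]]
  base
}

fake_residues <- function(modes, plddt = 30, chain = "A") {
  tibble::tibble(chain = chain, resno = seq_along(modes), icode = "",
                 mode_raw = modes, plddt = plddt)
}
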