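# Steric-contact enumeration and the per-residue packing score. Contacts are
# heavy-atom pairs whose van der Waals surfaces approach within a gap cutoff,
# after excluding sequence-local pairs and pairs internal to one
# secondary-structure element, so that only tertiary packing is counted.

atom_radius <- function(atom, element, radii) {
  cls <- ifelse(element == "C" & atom != "C", "CH",
         ifelse(element == "N" & atom != "N", "NH", element))
  r <- unname(radii[cls])
  r[is.na(r)] <- unname(radii[element[is.na(r)]])
  r[is.na(r)] <- unname(radii["*"])
  r
}

#' Enumerate tertiary steric contacts
#'
#' Finds all unordered pairs of non-hydrogen atoms whose van der Waals gap
#' (center distance minus summed radii) is at most `gap_max`, using a
#' cell-list spatial index. Pairs are excluded when both residues belong to
#' the same secondary-structure element, or when they sit on the same chain
#' within `min_seq_sep` residues of one another (ordinal position in the
#' chain). Inter-chain pairs are always eligible.
#'
#' @param structure A `bw_structure`.
#' @param ss Output of [assign_ss()] (per-residue `ss` and `ss_element`);
#'   `NULL` treats every residue as coil with no element exclusions.
#' @param radii Named radius vector from [load_vdw_radii()].
#' @param gap_max Maximum van der Waals surface separation (Angstrom).
#' @param min_seq_sep Same-chain pairs with ordinal separation at or below
#'   this value are omitted.
#' @return A tibble of contacts, one row per unordered atom pair: atom row
#'   indices `i`, `j` into `structure`, residue keys of both partners, the
#'   ordinal residue indices `res_i`, `res_j` (into [bw_residues()] order)
#'   and the `gap` in Angstrom.
#' @export
enumerate_contacts <- function(structure, ss = NULL,
                               radii = load_vdw_radii(),
                               gap_max = 0.5, min_seq_sep = 4) {
  heavy <- which(!structure$is_hydrogen)
  at <- structure[heavy, ]
  res <- bw_residues(structure)
  res_key <- paste(res$chain, res$resno, res$icode)
  res_idx <- match(paste(at$chain, at$resno, at$icode), res_key)
  # ordinal position within the chain, for the sequence-separation rule
  chain_pos <- stats::ave(seq_len(nrow(res)), res$chain, FUN = seq_along)
  elem <- if (is.null(ss)) rep(NA_integer_, nrow(res)) else
    ss$ss_element[match(res_key, paste(ss$chain, ss$resno, ss$icode))]

  rad <- atom_radius(at$atom, at$element, radii)
  dmax <- 2 * max(rad) + gap_max
  xyz <- as.matrix(at[, c("x", "y", "z")])
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / dmax)
  cell_id <- paste(cell[, 1], cell[, 2], cell[, 3])
  by_cell <- split(seq_len(nrow(at)), cell_id)
  cell_key <- do.call(rbind, strsplit(names(by_cell), " "))
  storage.mode(cell_key) <- "integer"

  pairs_i <- integer(0); pairs_j <- integer(0)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  lookup <- stats::setNames(seq_along(by_cell), names(by_cell))
  for (ci in seq_along(by_cell)) {
    a <- by_cell[[ci]]
    for (k in seq_len(nrow(offs))) {
      nb <- paste(cell_key[ci, 1] + offs[k, 1], cell_key[ci, 2] + offs[k, 2],
                  cell_key[ci, 3] + offs[k, 3])
      cj <- lookup[nb]
      if (is.na(cj) || cj < ci) next
      b <- by_cell[[cj]]
      if (cj == ci) {
        if (length(a) < 2) next
        cand <- t(utils::combn(a, 2))
      } else {
        cand <- cbind(rep(a, each = length(b)), rep(b, length(a)))
      }
      pairs_i <- c(pairs_i, cand[, 1]); pairs_j <- c(pairs_j, cand[, 2])
    }
  }
  if (length(pairs_i) == 0) return(empty_contacts())
  swap <- pairs_i > pairs_j
  tmp <- pairs_i[swap]; pairs_i[swap] <- pairs_j[swap]; pairs_j[swap] <- tmp

  keep_pairs(at, heavy, xyz, rad, res_idx, chain_pos, elem,
             pairs_i, pairs_j, gap_max, min_seq_sep, res)
}

empty_contacts <- function() {
  tibble::tibble(i = integer(), j = integer(),
                 chain_i = character(), resno_i = integer(),
                 chain_j = character(), resno_j = integer(),
                 res_i = integer(), res_j = integer(), gap = numeric())
}

keep_pairs <- function(at, heavy, xyz, rad, res_idx, chain_pos, elem,
                       pairs_i, pairs_j, gap_max, min_seq_sep, res) {
  gap <- sqrt(rowSums((xyz[pairs_i, , drop = FALSE] -
                         xyz[pairs_j, , drop = FALSE])^2)) -
    (rad[pairs_i] + rad[pairs_j])
  ri <- res_idx[pairs_i]; rj <- res_idx[pairs_j]
  same_chain <- res$chain[ri] == res$chain[rj]
  seq_sep <- abs(chain_pos[ri] - chain_pos[rj])
  same_elem <- !is.na(elem[ri]) & !is.na(elem[rj]) & elem[ri] == elem[rj]
  ok <- gap <= gap_max & ri != rj &
    !(same_chain & seq_sep <= min_seq_sep) & !same_elem
  ok[is.na(ok)] <- FALSE
  out <- tibble::tibble(
    i = heavy[pairs_i[ok]], j = heavy[pairs_j[ok]],
    chain_i = res$chain[ri[ok]], resno_i = res$resno[ri[ok]],
    chain_j = res$chain[rj[ok]], resno_j = res$resno[rj[ok]],
    res_i = ri[ok], res_j = rj[ok], gap = gap[ok])
  dplyr::distinct(out, .data$i, .data$j, .keep_all = TRUE) |>
    dplyr::arrange(.data$i, .data$j)
}

#' Per-residue packing score
#'
#' For each residue, counts the enumerated contacts touching any residue of
#' the five-residue window i-2..i+2 (truncated at chain termini and breaks),
#' divides by the number of non-hydrogen atoms in the same window, and calls
#' the residue packed when the score exceeds the secondary-structure-dependent
#' cutoff: `cutoff_strand` for strand residues, `cutoff_helix_coil`
#' otherwise.
#'
#' @param structure A `bw_structure`.
#' @param contacts Output of [enumerate_contacts()].
#' @param ss Output of [assign_ss()].
#' @param config A [bw_config()].
#' @return A tibble, one row per residue: residue keys, `ss`,
#'   `contact_count`, `heavy_atoms`, `score`, `packed`.
#' @export
packing_score <- function(structure, contacts, ss, config = bw_config()) {
  res <- bw_residues(structure)
  n <- nrow(res)
  res_key <- paste(res$chain, res$resno, res$icode)
  ss_ord <- ss[match(res_key, paste(ss$chain, ss$resno, ss$icode)), ]
  # break-free segment id per residue
  seg <- cumsum(c(TRUE, ss_ord$chain[-1] != ss_ord$chain[-n] |
                    ss_ord$chain_break_before[-1]))
  w <- config$window_halfwidth
  incident <- vector("list", n)
  if (nrow(contacts) > 0) {
    for (k in seq_len(nrow(contacts))) {
      a <- contacts$res_i[k]; b <- contacts$res_j[k]
      incident[[a]] <- c(incident[[a]], k)
      if (b != a) incident[[b]] <- c(incident[[b]], k)
    }
  }
  count <- integer(n); heavy <- integer(n)
  for (i in seq_len(n)) {
    win <- seq(max(1, i - w), min(n, i + w))
    win <- win[seg[win] == seg[i]]
    count[i] <- length(unique(unlist(incident[win])))
    heavy[i] <- sum(res$n_heavy_atoms[win])
  }
  score <- count / heavy
  cutoff <- ifelse(ss_ord$ss == "E", config$cutoff_strand,
                   config$cutoff_helix_coil)
  tibble::tibble(chain = res$chain, resno = res$resno, icode = res$icode,
                 resname = res$resname, ss = ss_ord$ss,
                 contact_count = count, heavy_atoms = heavy,
                 score = score, packed = score > cutoff)
}
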