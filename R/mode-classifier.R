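# The six-mode decision tree: residues branch first on pLDDT, then on
# packing, then on validation outliers (signature or high-density), followed
# by two smoothing passes that absorb isolated one- or two-residue islands.

#' Signature barbed-wire outliers
#'
#' A residue carries a signature outlier when any of the following hold:
#' it is a Ramachandran outlier in the upper-right box; it is a CA-geometry
#' outlier in a low-pLDDT unpacked context (the same outlier is permitted in
#' predictive regions); it shares a peptide bond carrying a C-N-CA angle
#' outlier, a cis-nonPro, or any twisted omega (both residues of such a bond
#' are marked); or it is a cis-Pro in a low-pLDDT unpacked context.
#'
#' @param flags Per-residue tibble carrying `rama_upper_right`,
#'   `ca_geom_outlier`, `cnca_outlier`, `omega_state`, `chain`,
#'   `chain_break_before`.
#' @param low_plddt,packed Logical vectors over the same residues.
#' @return Logical vector of signature calls.
#' @export
signature_outlier <- function(flags, low_plddt, packed) {
  n <- nrow(flags)
  bad_bond <- flags$cnca_outlier |
    flags$omega_state %in% c("cis_nonpro", "twisted")
  # the bond stored on residue i+1 also marks residue i when the bond exists
  has_next_bond <- c(flags$chain[-1] == flags$chain[-n] &
                       !flags$chain_break_before[-1], FALSE)
  bad_bond_after <- has_next_bond & c(bad_bond[-1], FALSE)
  flags$rama_upper_right |
    (flags$ca_geom_outlier & low_plddt & !packed) |
    bad_bond | bad_bond_after |
    (flags$omega_state == "cis_pro" & low_plddt & !packed)
}

#' High outlier density over a three-residue window
#'
#' True when at least two of four criteria hold for the window i-1..i+1
#' (truncated to the residues available at termini and chain breaks):
#' (1) two or more residues with cis-nonPro or twisted bonds; (2) two or more
#' CA-geometry outliers; (3) two or more covalent-geometry outliers; (4) all
#' available residues in the high-psi band and at least one Ramachandran
#' outlier.
#'
#' @param flags Tibble with `omega_state`, `ca_geom_outlier`,
#'   `bond_geom_outlier`, `high_psi_band`, `rama_outlier`, `chain`,
#'   `chain_break_before`.
#' @return Logical vector of high-density calls.
#' @export
high_outlier_density <- function(flags) {
  n <- nrow(flags)
  seg <- cumsum(c(TRUE, flags$chain[-1] != flags$chain[-n] |
                    flags$chain_break_before[-1]))
  bad_omega <- flags$omega_state %in% c("cis_nonpro", "twisted")
  out <- logical(n)
  for (i in seq_len(n)) {
    win <- seq(max(1, i - 1), min(n, i + 1))
    win <- win[seg[win] == seg[i]]
    crit <- c(sum(bad_omega[win]) >= 2,
              sum(flags$ca_geom_outlier[win]) >= 2,
              sum(flags$bond_geom_outlier[win]) >= 2,
              all(flags$high_psi_band[win]) && any(flags$rama_outlier[win]))
    out[i] <- sum(crit) >= 2
  }
  out
}

#' Raw mode assignment
#'
#' The decision tree: high-pLDDT residues are `predictive` when packed, else
#' `unpacked_high_plddt`; low-pLDDT packed residues are `unphysical` when a
#' signature or high-density outlier is present, else `near_predictive`;
#' low-pLDDT unpacked residues are `barbed_wire` with outliers, else
#' `pseudostructure`.
#'
#' @param plddt Numeric pLDDT values.
#' @param packed,signature,density Logical vectors.
#' @param plddt_cutoff High-confidence boundary, inclusive (default 70).
#' @return Character vector over [bw_modes()].
#' @export
#' @examples
#' assign_mode(c(90, 90, 30, 30), packed = c(TRUE, FALSE, FALSE, TRUE),
#'             signature = c(FALSE, FALSE, TRUE, TRUE),
#'             density = FALSE)
assign_mode <- function(plddt, packed, signature, density,
                        plddt_cutoff = 70) {
  k <- max(length(plddt), length(packed), length(signature), length(density))
  plddt <- rep_len(plddt, k); packed <- rep_len(packed, k)
  outl <- rep_len(signature, k) | rep_len(density, k)
  ifelse(plddt >= plddt_cutoff,
         ifelse(packed, "predictive", "unpacked_high_plddt"),
         ifelse(packed,
                ifelse(outl, "unphysical", "near_predictive"),
                ifelse(outl, "barbed_wire", "pseudostructure")))
}

smooth_runs_once <- function(modes, target, flank_modes) {
  n <- length(modes)
  r <- rle(modes)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- modes
  for (k in seq_along(r$values)) {
    if (r$values[k] != target || r$lengths[k] > 2) next
    if (starts[k] == 1 || ends[k] == n) next      # touches a terminus
    left <- modes[starts[k] - 1]; right <- modes[ends[k] + 1]
    if (left == right && left %in% flank_modes) {
      out[starts[k]:ends[k]] <- left
    }
  }
  out
}

#' Two-pass mode smoothing
#'
#' Pass 1: maximal runs of one or two `pseudostructure` residues whose
#' immediate neighbors on both sides share the same mode, either
#' `barbed_wire` or `near_predictive`, take that flanking mode. Pass 2: runs
#' of one or two `barbed_wire` residues still surrounded on both sides by
#' `pseudostructure` become `pseudostructure`. Runs touching a chain terminus
#' or chain break are never smoothed, and no other mode changes.
#'
#' @param modes Character vector of raw modes along one or more chains.
#' @param chain Optional chain id per residue.
#' @param break_before Optional logical; `TRUE` where a chain break precedes
#'   the residue. Smoothing never crosses a break.
#' @return Character vector of smoothed modes.
#' @export
#' @examples
#' smooth_modes(c("barbed_wire", "barbed_wire", "pseudostructure",
#'                "barbed_wire", "barbed_wire"))
smooth_modes <- function(modes, chain = NULL, break_before = NULL) {
  n <- length(modes)
  if (n == 0) return(modes)
  chain <- chain %||% rep("A", n)
  break_before <- break_before %||% rep(FALSE, n)
  seg <- cumsum(c(TRUE, chain[-1] != chain[-n] | break_before[-1]))
  unlist(lapply(split(seq_len(n), seg), function(idx) {
    m <- modes[idx]
    m <- smooth_runs_once(m, "pseudostructure",
                          c("barbed_wire", "near_predictive"))
    smooth_runs_once(m, "barbed_wire", "pseudostructure")
  }), use.names = FALSE)
}

#' Compose the Lprocg label
#'
#' Six fixed positions: L (low pLDDT), p (low packing), r (Ramachandran
#' outlier), o (omega outlier: cis or twisted), c (CA-geometry outlier),
#' g (covalent-geometry outlier); a dash marks each position that does not
#' apply.
#'
#' @param low_plddt,low_packing,rama,omega,cablam,geom Logical vectors.
#' @return Character vector of six-character labels.
#' @export
#' @examples
#' make_label(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)  # "L-----"
make_label <- function(low_plddt, low_packing, rama, omega, cablam, geom) {
  paste0(ifelse(low_plddt, "L", "-"), ifelse(low_packing, "p", "-"),
         ifelse(rama, "r", "-"), ifelse(omega, "o", "-"),
         ifelse(cablam, "c", "-"), ifelse(geom, "g", "-"))
}
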