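# Per-residue validation outlier panel: Ramachandran, peptide-bond omega,
# CA-trace geometry and covalent geometry. These flags feed the signature and
# high-density rules of the mode classifier and the r/o/c/g positions of the
# Lprocg label.

#' Classify a peptide-bond omega dihedral
#'
#' @param omega Omega dihedral(s) in degrees (the bond preceding the residue
#'   that carries the value).
#' @param is_pro Whether the later residue of the bond is proline.
#' @param cis_max,trans_min Classification bounds in degrees: `|omega|` at or
#'   below `cis_max` is cis, at or above `trans_min` is trans, in between
#'   twisted.
#' @return Character vector over `"trans"`, `"cis_pro"`, `"cis_nonpro"`,
#'   `"twisted"`, `"undefined"`.
#' @export
#' @examples
#' classify_omega(c(180, 5, 90), is_pro = c(FALSE, TRUE, FALSE))
classify_omega <- function(omega, is_pro = FALSE, cis_max = 30,
                           trans_min = 150) {
  is_pro <- rep_len(is_pro, length(omega))
  a <- abs(omega)
  out <- ifelse(is.na(omega), "undefined",
         ifelse(a <= cis_max, ifelse(is_pro, "cis_pro", "cis_nonpro"),
         ifelse(a < trans_min, "twisted", "trans")))
  out
}

in_rects <- function(x, y, rects, xmin, xmax, ymin, ymax) {
  hit <- rep(FALSE, length(x))
  for (k in seq_len(nrow(rects))) {
    hit <- hit | (x >= rects[[xmin]][k] & x <= rects[[xmax]][k] &
                    y >= rects[[ymin]][k] & y <= rects[[ymax]][k])
  }
  hit
}

#' Ramachandran flags
#'
#' Calls a (phi, psi) pair an outlier when it falls inside no allowed
#' rectangle of its residue class in the packaged map. Two signature regions
#' are reported alongside: the high-psi band (+60 < psi < +170) and the
#' upper-right outlier box (-15 < phi < +170 and the same psi band), the
#' region where implausible looping-coil conformations concentrate.
#'
#' @param phi,psi Dihedrals in degrees (may be vectors).
#' @param res_class One of `"general"`, `"gly"`, `"pro"`, `"prepro"` per
#'   residue.
#' @param map Rectangle map from [load_rama_map()].
#' @return A tibble with logical columns `rama_outlier`, `rama_upper_right`,
#'   `high_psi_band` and `rama_evaluated` (false where a dihedral is
#'   undefined; all flags false there).
#' @export
classify_rama <- function(phi, psi, res_class = "general",
                          map = load_rama_map()) {
  res_class <- rep_len(res_class, length(phi))
  evaluated <- !is.na(phi) & !is.na(psi)
  allowed <- rep(FALSE, length(phi))
  for (cls in unique(res_class[evaluated])) {
    idx <- which(res_class == cls & evaluated)
    rects <- map[map$class == cls, ]
    if (nrow(rects) == 0) rects <- map[map$class == "general", ]
    allowed[idx] <- in_rects(phi[idx], psi[idx], rects,
                             "phi_min", "phi_max", "psi_min", "psi_max")
  }
  outlier <- evaluated & !allowed
  band <- evaluated & psi > 60 & psi < 170
  upper_right <- outlier & band & phi > -15 & phi < 170
  tibble::tibble(rama_outlier = outlier, rama_upper_right = upper_right,
                 high_psi_band = band, rama_evaluated = evaluated)
}

#' CA-trace geometry flag
#'
#' A coarse CA-geometry check: a residue is an outlier when its
#' (mu_in, mu_out) pseudo-dihedral pair falls outside every allowed rectangle
#' of the packaged CA map, or when the CA pseudo-angle leaves the configured
#' window. Residues with undefined pseudo-geometry (termini, breaks) are not
#' evaluated and never flagged.
#'
#' @param ca_angle CA(i-1)-CA(i)-CA(i+1) pseudo-angle, degrees.
#' @param mu_in,mu_out Four-CA pseudo-dihedrals ending/starting at the
#'   residue, degrees.
#' @param map Rectangle map from [load_ca_map()].
#' @param angle_min,angle_max Pseudo-angle window (degrees).
#' @return A tibble with logical columns `ca_geom_outlier`, `ca_evaluated`.
#' @export
classify_ca_geometry <- function(ca_angle, mu_in, mu_out,
                                 map = load_ca_map(),
                                 angle_min = 70, angle_max = 155) {
  evaluated <- !is.na(mu_in) & !is.na(mu_out) & !is.na(ca_angle)
  allowed <- rep(FALSE, length(ca_angle))
  idx <- which(evaluated)
  if (length(idx)) {
    allowed[idx] <- in_rects(mu_in[idx], mu_out[idx], map,
                             "in_min", "in_max", "out_min", "out_max")
  }
  out <- evaluated & (!allowed | ca_angle < angle_min | ca_angle > angle_max)
  tibble::tibble(ca_geom_outlier = out, ca_evaluated = evaluated)
}

rama_class_of <- function(resname, next_resname) {
  ifelse(resname == "GLY", "gly",
  ifelse(resname == "PRO", "pro",
  ifelse(!is.na(next_resname) & next_resname == "PRO", "prepro", "general")))
}

#' Assemble the per-residue validation flag panel
#'
#' Runs the Ramachandran, omega, CA-geometry and covalent-geometry
#' classifiers over an [analyze_backbone()] table. Covalent terms of the
#' peptide bond preceding a residue (C-N, CA-C-N, C-N-CA) count toward that
#' residue's `bond_geom_outlier`; `cnca_outlier` isolates the C-N-CA angle,
#' the systematic barbed-wire distortion.
#'
#' @param geometry Output of [assign_ss()] or [analyze_backbone()].
#' @param config A [bw_config()].
#' @return `geometry` with columns `omega_state`, `rama_outlier`,
#'   `rama_upper_right`, `high_psi_band`, `ca_geom_outlier`,
#'   `bond_geom_outlier`, `cnca_outlier` appended.
#' @export
compute_validation_flags <- function(geometry, config = bw_config()) {
  n <- nrow(geometry)
  nxt <- c(geometry$resname[-1], NA)
  nxt[c(geometry$chain[-1] != geometry$chain[-n], TRUE)] <- NA
  cls <- rama_class_of(geometry$resname, nxt)
  rama <- classify_rama(geometry$phi, geometry$psi, cls,
                        map = load_rama_map(config$rama_map_path))
  cag <- classify_ca_geometry(geometry$ca_angle, geometry$mu_in,
                              geometry$mu_out,
                              map = load_ca_map(config$ca_map_path),
                              angle_min = config$ca_angle_min,
                              angle_max = config$ca_angle_max)
  zc <- config$z_cutoff
  zmat <- cbind(geometry$z_n_ca, geometry$z_ca_c, geometry$z_n_ca_c,
                geometry$z_ca_c_o, geometry$z_c_n, geometry$z_ca_c_n,
                geometry$z_c_n_ca)
  bond_out <- rowSums(abs(zmat) > zc, na.rm = TRUE) > 0
  dplyr::bind_cols(geometry, rama, cag) |>
    dplyr::mutate(
      omega_state = classify_omega(.data$omega, .data$resname == "PRO",
                                   config$omega_cis_max,
                                   config$omega_trans_min),
      bond_geom_outlier = bond_out,
      cnca_outlier = !is.na(geometry$z_c_n_ca) &
        abs(geometry$z_c_n_ca) > zc)
}

#' Override internal flags with external validation results
#'
#' Merges a JSON document of per-residue validation calls (for example
#' authentic CaBLAM or Ramachandran output from another program) over the
#' internally computed flags, enabling comparisons against the original
#' validation stack. The JSON is an array of records with keys `chain`,
#' `resno`, optional `icode`, and any subset of the logical flag columns.
#'
#' @param flags Output of [compute_validation_flags()].
#' @param path Path to the JSON file.
#' @return `flags` with matching records overridden.
#' @export
apply_external_validation <- function(flags, path) {
  ext <- jsonlite::fromJSON(path)
  if (is.null(ext$icode)) ext$icode <- ""
  ext$icode[is.na(ext$icode)] <- ""
  key <- paste(flags$chain, flags$resno, flags$icode)
  ekey <- paste(ext$chain, ext$resno, ext$icode)
  idx <- match(ekey, key)
  if (anyNA(idx)) stop("external validation references unknown residues: ",
                       paste(ekey[is.na(idx)], collapse = ", "))
  for (col in intersect(names(ext),
                        c("rama_outlier", "rama_upper_right", "high_psi_band",
                          "ca_geom_outlier", "bond_geom_outlier",
                          "cnca_outlier", "omega_state"))) {
    flags[[col]][idx] <- ext[[col]]
  }
  flags
}
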