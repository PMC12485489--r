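# Result writers: tabular text, JSON, mode-pruned PDB selection, and
# kinemage markup (a minimal dialect: @kinemage, @group, @vectorlist,
# @balllist, @labellist) viewable in KiNG.

annotation_records <- function(analysis) {
  analysis$residues |>
    dplyr::transmute(
      chain = .data$chain, resno = .data$resno, icode = .data$icode,
      resname = .data$resname, plddt = .data$plddt, ss = .data$ss,
      packing_score = .data$packing_score, packed = .data$packed,
      rama_outlier = .data$rama_outlier, omega_state = .data$omega_state,
      ca_geom_outlier = .data$ca_geom_outlier,
      bond_geom_outlier = .data$bond_geom_outlier,
      signature = .data$signature, density = .data$density,
      mode_raw = .data$mode_raw, mode = .data$mode, label = .data$label)
}

#' Write per-residue annotations as JSON
#'
#' A single JSON document with a metadata header (tool version, threshold
#' echo) and one ordered record per residue. [read_annotation_json()] parses
#' it back to an identical record table.
#'
#' @param analysis A [bw_analyze()] result.
#' @param path Output file.
#' @return Invisibly, the record tibble written.
#' @export
write_annotation_json <- function(analysis, path) {
  rec <- annotation_records(analysis)
  cfg <- analysis$config
  doc <- list(
    metadata = list(
      tool = "barbedwire",
      version = as.character(utils::packageVersion("barbedwire")),
      n_residues = nrow(rec),
      config = cfg[c("plddt_cutoff", "contact_gap_max", "cutoff_helix_coil",
                     "cutoff_strand", "window_halfwidth", "min_seq_sep",
                     "z_cutoff", "omega_cis_max", "omega_trans_min",
                     "chain_break_cn")]),
    residues = rec)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(rec)
}

#' @rdname write_annotation_json
#' @export
read_annotation_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  rec <- tibble::as_tibble(doc$residues)
  rec$icode[is.na(rec$icode)] <- ""
  rec
}

#' Write per-residue annotations as aligned text
#'
#' @param analysis A [bw_analyze()] result.
#' @param path Output file.
#' @return Invisibly, the record tibble written.
#' @export
write_annotation_text <- function(analysis, path) {
  rec <- annotation_records(analysis)
  lines <- c(sprintf("%-5s %5s %3s %-3s %6s %2s %7s %6s %-11s %-6s %s",
                     "chain", "resno", "ic", "res", "pLDDT", "ss", "score",
                     "packed", "omega", "label", "mode"),
             sprintf("%-5s %5d %3s %-3s %6.1f %2s %7.3f %6s %-11s %-6s %s",
                     rec$chain, rec$resno, rec$icode, rec$resname, rec$plddt,
                     rec$ss, rec$packing_score, ifelse(rec$packed, "yes", "no"),
                     rec$omega_state, rec$label, rec$mode))
  writeLines(lines, path)
  invisible(rec)
}

#' Write a mode-pruned PDB file
#'
#' Keeps exactly the residues whose post-smoothing mode is in `modes`; the
#' default returns the predictive and near-predictive residues, the subset
#' whose coordinates carry predictive value.
#'
#' @param analysis A [bw_analyze()] result.
#' @param path Output PDB file.
#' @param modes Character vector of modes to keep.
#' @return Invisibly, the number of residues written.
#' @export
write_selection <- function(analysis, path,
                            modes = c("predictive", "near_predictive")) {
  stopifnot(length(modes) > 0, all(modes %in% bw_modes()))
  keep <- analysis$residues[analysis$residues$mode %in% modes,
                            c("chain", "resno", "icode")]
  write_structure(analysis$structure, path, keep = keep)
}

#' Write kinemage markup
#'
#' Emits a kinemage with a CA-trace vectorlist, one individually togglable
#' balllist per mode (colored by the configured mode -> color map) and a
#' labellist carrying each residue's Lprocg string at its CA. Residues
#' without a CA atom are skipped with a warning.
#'
#' @param analysis A [bw_analyze()] result.
#' @param path Output `.kin` file.
#' @return Invisibly, the number of balls written.
#' @export
write_kinemage <- function(analysis, path) {
  res <- analysis$residues
  ca <- atom_matrix(analysis$structure,
                    paste(res$chain, res$resno, res$icode), "CA")
  has_ca <- !is.na(ca[, 1])
  if (any(!has_ca)) {
    warning(sum(!has_ca), " residue(s) without CA skipped in kinemage output")
  }
  colors <- analysis$config$mode_colors
  out <- c("@kinemage 1",
           "@title {prediction-mode analysis}",
           "@group {modes} dominant")
  # CA trace, broken at chain boundaries and chain breaks
  out <- c(out, "@vectorlist {CA trace} color= white")
  n <- nrow(res)
  new_seg <- c(TRUE, res$chain[-1] != res$chain[-n] |
                 res$chain_break_before[-1])
  for (i in which(has_ca)) {
    tag <- if (new_seg[i] || !has_ca[max(1, i - 1)]) "P" else "L"
    out <- c(out, sprintf("{%s %s%d}%s %.3f %.3f %.3f", res$resname[i],
                          res$chain[i], res$resno[i], tag,
                          ca[i, 1], ca[i, 2], ca[i, 3]))
  }
  n_balls <- 0L
  for (m in bw_modes()) {
    idx <- which(res$mode == m & has_ca)
    out <- c(out, sprintf("@balllist {%s} color= %s radius= 0.4 master= {%s}",
                          m, colors[[m]], m))
    if (length(idx)) {
      out <- c(out, sprintf("{%s %s%d %s} %.3f %.3f %.3f",
                            res$resname[idx], res$chain[idx], res$resno[idx],
                            res$label[idx],
                            ca[idx, 1], ca[idx, 2], ca[idx, 3]))
      n_balls <- n_balls + length(idx)
    }
  }
  out <- c(out, "@labellist {Lprocg} color= white master= {labels}")
  idx <- which(has_ca)
  out <- c(out, sprintf("{%s} %.3f %.3f %.3f", res$label[idx],
                        ca[idx, 1], ca[idx, 2], ca[idx, 3]))
  writeLines(out, path)
  invisible(n_balls)
}
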