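# Full analysis pipeline: read -> backbone geometry -> secondary structure ->
# contacts -> packing -> validation flags -> mode tree -> smoothing.

#' Analyze a predicted structure into prediction modes
#'
#' Runs the complete per-residue classification on a structure: backbone
#' geometry and chain breaks, CA-geometry secondary structure, tertiary
#' contact enumeration, the packing score, the validation flag panel, the
#' signature and high-density outlier rules, the six-mode decision tree, and
#' the two-pass smoothing.
#'
#' @param x A `bw_structure` (from [read_structure()] or [make_fixture()]) or
#'   a path to a PDB/mmCIF file.
#' @param config A [bw_config()].
#' @param external_validation Optional path to a JSON file of externally
#'   computed validation flags (see [apply_external_validation()]).
#' @return An object of class `bw_analysis`: a list with the input
#'   `structure`, the per-residue annotation tibble `residues` (pLDDT,
#'   secondary structure, packing, flags, signature/density, raw and smoothed
#'   mode, Lprocg label), the contact table, and the configuration. Use
#'   [tidy()] for the residue table, [glance()] for mode counts,
#'   [autoplot()] for a sequence-track plot.
#' @export
#' @examples
#' fit <- bw_analyze(make_fixture("helix_bundle", length = 12, plddt = 90))
#' glance(fit)
bw_analyze <- function(x, config = bw_config(), external_validation = NULL) {
  structure <- if (is.character(x)) read_structure(x) else x
  stopifnot(inherits(structure, "bw_structure"))
  targets <- load_geometry_targets(config$targets_path)
  geom <- analyze_backbone(structure, targets = targets,
                           chain_break_cn = config$chain_break_cn)
  geom <- assign_ss(structure, geom, config)
  flags <- compute_validation_flags(geom, config)
  if (!is.null(external_validation)) {
    flags <- apply_external_validation(flags, external_validation)
  }
  contacts <- enumerate_contacts(structure, ss = geom,
                                 radii = load_vdw_radii(config$radii_path),
                                 gap_max = config$contact_gap_max,
                                 min_seq_sep = config$min_seq_sep)
  pack <- packing_score(structure, contacts, geom, config)

  low <- flags$plddt < config$plddt_cutoff
  sig <- signature_outlier(flags, low, pack$packed)
  dens <- high_outlier_density(flags)
  omega_out <- flags$omega_state %in% c("cis_pro", "cis_nonpro", "twisted")

  residues <- tibble::tibble(
    chain = flags$chain, resno = flags$resno, icode = flags$icode,
    resname = flags$resname, plddt = flags$plddt,
    ss = pack$ss, phi = flags$phi, psi = flags$psi, omega = flags$omega,
    packing_score = pack$score, contact_count = pack$contact_count,
    heavy_atoms = pack$heavy_atoms, packed = pack$packed,
    rama_outlier = flags$rama_outlier,
    rama_upper_right = flags$rama_upper_right,
    high_psi_band = flags$high_psi_band,
    omega_state = flags$omega_state,
    ca_geom_outlier = flags$ca_geom_outlier,
    bond_geom_outlier = flags$bond_geom_outlier,
    cnca_outlier = flags$cnca_outlier,
    chain_break_before = flags$chain_break_before,
    chain_break_after = flags$chain_break_after,
    signature = sig, density = dens,
    mode_raw = assign_mode(flags$plddt, pack$packed, sig, dens,
                           config$plddt_cutoff))
  residues$mode <- smooth_modes(residues$mode_raw, residues$chain,
                                residues$chain_break_before)
  residues$label <- make_label(low, !pack$packed, flags$rama_outlier,
                               omega_out, flags$ca_geom_outlier,
                               flags$bond_geom_outlier)
  structure(list(structure = structure, residues = residues,
                 contacts = contacts, config = config),
            class = "bw_analysis")
}

#' @export
print.bw_analysis <- function(x, ...) {
  cat("Prediction-mode analysis:",
      nrow(x$residues), "residues,",
      length(unique(x$residues$chain)), "chain(s)\n")
  tab <- table(factor(x$residues$mode, levels = bw_modes()))
  for (m in names(tab)) {
    if (tab[[m]] > 0) cat(sprintf("  %-20s %5d (%.1f%%)\n", m, tab[[m]],
                                  100 * tab[[m]] / nrow(x$residues)))
  }
  invisible(x)
}

#' Broom-style accessors for an analysis
#'
#' `tidy()` returns the per-residue annotation tibble; `glance()` a one-row
#' summary with residue, chain, contact and per-mode counts.
#'
#' @param x A `bw_analysis` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
#' @name bw_tidiers
tidy.bw_analysis <- function(x, ...) x$residues

#' @rdname bw_tidiers
#' @export
glance.bw_analysis <- function(x, ...) {
  tab <- table(factor(x$residues$mode, levels = bw_modes()))
  out <- tibble::tibble(n_residues = nrow(x$residues),
                        n_chains = length(unique(x$residues$chain)),
                        n_contacts = nrow(x$contacts))
  for (m in bw_modes()) out[[paste0("n_", m)]] <- unname(tab[m])
  out
}

#' Sequence-track plot of an analysis
#'
#' Draws pLDDT and the packing score along the sequence with a mode-colored
#' band beneath, one facet per chain.
#'
#' @param object A `bw_analysis`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bw_analysis <- function(object, ...) {
  d <- object$residues |>
    dplyr::group_by(.data$chain) |>
    dplyr::mutate(pos = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(mode = factor(.data$mode, levels = bw_modes()))
  cols <- c(predictive = "#2166ac", unpacked_high_plddt = "#9aa0a6",
            near_predictive = "#1a9850", pseudostructure = "#d4a017",
            barbed_wire = "#d73027", unphysical = "#6a3d9a")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos)) +
    ggplot2::geom_tile(ggplot2::aes(y = -8, fill = .data$mode), height = 14) +
    ggplot2::geom_line(ggplot2::aes(y = .data$plddt, color = "pLDDT")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$packing_score * 100,
                                    color = "packing score x 100")) +
    ggplot2::geom_hline(yintercept = object$config$plddt_cutoff,
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = cols, drop = FALSE) +
    ggplot2::scale_color_manual(values = c("pLDDT" = "black",
                                           "packing score x 100" = "#555599")) +
    ggplot2::facet_wrap(~chain, ncol = 1) +
    ggplot2::labs(x = "residue position", y = NULL, fill = "mode",
                  color = NULL) +
    ggplot2::theme_minimal()
}
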