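#' Analysis configuration
#'
#' Builds the configuration list consumed by [bw_analyze()] and the lower-level
#' module functions. Every numeric threshold of the classifier is exposed here;
#' the defaults reproduce the published decision rules.
#'
#' @param plddt_cutoff pLDDT at or above which a residue counts as
#'   high-confidence (default 70, the conventional rule-of-thumb cutoff).
#' @param contact_gap_max Maximum van der Waals surface separation, in
#'   Angstrom, for two heavy atoms to count as a steric contact (default 0.5).
#' @param cutoff_helix_coil Packing score above which a helix or coil residue
#'   is considered adequately packed (default 0.6 contacts per heavy atom).
#' @param cutoff_strand Packing score cutoff for beta-strand residues, lowered
#'   because intra-sheet contacts are excluded (default 0.35).
#' @param window_halfwidth Half-width of the residue window used by the packing
#'   score (default 2, i.e. a five-residue window).
#' @param min_seq_sep Minimum same-chain sequence separation for a contact;
#'   pairs with `|i - j| <=` this value are omitted (default 4).
#' @param z_cutoff Absolute z-score beyond which a covalent bond length or
#'   angle is an outlier (default 4).
#' @param omega_cis_max Peptide bonds with `|omega|` at or below this value
#'   (degrees) are cis (default 30).
#' @param omega_trans_min `|omega|` at or above this value is trans; between
#'   the two bounds the bond is twisted (default 150).
#' @param chain_break_cn C(i-1)-N(i) distance in Angstrom beyond which a chain
#'   break is declared (default 2.5).
#' @param ca_angle_min,ca_angle_max Bounds on the CA(i-1)-CA(i)-CA(i+1)
#'   pseudo-angle outside which the residue is a CA-geometry outlier
#'   (defaults 70 and 155 degrees).
#' @param helix_d13_min,helix_d13_max CA(i)-CA(i+3) distance window (Angstrom)
#'   for a helix candidate (defaults 4.5 and 6.0).
#' @param helix_dihed_min,helix_dihed_max CA pseudo-dihedral window (degrees)
#'   for a helix candidate (defaults 35 and 65).
#' @param strand_d02_min,strand_d02_max CA(i)-CA(i+2) distance window for a
#'   strand candidate (defaults 6.2 and 7.2).
#' @param strand_dihed_min Minimum CA pseudo-dihedral magnitude for a strand
#'   candidate (default 120 degrees).
#' @param helix_min_len,strand_min_len Minimum element lengths (4 and 3).
#' @param rama_map_path,ca_map_path,radii_path,targets_path Optional paths to
#'   replacement plain-text tables; `NULL` uses the packaged defaults.
#' @param mode_colors Named character vector mapping each mode to a kinemage
#'   color keyword.
#'
#' @return A named list of class `bw_config`.
#' @export
#' @examples
#' cfg <- bw_config(cutoff_strand = 0.4)
#' cfg$cutoff_strand
bw_config <- function(plddt_cutoff = 70,
                      contact_gap_max = 0.5,
                      cutoff_helix_coil = 0.6,
                      cutoff_strand = 0.35,
                      window_halfwidth = 2,
                      min_seq_sep = 4,
                      z_cutoff = 4,
                      omega_cis_max = 30,
                      omega_trans_min = 150,
                      chain_break_cn = 2.5,
                      ca_angle_min = 70,
                      ca_angle_max = 155,
                      helix_d13_min = 4.5,
                      helix_d13_max = 6.0,
                      helix_dihed_min = 35,
                      helix_dihed_max = 65,
                      strand_d02_min = 6.2,
                      strand_d02_max = 7.2,
                      strand_dihed_min = 120,
                      helix_min_len = 4,
                      strand_min_len = 3,
                      rama_map_path = NULL,
                      ca_map_path = NULL,
                      radii_path = NULL,
                      targets_path = NULL,
                      mode_colors = c(predictive = "blue",
                                      unpacked_high_plddt = "gray",
                                      near_predictive = "green",
                                      pseudostructure = "gold",
                                      barbed_wire = "red",
                                      unphysical = "purple")) {
  cfg <- list(plddt_cutoff = plddt_cutoff,
              contact_gap_max = contact_gap_max,
              cutoff_helix_coil = cutoff_helix_coil,
              cutoff_strand = cutoff_strand,
              window_halfwidth = window_halfwidth,
              min_seq_sep = min_seq_sep,
              z_cutoff = z_cutoff,
              omega_cis_max = omega_cis_max,
              omega_trans_min = omega_trans_min,
              chain_break_cn = chain_break_cn,
              ca_angle_min = ca_angle_min,
              ca_angle_max = ca_angle_max,
              helix_d13_min = helix_d13_min,
              helix_d13_max = helix_d13_max,
              helix_dihed_min = helix_dihed_min,
              helix_dihed_max = helix_dihed_max,
              strand_d02_min = strand_d02_min,
              strand_d02_max = strand_d02_max,
              strand_dihed_min = strand_dihed_min,
              helix_min_len = helix_min_len,
              strand_min_len = strand_min_len,
              rama_map_path = rama_map_path,
              ca_map_path = ca_map_path,
              radii_path = radii_path,
              targets_path = targets_path,
              mode_colors = mode_colors)
  stopifnot(contact_gap_max > 0 || contact_gap_max <= 0,  # numeric
            cutoff_helix_coil > 0, cutoff_strand > 0,
            window_halfwidth >= 0, z_cutoff > 0,
            omega_cis_max > 0, omega_trans_min > omega_cis_max,
            chain_break_cn > 0)
  structure(cfg, class = c("bw_config", "list"))
}

#' The six prediction modes, in decision-tree order
#' @export
bw_modes <- function() {
  c("predictive", "unpacked_high_plddt", "near_predictive",
    "pseudostructure", "barbed_wire", "unphysical")
}

bw_extdata <- function(file) {
  system.file("extdata", file, package = "barbedwire", mustWork = TRUE)
}

read_tsv_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Load backbone geometry targets
#'
#' Reads the (name, kind, ideal, sigma) table of ideal backbone bond lengths
#' and angles used for z-scores and for the internal-coordinate builder.
#'
#' @param path Optional replacement table; `NULL` loads the packaged set.
#' @return A tibble with columns `name`, `kind`, `ideal`, `sigma`.
#' @export
load_geometry_targets <- function(path = NULL) {
  tab <- read_tsv_table(path %||% bw_extdata("geometry_targets.tsv"))
  stopifnot(all(c("name", "kind", "ideal", "sigma") %in% names(tab)),
            all(tab$sigma > 0))
  tibble::as_tibble(tab)
}

#' Load the van der Waals radius table
#'
#' @param path Optional replacement table; `NULL` loads the packaged
#'   united-atom set.
#' @return A named numeric vector of radii in Angstrom, including a `*`
#'   fallback entry.
#' @export
load_vdw_radii <- function(path = NULL) {
  tab <- read_tsv_table(path %||% bw_extdata("vdw_radii.tsv"))
  stats::setNames(tab$radius, tab$class)
}

#' Load a rectangular Ramachandran allowed-region map
#'
#' @param path Optional replacement table; `NULL` loads the packaged coarse
#'   map (classes general, gly, pro, prepro).
#' @return A tibble of rectangles with columns `class`, `region`, `phi_min`,
#'   `phi_max`, `psi_min`, `psi_max`.
#' @export
load_rama_map <- function(path = NULL) {
  tab <- read_tsv_table(path %||% bw_extdata("rama_allowed.tsv"))
  tibble::as_tibble(tab)
}

#' Load the CA-trace pseudo-dihedral allowed map
#'
#' Rectangles in (mu_in, mu_out) space; a defined pseudo-dihedral pair outside
#' every rectangle is a CA-geometry outlier.
#'
#' @param path Optional replacement table; `NULL` loads the packaged map.
#' @return A tibble of rectangles with columns `region`, `in_min`, `in_max`,
#'   `out_min`, `out_max`.
#' @export
load_ca_map <- function(path = NULL) {
  tab <- read_tsv_table(path %||% bw_extdata("ca_geometry_allowed.tsv"))
  tibble::as_tibble(tab)
}
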