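# Comparison of prediction modes against per-residue disorder-annotation
# tracks (MobiDB-style feature -> residue-range JSON supplied by the user).
# Segment pruning keeps only unambiguous interior residues of each mode.

#' Prune mode segments to unambiguous cores
#'
#' Works on PRE-smoothing modes. For each maximal same-mode run of
#' `barbed_wire`, `pseudostructure` or `near_predictive`, the first and last
#' `trim` residues are removed and the remainder is retained only when at
#' least `min_core` residues survive (so runs shorter than
#' `2 * trim + min_core` contribute nothing). High-confidence residues are
#' retained by the plain pLDDT cutoff, as category `"high_plddt"`.
#'
#' @param residues A per-residue tibble with `chain`, `resno`, `icode`,
#'   `mode_raw`, `plddt` (e.g. `tidy(bw_analyze(x))`).
#' @param min_core Minimum surviving run length (default 3).
#' @param trim Residues removed from each end of a run (default 3).
#' @param plddt_cutoff High-confidence boundary (default 70).
#' @return `residues` with logical `retained` and character `category`
#'   (`"high_plddt"`, the low-confidence mode name, or `NA`) appended.
#' @export
prune_segments <- function(residues, min_core = 3, trim = 3,
                           plddt_cutoff = 70) {
  n <- nrow(residues)
  pruned_modes <- c("barbed_wire", "pseudostructure", "near_predictive")
  retained <- logical(n)
  category <- rep(NA_character_, n)
  high <- residues$plddt >= plddt_cutoff
  retained[high] <- TRUE
  category[high] <- "high_plddt"
  seg <- cumsum(c(TRUE, residues$chain[-1] != residues$chain[-n]))
  r <- rle(paste(seg, residues$mode_raw))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (k in seq_along(r$values)) {
    mode <- sub("^\\S+ ", "", r$values[k])
    if (!mode %in% pruned_modes) next
    core <- (starts[k] + trim):(ends[k] - trim)
    if (r$lengths[k] - 2 * trim < min_core) next
    retained[core] <- TRUE
    category[core] <- mode
  }
  out <- residues
  out$retained <- retained
  out$category <- category
  out
}

#' Read disorder-annotation tracks from JSON
#'
#' The document maps feature names to arrays of `[start, end]` inclusive,
#' 1-based residue-number ranges, e.g.
#' `{"prediction-disorder-iupl": [[1, 40], [90, 120]]}`.
#'
#' @param path Path to the JSON file.
#' @return A named list of two-column start/end matrices.
#' @export
read_annotation_tracks <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  lapply(doc, function(rg) {
    if (length(rg) == 0) return(matrix(integer(0), ncol = 2))
    m <- if (is.matrix(rg)) rg else matrix(unlist(rg), ncol = 2, byrow = TRUE)
    storage.mode(m) <- "integer"
    if (any(m[, 1] > m[, 2])) stop("annotation range with start > end")
    m
  })
}

#' Overlap fractions of modes with annotation tracks
#'
#' For every (category, feature) pair, the fraction of retained residues of
#' that category whose author residue number lies inside any range of the
#' feature. Categories with no retained residues are absent from the output.
#'
#' @param pruned Output of [prune_segments()].
#' @param tracks Named list of range matrices from [read_annotation_tracks()]
#'   (or built in code).
#' @return A tidy tibble with columns `category`, `feature`, `n_retained`,
#'   `n_overlap`, `fraction`.
#' @export
overlap_fractions <- function(pruned, tracks) {
  kept <- pruned[pruned$retained, ]
  if (nrow(kept) == 0) return(tibble::tibble(
    category = character(), feature = character(),
    n_retained = integer(), n_overlap = integer(), fraction = numeric()))
  span <- range(pruned$resno)
  for (f in names(tracks)) {
    rg <- tracks[[f]]
    if (nrow(rg) > 0 && (min(rg[, 1]) < span[1] || max(rg[, 2]) > span[2])) {
      stop("annotation track '", f, "' references residues outside ",
           span[1], "..", span[2],
           ": numbering mismatch between track and structure")
    }
  }
  purrr::map_dfr(names(tracks), function(f) {
    rg <- tracks[[f]]
    inside <- if (nrow(rg) == 0) rep(FALSE, nrow(kept)) else
      purrr::map_lgl(kept$resno,
                     function(r) any(r >= rg[, 1] & r <= rg[, 2]))
    kept |>
      dplyr::mutate(inside = inside) |>
      dplyr::group_by(category = .data$category) |>
      dplyr::summarise(feature = f, n_retained = dplyr::n(),
                       n_overlap = sum(.data$inside),
                       fraction = mean(.data$inside), .groups = "drop")
  }) |>
    dplyr::select("category", "feature", "n_retained", "n_overlap",
                  "fraction")
}
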