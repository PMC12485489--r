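# Structure input/output. Parsing is delegated to bio3d; the package works on
# a flat atom tibble so every downstream stage is a data-frame verb.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL", "MSE", "SEC", "PYL")

#' Read a predicted structure with per-residue pLDDT
#'
#' Parses a single-model protein structure in PDB or mmCIF format and returns
#' a flat atom tibble. The AlphaFold convention of storing pLDDT in the
#' B-factor field is applied: each residue's pLDDT is the B value on its CA
#' atom (mean over the residue's atoms when CA is absent), and files written
#' on the 0-1 confidence scale (all B values at most 1) are rescaled to 0-100.
#'
#' Waters, ligands and other non-polypeptide residues are dropped. For
#' residues with alternate conformers only the highest-occupancy conformer is
#' kept (ties broken by altloc identifier). Multi-model files are truncated to
#' the first model with a warning.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param format Optional override, `"pdb"` or `"mmcif"`; by default inferred
#'   from the file extension (`.cif`/`.mmcif` vs anything else).
#' @return A tibble of class `bw_structure`, one row per heavy or hydrogen
#'   atom, with columns `chain`, `resno`, `icode`, `resname`, `atom`,
#'   `element`, `is_hydrogen`, `x`, `y`, `z`, `b`, `plddt`, and attributes
#'   `source_format` and `title`.
#' @export
#' @examples
#' pdb <- make_fixture("lone_helix", length = 8, plddt = 92)
#' tf <- tempfile(fileext = ".pdb")
#' write_structure(pdb, tf)
#' s <- read_structure(tf)
#' dplyr::count(s, chain)
read_structure <- function(path, format = NULL) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  format <- format %||%
    (if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb")
  format <- match.arg(format, c("pdb", "mmcif"))
  parsed <- tryCatch(
    if (format == "mmcif") {
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    } else {
      suppressWarnings(bio3d::read.pdb(path, verbose = FALSE, multi = FALSE,
                                       rm.alt = FALSE))
    },
    error = function(e) stop("could not parse ", path, " as ", format, ": ",
                             conditionMessage(e)))
  at <- parsed$atom
  if (format == "pdb" &&
      any(startsWith(readLines(path, n = 100000L, warn = FALSE), "MODEL"))) {
    warning("multi-model file; using the first model only")
  }
  at <- at[at$type == "ATOM" & at$resid %in% AA3, , drop = FALSE]
  if (nrow(at) == 0) stop("no polymer protein residues in ", path)

  tb <- tibble::tibble(
    chain    = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    resno    = as.integer(at$resno),
    icode    = ifelse(is.na(at$insert), "", at$insert),
    resname  = at$resid,
    atom     = at$elety,
    element  = guess_element(at$elesy, at$elety),
    occ      = ifelse(is.na(at$o), 1, at$o),
    alt      = ifelse(is.na(at$alt), "", at$alt),
    x = at$x, y = at$y, z = at$z,
    b = ifelse(is.na(at$b), 0, at$b))
  tb$is_hydrogen <- tb$element %in% c("H", "D")

  # altloc policy: highest occupancy, ties -> first altloc id; file order of
  # atoms within a residue is preserved otherwise
  tb$.ord <- seq_len(nrow(tb))
  tb <- tb |>
    dplyr::group_by(.data$chain, .data$resno, .data$icode, .data$atom) |>
    dplyr::arrange(dplyr::desc(.data$occ), .data$alt, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()

  chain_order <- unique(tb$chain[order(tb$.ord)])
  tb <- tb |>
    dplyr::arrange(match(.data$chain, chain_order), .data$resno, .data$icode,
                   .data$.ord)
  tb$.ord <- NULL

  # per-residue pLDDT: CA value, fallback mean over atoms
  res_b <- tb |>
    dplyr::group_by(.data$chain, .data$resno, .data$icode) |>
    dplyr::summarise(
      plddt = if (any(.data$atom == "CA")) .data$b[.data$atom == "CA"][1]
              else mean(.data$b),
      .groups = "drop")
  if (all(tb$b == 0)) {
    warning("B-factor field absent or constant zero; pLDDT treated as 0")
  } else if (all(tb$b <= 1.0)) {
    message("B values all <= 1.0: interpreting as 0-1-scale pLDDT, rescaling to 0-100")
    res_b$plddt <- res_b$plddt * 100
  }
  tb <- dplyr::left_join(tb, res_b, by = c("chain", "resno", "icode"))
  tb$occ <- NULL
  tb$alt <- NULL
  new_bw_structure(tb, source_format = format, title = basename(path))
}

guess_element <- function(elesy, elety) {
  el <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  miss <- el == ""
  if (any(miss)) {
    nm <- gsub("[^A-Za-z]", "", elety[miss])
    two <- toupper(substr(nm, 1, 2)) %in% c("FE", "ZN", "MG", "SE", "CL", "BR")
    el[miss] <- ifelse(two, toupper(substr(nm, 1, 2)), toupper(substr(nm, 1, 1)))
  }
  el
}

new_bw_structure <- function(tb, source_format = "pdb", title = "") {
  stopifnot(all(c("chain", "resno", "icode", "resname", "atom", "element",
                  "is_hydrogen", "x", "y", "z", "b", "plddt") %in% names(tb)))
  structure(tibble::as_tibble(tb),
            source_format = source_format, title = title,
            class = c("bw_structure", class(tibble::tibble())))
}

#' Per-residue view of a structure
#'
#' @param structure A `bw_structure` atom tibble.
#' @return A tibble with one row per residue, in structure order, with columns
#'   `chain`, `resno`, `icode`, `resname`, `plddt`, `n_atoms`,
#'   `n_heavy_atoms`, and the row index span of the residue's atoms.
#' @export
bw_residues <- function(structure) {
  structure |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$chain, .data$resno, .data$icode) |>
    dplyr::summarise(resname = .data$resname[1],
                     plddt = .data$plddt[1],
                     n_atoms = dplyr::n(),
                     n_heavy_atoms = sum(!.data$is_hydrogen),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$chain, unique(structure$chain)),
                   .data$resno, .data$icode)
}

#' Write a structure (or residue selection) as PDB
#'
#' Emits standard `ATOM`/`TER`/`END` records via bio3d, preserving chain ids,
#' author residue numbering, coordinates and B factors. The selection is a
#' predicate over residues; an empty selection writes an `END`-only file with
#' a warning.
#'
#' @param structure A `bw_structure`.
#' @param path Output file path.
#' @param keep `NULL` (keep everything), a logical vector over
#'   `bw_residues(structure)` rows, a function taking the residue tibble and
#'   returning such a vector, or a data frame of (`chain`, `resno`, `icode`)
#'   keys to keep.
#' @return Invisibly, the number of residues written.
#' @export
write_structure <- function(structure, path, keep = NULL) {
  stopifnot(nrow(structure) > 0)
  res <- bw_residues(structure)
  keep_vec <- resolve_keep(keep, res)
  sel <- res[keep_vec, c("chain", "resno", "icode"), drop = FALSE]
  at <- dplyr::semi_join(structure, sel, by = c("chain", "resno", "icode"))
  if (nrow(at) == 0) {
    warning("empty residue selection; writing header-only file")
    writeLines("END", path)
    return(invisible(0L))
  }
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(at)),
                   resno = at$resno,
                   resid = at$resname,
                   eleno = seq_len(nrow(at)),
                   elety = at$atom,
                   chain = at$chain,
                   insert = ifelse(at$icode == "", NA, at$icode),
                   o = rep(1, nrow(at)),
                   b = at$b,
                   elesy = at$element,
                   chainter = TRUE)
  invisible(nrow(sel))
}

resolve_keep <- function(keep, res) {
  if (is.null(keep)) return(rep(TRUE, nrow(res)))
  if (is.function(keep)) keep <- keep(res)
  if (is.logical(keep)) {
    stopifnot(length(keep) == nrow(res))
    return(keep & !is.na(keep))
  }
  if (is.data.frame(keep)) {
    if (!"icode" %in% names(keep)) keep$icode <- ""
    key <- paste(res$chain, res$resno, res$icode)
    return(key %in% paste(keep$chain, keep$resno, keep$icode))
  }
  stop("unsupported 'keep' selector")
}

#' @export
print.bw_structure <- function(x, ...) {
  res <- bw_residues(x)
  cat(sprintf("# bw_structure: %d atoms, %d residues, %d chain(s) [%s]\n",
              nrow(x), nrow(res), length(unique(x$chain)),
              attr(x, "source_format") %||% "?"))
  NextMethod()
}
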