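# CA-geometry secondary-structure assignment. Elements defined here decide
# which contacts are "internal" (excluded from packing) and which packing
# cutoff applies (strand vs helix/coil).

#' Assign secondary structure from CA geometry
#'
#' A residue opens a helix candidate when the CA(i)-CA(i+3) distance and the
#' CA(i..i+3) pseudo-dihedral fall in the helix windows; a strand candidate
#' when the CA(i)-CA(i+2) distance is extended and the pseudo-dihedral
#' magnitude is large. A candidate at i marks residues i..i+3 (helix) or
#' i..i+2 (strand); marked runs below the minimum element length (4 for
#' helix, 3 for strand) revert to coil. No element crosses a chain break.
#'
#' @param structure A `bw_structure`.
#' @param geometry Output of [analyze_backbone()] for the same structure.
#' @param config A [bw_config()] list carrying the geometric windows.
#' @return The `geometry` tibble with columns `ss` (one of `"H"`, `"E"`,
#'   `"C"`) and `ss_element` (integer element id, `NA` for coil) appended.
#' @export
assign_ss <- function(structure, geometry = analyze_backbone(structure),
                      config = bw_config()) {
  ca <- atom_matrix(structure,
                    paste(geometry$chain, geometry$resno, geometry$icode), "CA")
  n <- nrow(geometry)
  ss <- rep("C", n)
  if (n >= 3) {
    # connectivity i -> i+1 (same chain, no break)
    linked <- c(!(geometry$chain_break_before[-1] |
                    geometry$chain[-n] != geometry$chain[-1]), FALSE)
    run_ok <- function(i, span) {
      if (i + span > n) return(FALSE)
      all(linked[i:(i + span - 1)])
    }
    d_at <- function(i, k) sqrt(sum((ca[i, ] - ca[i + k, ])^2))
    dihed_at <- function(i) {
      if (i + 3 > n) return(NA_real_)
      compute_dihedral(ca[i, ], ca[i + 1, ], ca[i + 2, ], ca[i + 3, ])
    }
    helix_mark <- rep(FALSE, n)
    strand_mark <- rep(FALSE, n)
    for (i in seq_len(n)) {
      if (run_ok(i, 3) && !anyNA(ca[i:(i + 3), ])) {
        d13 <- d_at(i, 3); mu <- dihed_at(i)
        if (!is.na(mu) &&
            d13 >= config$helix_d13_min && d13 <= config$helix_d13_max &&
            mu >= config$helix_dihed_min && mu <= config$helix_dihed_max) {
          helix_mark[i:(i + 3)] <- TRUE
        }
      }
      if (run_ok(i, 2) && !anyNA(ca[i:(i + 2), ])) {
        d02 <- d_at(i, 2)
        mu <- if (i + 3 <= n && run_ok(i, 3)) dihed_at(i) else NA_real_
        if (is.na(mu) && i >= 2 && run_ok(i - 1, 3)) {
          mu <- compute_dihedral(ca[i - 1, ], ca[i, ], ca[i + 1, ], ca[i + 2, ])
        }
        if (!is.na(mu) &&
            d02 >= config$strand_d02_min && d02 <= config$strand_d02_max &&
            abs(mu) >= config$strand_dihed_min) {
          strand_mark[i:(i + 2)] <- TRUE
        }
      }
    }
    strand_mark <- strand_mark & !helix_mark   # helix wins ties
    ss[strand_mark] <- "E"
    ss[helix_mark] <- "H"
    # enforce minimum run lengths within break-free stretches
    seg <- cumsum(c(TRUE, !linked[-n])) + as.integer(factor(geometry$chain)) * 0
    ss <- unlist(lapply(split(seq_len(n), seg), function(idx) {
      s <- ss[idx]
      r <- rle(s)
      keep <- !((r$values == "H" & r$lengths < config$helix_min_len) |
                  (r$values == "E" & r$lengths < config$strand_min_len))
      r$values[!keep] <- "C"
      inverse.rle(r)
    }), use.names = FALSE)
  }
  out <- geometry
  out$ss <- ss
  # element ids: maximal same-kind non-coil runs within a segment
  seg <- cumsum(c(TRUE, geometry$chain[-1] != geometry$chain[-n] |
                    geometry$chain_break_before[-1]))
  r <- rle(paste(seg, ss))
  elem_of_run <- ifelse(grepl(" C$", r$values), NA_integer_,
                        cumsum(!grepl(" C$", r$values)))
  out$ss_element <- rep(elem_of_run, r$lengths)
  out
}
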