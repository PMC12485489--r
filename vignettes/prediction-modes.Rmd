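---
title: "Classifying AlphaFold2 predictions into per-residue modes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying AlphaFold2 predictions into per-residue modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barbedwire)
```

## The problem

AlphaFold2 emits coordinates for every residue of every submitted sequence,
whether or not it has any business doing so, and reports its per-residue
confidence as pLDDT in the B-factor field. High-pLDDT regions are usually
usable as-is. Low-pLDDT regions are heterogeneous: some are well-packed,
cleanly built structure that happens to score badly and is often close to
the experimental truth; some are isolated helix- or strand-shaped ribbon
with no tertiary contacts and no hydrogen-bonding partner (including long
polyproline-II runs on proline-rich sequence); and some are wide looping
coil whose backbone is physically impossible — dense Ramachandran outliers
concentrated at high ψ, twisted and cis-nonPro peptide bonds, and C–N–CA
bond angles systematically compressed by about 4σ. This package separates
those regimes residue by residue, because they call for opposite downstream
decisions: keep the coordinates, or read them only as a disorder signal.

## The classification

Each residue is measured three ways and then pushed through a fixed
decision tree.

**pLDDT.** Taken from the CA B-factor (mean over the residue's atoms if CA
is absent). Files on the 0–1 dialect (all B ≤ 1) are rescaled by 100; a
silent misread here would flip every downstream call, so the rescaling is
announced. The high-confidence boundary is pLDDT ≥ 70, inclusive.

**Packing.** Steric contacts are unordered pairs of non-hydrogen atoms whose
van der Waals gap (center distance minus summed radii) is at most 0.5 Å.
Two exclusions restrict the count to *tertiary* structure: pairs whose
residues belong to the same secondary-structure element, and same-chain
pairs within a sequence separation of 4 (ordinal position within the chain;
inter-chain pairs are always eligible). The packing score of residue *i* is
the number of surviving contacts touching any residue of the window
*i*−2..*i*+2, divided by the number of heavy atoms in that window, with the
window truncated at chain termini and breaks so the score stays
well-defined at edges. A residue is packed when its score exceeds 0.6
(helix or coil) or 0.35 (β-strand, whose richest contacts were excluded
with its sheet). Contacts are found with a cell-list spatial index whose
output is checked against a naive all-pairs scan in the test suite.

The original analysis counts dot contacts on hydrogen-added models; this
package instead counts unique heavy-atom pairs against a packaged
united-atom radius table (carbons and nitrogens bearing implicit hydrogens
are inflated). The 0.6/0.35 cutoffs are retained as defaults but exposed in
`bw_config()`, since the two contact currencies need not be on identical
scales. Whether "number of different steric contacts" means unique pairs or
unique partner atoms is ambiguous; we count unique pairs, the most literal
reading.

**Secondary structure** is assigned from CA geometry alone, since the
packing exclusions need elements, not hydrogen bonds: residue *i* opens a
helix candidate when the CA(*i*)–CA(*i*+3) distance lies in [4.5, 6.0] Å
and the four-CA pseudo-dihedral in [+35°, +65°]; a strand candidate when
CA(*i*)–CA(*i*+2) lies in [6.2, 7.2] Å with pseudo-dihedral magnitude
≥ 120°. A candidate marks its whole span, runs shorter than 4 (helix) or 3
(strand) revert to coil, and no element crosses a chain break. The bins are
our own calibration — chosen once to accept ideal helix (measured
d₁₃ = 5.24 Å, μ = +51.5°) and extended strand with margin while rejecting
polyproline II (d₁₃ = 9.25 Å, d₀₂ = 6.6 Å but |μ| = 106°) — and are all
config keys. Note the consequences: unpaired strands still receive the
0.35 cutoff (geometry-only assignment, no pairing requirement), and a
stretched pseudostructure helix may or may not pass the helix test, which
only moves it between two cutoffs that are themselves configurable.

**Validation flags.** Per residue: Ramachandran outlier against a packaged
coarse rectangular allowed-region map keyed by residue class (general,
Gly, Pro, pre-Pro), with two derived signature regions — the high-ψ band
(+60° < ψ < +170°) and the upper-right box (−15° < φ < +170° within that
band); ω state with the conventional thresholds |ω| ≤ 30° cis,
30°–150° twisted, else trans, stored on the later residue of each peptide
bond; a CA-geometry check that flags residues whose
(μ_in, μ_out) pseudo-dihedral pair falls outside a packaged coarse allowed
map or whose CA pseudo-angle leaves [70°, 155°]; and covalent-geometry
z-scores of seven backbone terms (N–CA, CA–C, C–N lengths; N–CA–C, CA–C–N,
C–N–CA, CA–C–O angles) against a single Engh–Huber-style target table,
outliers at |z| > 4. The Ramachandran and CA maps are deliberately coarse
polygonal stand-ins for the contour tables used by full validation stacks:
the classifier only consumes outlier calls plus the quoted boxes, both maps
are plain-text and config-replaceable, and externally computed per-residue
calls (e.g. authentic CaBLAM output) can be imported with
`apply_external_validation()` to override the built-in flags. Only outright
outliers feed the classifier; "disfavored" intermediate calls do not exist
in this proxy.

**Signature outliers and outlier density.** A residue carries a *signature*
outlier if (a) it is a Ramachandran outlier in the upper-right box; (b) it
is a CA-geometry outlier *and* sits in a low-pLDDT unpacked context (the
same outlier is permitted in predictive regions); (c) it shares a peptide
bond carrying a C–N–CA |z| > 4, a cis-nonPro, or any twisted ω — both
residues of such a bond are marked; or (d) it is a cis-Pro in a low-pLDDT
unpacked context. A residue has *high outlier density* when at least two of
four criteria hold over the window *i*−1..*i*+1 (truncated at termini and
breaks to the available residues): ≥ 2 residues with cis-nonPro/twisted
bonds; ≥ 2 CA-geometry outliers; ≥ 2 covalent-geometry outliers; all
available residues in the high-ψ band with ≥ 1 Ramachandran outlier.

**Decision tree and smoothing.** pLDDT ≥ 70 → packed ? `predictive` :
`unpacked_high_plddt` (validation outliers are rare there and define no
further modes). pLDDT < 70, packed → outliers ? `unphysical` :
`near_predictive`. pLDDT < 70, unpacked → outliers ? `barbed_wire` :
`pseudostructure`. Two smoothing passes then remove fragmentation: first,
1–2-residue pseudostructure runs flanked on *both* sides by the *same* mode
(barbed wire, or near-predictive) take the flanking mode; second, remaining
1–2-residue barbed-wire runs flanked by pseudostructure become
pseudostructure. We read "surrounded on both sides by X or by Y" as two
homogeneous cases, so mixed flanks never smooth — a divergence risk we
accept and note. Runs touching a terminus or break are never smoothed
(one flank is missing), `unphysical` never participates, and no other mode
ever changes. Smoothing is verified against an independently written
brute-force reference on every mode string of length ≤ 8 and is idempotent.

## The synthetic-structure generator

Because the rules above are sharply geometric, every one of them can be
exercised with structures built from internal coordinates; no downloads are
involved anywhere in the package. `build_backbone()` places N/CA/C/O (+CB
for non-Gly) sequentially from per-residue (φ, ψ, ω) and the ideal geometry
table, with named per-site overrides of any bond length or angle;
`analyze_backbone()` inverts it, and the round trip recovers all dihedrals
and overrides to 10⁻⁶ degrees (tested on random specs). On top of it,
`make_fixture()` provides:

* `helix_bundle` — two antiparallel ideal helices (chains A/B) at 6.2 Å
  axis separation, phased to interdigitate. With only backbone + CB atoms a
  fixture needs tighter spacing than a real side-chain-bearing bundle to
  reach the same contact density; 6.2 Å puts every residue's packing score
  above 1.1, comfortably past the 0.6 cutoff, and steric overlap is
  irrelevant to the classifier.
* `lone_helix`, `lone_strand`, `ppii` — single isolated elements: clean
  geometry, zero tertiary contacts by construction.
* `barbed_coil` — a slowly varying dihedral base drawn from the upper-right
  band (φ₀ ∈ (−7, 162), ψ₀ ∈ (68, 162), ±8° per-residue jitter, clamped to
  the signature box), with 25% of peptide bonds set to ω = ±130° (twisted)
  or +8° (cis-nonPro) and 25% of C–N–CA angles compressed to −4.5σ — past
  the |z| > 4 flag threshold, matching the observed distortion peak near
  −4σ. A base whose coil still curls back on itself (any nonlocal CA pair
  closer than 8.5 Å) is redrawn: the emulated regime is *wide* looping
  coil, and an unconstrained per-residue draw instead produces a compact
  tangle that self-packs, which is exactly what barbed wire is not. The
  25% rates are our chosen study condition: dense enough that nearly every
  residue is within one bond or one window of a signature outlier, as the
  regime's description demands.
* `mixed` — helix (pLDDT 85), PPII (40) and barbed coil (30) concatenated
  on one chain across > 2.5 Å C–N gaps, exercising chain-break handling.

Everything is deterministic under `seed`, and generation restores the
caller's RNG state.

What the generator does *not* emulate: side chains beyond CB, hydrogen
bonding, sheets with real pairing, clash-free packing, or the pLDDT noise
of real predictions. Passing fixtures therefore demonstrate that the
decision rules are implemented exactly as stated and behave correctly on
unambiguous instances of each regime — not that the packaged coarse
Ramachandran/CA maps reproduce any particular validation stack's outlier
calls on borderline real-world geometry. For fidelity studies on real
models, replace the maps (`rama_map_path`, `ca_map_path`) or import
external calls.

## Numerical choices and degenerate inputs

* Dihedrals are IUPAC-signed, in (−180°, 180]; the builder and analyzer
  share one convention, so round trips are exact to floating-point.
* ω and the inter-residue covalent terms (C–N, CA–C–N, C–N–CA) are stored
  on the *later* residue of the bond; the both-residues marking of rule (c)
  is applied in the signature step via partner lookup.
* A chain break is declared when C(*i*−1)–N(*i*) exceeds 2.5 Å (~1.8× the
  ideal bond) or an atom is missing; no dihedral, z-score, window or
  smoothing run spans a break.
* Missing atoms yield `NA` fields and "unevaluated" flags (false), never
  errors; terminal residues are unevaluated for CA geometry.
* Altlocs keep the highest-occupancy conformer (ties: first altloc id).
  Waters/ligands are dropped; multi-model files use model 1 with a warning.
* Tie between helix and strand candidate marks: helix wins.
* The helix/strand bins, both packing cutoffs, the gap cutoff, |z| and ω
  thresholds, the pLDDT boundary and the break cutoff are all `bw_config()`
  keys; defaults are the published values where stated, our calibration
  where not (flagged above).

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
structures: fixtures of 10–36 residues (≤ 500 atoms), 50 random-fixture
contact-oracle comparisons, 100 random builder round-trips, exhaustive
smoothing enumeration to length 8 (9 840 strings) and the 16-branch
decision table. These sizes give exact or exhaustive coverage of every
rule; nothing in the method scales worse than the contact enumeration,
which is linear-ish in atoms via the cell list.

## Known limitations

* The Ramachandran and CA-geometry maps are coarse by design; absolute
  outlier rates on real structures will differ from full-contour
  validation, though the signature *boxes* (the load-bearing part of the
  barbed-wire logic) are exact.
* Secondary-structure assignment is CA-geometric; it does not require
  strand pairing, and heavily stretched helices may land in coil.
* The packing score's absolute scale differs from dot-based contact
  scoring; tune the cutoffs if you replace the radius table.
* Cβ-deviation, rotamer and clash analysis are out of scope (not
  diagnostic for these regimes).
* One structure, first model only; no assemblies, no PAE, no rescoring.

## Session info

```{r}
sessionInfo()
```
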