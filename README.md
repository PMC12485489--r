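# barbedwire

Per-residue prediction-mode analysis of AlphaFold2 models in R.

AlphaFold2 writes its per-residue confidence (pLDDT, 0–100) into the
B-factor field of the files it produces, and a pLDDT ≥ 70 rule of thumb is
widely used to trim predictions before downstream use. But the low-pLDDT
remainder is not one thing. Some of it is compact, cleanly built protein
whose coordinates are nearly right despite the low score; some of it is
isolated secondary-structure mimicry with no tertiary contacts; and some of
it is *barbed wire* — wide, rigid looping coil saturated with backbone
geometry violations (high-ψ Ramachandran outliers, twisted and cis-nonPro
peptide bonds, C—N—CA bond angles systematically compressed by ~4σ) that no
real polypeptide could adopt. These regimes carry very different
information: one is a usable structure, another is a sequence-level
disorder signal wearing impossible coordinates.

`barbedwire` classifies every residue of a predicted structure into one of
six modes by combining three measurements:

1. **pLDDT** — read from the B-factor of each residue's CA (0–1-scale files
   are auto-rescaled).
2. **Packing score** — tertiary steric contacts per non-hydrogen atom over
   a five-residue window *i*−2..*i*+2. A contact is a heavy-atom pair whose
   van der Waals surfaces approach within 0.5 Å, excluding pairs inside one
   secondary-structure element and same-chain pairs with |Δ*i*| ≤ 4, so
   only tertiary structure counts. Packed means score > 0.6 for helix/coil
   residues, > 0.35 for β-strand residues (whose intra-sheet contacts were
   excluded).
3. **Validation flags** — Ramachandran outliers (with the upper-right box
   −15° < φ < +170°, +60° < ψ < +170° and the high-ψ band as signature
   regions), peptide-bond ω state (cis/twisted/trans), a CA-trace geometry
   check, and covalent bond-length/angle z-scores against ideal backbone
   geometry (|z| > 4 is an outlier).

The decision tree branches on pLDDT (≥ 70), then packing, then outliers:

| pLDDT | packed | signature/density outliers | mode |
|-------|--------|---------------------------|------|
| ≥ 70  | yes    | (not used)                | `predictive` |
| ≥ 70  | no     | (not used)                | `unpacked_high_plddt` |
| < 70  | yes    | no                        | `near_predictive` |
| < 70  | yes    | yes                       | `unphysical` |
| < 70  | no     | no                        | `pseudostructure` |
| < 70  | no     | yes                       | `barbed_wire` |

followed by two smoothing passes that absorb isolated 1–2-residue islands of
pseudostructure (into flanking barbed wire or near-predictive) and of barbed
wire (into flanking pseudostructure).

## Worked example

The package ships a deterministic generator of synthetic structures covering
every regime, so the full pipeline can be exercised without downloading
models. The `"mixed"` fixture concatenates a lone helix (pLDDT 85), a
polyproline-II ribbon (pLDDT 40) and a distorted barbed-wire coil (pLDDT 30)
on one chain across chain breaks:

```r
library(barbedwire)

s   <- make_fixture("mixed", length = 10, seed = 3)
fit <- bw_analyze(s)
fit
#> Prediction-mode analysis: 30 residues, 1 chain(s)
#>   unpacked_high_plddt     10 (33.3%)
#>   pseudostructure         11 (36.7%)
#>   barbed_wire              9 (30.0%)
```

The helix is confidently predicted but touches nothing, so it is
`unpacked_high_plddt`; the PPII ribbon has legal geometry but no packing
(`pseudostructure`); the coil segment carries signature outliers at almost
every residue (`barbed_wire` — 9 of its 10 residues here; the chain-final
residue has no following peptide bond to incriminate it and stays
`pseudostructure`). `tidy(fit)` returns the full per-residue tibble
(φ/ψ/ω, packing score, every flag, the raw and smoothed mode, and the
six-position `Lprocg` label — e.g. residue 27 above is `Lproc-`: low pLDDT,
low packing, Ramachandran + ω + CA-geometry outliers); `glance(fit)` gives
one-row mode totals and `autoplot(fit)` draws pLDDT and packing along the
sequence over a mode-colored band.

Results can be written as JSON or aligned text (`write_annotation_json()`,
`write_annotation_text()`), as kinemage markup with per-mode togglable,
color-coded balls on each CA and Lprocg labels (`write_kinemage()`, viewable
in KiNG), or as a pruned PDB keeping selected modes only
(`write_selection()`, default `predictive` + `near_predictive`).

For real models: `bw_analyze("AF-P60228-F1-model_v4.pdb")` (PDB or mmCIF).
A command-line front end with phenix-style flags lives at
`inst/cli/barbed_wire_analysis.R`:

```sh
Rscript inst/cli/barbed_wire_analysis.R analyze input=model.pdb output.type=kin
Rscript inst/cli/barbed_wire_analysis.R analyze input=model.pdb \
    output.type=selection_file modes=predictive,near_predictive
Rscript inst/cli/barbed_wire_analysis.R compare input=model.pdb tracks=mobidb.json
```

The `compare` subcommand reproduces the disorder-annotation overlap
analysis: modes are pruned to unambiguous segment cores (trim 3 from each
end of a pre-smoothing run, keep cores ≥ 3), then the fraction of retained
residues inside each user-supplied annotation range is tabulated.

## Kinemage dialect

The writer emits a minimal subset of the kinemage format: `@kinemage`,
`@title`, `@group`, one `@vectorlist` (CA trace), one `@balllist` per mode
with `master=` toggles, and an `@labellist` of Lprocg strings. Default mode
colors: predictive blue, unpacked high-pLDDT gray, near-predictive green,
pseudostructure gold, barbed wire red, unphysical purple (configurable via
`bw_config(mode_colors = ...)`).
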