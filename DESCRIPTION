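Package: barbedwire
Title: Per-Residue Prediction-Mode Analysis of AlphaFold2 Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Categorizes each residue of an AlphaFold2 predicted structure into
    one of six prediction modes (predictive, unpacked high-pLDDT, near-predictive,
    pseudostructure, barbed wire, unphysical) by combining the per-residue pLDDT
    confidence stored in the B-factor field with a tertiary-contact packing score
    and a panel of backbone-geometry validation flags (Ramachandran, peptide-bond
    omega, CA-trace geometry, covalent bond lengths and angles). Provides text,
    JSON, kinemage-markup and mode-pruned PDB outputs, a deterministic synthetic
    structure generator covering every conformational regime the classifier
    distinguishes, and an optional comparison of modes against user-supplied
    disorder-annotation tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
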