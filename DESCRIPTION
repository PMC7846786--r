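Package: dualfv
Title: Dual-Paratope Antibody Fv Engineering Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for engineering bispecific antibody Fab fragments that
    carry two independent paratopes on a single VH3-Vk1 Fv. Provides
    template-based Kabat numbering and CDR annotation under multiple scheme
    definitions, H-side/L-side paratope partitioning with scaffold stability
    auditing (kinked-HCDR3 rules, invariant interface residues), merging of
    monospecific binders into bispecific sequences with per-position
    provenance, phage-display diversification library design with exact
    theoretical diversity and seeded sampling, and structural analyses of
    antibody-antigen complexes: Shrake-Rupley solvent-accessible surface
    areas, buried-surface paratope footprints with CDR attribution, Kabsch
    superposition, ternary co-binding models with steric clash detection, and
    Matthews coefficient/solvent content. Includes four-parameter logistic
    dose-response fitting and a DLS-bead viscosity conversion, plus a seeded
    synthetic-fixture generator for download-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    dplyr,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
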