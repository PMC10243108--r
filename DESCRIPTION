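Package: decoyFLR
Title: Decoy Amino Acid Post-Processing for PTM Site Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of peptide-spectrum-match (PSM) site tables from
    phosphoproteomics searches run with a decoy amino acid (alanine, "pAla").
    Provides binomial adjustment of site localization scores by observation
    frequency, global false localization rate (FLR) estimation from decoy
    matches with conservative per-PSM decoy propagation and q-value style
    monotonisation, collapsing from PSM-site to peptidoform-site and
    protein-site level by four strategies, multi-dataset meta-analysis with
    Gold/Silver/Bronze confidence classes, and a seeded synthetic-data
    generator with ground-truth localization labels for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
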