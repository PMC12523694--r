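Package: singlestep
Title: Single-Step GBLUP Evaluation with Blending, Tuning and Scaling of the Hybrid Relationship Matrix
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-step genomic BLUP (ssGBLUP) evaluation of dairy
    populations: pedigree renumbering and numerator relationship matrices
    (tabular A and the Meuwissen-Luo sparse inverse with inbreeding), genotype
    quality control and the VanRaden genomic relationship matrix, blending,
    tuning (TG0-TG4) and tau/omega scaling of the hybrid H inverse, the
    single-trait repeatability animal model solved from Henderson's mixed model
    equations, forward validation with realized accuracy, parameter sweeps over
    blending/tuning/scaling grids, and a synthetic dairy-population generator
    (multi-generation pedigree, gene-dropped SNP genotypes, repeated lactation
    records with herd-year-season structure) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
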