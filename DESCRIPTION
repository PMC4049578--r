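Package: mmpevol
Title: Hydropathy and Ser/Thr Composition of Mitochondrial Membrane Proteins
    Across Metazoan Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative analysis of the 13 mtDNA-encoded membrane proteins
    (ND1-ND6, ND4L, CYTB, CO1-CO3, ATP6, ATP8) across animal groups:
    per-site hydrophobicity profiles smoothed by an iterated three-site
    moving average, the scalar hydrophobicity HYD (mean of the smoothed
    profile over its positive domain), Thr/Ser/Cys composition and total
    site number over nested protein sets, the allometric transform from
    mass-specific to per-mitochondrion basal metabolic rate with its
    scaling-adjustment parameter F (including the F-sweep that maximises
    the Ser/Thr-composition correlation), a correlation/regression battery
    linking composition to metabolic rate and maximum lifespan, and a
    neighbor-joining tree of animal groups built from a variance-scaled
    composition distance.  Includes a seeded synthetic-cohort generator so
    the whole pipeline is testable without any sequence download.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ape,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
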