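Package: triocnv
Title: Trio-Based Rare Copy Number Variant Analysis from Low-Pass Genome
    Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Read-depth copy number variant (CNV) analysis for trio-based
    low-pass (~0.25-0.3 fold) whole-genome sequencing. Turns binned read
    counts into GC-corrected, panel-normalized copy ratios on a 5-kb fine
    grid and a 50-kb sliding grid; calls aneuploidies and CNVs with mosaic
    level estimation, change-point breakpoint refinement and statistical
    false-positive filters; assigns de novo or inherited status from
    parental profiles; filters to rare variants against a population
    panel; annotates gene content and assigns a simplified clinical
    category with ISCN/HGVS-style nomenclature; and summarises cohort
    incidences with Wilson confidence intervals. A synthetic coverage
    simulator generates trios and population panels with implanted
    constitutional and mosaic CNVs and machine-readable truth sets.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
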