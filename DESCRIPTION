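Package: intronscape
Title: Comparative Evolution of Organellar Group II Introns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of organellar group II introns:
    family definition from shared insertion sites and sequence homology,
    rule-based annotation of ribozyme secondary-structure features (domain
    layout, terminal motifs, branch-point adenosine, EBS-IBS recognition
    interfaces, subgroup-diagnostic junction motifs), detection and
    classification of intron-encoded proteins (reverse transcriptase/maturase
    and LAGLIDADG homing endonuclease), occurrence-frequency analysis across
    genome cohorts, and neighbor-joining phylogenetics with bootstrap support
    and Robinson-Foulds congruence tests between RNA-scaffold and protein
    trees. Includes a synthetic cohort generator that emulates the structural
    and statistical properties of mitochondrial and chloroplast group II
    intron repertoires, so the whole pipeline is testable end to end with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    car,
    GenomicRanges,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
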