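Package: oncoprofiler
Title: Microsatellite Instability, Tumor Mutational Burden, and Structural
    Variant Calling for Targeted Pan-Solid-Tumor Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bioinformatics core of a targeted pan-solid-tumor comprehensive
    genomic profiling workflow. Implements microsatellite-instability (MSI)
    detection from mononucleotide-repeat tract length distributions (local
    realignment against flanking seeds, stutter-robust peak finding) combined
    with a position-weight-matrix mutation-context signature in a linear
    ensemble classifier; tumor-mutational-burden (TMB) estimation from
    filtered somatic variant tables with exome-equivalent extrapolation and a
    CLSI EP17-A limit of blank; in silico simulation of TMB accuracy as a
    function of targeted-panel size under a metastatic-population weighting;
    simplified coverage-based amplification and discordant-read-pair
    translocation calling; diagnostic agreement statistics (PPA/NPA, Wilson
    intervals, variance-component CVs); and synthetic-data generators with
    known ground truth for every input the toolkit consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
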