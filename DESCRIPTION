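Package: cladecall
Title: Novelty-Aware Strain-Level Metagenomic Profiling with Clade-Specific SNV Barcodes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds hierarchical intraspecies reference databases of
    clade-specific single-nucleotide variants (SNV barcodes) from whole-genome
    allele-count tables and a species phylogeny, and classifies metagenomic
    samples against them with a Bayesian zero-inflated negative-binomial model
    that jointly estimates each clade's relative abundance and its divergence
    from the nearest reference clade.  Includes a synthetic-data generator and
    benchmark harness for hold-out (novel-diversity) and multi-strain mixture
    experiments, and a command-line interface covering the makedb, classify
    and benchmark workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    optparse,
    phangorn,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
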