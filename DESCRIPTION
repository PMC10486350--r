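Package: glutenscreen
Title: Immunogenic Epitope Screening and Targeted Quantitation of Gluten
    Peptides
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for screening prolamin (gluten) proteins and peptides for
    coeliac-disease-relevant immunogenic epitopes and for aggregating targeted
    mass-spectrometry (multiple reaction monitoring, MRM) peak areas into
    peptide-, protein-class- and sample-level gluten abundance summaries.
    Implements in silico trypsin and chymotrypsin digestion with the
    proline-suppression rule, overlapping motif scanning against R5 antibody
    motifs and HLA-DQ epitope cores, the intact-core (nine-residue) criterion
    for peptide-level immunogenicity, transition-level peak-area summation
    with replicate coefficients of variation, net hordein totals excluding
    avenin-like proteins, wheat-contamination marker panels, and
    ELISA-versus-LC-MS concordance reports. Includes seeded simulators for
    prolamin-like repetitive sequences with planted epitopes and for MRM
    transition tables with known ground-truth abundances, so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
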