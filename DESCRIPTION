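Package: apomut
Title: APOBEC3 Mutagenesis Analysis in Clonal Lineages
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to measure de novo APOBEC3 mutagenesis in single-cell-derived
    clone lineages from somatic single-base-substitution (SBS) call tables:
    locus- and lineage-level mutation filtering against parent/reference
    samples, sequence-context classification into 6/96/288/1536 channel
    systems, fold-enrichment of cytosine mutations at TCN/TCA/YTCA/RTCA
    motifs against genomic context availability, simulation-calibrated
    detection of clustered mutations (kataegis, omikli, doublets, multibase
    runs) via sample-dependent intermutation-distance cutoffs, penalized
    non-negative refitting of mutation catalogues onto reference signature
    sets, and the Mann-Whitney/Benjamini-Hochberg comparisons used to contrast
    genotypes. A fully synthetic clone-lineage study generator with recorded
    ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    optparse
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    yaml
Config/testthat/edition: 3
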