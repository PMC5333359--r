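Package: pqtlpipe
Title: Genome-Wide Mapping of Protein Quantitative Trait Loci with
    Replication and Network Integration
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for plasma protein quantitative trait
    locus (pQTL) discovery. Provides variant quality control (call rate,
    minor allele frequency, exact Hardy-Weinberg testing), inverse-normal
    trait transformation, additive linear-model association scans with
    covariate adjustment, genomic-inflation diagnostics, two-stage
    linkage-disequilibrium lumping of association signals into sentinel
    loci with cis/trans classification, conditional multi-variant variance
    decomposition, p-gain statistics for ratio traits, replication in an
    independent cohort with tag-SNP selection and subsampling-based power
    estimation (p95), shrinkage-estimated Gaussian graphical models of the
    trait panel, and assembly of an integrated SNP-protein-disease network
    with GraphML/JSON export. A synthetic-cohort generator with known
    ground truth supports calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
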