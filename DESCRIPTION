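Package: domannot
Title: Probabilistic Gene Ontology Annotation of Protein Structural Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns Gene Ontology (GO) terms to protein structural domains by
    integrating four evidence channels: structural-neighbor voting over
    protein-domain mappings filtered by protein structure distance, InterPro
    domain mapping fractions, support vector machine classifiers over
    auto-covariance-compressed PSSM profiles with sigmoid-calibrated
    probabilities, and E-value-weighted transfer from sequence homologs.
    Channel scores are fused by a binned likelihood-ratio naive-Bayes
    integrator into a posterior probability per (domain, term) pair.
    Includes CAFA-style precision-recall / Fmax evaluation, train-test
    decontamination by sequence identity, readers for the standard input
    formats (OBO, GAF, BLAST tabular, PSI-BLAST ASCII PSSM, InterProScan
    TSV, InterPro2GO), and a synthetic-fixture generator with known
    ground-truth parameters for desk-scale testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
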