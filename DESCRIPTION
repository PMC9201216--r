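Package: ppinet
Title: Patient Protein-Protein Interaction Network Clustering for
    Case/Control Exome Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for case/control exome cohort analysis by
    patient-specific protein-protein interaction (PPI) networks. Variants
    are filtered on site quality and predicted deleteriousness
    (PolyPhen-2 HDIV, SIFT, CADD, reference minor allele frequency),
    tested for genotype association between cases and controls with exact
    or Monte Carlo Fisher tests on 2x3 genotype tables, and each
    patient's top-ranked seed genes are expanded into a PPI subnetwork on
    a STRING-style interactome using paths of length at most two. Patients
    are clustered by Jaccard distance between their networks with UPGMA,
    clusters are tested for case/control enrichment, and gene sets unique
    to case- and control-dominated clusters are compared with an
    interactome separation score and a hypergeometric over-representation
    test. A synthetic-cohort generator with a planted interactome disease
    module makes the full pipeline reproducible without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
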