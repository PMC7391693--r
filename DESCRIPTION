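Package: amlsig
Title: Survival-Divergent Subgroups and Molecular Signatures of DNMT3A-Mutant AML
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies DNMT3A-mutant acute myeloid leukemia patients into
    survival-divergent subgroups from binary somatic-mutation profiles
    (phi-coefficient distance with Ward.D2 hierarchical clustering), and
    provides the downstream molecular-signature machinery: Kaplan-Meier and
    log-rank survival comparison, exclusion-resampling robustness analysis,
    empirical-Bayes moderated-t differential expression of genes and miRNAs,
    miRNA to host-gene coexpression categorization, consensus lasso
    regulatory-network inference with covariance-test link significance, and
    transfer classification of independent patients by mutation-profile
    nearest neighbor or Kendall-tau nearest centroid.  A synthetic multi-omic
    cohort generator with planted ground truth supports end-to-end testing of
    every stage at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    limma,
    edgeR,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
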