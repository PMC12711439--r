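Package: hgtscreen
Title: Reassessment of Interkingdom Horizontal Gene Transfer Candidates in Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reassess published interkingdom horizontal gene transfer
    (HGT) candidates in plant genomes from taxonomically annotated gene trees.
    Provides homology-hit filtering with similarity, coverage and e-value
    thresholds; mapping of NCBI-style lineages onto a fixed supergroup scheme;
    support-aware collapsing and bipartition-based interrogation of unrooted
    gene trees (monophyly, maximal ingroup clades, neighbourhood census);
    a rule-based classifier assigning each candidate to one of six verdict
    categories (HGT, HGT_recipient_shifted, NoHGT, Inconclusive, Putative_EGT,
    Potential_Contamination); a genomic-context contamination rule; cohort
    summary tables; and a synthetic-data generator producing trees, hit tables
    and context records with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    phangorn,
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
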