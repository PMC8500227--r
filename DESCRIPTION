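Package: OrthoCover
Title: Targeted Functional Annotation of Ortholog Clusters and Prediction of
    Synergistic Species Interactions by Pathway Set-Cover
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates ortholog clusters of predicted proteins against a
    user-defined ortholog-reaction association database (ORAdb) with a
    two-stage (relaxed/restrictive) local-alignment search, evaluates
    boolean gene-protein-reaction (GPR) rules per genome to obtain a binary
    species-by-reaction capability table, and enumerates combinations of
    species whose combined genomic potential covers a user-defined pathway,
    optionally under single-species and transporter constraints. Includes a
    self-contained Smith-Waterman aligner with Karlin-Altschul bit-score and
    E-value statistics, importers for OrthoFinder orthogroup tables and
    BLAST 12-column tabular hits, pairwise clustering precision/recall
    metrics, a point-mutation coding-sequence simulator, and generators of
    synthetic communities with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
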