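Package: maitcr
Title: Single-Cell MAIT Cell TCR Repertoire Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-cell T cell receptor (TCR)
    repertoires of mucosal-associated invariant T (MAIT) cells profiled by
    CITE-Seq. Provides quality-control filtering, marker-based MAIT lineage
    gating, dual-modality (transcript plus antibody-derived-tag) CD4/CD8/DN
    subset assignment, alpha/beta chain pairing with dual-alpha detection,
    canonical versus noncanonical TCR classification (TRAV1-2 with
    TRAJ33/20/12 and TRBV6/TRBV20-1), per-subset V/J gene usage and
    diversity statistics, CDR3 length/positional/motif analysis, and fuzzy
    CDR3-epitope matching against a local reference table with in-silico
    single and double amino-acid insertions or deletions. A seeded
    synthetic-repertoire generator emulating the repertoire structure of
    published MAIT datasets makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr
Config/testthat/edition: 3
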