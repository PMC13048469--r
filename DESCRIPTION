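Package: domaintriage
Title: Post-Prediction Triage and ECOD-Style Accession of Parsed Protein Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the downstream annotation of protein domains parsed
    from predicted structures: quality ("judge") categorization from
    assignment confidence, secondary-structure content and reference
    coverage; multi-threshold sequence-identity clustering statistics;
    rank-weighted taxonomic diversity scoring of clusters; mapping of
    domains to Pfam families from HMMER hits by optimal selection of
    non-overlapping hits with tiered confidence; classification of the
    Pfam mapping gap (sensitivity gaps, underspecified sub-groups,
    unrepresented topology groups) including temporal capture across Pfam
    releases; and overlap-aware accession of candidate domains into an
    ECOD-style five-level hierarchy with creation of simple and composite
    family groups. Includes a synthetic-data generator that plants ground
    truth for every stage so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
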