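Package: CrossPhos
Title: Proteome-Wide Screen for Phosphosite Antibody Cross-Reactivity Candidates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens annotated phosphoserine and phosphotyrosine sites in a
    reviewed proteome for local sequence similarity to phosphosite-centered
    antibody epitope fragments, such as the six 13-mer windows around the
    phosphorylation sites of human alpha-synuclein (Y39, S87, Y125, S129,
    Y133, Y136). Candidate sites must match the seed exactly at the residues
    flanking the phosphosite; passing sites are scored by exact and
    PAM120-similar residue counts and by the longest matching stretch
    encompassing the phosphosite, then ranked by a five-key comparator.
    Includes a UniProtKB flat-text parser and writer, cross-organism
    commonality and biofluid-overlap summaries, TSV reporting, and a
    synthetic-proteome generator with planted, metric-controlled candidate
    sites plus an independent brute-force scoring oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    IRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
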