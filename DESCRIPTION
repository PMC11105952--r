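Package: orthoenrich
Title: Ortholog-Aware Gene-Set Enrichment Analysis for Zebrafish
    Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for functional enrichment analysis in zebrafish
    (Danio rerio) transcriptomics. Converts gene identifiers between NCBI
    Entrez, Ensembl, ZFIN and gene-symbol namespaces, maps genes between
    zebrafish and human through many-to-many orthology tables, and tests
    KEGG- and GO-style gene-set collections for enrichment by Fisher's
    exact test (hypergeometric overrepresentation) or by a cut-off-free
    logistic regression of set membership on -log differential-expression
    p-values with a Wald test. Human-annotated collections can be
    projected into zebrafish gene space through orthology and merged with
    zebrafish-native annotations, optionally keeping only pathways that
    lack a zebrafish counterpart, so that pathways and diseases annotated
    only for human become testable in zebrafish experiments. Includes
    dot, bar and volcano plots of enrichment results and a seeded
    synthetic-data generator (mapping tables, duplication-aware orthology,
    gene-set collections, differential-expression tables with planted
    signal) for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, tools
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
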