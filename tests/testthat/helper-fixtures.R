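# shared in-code fixtures: everything is generated, nothing read from disk

write_tsv_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

toy_mapping <- function() {
  mapping_table(data.frame(
    ncbi = c("100", "200", "300"),
    zfin = c("ZDB-GENE-1", "ZDB-GENE-2", "ZDB-GENE-3"),
    symbol = c("shha", "pax2a", "fgf8a"),
    stringsAsFactors = FALSE))
}

toy_ortho <- function() {
  orthology_table(zfish_id = c("Z1", "Z2", "Z3", "Z3"),
                  human_id = c("H1", "H1", "H2", "H3"),
                  zfish_ns = "symbol", human_ns = "symbol")
}

# four-gene universe from the contingency hand example
toy_de <- function() {
  de_table(gene = c("g1", "g2", "g3", "g4"),
           pvalue = c(0.01, 0.20, 0.03, 0.90),
           log2fc = c(1.5, -0.7, -2.0, 0.3))
}

small_study <- function(seed = 11, n_genes = 400, n_sets = 12,
                        planted = NULL) {
  cfg <- sim_config(n_zfish_genes = n_genes, n_human_genes = n_genes,
                    n_sets = n_sets, set_size_range = c(10, 40),
                    planted_sets = planted, seed = seed)
  uni <- gen_mapping_table(cfg)$symbol
  coll <- gen_collection(cfg, uni)
  list(cfg = cfg, universe = uni, coll = coll,
       de = gen_de_table(cfg, uni, coll))
}
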