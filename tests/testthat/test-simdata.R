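test_that("generators are seed-deterministic and config-validated", {
  cfg <- sim_config(n_zfish_genes = 200, n_human_genes = 200,
                    n_sets = 20, seed = 99)
  expect_identical(gen_orthology(cfg), gen_orthology(cfg))
  uni <- gen_mapping_table(cfg)$symbol
  expect_identical(gen_collection(cfg, uni), gen_collection(cfg, uni))
  coll <- gen_collection(cfg, uni)
  expect_identical(gen_de_table(cfg, uni, coll),
                   gen_de_table(cfg, uni, coll))

  # byte-identical on disk too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_sim_study(cfg, d1); f2 <- write_sim_study(cfg, d2)
  for (k in c("map", "ortho", "sets", "de"))
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]))

  # a different seed changes the draws
  cfg2 <- sim_config(n_zfish_genes = 200, n_human_genes = 200,
                     n_sets = 20, seed = 100)
  expect_false(identical(gen_de_table(cfg2, uni, coll),
                         gen_de_table(cfg, uni, coll)))

  expect_error(sim_config(p_no_ortholog = 0.8, p_two_orthologs = 0.5))
  expect_error(sim_config(set_size_range = c(10, 5)))
})

test_that("substreams isolate artifacts: set count does not disturb gene draws", {
  a <- sim_config(n_zfish_genes = 300, n_sets = 10, seed = 7)
  b <- sim_config(n_zfish_genes = 300, n_sets = 99, seed = 7)
  uni <- gen_mapping_table(a)$symbol
  expect_identical(gen_de_table(a, uni), gen_de_table(b, uni))
  expect_identical(gen_orthology(a)$zfish_id, gen_orthology(b)$zfish_id)
})

test_that("mapping generator yields a fully-populated bijective table", {
  mt <- gen_mapping_table(sim_config(n_zfish_genes = 10))
  expect_equal(nrow(mt), 10L)
  expect_equal(names(mt), c("ncbi", "ensembl", "zfin", "symbol"))
  expect_true(all(!is.na(as.matrix(mt))))
  for (col in names(mt)) expect_equal(anyDuplicated(mt[[col]]), 0L)
})

test_that("orthology generator honours the duplication mixture", {
  base <- list(n_zfish_genes = 500, n_human_genes = 500, seed = 31)
  none <- do.call(sim_config, c(base, list(p_no_ortholog = 1,
                                           p_two_orthologs = 0)))
  expect_equal(nrow(gen_orthology(none)), 0L)

  bij <- do.call(sim_config, c(base, list(p_no_ortholog = 0,
                                          p_two_orthologs = 0)))
  ot <- gen_orthology(bij)
  expect_equal(nrow(ot), 500L)
  expect_equal(anyDuplicated(ot$human_id), 0L)

  big <- sim_config(n_zfish_genes = 5000, n_human_genes = 10000,
                    p_no_ortholog = 0.35, p_two_orthologs = 0.3, seed = 31)
  counts <- table(factor(table(gen_orthology(big)$human_id),
                         levels = c("1", "2")))
  n <- 10000
  freq0 <- 1 - sum(counts) / n
  freq1 <- counts[["1"]] / n
  freq2 <- counts[["2"]] / n
  se <- function(p) sqrt(p * (1 - p) / n)
  expect_lt(abs(freq0 - 0.35), 4 * se(0.35))
  expect_lt(abs(freq1 - 0.35), 4 * se(0.35))
  expect_lt(abs(freq2 - 0.30), 4 * se(0.30))
})

test_that("collection generator respects size range without duplicate members", {
  cfg <- sim_config(n_zfish_genes = 300, n_sets = 40,
                    set_size_range = c(5, 15), seed = 3)
  uni <- gen_mapping_table(cfg)$symbol
  coll <- gen_collection(cfg, uni)
  sizes <- lengths(coll$members)
  expect_true(all(sizes >= 5 & sizes <= 15))
  expect_true(all(vapply(coll$members, anyDuplicated, 0L) == 0L))
  expect_true(all(unlist(coll$members) %in% uni))
})

test_that("planted signal shifts p-values; a unit effect is the null", {
  cfg0 <- sim_config(n_zfish_genes = 1000, n_sets = 20,
                     set_size_range = c(50, 50), seed = 41)
  uni <- gen_mapping_table(cfg0)$symbol
  coll <- gen_collection(cfg0, uni)

  plant <- function(a) {
    cfg <- sim_config(n_zfish_genes = 1000, n_sets = 20,
                      set_size_range = c(50, 50),
                      planted_sets = data.frame(set_id = "dre00003",
                                                effect = a,
                                                direction = "up"),
                      seed = 41)
    gen_de_table(cfg, uni, coll)
  }
  members <- coll$members[[3]]

  de_null <- plant(1)  # Beta(1,1) is Uniform: indistinguishable from null
  expect_gt(stats::ks.test(de_null$pvalue[de_null$gene %in% members],
                           "punif")$p.value, 1e-3)

  de_sig <- plant(0.1)
  expect_lt(median(de_sig$pvalue[de_sig$gene %in% members]),
            median(de_sig$pvalue[!de_sig$gene %in% members]))
  # Beta(0.1, 1) median is 0.5^10 ~ 1e-3; order statistics put the
  # planted median far below the null's ~0.5 at n = 50
  expect_lt(median(de_sig$pvalue[de_sig$gene %in% members]), 0.1)
  # planted direction dominates the fold-change signs
  expect_gt(mean(de_sig$log2fc[de_sig$gene %in% members] > 0), 0.7)

  expect_error(plant_bad <- gen_de_table(
    sim_config(planted_sets = data.frame(set_id = "nope", effect = 0.5,
                                         direction = "up"), seed = 1),
    uni, coll), "planted set ids")
})

test_that("calibration harness is reproducible and warns on tiny rep counts", {
  cfg <- sim_config(n_zfish_genes = 300, n_sets = 15,
                    set_size_range = c(10, 30), seed = 23)
  expect_warning(calibration_run(cfg, "fisher", reps = 10), "50")
  r1 <- suppressWarnings(calibration_run(cfg, "fisher", reps = 20))
  r2 <- suppressWarnings(calibration_run(cfg, "fisher", reps = 20))
  expect_identical(r1, r2)
  expect_true(r1$type_I_rate >= 0 && r1$type_I_rate <= 1)
})

test_that("logistic test is calibrated on null data; the exact test is conservative", {
  # moderate-size null study: enough replicates for a meaningful rate but
  # fast enough for routine runs (the full-scale study lives in the
  # acceptance suite)
  cfg <- sim_config(n_zfish_genes = 800, n_sets = 60,
                    set_size_range = c(10, 60), seed = 77)
  lg <- calibration_run(cfg, "logistic", alpha = 0.05, reps = 60)
  expect_lt(abs(lg$type_I_rate - 0.05), 3 * lg$type_I_se + 0.005)
  fi <- calibration_run(cfg, "fisher", alpha = 0.05, reps = 60)
  # a discrete exact test never exceeds its nominal level
  expect_lte(fi$type_I_rate, 0.05 + 2 * fi$type_I_se)
})

test_that("equal_size_sets returns same-size sets for like-for-like planting", {
  cfg <- sim_config(n_zfish_genes = 500, n_sets = 80,
                    set_size_range = c(10, 20), seed = 2)
  coll <- gen_collection(cfg, gen_mapping_table(cfg)$symbol)
  ids <- equal_size_sets(coll, 3)
  expect_length(ids, 3L)
  expect_length(unique(lengths(coll$members[match(ids, coll$ids)])), 1L)
})
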