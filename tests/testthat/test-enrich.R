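test_that("DE tables collapse duplicates to the minimum p-value", {
  de <- de_table(c("g1", "g2", "g1"), c(0.5, 0.2, 0.01), c(1, -1, 2))
  expect_equal(nrow(de), 2L)
  expect_equal(de$pvalue[de$gene == "g1"], 0.01)
  expect_equal(de$log2fc[de$gene == "g1"], 2)
  expect_equal(attr(de, "n_collapsed"), 1L)
  # p = 0 is clamped so -log(p) stays finite
  expect_equal(de_table("g", 0)$pvalue, 1e-300)
  expect_error(de_table("g", 1.2), "0, 1")
})

test_that("contingency tables classify by membership and directional significance", {
  de <- toy_de()  # sig at 0.05: g1 (up), g3 (down)
  t <- build_contingency(de, c("g1", "g2"))
  expect_equal(unlist(t[c("a", "b", "c", "d")]),
               c(a = 1L, b = 1L, c = 1L, d = 1L))
  expect_equal(t$N, 4L)
  expect_false(t$degenerate)

  up <- build_contingency(de, c("g1", "g2"), direction = "up")
  expect_equal(up$a, 1L)   # g1 is up-significant
  down <- build_contingency(de, c("g1", "g2"), direction = "down")
  expect_equal(down$a, 0L)

  # all fold changes negative: no gene can be up-significant
  de2 <- de_table(c("a", "b"), c(0.01, 0.01), c(-1, -2))
  t2 <- build_contingency(de2, "a", direction = "up")
  expect_equal(t2$a + t2$b, 0L)

  expect_true(build_contingency(de, c("zz"))$degenerate)
  expect_error(build_contingency(de, "g1", sig_threshold = 1), "between")
})

test_that("contingency counts equal a brute-force double loop on random data", {
  study <- small_study(seed = 21)
  de <- study$de
  for (i in c(1, 5, 9)) {
    members <- study$coll$members[[i]]
    for (dir in c("nondirectional", "up", "down")) {
      t <- build_contingency(de, members, 0.05, dir)
      a <- b <- cc <- d <- 0L
      for (g in seq_len(nrow(de))) {
        sig <- de$pvalue[g] < 0.05 &&
          switch(dir, nondirectional = TRUE,
                 up = de$log2fc[g] > 0, down = de$log2fc[g] < 0)
        inset <- de$gene[g] %in% members
        if (inset && sig) a <- a + 1L
        else if (!inset && sig) b <- b + 1L
        else if (inset) cc <- cc + 1L
        else d <- d + 1L
      }
      expect_equal(unlist(t[c("a", "b", "c", "d")]),
                   c(a = a, b = b, c = cc, d = d))
    }
  }
})

test_that("hypergeometric point probability matches closed forms", {
  expect_equal(hypergeom_point_prob(list(a = 1, b = 1, c = 1, d = 1)), 2 / 3)
  # set equal to the whole universe: only one table is possible
  expect_equal(hypergeom_point_prob(list(a = 3, b = 0, c = 2, d = 0)), 1)
  expect_equal(hypergeom_point_prob(list(a = 5, b = 5, c = 5, d = 5)),
               63504 / 184756, tolerance = 1e-12)
})

test_that("fisher tail sums agree with enumeration and fisher.test", {
  expect_equal(fisher_pvalue(list(a = 0, b = 5, c = 3, d = 7), "over"), 1)
  expect_equal(fisher_pvalue(list(a = 4, b = 0, c = 6, d = 0), "over"), 1)

  t <- list(a = 8, b = 2, c = 2, d = 8)
  enum <- sum(vapply(8:10, function(a2)
    hypergeom_point_prob(list(a = a2, b = 10 - a2, c = 10 - a2,
                              d = a2)), 0))
  expect_equal(fisher_pvalue(t, "over"), enum, tolerance = 1e-12)

  set.seed(7)
  for (i in 1:25) {
    tt <- as.list(stats::setNames(sample(0:12, 4, TRUE),
                                  c("a", "b", "c", "d")))
    m <- matrix(unlist(tt), 2, byrow = TRUE)
    expect_equal(fisher_pvalue(tt, "over"),
                 stats::fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-10)
    expect_equal(fisher_pvalue(tt, "under"),
                 stats::fisher.test(m, alternative = "less")$p.value,
                 tolerance = 1e-10)
    # tail overlap identity: over + under counts the point mass twice
    expect_equal(fisher_pvalue(tt, "over") + fisher_pvalue(tt, "under"),
                 1 + hypergeom_point_prob(tt), tolerance = 1e-10)
  }
})

test_that("logistic fit is shift-invariant and zero on symmetric designs", {
  set.seed(2)
  x <- rexp(100)
  y <- rbinom(100, 1, plogis(-1 + 0.8 * x))
  f1 <- logistic_fit(x, y)
  f2 <- logistic_fit(x + 5, y)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  expect_equal(f2$alpha, f1$alpha - 5 * f1$beta, tolerance = 1e-6)

  # both classes see the same x multiset: slope must vanish
  f0 <- logistic_fit(c(1, 2, 3, 1, 2, 3), c(0, 0, 0, 1, 1, 1))
  expect_equal(f0$beta, 0, tolerance = 1e-10)
  expect_equal(wald_test(f0)$W, 0, tolerance = 1e-8)
  expect_equal(wald_test(f0)$pvalue, 1, tolerance = 1e-6)

  expect_error(logistic_fit(x, rep(1, 100)), "single class")
  expect_error(logistic_fit(1:3, c(0, 1)), "equal length")
})

test_that("logistic fit matches a reference GLM on a fixed toy dataset", {
  x <- c(0.1, 0.5, 1.2, 2.3, 0.7, 3.1, 0.2, 1.8, 2.9, 0.4)
  y <- c(0, 0, 1, 1, 0, 1, 0, 0, 1, 0)
  f <- logistic_fit(x, y)
  g <- stats::glm(y ~ x, family = stats::binomial,
                  control = stats::glm.control(epsilon = 1e-12))
  expect_equal(f$beta, unname(stats::coef(g)[2]), tolerance = 1e-6)
  expect_equal(f$alpha, unname(stats::coef(g)[1]), tolerance = 1e-6)
  expect_equal(f$se_beta, unname(summary(g)$coefficients[2, 2]),
               tolerance = 1e-6)
  expect_true(f$converged)
})

test_that("complete separation is diagnosed rather than reported as a fit", {
  x <- c(0, 0.1, 0.2, 5, 6, 7)
  y <- c(0, 0, 0, 1, 1, 1)
  f <- logistic_fit(x, y)
  expect_false(f$converged)
  expect_match(f$diagnostic, "separation|converge")
  expect_error(wald_test(f), "converge")
})

test_that("Wald p-values are invariant under affine rescaling of the evidence", {
  set.seed(4)
  x <- rexp(150)
  y <- rbinom(150, 1, plogis(-1.5 + x))
  p0 <- wald_test(logistic_fit(x, y))$pvalue
  expect_equal(wald_test(logistic_fit(3.7 * x, y))$pvalue, p0,
               tolerance = 1e-10)
  expect_equal(wald_test(logistic_fit(x + 11, y))$pvalue, p0,
               tolerance = 1e-10)
  # chi-square(1) quantile: |W| = 1.959964 sits at p ~ 0.05
  fake <- structure(list(beta = 1.959964, se_beta = 1, converged = TRUE),
                    class = "logistic_fit")
  expect_equal(wald_test(fake)$pvalue, 0.05, tolerance = 1e-6)
  expect_true(wald_test(fake)$enriched)
})

test_that("p-value adjustment follows BH step-up and stays monotone", {
  expect_equal(adjust_pvalues(0.03, "BH"), 0.03)
  expect_equal(adjust_pvalues(rep(0.2, 5), "BH"), rep(0.2, 5))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(c(0.01, 0.4), "bonferroni"),
               c(0.02, 0.8))
  expect_equal(adjust_pvalues(numeric(0), "BH"), numeric(0))

  set.seed(6)
  for (i in 1:10) {
    p <- runif(15)
    q <- pmin(p + runif(15, 0, 0.2), 1)
    expect_true(all(adjust_pvalues(p, "BH") >= p))
    # pointwise larger inputs never give pointwise smaller adjusted values
    expect_true(all(adjust_pvalues(q, "BH") >= adjust_pvalues(p, "BH") - 1e-12))
  }
})

test_that("pct_sig_genes recounts the contingency ratio", {
  de <- toy_de()
  expect_equal(pct_sig_genes(de, c("g1", "g2")), 50)
  expect_equal(pct_sig_genes(de, c("g2", "g4")), 0)
  study <- small_study(seed = 30)
  for (i in c(2, 7)) {
    m <- study$coll$members[[i]]
    t <- build_contingency(study$de, m)
    expect_equal(pct_sig_genes(study$de, m), 100 * t$a / (t$a + t$c))
  }
})

test_that("enrich_collection honours subsets, sorting and adjustment scope", {
  study <- small_study(seed = 12)

  one <- enrich_collection(study$de, study$coll[1], method = "fisher")
  expect_equal(one$adj_pvalue, one$pvalue)

  sub <- enrich_collection(study$de, study$coll, method = "fisher",
                           subset_ids = study$coll$ids[c(3, 5, 8)])
  expect_equal(nrow(sub), 3L)
  # BH over exactly the three tested sets
  expect_equal(sub$adj_pvalue, adjust_pvalues(sub$pvalue, "BH"))

  full <- enrich_collection(study$de, study$coll, method = "logistic",
                            direction = "both")
  expect_equal(nrow(full), 2L * length(study$coll))
  expect_true(!is.unsorted(full$pvalue))
  expect_true(all(full$adj_pvalue >= full$pvalue))
  expect_true(all(full$pct_sig_genes >= 0 & full$pct_sig_genes <= 100))
  # per-direction adjustment scope
  up <- full[full$direction == "UP", ]
  expect_equal(up$adj_pvalue[order(up$set_id)],
               adjust_pvalues(up$pvalue[order(up$set_id)], "BH"))

  expect_error(enrich_collection(study$de, study$coll,
                                 subset_ids = "nope"), "subset_ids")

  # a set wholly outside the universe is skipped and recorded
  coll2 <- study$coll
  coll2$members[[2]] <- c("alien1", "alien2")
  res2 <- enrich_collection(study$de, coll2, method = "fisher")
  expect_equal(nrow(res2), length(study$coll) - 1L)
  expect_equal(attr(res2, "skipped"), coll2$ids[2])
})

test_that("enrichment tables serialize to TSV and JSON", {
  study <- small_study(seed = 14)
  res <- enrich_collection(study$de, study$coll, method = "fisher")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment(res, f)
  back <- utils::read.delim(f)
  expect_equal(nrow(back), nrow(res))
  expect_equal(back$pvalue, res$pvalue, tolerance = 1e-12)
  fj <- withr::local_tempfile(fileext = ".json")
  write_enrichment(res, fj)
  expect_equal(length(jsonlite::read_json(fj)), nrow(res))
})
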