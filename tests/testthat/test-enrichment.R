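# Hypergeometric tails, correction, scoring and the per-ontology test.

test_that("upper tail matches closed forms and the subset-enumeration oracle", {
  # n_t = 0 spans the whole support
  expect_equal(hypergeometric_pvalue(5, 10, 0, 4), 1)
  # study equals background: only k = m_t is possible
  expect_equal(hypergeometric_pvalue(7, 7, 3, 3), 1)
  # frozen from exhaustive enumeration of the C(10,5) = 252 subsets:
  # 66 contain >= 3 of the 4 marked genes
  expect_equal(hypergeometric_pvalue(5, 10, 3, 4), 66 / 252,
               tolerance = 1e-14)
  oracle <- enum_hyper(5, 10, 3)
  expect_equal(hypergeometric_pvalue(5, 10, 2, 3), oracle$upper(2),
               tolerance = 1e-12)
})

test_that("lower tail matches the oracle and complements the upper tail", {
  expect_equal(depletion_pvalue(5, 10, 0, 4), 6 / 252, tolerance = 1e-14)
  # n_t at the top of the support spans the full lower tail
  expect_equal(depletion_pvalue(5, 10, 4, 4), 1)
  set.seed(5)
  for (i in 1:200) {
    m <- sample(2:60, 1)
    n <- sample(m, 1)
    m_t <- sample(0:m, 1)
    lo <- max(0L, n - (m - m_t))
    hi <- min(n, m_t)
    n_t <- if (lo == hi) lo else sample(lo:hi, 1)
    up <- hypergeometric_pvalue(n, m, n_t, m_t)
    dn <- depletion_pvalue(n, m, n_t, m_t)
    pm <- hypergeometric_pmf(n, m, n_t, m_t)
    expect_equal(up + dn - pm, 1, tolerance = 1e-12)
  }
})

test_that("pmf normalizes and the upper tail is monotone in n_t", {
  n <- 8; m <- 25; m_t <- 9
  lo <- max(0L, n - (m - m_t)); hi <- min(n, m_t)
  expect_equal(sum(vapply(lo:hi, function(k) hypergeometric_pmf(n, m, k, m_t),
                          numeric(1))), 1, tolerance = 1e-12)
  ps <- vapply(lo:hi, function(k) hypergeometric_pvalue(n, m, k, m_t),
               numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("log-space evaluation agrees with phyper and survives large counts", {
  set.seed(11)
  for (i in 1:50) {
    m <- sample(100:20000, 1)
    n <- sample(10:min(m, 500), 1)
    m_t <- sample(1:min(m, 900), 1)
    n_t <- sample(0:min(n, m_t), 1)
    if (n_t < max(0, n - (m - m_t))) next
    expect_equal(hypergeometric_pvalue(n, m, n_t, m_t),
                 stats::phyper(n_t - 1, m_t, m - m_t, n,
                               lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  big <- hypergeometric_pvalue(500, 20000, 100, 800)
  expect_true(is.finite(big) && big > 0 && big < 1)
})

test_that("count invariants are enforced with the violated inequality named", {
  expect_error(hypergeometric_pvalue(11, 10, 1, 4), "n <= m")
  expect_error(hypergeometric_pvalue(5, 10, 1, 11), "m_t <= m")
  expect_error(hypergeometric_pvalue(5, 10, 6, 8), "n_t <= n")
  expect_error(hypergeometric_pvalue(5, 10, 4, 3), "n_t <= m_t")
  expect_error(hypergeometric_pvalue(5, 10, -1, 3), "nonnegative")
})

test_that("the three corrections behave as specified", {
  expect_equal(adjust_pvalues(0.03, "bonferroni"), 0.03)
  expect_equal(adjust_pvalues(0.03, "holm"), 0.03)
  expect_equal(adjust_pvalues(0.03, "benjamini_hochberg"), 0.03)
  # step-up by hand: p * 4 / rank is 0.04 at every rank
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(rep(0.3, 5), "bonferroni"), rep(1, 5))
  expect_error(adjust_pvalues(c(0.1, 1.2), "holm"), "\\[0, 1\\]")
  set.seed(8)
  for (i in 1:50) {
    p <- stats::runif(sample(1:40, 1))
    bonf <- adjust_pvalues(p, "bonferroni")
    holm <- adjust_pvalues(p, "holm")
    bh <- adjust_pvalues(p, "bh")
    expect_true(all(holm <= bonf + 1e-15))
    expect_true(all(bh <= holm + 1e-15))
    expect_true(all(bonf >= p & holm >= p & bh >= p))
    expect_true(all(bonf <= 1 & holm <= 1 & bh <= 1))
  }
})

test_that("significance scores are -log10 with a capped zero", {
  expect_equal(as.numeric(significance_score(0.01)), 2)
  expect_equal(as.numeric(significance_score(1)), 0)
  expect_equal(as.numeric(significance_score(1e-25)), 25)
  s <- significance_score(0, max_score = 320)
  expect_equal(as.numeric(s), 320)
  expect_true(attr(s, "capped"))
  expect_error(significance_score(-0.1), "\\[0, 1\\]")
  expect_error(significance_score(1.5), "\\[0, 1\\]")
})

# helper: annotation set / ontology where all bg genes carry the root and a
# chosen few carry term X
two_term_setup <- function(n_marked = 3, n_bg = 100) {
  ont <- parse_obo(tiny_obo(list(
    list(id = "E:ROOT", name = "everything term"),
    list(id = "E:X", name = "marked trait", is_a = "E:ROOT")
  )), id = "E")
  genes <- sprintf("g%03d", seq_len(n_bg))
  marked <- genes[seq_len(n_marked)]
  asg <- rbind(
    data.frame(gene_id = genes, ontology_id = "E",
               term_accession = "E:ROOT", stringsAsFactors = FALSE),
    data.frame(gene_id = marked, ontology_id = "E",
               term_accession = "E:X", stringsAsFactors = FALSE))
  ann <- ontenrich:::new_annotation_set(
    asg, ontenrich:::empty_annotation_set()$provenance)
  list(ont = ont, ann = ann, genes = genes, marked = marked)
}

test_that("the closed-form example p = 1/161700 is reproduced", {
  s <- two_term_setup(n_marked = 3, n_bg = 100)
  res <- run_enrichment(s$marked, background_set("all", s$genes), s$ann,
                        s$ont, method = "bonferroni")
  row <- res[res$term_accession == "E:X", ]
  expect_equal(row$n_t, 3L)
  expect_equal(row$m_t, 3L)
  expect_equal(row$n, 3L)
  expect_equal(row$m, 100L)
  expect_equal(row$p_raw, 1 / 161700, tolerance = 1e-12)
  expect_equal(row$study_genes, paste(sort(s$marked), collapse = ","))
})

test_that("the minimum-gene rule blocks significance regardless of p", {
  s <- two_term_setup(n_marked = 2, n_bg = 1000)
  res <- run_enrichment(s$marked, background_set("all", s$genes), s$ann,
                        s$ont)
  row <- res[res$term_accession == "E:X", ]
  expect_lt(row$p_adjusted, 0.05)  # astronomically small
  expect_false(row$significant)    # but n_t = 2 < 3
  res3 <- run_enrichment(s$marked, background_set("all", s$genes), s$ann,
                         s$ont, min_genes = 2)
  expect_true(res3[res3$term_accession == "E:X", "significant"])
})

test_that("genes without annotation in the ontology are ignored in n and m", {
  s <- two_term_setup(n_marked = 3, n_bg = 50)
  # extend background with genes carrying no annotation at all
  bg <- background_set("all", c(s$genes, sprintf("x%02d", 1:50)))
  res <- run_enrichment(c(s$marked, "x01"), bg, s$ann, s$ont)
  expect_equal(unique(res$m), 50L)  # unannotated genes not counted
  expect_equal(unique(res$n), 3L)
  # study genes must be inside the background
  expect_error(run_enrichment("zz", bg, s$ann, s$ont), "resolve_study")
})

test_that("an ontology with no annotated study gene yields an empty notice", {
  s <- two_term_setup()
  other <- parse_obo(tiny_obo(list(list(id = "F:1", name = "other topic"))),
                     id = "F")
  expect_message(
    res <- run_enrichment(s$marked, background_set("all", s$genes), s$ann,
                          other),
    "nothing to test")
  expect_equal(nrow(res), 0L)
})

test_that("the planted fixture term ranks first by adjusted p", {
  fx <- make_fixture(seed = 7, n_genes = 1000)
  ann <- annotate_corpus(fx$corpus, fx$lexicon, fx$catalog)
  res <- run_all_ontologies(fx$study, fx$background, ann, fx$catalog)
  merged <- merge_by_name(res)
  expect_equal(merged$display_name[1],
               normalize_phrase(planted_name(fx$catalog, fx$spec)))
  expect_true(merged$significant[1])
  # and the ranking agrees with direct p computation across all terms
  flat <- do.call(rbind, res)
  expect_equal(min(flat$p_adjusted), merged$p_adjusted[1])
})

test_that("results are ordered by adjusted p, raw p, then accession", {
  fx <- make_fixture(seed = 43, n_genes = 200)
  ann <- annotate_corpus(fx$corpus, fx$lexicon, fx$catalog)
  res <- run_enrichment(fx$study, fx$background, ann,
                        fx$catalog$ontologies[["ONT1"]])
  key <- order(res$p_adjusted, res$p_raw, res$term_accession)
  expect_equal(key, seq_len(nrow(res)))
})

test_that("per-ontology results are independent of the rest of the catalog", {
  fx <- make_fixture(seed = 45, n_genes = 300)
  ann <- annotate_corpus(fx$corpus, fx$lexicon, fx$catalog)
  full <- run_all_ontologies(fx$study, fx$background, ann, fx$catalog)
  sub <- ontology_catalog(unname(fx$catalog$ontologies[1:2]))
  partial <- run_all_ontologies(fx$study, fx$background, ann, sub)
  expect_identical(partial[["ONT1"]], full[["ONT1"]])
  expect_identical(partial[["ONT2"]], full[["ONT2"]])
  # singleton catalog equals a direct run_enrichment call
  solo <- run_all_ontologies(fx$study, fx$background, ann,
                             ontology_catalog(list(fx$catalog$ontologies[["ONT3"]])))
  expect_identical(solo[["ONT3"]],
                   run_enrichment(fx$study, fx$background, ann,
                                  fx$catalog$ontologies[["ONT3"]]))
})

test_that("the tested family is exactly the terms with n_t >= 1", {
  fx <- make_fixture(seed = 47, n_genes = 200)
  ann <- annotate_corpus(fx$corpus, fx$lexicon, fx$catalog)
  res <- run_all_ontologies(fx$study, fx$background, ann, fx$catalog)
  # independent recount from the raw assignment table
  asg <- ann$assignments
  sasg <- asg[asg$gene_id %in% fx$study, ]
  for (oid in names(res)) {
    want <- sort(unique(sasg$term_accession[sasg$ontology_id == oid]))
    expect_setequal(res[[oid]]$term_accession, want)
    expect_true(all(res[[oid]]$n_t >= 1L))
  }
})

test_that("depletion mode flags terms absent from the study", {
  fx <- make_fixture(seed = 49, n_genes = 400, study_size = 40)
  ann <- annotate_corpus(fx$corpus, fx$lexicon, fx$catalog)
  dep <- run_enrichment(fx$study, fx$background, ann,
                        fx$catalog$ontologies[["ONT1"]],
                        direction = "depleted")
  expect_true(all(dep$direction == "depleted"))
  # lower-tail p must agree with the hand computation on the first row
  r <- dep[1, ]
  expect_equal(r$p_raw, depletion_pvalue(r$n, r$m, r$n_t, r$m_t))
})
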