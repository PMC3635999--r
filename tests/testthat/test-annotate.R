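# Concept matching, is_a propagation and corpus-wide annotation.

go_like_ontology <- function() {
  parse_obo(tiny_obo(list(
    list(id = "GO:0008150", name = "biological process"),
    list(id = "GO:0034514", name = "mitochondrial unfolded protein response",
         is_a = "GO:0008150"),
    list(id = "GO:0050783", name = "cocaine metabolic process",
         synonyms = "cocaine metabolism", is_a = "GO:0008150")
  )), id = "GO")
}

test_that("term names and synonyms are found verbatim in curated titles", {
  lex <- build_lexicon(go_like_ontology())
  m1 <- match_concepts(paste("ClpP mediates activation of a mitochondrial",
                             "unfolded protein response in C. elegans"), lex)
  expect_equal(m1$term_accession, "GO:0034514")
  m2 <- match_concepts(paste("Structural basis of heroin and cocaine",
                             "metabolism by a promiscuous human",
                             "drug-processing enzyme"), lex)
  expect_equal(m2$term_accession, "GO:0050783")
  expect_equal(m2$matched_phrase, "cocaine metabolism")
  expect_equal(nrow(match_concepts("", lex)), 0L)
})

test_that("reported offsets index the normalized text exactly", {
  lex <- build_lexicon(go_like_ontology())
  txt <- "Cocaine metabolism; also a mitochondrial unfolded protein response."
  m <- match_concepts(txt, lex)
  norm <- normalize_phrase(txt)
  for (i in seq_len(nrow(m))) {
    expect_equal(substr(norm, m$start[i] + 1L, m$end[i]),
                 m$matched_phrase[i])
  }
})

test_that("matches never fire inside words", {
  ont <- parse_obo(tiny_obo(list(list(id = "R:1", name = "rat"))), id = "R")
  lex <- build_lexicon(ont)
  expect_equal(nrow(match_concepts("a delicate operation", lex)), 0L)
  expect_equal(nrow(match_concepts("the rat runs", lex)), 1L)
  expect_equal(nrow(match_concepts("Rat: observed", lex)), 1L)
})

test_that("matching equals the naive substring-scan oracle on random text", {
  fx <- make_fixture(seed = 31, n_genes = 40, study_size = 5)
  set.seed(77)
  phrases <- sample(fx$lexicon$entries$phrase, 30, replace = TRUE)
  decoy <- c("quiet", "signal", "between", "cells", "under", "light")
  for (i in 1:30) {
    toks <- sample(decoy, sample(4:9, 1), replace = TRUE)
    pos <- sample(length(toks) + 1L, 1L)
    toks <- append(toks, strsplit(phrases[i], " ")[[1]], after = pos - 1L)
    txt <- paste(toks, collapse = " ")
    got <- match_concepts(txt, fx$lexicon)
    want <- naive_matches(txt, fx$lexicon)
    expect_equal(got, want, ignore_attr = TRUE)
    expect_true(phrases[i] %in% got$matched_phrase)
  }
})

test_that("overlapping and nested phrases are all reported", {
  ont <- parse_obo(tiny_obo(list(
    list(id = "N:1", name = "protein response"),
    list(id = "N:2", name = "unfolded protein response"),
    list(id = "N:3", name = "protein")
  )), id = "N")
  lex <- build_lexicon(ont)
  m <- match_concepts("the unfolded protein response pathway", lex)
  expect_setequal(m$term_accession, c("N:1", "N:2", "N:3"))
})

chain_record <- function(text2 = NULL) {
  rows <- data.frame(
    gene_id = "g1", species = "s", segment_kind = "summary",
    text = "shows strong bottom concept activity", stringsAsFactors = FALSE)
  if (!is.null(text2)) {
    rows <- rbind(rows, data.frame(gene_id = "g1", species = "s",
                                   segment_kind = "generif", text = text2,
                                   stringsAsFactors = FALSE))
  }
  class(rows) <- c("gene_corpus", "data.frame")
  rows
}

chain_catalog <- function() {
  ontology_catalog(list(parse_obo(tiny_obo(list(
    list(id = "C:3", name = "top concept"),
    list(id = "C:2", name = "middle concept", is_a = "C:3"),
    list(id = "C:1", name = "bottom concept", is_a = "C:2")
  )), id = "C")))
}

test_that("a single match propagates along the chain with provenance flags", {
  catalog <- chain_catalog()
  lex <- build_lexicon(catalog)
  ann <- annotate_gene(chain_record(), lex, catalog)
  expect_setequal(ann$assignments$term_accession, c("C:1", "C:2", "C:3"))
  prov <- ann$provenance
  expect_true(prov$direct[prov$term_accession == "C:1"])
  expect_false(any(prov$direct[prov$term_accession %in% c("C:2", "C:3")]))
  expect_true(all(prov$matched_phrase == "bottom concept"))
})

test_that("two segments hitting the same term give one assignment, two provenance rows", {
  catalog <- chain_catalog()
  lex <- build_lexicon(catalog)
  ann <- annotate_gene(chain_record("bottom concept again"), lex, catalog)
  expect_equal(sum(ann$assignments$term_accession == "C:1"), 1L)
  direct <- ann$provenance[ann$provenance$term_accession == "C:1" &
                             ann$provenance$direct, ]
  expect_setequal(direct$segment_kind, c("summary", "generif"))
})

test_that("diamond-shaped propagation deduplicates the shared ancestor", {
  catalog <- ontology_catalog(list(parse_obo(tiny_obo(list(
    list(id = "D:4", name = "apex term"),
    list(id = "D:2", name = "left branch", is_a = "D:4"),
    list(id = "D:3", name = "right branch", is_a = "D:4"),
    list(id = "D:1", name = "left branch base", is_a = "D:2")
  )), id = "D")))
  lex <- build_lexicon(catalog)
  rec <- data.frame(gene_id = "g1", species = "s",
                    segment_kind = "summary",
                    text = "left branch base near the right branch",
                    stringsAsFactors = FALSE)
  class(rec) <- c("gene_corpus", "data.frame")
  ann <- annotate_gene(rec, lex, catalog)
  # set union across two matched terms sharing D:4: each term once
  expect_equal(sum(ann$assignments$term_accession == "D:4"), 1L)
  expect_setequal(ann$assignments$term_accession,
                  c("D:1", "D:2", "D:3", "D:4"))
})

test_that("an empty or matchless corpus annotates nothing", {
  fx <- make_fixture(seed = 33, n_genes = 30, study_size = 3)
  empty <- fx$corpus[0, ]
  expect_equal(nrow(annotate_corpus(empty, fx$lexicon, fx$catalog)$assignments),
               0L)
  nolex <- fx$corpus
  nolex$text <- "plain filler words only"
  ann <- annotate_corpus(nolex, fx$lexicon, fx$catalog)
  expect_equal(nrow(ann$assignments), 0L)
})

test_that("every emitted annotation set is closed under is_a", {
  fx <- make_fixture(seed = 35, n_genes = 100, study_size = 10)
  ann <- annotate_corpus(fx$corpus, fx$lexicon, fx$catalog)
  expect_gt(nrow(ann$assignments), 0L)
  expect_true(closure_holds(ann, fx$catalog))
})

test_that("annotation output is byte-identical across regenerated runs", {
  out1 <- tempfile(fileext = ".tsv")
  out2 <- tempfile(fileext = ".tsv")
  for (out in c(out1, out2)) {
    fx <- make_fixture(seed = 37, n_genes = 60, study_size = 5)
    ann <- annotate_corpus(fx$corpus, fx$lexicon, fx$catalog)
    write_annotations(ann, out)
  }
  expect_identical(readLines(out1), readLines(out2))
})

test_that("adding a segment never removes an assignment", {
  fx <- make_fixture(seed = 39, n_genes = 20, study_size = 3)
  gene <- fx$corpus$gene_id[1]
  rec <- fx$corpus[fx$corpus$gene_id == gene, ]
  before <- annotate_gene(rec, fx$lexicon, fx$catalog)$assignments
  extra <- rec[1, ]
  extra$segment_kind <- "keyword"
  extra$text <- fx$catalog$ontologies[["ONT2"]]$terms$name[5]
  rec2 <- rbind(rec, extra)
  class(rec2) <- c("gene_corpus", "data.frame")
  after <- annotate_gene(rec2, fx$lexicon, fx$catalog)$assignments
  key <- function(df) paste(df$gene_id, df$ontology_id, df$term_accession)
  expect_true(all(key(before) %in% key(after)))
  expect_gt(nrow(after), nrow(before))
})

test_that("annotation TSVs round-trip through read_annotations", {
  fx <- make_fixture(seed = 41, n_genes = 30, study_size = 3)
  ann <- annotate_corpus(fx$corpus, fx$lexicon, fx$catalog)
  p <- tempfile(fileext = ".tsv")
  write_annotations(ann, p)
  back <- read_annotations(p)
  expect_equal(back$assignments, ann$assignments)
})
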