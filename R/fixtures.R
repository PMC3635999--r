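# Deterministic synthetic fixtures: ontology catalogs, gene description
# corpora with planted term occurrences, gold-standard tables and
# study/background sets.  Everything is a pure function of the spec's seed
# (Mersenne-Twister, fixed explicitly), so regeneration is byte-identical.
#
# Construction guarantees used by the tests:
#   * term/synonym vocabulary and decoy vocabulary are disjoint, and every
#     vocabulary word is used in at most one term label, so a planted term
#     name can only ever match its own term -- planted recall is 1 by
#     construction;
#   * parents are drawn only among earlier terms, so the DAG is acyclic by
#     construction.

#' Specification of a synthetic fixture
#'
#' Defaults encode the reference study conditions used throughout the test
#' suite: a 20-gene study inside a 1000-gene background, three ontologies
#' of 40 terms, and one planted term embedded in half of the study genes
#' versus 1.5% of the background.
#'
#' @param seed integer seed; all generated artifacts derive from it.
#' @param n_ontologies number of ontologies in the catalog.
#' @param terms_per_ontology terms per ontology.
#' @param max_parents maximum is_a parents per term (at least 1).
#' @param n_genes corpus size.
#' @param segments_per_gene text segments per gene.
#' @param study_size number of study genes (the first genes of the corpus).
#' @param planted_terms data.frame with columns `ontology` (index into the
#'   catalog), `term_index` (index within the ontology), `study_frequency`,
#'   `background_frequency`.
#' @param ambient_rate probability that a segment additionally embeds one
#'   uniformly drawn catalog term name, giving every term a realistic
#'   nonzero background frequency.
#' @param decoy_vocab_size size of the non-term filler vocabulary.
#' @param stopword_rate fraction of filler tokens replaced by stopwords.
#' @return a validated `"fixture_spec"` list.
#' @export
fixture_spec <- function(seed = 1L,
                         n_ontologies = 3L,
                         terms_per_ontology = 40L,
                         max_parents = 2L,
                         n_genes = 1000L,
                         segments_per_gene = 3L,
                         study_size = 20L,
                         planted_terms = data.frame(
                           ontology = 1L, term_index = 30L,
                           study_frequency = 0.5,
                           background_frequency = 0.015),
                         ambient_rate = 0.3,
                         decoy_vocab_size = 300L,
                         stopword_rate = 0.1) {
  spec <- list(seed = as.integer(seed),
               n_ontologies = as.integer(n_ontologies),
               terms_per_ontology = as.integer(terms_per_ontology),
               max_parents = as.integer(max_parents),
               n_genes = as.integer(n_genes),
               segments_per_gene = as.integer(segments_per_gene),
               study_size = as.integer(study_size),
               planted_terms = planted_terms,
               ambient_rate = ambient_rate,
               decoy_vocab_size = as.integer(decoy_vocab_size),
               stopword_rate = stopword_rate)
  if (spec$max_parents < 1L) oe_stop("max_parents must be >= 1",
                                     "oe_usage_error")
  if (spec$n_ontologies < 1L || spec$terms_per_ontology < 1L) {
    oe_stop("catalog dimensions must be positive", "oe_usage_error")
  }
  if (spec$study_size > spec$n_genes) {
    oe_stop("study_size cannot exceed n_genes", "oe_usage_error")
  }
  pt <- spec$planted_terms
  if (nrow(pt)) {
    freqs <- c(pt$study_frequency, pt$background_frequency)
    if (any(freqs < 0 | freqs > 1)) {
      oe_stop("planted frequencies must lie in [0, 1]", "oe_usage_error")
    }
    if (any(pt$ontology < 1L | pt$ontology > spec$n_ontologies) ||
        any(pt$term_index < 1L | pt$term_index > spec$terms_per_ontology)) {
      oe_stop("planted term reference outside the catalog", "oe_usage_error")
    }
  }
  if (spec$ambient_rate < 0 || spec$ambient_rate > 1 ||
      spec$stopword_rate < 0 || spec$stopword_rate > 1) {
    oe_stop("rates must lie in [0, 1]", "oe_usage_error")
  }
  structure(spec, class = "fixture_spec")
}

# Deterministic pool of unique pronounceable words; the first
# 4 * terms-per-catalog words label terms and synonyms, the tail is the
# decoy vocabulary.
fixture_word_pool <- function(spec) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t",
            "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  syl <- as.vector(outer(cons, vow, paste0))  # 70 syllables
  total <- spec$n_ontologies * spec$terms_per_ontology * 4L +
    spec$decoy_vocab_size
  if (total > length(syl)^3) oe_stop("fixture vocabulary exhausted")
  idx <- with_seed(spec$seed + 17L, sample.int(length(syl)^3, total)) - 1L
  ns <- length(syl)
  paste0(syl[idx %/% (ns * ns) + 1L],
         syl[(idx %/% ns) %% ns + 1L],
         syl[idx %% ns + 1L])
}

fixture_ontology_id <- function(index) sprintf("ONT%d", index)

fixture_accession <- function(index, term_index) {
  sprintf("%s:%06d", fixture_ontology_id(index), term_index)
}

#' Generate one synthetic ontology
#'
#' Terms carry unique two-word names and one unique two-word EXACT synonym;
#' each non-root term receives 1..`max_parents` is_a parents drawn among
#' earlier terms, so the graph is acyclic by construction.  With a fixed
#' seed the OBO serialization is byte-identical across runs.
#'
#' @param spec a `"fixture_spec"`.
#' @param index ontology index in `1:spec$n_ontologies`.
#' @param dir if non-NULL, the ontology is also written to
#'   `<dir>/ont<index>.obo`.
#' @return an `"ontology"`.
#' @export
generate_ontology <- function(spec, index = 1L, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (index < 1L || index > spec$n_ontologies) {
    oe_stop("ontology index outside the spec", "oe_usage_error")
  }
  tt <- spec$terms_per_ontology
  pool <- fixture_word_pool(spec)
  off <- (index - 1L) * tt * 4L
  words <- pool[(off + 1L):(off + tt * 4L)]
  i2 <- seq_len(tt) * 2L
  name <- paste(words[i2 - 1L], words[i2])
  syn <- paste(words[2L * tt + i2 - 1L], words[2L * tt + i2])
  acc <- fixture_accession(index, seq_len(tt))

  edges <- with_seed(spec$seed + 1000L + index, {
    child <- parent <- character(0)
    for (j in seq_len(tt)[-1]) {
      k <- sample.int(min(spec$max_parents, j - 1L), 1L)
      ps <- sample.int(j - 1L, k)
      child <- c(child, rep.int(acc[j], k))
      parent <- c(parent, acc[ps])
    }
    data.frame(child = child, parent = parent, stringsAsFactors = FALSE)
  })

  ont <- new_ontology(
    id = fixture_ontology_id(index),
    title = sprintf("Synthetic ontology %d", index),
    category = if (index == 1L) "Preferred" else "General",
    terms = data.frame(accession = acc, name = name, obsolete = FALSE,
                       stringsAsFactors = FALSE),
    synonyms = data.frame(accession = acc, synonym = syn, scope = "EXACT",
                          stringsAsFactors = FALSE),
    parents = edges
  )
  if (!is.null(dir)) {
    write_obo(ont, file.path(dir, sprintf("ont%d.obo", index)))
  }
  ont
}

#' Generate the full synthetic catalog
#'
#' @param spec a `"fixture_spec"`.
#' @param dir if non-NULL, writes one OBO file per ontology plus a
#'   `catalog.tsv` manifest readable by [read_catalog()].
#' @return an `"ontology_catalog"`.
#' @export
generate_catalog <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  onts <- lapply(seq_len(spec$n_ontologies),
                 function(i) generate_ontology(spec, i, dir = dir))
  cat <- ontology_catalog(onts)
  if (!is.null(dir)) {
    man <- data.frame(
      id = vapply(onts, function(o) o$id, ""),
      title = vapply(onts, function(o) o$title, ""),
      category = vapply(onts, function(o) o$category, ""),
      path = sprintf("ont%d.obo", seq_along(onts)),
      stringsAsFactors = FALSE
    )
    write_tsv(man, file.path(dir, "catalog.tsv"))
  }
  cat
}

# A whole multi-word name is inserted as one atomic element so that a later
# insertion into the same segment can never split it; segments are joined
# with single spaces at the end, which keeps every embedded name verbatim.
insert_phrase_at <- function(tokens, phrase, pos) {
  append(tokens, phrase, after = pos - 1L)
}

#' Generate a synthetic gene description corpus with planted terms
#'
#' Each gene receives `segments_per_gene` text segments of filler tokens
#' (decoy vocabulary plus stopwords).  Segments may additionally embed one
#' uniformly drawn catalog term name ("ambient" occurrences), and the
#' planted terms of the spec are embedded verbatim in study-pool genes at
#' `study_frequency` and in the remaining genes at `background_frequency`.
#' The gold table is the is_a closure of every embedded term, and the truth
#' map records each direct embedding for oracle-style recounting.
#'
#' @param spec a `"fixture_spec"`.
#' @param catalog the catalog from [generate_catalog()] (same spec).
#' @param dir if non-NULL, writes `corpus.tsv` and `gold.tsv`.
#' @return a `"fixture_corpus"`: list with `corpus` (a `"gene_corpus"`),
#'   `gold` (gene/ontology/term data.frame) and `truth` (direct embeddings
#'   with a `source` column, `"planted"` or `"ambient"`).
#' @export
generate_corpus <- function(spec, catalog, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"),
            inherits(catalog, "ontology_catalog"))
  ng <- spec$n_genes
  spg <- spec$segments_per_gene
  nseg <- ng * spg
  gene_ids <- sprintf("g%05d", seq_len(ng))
  kinds <- rep_len(c("summary", "generif", "publication_title"), spg)
  pool <- fixture_word_pool(spec)
  decoys <- pool[(length(pool) - spec$decoy_vocab_size + 1L):length(pool)]
  sw <- default_stopwords()
  terms <- catalog_terms(catalog)

  gen <- with_seed(spec$seed + 29L, {
    lens <- sample(6:12, nseg, replace = TRUE)
    toks <- sample(decoys, sum(lens), replace = TRUE)
    swm <- stats::runif(sum(lens)) < spec$stopword_rate
    if (any(swm)) toks[swm] <- sample(sw, sum(swm), replace = TRUE)
    segs <- split(toks, rep.int(seq_len(nseg), lens))

    truth_gene <- truth_ont <- truth_acc <- truth_src <- character(0)

    # ambient occurrences: uniform over the whole catalog
    amb_idx <- which(stats::runif(nseg) < spec$ambient_rate)
    if (length(amb_idx)) {
      amb_term <- sample.int(nrow(terms), length(amb_idx), replace = TRUE)
      for (k in seq_along(amb_idx)) {
        si <- amb_idx[k]
        pos <- sample.int(length(segs[[si]]) + 1L, 1L)
        segs[[si]] <- insert_phrase_at(segs[[si]], terms$name[amb_term[k]],
                                       pos)
      }
      truth_gene <- gene_ids[(amb_idx - 1L) %/% spg + 1L]
      truth_ont <- terms$ontology_id[amb_term]
      truth_acc <- terms$accession[amb_term]
      truth_src <- rep.int("ambient", length(amb_idx))
    }

    # planted terms: elevated frequency in the study pool
    pt <- spec$planted_terms
    for (r in seq_len(nrow(pt))) {
      acc <- fixture_accession(pt$ontology[r], pt$term_index[r])
      oid <- fixture_ontology_id(pt$ontology[r])
      nm <- terms$name[terms$ontology_id == oid & terms$accession == acc]
      carrier <- c(stats::runif(spec$study_size) < pt$study_frequency[r],
                   stats::runif(ng - spec$study_size) <
                     pt$background_frequency[r])
      for (gi in which(carrier)) {
        si <- (gi - 1L) * spg + sample.int(spg, 1L)
        pos <- sample.int(length(segs[[si]]) + 1L, 1L)
        segs[[si]] <- insert_phrase_at(segs[[si]], nm, pos)
        truth_gene <- c(truth_gene, gene_ids[gi])
        truth_ont <- c(truth_ont, oid)
        truth_acc <- c(truth_acc, acc)
        truth_src <- c(truth_src, "planted")
      }
    }
    list(texts = vapply(segs, paste, "", collapse = " "),
         truth = data.frame(gene_id = truth_gene, ontology_id = truth_ont,
                            term_accession = truth_acc, source = truth_src,
                            stringsAsFactors = FALSE))
  })

  corpus <- as_gene_corpus(data.frame(
    gene_id = rep(gene_ids, each = spg),
    species = "synthetic",
    segment_kind = rep.int(kinds, ng),
    text = unname(gen$texts),
    stringsAsFactors = FALSE
  ))

  truth <- gen$truth
  truth <- truth[order(truth$gene_id, truth$ontology_id,
                       truth$term_accession, truth$source), , drop = FALSE]
  rownames(truth) <- NULL

  # gold standard: is_a closure of every direct embedding
  gold <- empty_annotation_set()$assignments
  if (nrow(truth)) {
    uniq <- unique(truth[c("ontology_id", "term_accession")])
    anc <- do.call(rbind, lapply(split(uniq, uniq$ontology_id), function(u) {
      tab <- ancestor_table(catalog$ontologies[[u$ontology_id[1]]],
                            u$term_accession)
      tab$ontology_id <- u$ontology_id[1]
      tab
    }))
    gg <- merge(truth[c("gene_id", "ontology_id", "term_accession")], anc,
                by = c("ontology_id", "term_accession"))
    gold <- data.frame(gene_id = gg$gene_id, ontology_id = gg$ontology_id,
                       term_accession = gg$ancestor_accession,
                       stringsAsFactors = FALSE)
    gold <- gold[!duplicated(gold), , drop = FALSE]
    gold <- gold[order(gold$gene_id, gold$ontology_id,
                       gold$term_accession), , drop = FALSE]
    rownames(gold) <- NULL
  }

  if (!is.null(dir)) {
    write_tsv(corpus, file.path(dir, "corpus.tsv"))
    write_tsv(gold, file.path(dir, "gold.tsv"))
  }
  structure(list(corpus = corpus, gold = gold, truth = truth),
            class = "fixture_corpus")
}

#' Generate the study list and background set for a fixture
#'
#' The study is the planted study pool (the first `study_size` genes of
#' the corpus); the raw study string joins the identifiers with a mixed
#' sample of the five supported delimiters so that list parsing is
#' exercised end to end.  The background is the full corpus.
#'
#' @param spec a `"fixture_spec"`.
#' @param corpus a `"fixture_corpus"` from [generate_corpus()].
#' @param dir if non-NULL, writes `study.txt` (raw delimited string) and
#'   `background.txt`.
#' @return list with `study` (character vector), `study_raw` (delimited
#'   string) and `background` (a `"background_set"`).
#' @export
generate_study <- function(spec, corpus, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"),
            inherits(corpus, "fixture_corpus"))
  if (spec$study_size < 1L) oe_stop("study_size must be positive",
                                    "oe_usage_error")
  gene_ids <- unique(corpus$corpus$gene_id)
  study <- gene_ids[seq_len(spec$study_size)]
  delims <- with_seed(spec$seed + 43L, {
    sample(c(", ", "; ", " ", "\t", "\n"), max(0L, length(study) - 1L),
           replace = TRUE)
  })
  study_raw <- paste0(study, c(delims, ""), collapse = "")
  bg <- background_set("all", gene_ids)
  if (!is.null(dir)) {
    writeLines(study_raw, file.path(dir, "study.txt"))
    writeLines(bg$gene_ids, file.path(dir, "background.txt"))
  }
  list(study = study, study_raw = study_raw, background = bg)
}
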