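# Shared fixtures and independent oracles used across the suite.

`%or%` <- function(a, b) if (is.null(a)) b else a

# Write a small OBO file from a list of term definitions:
# list(id=, name=, synonyms=, is_a=, obsolete=)
tiny_obo <- function(terms, path = tempfile(fileext = ".obo"),
                     header_id = "toy") {
  lines <- c("format-version: 1.2", paste0("ontology: ", header_id))
  for (t in terms) {
    lines <- c(lines, "", "[Term]", paste0("id: ", t$id),
               paste0("name: ", t$name %or% ""))
    for (s in t$synonyms %or% character(0)) {
      lines <- c(lines, sprintf('synonym: "%s" EXACT []', s))
    }
    for (p in t$is_a %or% character(0)) {
      lines <- c(lines, paste0("is_a: ", p))
    }
    if (isTRUE(t$obsolete)) lines <- c(lines, "is_obsolete: true")
  }
  writeLines(lines, path)
  path
}

# Ancestor oracle: enumerate every is_a path and pool the visited nodes.
enum_ancestors <- function(ont, acc) {
  res <- character(0)
  walk <- function(a) {
    res <<- c(res, a)
    for (p in ont$parents$parent[ont$parents$child == a]) walk(p)
  }
  walk(acc)
  sort(unique(res))
}

# Naive O(phrases x positions) substring scan at token boundaries in the
# normalized text; the reference semantics for match_concepts().
naive_matches <- function(text, lexicon) {
  norm <- normalize_phrase(text)
  ent <- lexicon$entries
  rows <- list()
  n_char <- nchar(norm)
  for (r in seq_len(nrow(ent))) {
    ph <- ent$phrase[r]
    len <- nchar(ph)
    if (len > n_char) next
    for (s in 0:(n_char - len)) {
      if (substr(norm, s + 1L, s + len) != ph) next
      ok_before <- s == 0L || substr(norm, s, s) == " "
      ok_after <- s + len == n_char ||
        substr(norm, s + len + 1L, s + len + 1L) == " "
      if (ok_before && ok_after) {
        rows[[length(rows) + 1L]] <- data.frame(
          ontology_id = ent$ontology_id[r],
          term_accession = ent$accession[r],
          matched_phrase = ph, start = s, end = s + len,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(ontology_id = character(0),
                      term_accession = character(0),
                      matched_phrase = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$start, df$end, df$ontology_id, df$term_accession), ]
  rownames(df) <- NULL
  df
}

# Exhaustive urn oracle: enumerate all C(m, n) study subsets (marked genes
# are 1..m_t) and return the empirical distribution of the overlap count.
enum_hyper <- function(n, m, m_t) {
  subs <- utils::combn(m, n)
  k <- colSums(matrix(subs <= m_t, nrow = n))
  list(upper = function(nt) mean(k >= nt),
       lower = function(nt) mean(k <= nt),
       pmf = function(nt) mean(k == nt))
}

# Reference step-up / step-down correction implementations.
ref_bonferroni <- function(p) pmin(1, p * length(p))
ref_holm <- function(p) {
  M <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((M - seq_len(M) + 1L) * p[o]))
  out <- numeric(M)
  out[o] <- adj
  out
}
ref_bh <- function(p) {
  M <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(M / (M:1) * p[o]))
  out <- numeric(M)
  out[o] <- adj
  out
}

# Exhaustive check that an annotation set is closed under is_a.
closure_holds <- function(ann, catalog) {
  asg <- ann$assignments
  if (!nrow(asg)) return(TRUE)
  key <- paste(asg$gene_id, asg$ontology_id, asg$term_accession)
  uniq <- unique(asg[c("ontology_id", "term_accession")])
  for (i in seq_len(nrow(uniq))) {
    ont <- catalog$ontologies[[uniq$ontology_id[i]]]
    anc <- ancestors(ont, uniq$term_accession[i])
    genes <- asg$gene_id[asg$ontology_id == uniq$ontology_id[i] &
                           asg$term_accession == uniq$term_accession[i]]
    need <- paste(rep(genes, each = length(anc)), uniq$ontology_id[i],
                  rep(anc, times = length(genes)))
    if (!all(need %in% key)) return(FALSE)
  }
  TRUE
}

# Standard small fixture used by several files (cheap to regenerate).
make_fixture <- function(seed = 7, n_genes = 300, study_size = 20,
                         ...) {
  spec <- fixture_spec(seed = seed, n_genes = n_genes,
                       study_size = study_size, ...)
  catalog <- generate_catalog(spec)
  fx <- generate_corpus(spec, catalog)
  st <- generate_study(spec, fx)
  lex <- build_lexicon(catalog)
  list(spec = spec, catalog = catalog, corpus = fx$corpus, gold = fx$gold,
       truth = fx$truth, study = st$study, study_raw = st$study_raw,
       background = st$background, lexicon = lex)
}

planted_accession <- function(spec, row = 1L) {
  sprintf("ONT%d:%06d", spec$planted_terms$ontology[row],
          spec$planted_terms$term_index[row])
}

planted_name <- function(catalog, spec, row = 1L) {
  oid <- sprintf("ONT%d", spec$planted_terms$ontology[row])
  ont <- catalog$ontologies[[oid]]
  ont$terms$name[match(planted_accession(spec, row), ont$terms$accession)]
}
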