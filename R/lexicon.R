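# Matching lexicon: normalized term names and synonyms -> term references.

#' Default matching stopwords
#'
#' Common English function words that are filtered from the lexicon: a
#' phrase consisting only of these tokens never becomes a dictionary entry,
#' so e.g. a term literally named "the" cannot fire on every sentence.
#'
#' @return character vector of lowercase tokens.
#' @export
default_stopwords <- function() {
  c("the", "and", "is", "of", "in", "to", "a", "an", "for", "on",
    "with", "by", "at", "or", "as", "are", "was", "were", "be",
    "that", "this", "it", "from", "its")
}

#' Build the exact-matching lexicon from a set of ontologies
#'
#' One entry is created per normalized term name and per in-scope synonym of
#' every non-obsolete term.  Entries are dropped when the normalized phrase
#' is shorter than `min_length` characters or consists entirely of
#' stopwords.  A phrase shared by several terms (within or across
#' ontologies) maps to all of them; disambiguation is deliberately left to
#' downstream merging.
#'
#' @param ontologies an `"ontology_catalog"`, a single `"ontology"` or a
#'   list of ontologies.
#' @param stopwords set of normalized stopword tokens.
#' @param min_length minimum phrase length in characters (default 3,
#'   suppressing spurious one/two-letter symbol matches).
#' @param synonym_scopes synonym scopes admitted to the lexicon; defaults to
#'   all four OBO scopes, restrict to `"EXACT"` for conservative matching.
#' @return an object of class `"lexicon"` with an `entries` data.frame
#'   (`phrase`, `ontology_id`, `accession`, `source`, `n_tokens`).
#' @export
build_lexicon <- function(ontologies,
                          stopwords = default_stopwords(),
                          min_length = 3L,
                          synonym_scopes = c("EXACT", "RELATED",
                                             "BROAD", "NARROW")) {
  if (inherits(ontologies, "ontology_catalog")) {
    ontologies <- ontologies$ontologies
  } else if (inherits(ontologies, "ontology")) {
    ontologies <- list(ontologies)
  }
  if (!length(ontologies)) {
    oe_stop("build_lexicon() needs at least one ontology", "oe_usage_error")
  }
  stopwords <- unique(normalize_phrase(stopwords))
  synonym_scopes <- match.arg(synonym_scopes, several.ok = TRUE)

  parts <- lapply(ontologies, function(o) {
    live <- o$terms[!o$terms$obsolete, , drop = FALSE]
    nm <- data.frame(label = live$name,
                     ontology_id = rep.int(o$id, nrow(live)),
                     accession = live$accession,
                     source = rep.int("name", nrow(live)),
                     stringsAsFactors = FALSE)
    syn <- o$synonyms[o$synonyms$scope %in% synonym_scopes &
                        o$synonyms$accession %in% live$accession, ,
                      drop = FALSE]
    sy <- data.frame(label = syn$synonym,
                     ontology_id = rep.int(o$id, nrow(syn)),
                     accession = syn$accession,
                     source = rep.int("synonym", nrow(syn)),
                     stringsAsFactors = FALSE)
    rbind(nm, sy)
  })
  ent <- do.call(rbind, parts)
  ent$phrase <- normalize_phrase(ent$label)
  ent$label <- NULL

  keep <- nzchar(ent$phrase) & nchar(ent$phrase) >= min_length
  toks <- strsplit(ent$phrase, " ", fixed = TRUE)
  all_stop <- vapply(toks, function(tk) all(tk %in% stopwords), TRUE)
  ent <- ent[keep & !all_stop, , drop = FALSE]
  ent <- ent[!duplicated(ent[c("phrase", "ontology_id", "accession")]), ,
             drop = FALSE]
  ent$n_tokens <- lengths(strsplit(ent$phrase, " ", fixed = TRUE))
  ent <- ent[order(ent$phrase, ent$ontology_id, ent$accession), , drop = FALSE]
  rownames(ent) <- NULL

  structure(list(entries = ent, min_length = as.integer(min_length),
                 stopwords = stopwords, synonym_scopes = synonym_scopes),
            class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon: %d entries (%d distinct phrases), min_length %d, %d stopwords>\n",
              nrow(x$entries), length(unique(x$entries$phrase)),
              x$min_length, length(x$stopwords)))
  invisible(x)
}
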