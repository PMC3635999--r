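# Concept recognition and annotation: exact dictionary matching of lexicon
# phrases in normalized gene text, is_a propagation to the roots, and
# deduplicated per-gene annotation sets with provenance.

# Bulk matcher over a character vector of texts.  Matching is performed on
# token n-grams of the normalized text, which is exactly equivalent to a
# naive substring scan restricted to token boundaries (normalization
# collapses every token separator to a single space).  Returns a data.frame
# with columns seg (index into texts), ontology_id, term_accession,
# matched_phrase, start, end (0-based half-open offsets into the normalized
# text of that segment).
match_concepts_bulk <- function(texts, lexicon) {
  empty <- data.frame(seg = integer(0), ontology_id = character(0),
                      term_accession = character(0),
                      matched_phrase = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  ent <- lexicon$entries
  if (!length(texts) || !nrow(ent)) return(empty)

  norm <- normalize_phrase(texts)
  tokl <- strsplit(norm, " ", fixed = TRUE)
  tokl <- lapply(tokl, function(t) t[nzchar(t)])
  ntok <- lengths(tokl)
  if (!sum(ntok)) return(empty)

  seg <- rep.int(seq_along(texts), ntok)
  tok <- unlist(tokl, use.names = FALSE)
  nch <- nchar(tok)
  # 0-based start offset of each token within its own segment
  gcum <- cumsum(nch + 1L)
  gstart0 <- gcum - (nch + 1L)            # global running offsets
  first <- !duplicated(seg)
  seg_base <- gstart0[first][match(seg, seg[first])]
  tok_start <- gstart0 - seg_base

  out <- list()
  for (n in sort(unique(ent$n_tokens))) {
    k <- length(tok) - n + 1L
    if (k < 1L) next
    i0 <- seq_len(k)
    if (n == 1L) {
      ok <- rep.int(TRUE, k)
      grams <- tok
    } else {
      ok <- seg[i0] == seg[i0 + n - 1L]
      grams <- tok[i0]
      for (j in seq_len(n - 1L)) grams <- paste(grams, tok[i0 + j])
    }
    sub <- ent[ent$n_tokens == n, c("phrase", "ontology_id", "accession"),
               drop = FALSE]
    hit <- ok & (grams %in% sub$phrase)
    if (!any(hit)) next
    hi <- i0[hit]
    hits <- data.frame(gi = hi, phrase = grams[hit],
                       stringsAsFactors = FALSE)
    mg <- merge(hits, sub, by = "phrase")
    last <- mg$gi + n - 1L
    out[[length(out) + 1L]] <- data.frame(
      seg = seg[mg$gi],
      ontology_id = mg$ontology_id,
      term_accession = mg$accession,
      matched_phrase = mg$phrase,
      start = tok_start[mg$gi],
      end = tok_start[last] + nch[last],
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$seg, res$start, res$end, res$ontology_id,
                   res$term_accession), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Find all exact lexicon matches in a text
#'
#' Reports every occurrence of every lexicon phrase that appears at token
#' boundaries in the normalized text (a match never starts or ends inside a
#' word, so "rat" does not fire inside "operation").  Overlapping and
#' nested matches are all reported, and a phrase owned by several terms
#' yields one match per owning term.
#'
#' @param text a single string.
#' @param lexicon a `"lexicon"` from [build_lexicon()].
#' @return data.frame with columns `ontology_id`, `term_accession`,
#'   `matched_phrase`, `start`, `end`; offsets are 0-based half-open
#'   positions in `normalize_phrase(text)`.
#' @export
match_concepts <- function(text, lexicon) {
  stopifnot(length(text) == 1L)
  res <- match_concepts_bulk(text, lexicon)
  res$seg <- NULL
  res
}

new_annotation_set <- function(assignments, provenance) {
  o <- order(assignments$gene_id, assignments$ontology_id,
             assignments$term_accession)
  assignments <- assignments[o, , drop = FALSE]
  rownames(assignments) <- NULL
  if (nrow(provenance)) {
    o <- order(provenance$gene_id, provenance$ontology_id,
               provenance$term_accession, provenance$segment_kind,
               provenance$matched_phrase, !provenance$direct)
    provenance <- provenance[o, , drop = FALSE]
    rownames(provenance) <- NULL
  }
  structure(list(assignments = assignments, provenance = provenance),
            class = "annotation_set")
}

empty_annotation_set <- function() {
  new_annotation_set(
    data.frame(gene_id = character(0), ontology_id = character(0),
               term_accession = character(0), stringsAsFactors = FALSE),
    data.frame(gene_id = character(0), ontology_id = character(0),
               term_accession = character(0), segment_kind = character(0),
               matched_phrase = character(0), direct = logical(0),
               stringsAsFactors = FALSE)
  )
}

#' Annotate every gene of a corpus
#'
#' Matches the lexicon against every text segment, unions the direct
#' matches per gene and propagates each matched term to all of its is_a
#' ancestors (obsolete ancestors are skipped).  The resulting assignment
#' set satisfies the propagation-closure invariant: whenever a gene is
#' annotated to a term it is annotated to every ancestor of that term.
#' Provenance records, for each (gene, term), the contributing segment
#' kinds and matched phrases and whether the annotation is direct or
#' propagated.
#'
#' @param corpus a `"gene_corpus"`.
#' @param lexicon a `"lexicon"`.
#' @param catalog the `"ontology_catalog"` the lexicon was built from.
#' @return an `"annotation_set"` with `assignments`
#'   (`gene_id`, `ontology_id`, `term_accession`) and `provenance`
#'   data.frames, both deterministically ordered.
#' @export
annotate_corpus <- function(corpus, lexicon, catalog) {
  stopifnot(inherits(catalog, "ontology_catalog"))
  if (!nrow(corpus)) return(empty_annotation_set())
  hits <- match_concepts_bulk(corpus$text, lexicon)
  if (!nrow(hits)) return(empty_annotation_set())

  direct <- data.frame(
    gene_id = corpus$gene_id[hits$seg],
    segment_kind = corpus$segment_kind[hits$seg],
    ontology_id = hits$ontology_id,
    term_accession = hits$term_accession,
    matched_phrase = hits$matched_phrase,
    stringsAsFactors = FALSE
  )
  direct <- direct[!duplicated(direct), , drop = FALSE]

  # closure of every matched term, computed once per distinct term
  uniq <- unique(direct[c("ontology_id", "term_accession")])
  anc <- do.call(rbind, lapply(split(uniq, uniq$ontology_id), function(u) {
    ont <- catalog$ontologies[[u$ontology_id[1]]]
    if (is.null(ont)) {
      oe_stop(sprintf("lexicon refers to ontology '%s' absent from catalog",
                      u$ontology_id[1]))
    }
    tab <- ancestor_table(ont, u$term_accession)
    obs <- ont$terms$accession[ont$terms$obsolete]
    tab <- tab[!tab$ancestor_accession %in% obs, , drop = FALSE]
    tab$ontology_id <- ont$id
    tab
  }))
  rownames(anc) <- NULL

  prov <- merge(direct, anc, by = c("ontology_id", "term_accession"))
  provenance <- data.frame(
    gene_id = prov$gene_id,
    ontology_id = prov$ontology_id,
    term_accession = prov$ancestor_accession,
    segment_kind = prov$segment_kind,
    matched_phrase = prov$matched_phrase,
    direct = prov$ancestor_accession == prov$term_accession,
    stringsAsFactors = FALSE
  )
  provenance <- provenance[!duplicated(provenance), , drop = FALSE]

  assignments <- provenance[c("gene_id", "ontology_id", "term_accession")]
  assignments <- assignments[!duplicated(assignments), , drop = FALSE]

  new_annotation_set(assignments, provenance)
}

#' Annotate a single gene record
#'
#' @param record a `"gene_corpus"` restricted to one gene.
#' @inheritParams annotate_corpus
#' @return an `"annotation_set"` for that gene.
#' @export
annotate_gene <- function(record, lexicon, catalog) {
  if (length(unique(record$gene_id)) > 1L) {
    oe_stop("annotate_gene() expects segments of a single gene")
  }
  annotate_corpus(record, lexicon, catalog)
}

#' Write an annotation set to TSV
#'
#' @param x an `"annotation_set"`.
#' @param path output path.
#' @param provenance if `TRUE`, write the full provenance table
#'   (`segment_kind`, `matched_phrase`, `direct`) instead of the compact
#'   gene-to-term table.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(x, path, provenance = FALSE) {
  stopifnot(inherits(x, "annotation_set"))
  write_tsv(if (provenance) x$provenance else x$assignments, path)
}

#' Read a precomputed annotation TSV
#'
#' Accepts the compact dialect written by [write_annotations()] (columns
#' `gene_id`, `ontology_id`, `term_accession`); the same dialect is used
#' for gold-standard tables.
#'
#' @param path annotation TSV path.
#' @return an `"annotation_set"` with empty provenance.
#' @export
read_annotations <- function(path) {
  df <- read_tsv(path, required = c("gene_id", "ontology_id",
                                    "term_accession"))
  if (!nrow(df)) oe_stop(sprintf("annotation file is empty: %s", path))
  df <- df[c("gene_id", "ontology_id", "term_accession")]
  df <- df[!duplicated(df), , drop = FALSE]
  new_annotation_set(df, empty_annotation_set()$provenance)
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation set: %d genes, %d (gene, term) assignments across %d ontologies>\n",
              length(unique(x$assignments$gene_id)),
              nrow(x$assignments),
              length(unique(x$assignments$ontology_id))))
  invisible(x)
}
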