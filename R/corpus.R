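# Gene description corpus: typed text segments per gene, study / background
# gene lists, and the text-hygiene filters applied before matching.

SEGMENT_KINDS <- c("summary", "generif", "publication_title", "keyword",
                   "annotation_text")

#' Read a gene description corpus
#'
#' The corpus dialect is a TSV with columns `gene_id`, `species`,
#' `segment_kind`, `text`: one typed text segment per row (gene summaries,
#' GeneRIFs, publication titles, keywords, free annotation text).  Rows that
#' are identical in `(gene_id, segment_kind, text)` are deduplicated.
#'
#' @param path corpus TSV path.
#' @return data.frame of class `"gene_corpus"`.
#' @export
read_corpus <- function(path) {
  df <- read_tsv(path, required = c("gene_id", "species", "segment_kind",
                                    "text"))
  if (!nrow(df)) oe_stop(sprintf("corpus file is empty: %s", path))
  as_gene_corpus(df)
}

as_gene_corpus <- function(df) {
  bad <- setdiff(unique(df$segment_kind), SEGMENT_KINDS)
  if (length(bad)) {
    oe_stop(sprintf("unknown segment_kind value(s): %s (expected one of %s)",
                    paste(bad, collapse = ", "),
                    paste(SEGMENT_KINDS, collapse = ", ")))
  }
  df <- df[!duplicated(df[c("gene_id", "segment_kind", "text")]), ,
           drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_corpus", "data.frame")
  df
}

#' Default description blocklist
#'
#' Names of interaction databases that are pervasive in curated gene
#' descriptions ("interaction stored in the MINT database") and would
#' otherwise surface as spuriously enriched concepts; they are removed from
#' the text before matching.
#'
#' @return character vector of phrases.
#' @export
default_blocklist <- function() {
  c("MINT", "BIND", "IntAct", "HPRD", "STRING")
}

#' Remove blocklisted phrases from text
#'
#' Deletes whole-token, case-insensitive occurrences of each blocklist
#' phrase and collapses the resulting double spaces.  No characters that
#' were absent from the input are introduced.
#'
#' @param text character vector of segment texts.
#' @param blocklist character vector of phrases (may be multi-word).
#' @return character vector; entries can become empty strings, in which case
#'   the segment should be dropped (see [filter_corpus()]).
#' @export
filter_text <- function(text, blocklist) {
  if (!length(blocklist)) return(text)
  for (ph in blocklist) {
    toks <- strsplit(normalize_phrase(ph), " ", fixed = TRUE)[[1]]
    if (!length(toks)) next
    pat <- paste0("(?<![A-Za-z0-9])",
                  paste(escape_regex(toks), collapse = "[^A-Za-z0-9]+"),
                  "(?![A-Za-z0-9])")
    text <- gsub(pat, "", text, perl = TRUE, ignore.case = TRUE)
  }
  text <- gsub(" {2,}", " ", text)
  trimws(text)
}

#' Apply the blocklist to a whole corpus
#'
#' @param corpus a `"gene_corpus"`.
#' @param blocklist phrases to remove; see [filter_text()].
#' @return the filtered corpus; segments whose text is empty after
#'   filtering are dropped.
#' @export
filter_corpus <- function(corpus, blocklist = default_blocklist()) {
  corpus$text <- filter_text(corpus$text, blocklist)
  corpus <- corpus[nzchar(normalize_phrase(corpus$text)), , drop = FALSE]
  rownames(corpus) <- NULL
  corpus
}

#' Parse a free-form gene list
#'
#' Splits the pasted input on any run of whitespace, comma, semicolon, tab
#' or newline, drops empty tokens and deduplicates while preserving
#' first-occurrence order.
#'
#' @param raw a single string (or character vector, concatenated).
#' @return character vector of unique identifiers.
#' @export
parse_gene_list <- function(raw) {
  toks <- unlist(strsplit(paste(raw, collapse = "\n"), "[,;[:space:]]+"),
                 use.names = FALSE)
  toks <- toks[nzchar(toks)]
  toks <- toks[!duplicated(toks)]
  if (!length(toks)) oe_stop("no gene identifiers found in input")
  toks
}

#' Construct a background gene set
#'
#' @param name label, e.g. `"all"`, `"refseq_reviewed"`, `"swissprot"`.
#' @param gene_ids character vector of identifiers.
#' @return a `"background_set"` object.
#' @export
background_set <- function(name, gene_ids) {
  gene_ids <- unique(as.character(gene_ids))
  if (!length(gene_ids)) oe_stop("background set is empty")
  structure(list(name = name, gene_ids = gene_ids),
            class = "background_set")
}

#' Read a gene set file into a background set
#'
#' @param path file containing identifiers in any delimiter mix accepted by
#'   [parse_gene_list()].
#' @param name label for the set (defaults to the file name).
#' @return a `"background_set"`.
#' @export
read_gene_set <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) oe_stop(sprintf("gene set file not found: %s", path))
  background_set(name, parse_gene_list(readLines(path, warn = FALSE)))
}

#' Resolve a study list against a background set
#'
#' Applies an optional identifier mapping (alias -> canonical id), then
#' partitions the study into identifiers present in the background
#' (retained) and absent ones (dropped, with a warning).  Identifier
#' comparison is case-sensitive after mapping.
#'
#' @param study character vector of study identifiers.
#' @param background a `"background_set"` or character vector.
#' @param mapping optional named character vector or two-column data.frame
#'   (from, to).
#' @return list with elements `study` (resolved, ordered, unique) and
#'   `dropped`.
#' @export
resolve_study <- function(study, background, mapping = NULL) {
  study <- as.character(study)
  study <- study[!duplicated(study)]
  if (!length(study)) oe_stop("study list is empty")
  if (!is.null(mapping)) {
    if (is.data.frame(mapping)) {
      mapping <- stats::setNames(as.character(mapping[[2]]),
                                 as.character(mapping[[1]]))
    }
    hit <- study %in% names(mapping)
    study[hit] <- unname(mapping[study[hit]])
    study <- study[!duplicated(study)]
  }
  bg <- if (inherits(background, "background_set")) background$gene_ids
        else as.character(background)
  keep <- study %in% bg
  resolved <- study[keep]
  dropped <- study[!keep]
  if (length(dropped)) {
    warning(sprintf("%d study identifier(s) absent from the background were dropped (e.g. %s)",
                    length(dropped),
                    paste(utils::head(dropped, 5L), collapse = ", ")),
            call. = FALSE)
  }
  if (!length(resolved)) {
    oe_stop("no study identifiers remain after resolving against the background")
  }
  list(study = resolved, dropped = dropped)
}
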