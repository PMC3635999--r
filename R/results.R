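# Display-level handling of enrichment results: merging same-named terms
# across ontologies, conjunctive filtering, and table output.  Merging is
# purely presentational -- correction has already happened per ontology and
# is never redone here.

#' Merge enrichment results sharing a term name
#'
#' Groups results (typically from several ontologies) by normalized term
#' name.  Each group is reported once, carrying the statistics of its best
#' member -- minimal adjusted p, ties broken by raw p, then ontology id,
#' then accession -- together with the number of distinct ontologies the
#' name was found in.
#'
#' @param results an `"enrichment_result"` data.frame or a (possibly named)
#'   list of them, e.g. the output of [run_all_ontologies()].
#' @return data.frame of class `"merged_result"`, ordered by the best
#'   member's adjusted then raw p; the `members` list-column retains every
#'   contributing per-ontology row.
#' @export
merge_by_name <- function(results) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- do.call(rbind, c(results, list(make.row.names = FALSE)))
  }
  if (is.null(results) || !nrow(results)) {
    out <- data.frame(display_name = character(0),
                      ontology_count = integer(0),
                      best_ontology = character(0), stringsAsFactors = FALSE)
    class(out) <- c("merged_result", "data.frame")
    return(out)
  }
  results$display_name <- normalize_phrase(results$name)
  results <- results[order(results$display_name, results$p_adjusted,
                           results$p_raw, results$ontology_id,
                           results$term_accession), , drop = FALSE]
  groups <- split(results, results$display_name)
  merged <- do.call(rbind, lapply(groups, function(g) g[1L, , drop = FALSE]))
  merged$best_ontology <- merged$ontology_id
  merged$ontology_count <- vapply(groups,
                                  function(g) length(unique(g$ontology_id)),
                                  integer(1))
  merged$members <- I(unname(lapply(groups, function(g) {
    rownames(g) <- NULL
    g
  })))
  merged <- merged[order(merged$p_adjusted, merged$p_raw,
                         merged$best_ontology, merged$term_accession), ,
                   drop = FALSE]
  rownames(merged) <- NULL
  class(merged) <- c("merged_result", "data.frame")
  merged
}

#' Filter merged enrichment results
#'
#' Applies, conjunctively: an ontology filter, an ontology-category filter
#' (e.g. `"Preferred"` for the curated high-information subset) and a
#' case-insensitive keyword substring match on the display name.  Ontology
#' and category filters act on the member level: members from filtered-out
#' ontologies are removed, the best member and ontology count are
#' recomputed, and groups left without members are dropped.
#'
#' @param merged a `"merged_result"` data.frame.
#' @param ontology_filter optional character vector of ontology ids; ids
#'   that occur nowhere in the results produce a warning and are ignored.
#' @param category_filter optional character vector of categories.
#' @param keyword optional substring to require in the display name.
#' @return the filtered `"merged_result"`.
#' @export
filter_results <- function(merged, ontology_filter = NULL,
                           category_filter = NULL, keyword = NULL) {
  stopifnot(inherits(merged, "merged_result"))
  if (!nrow(merged)) return(merged)

  if (!is.null(ontology_filter)) {
    known <- unique(unlist(lapply(merged$members,
                                  function(g) g$ontology_id)))
    bad <- setdiff(ontology_filter, known)
    if (length(bad)) {
      warning(sprintf("ignoring unknown ontology id(s) in filter: %s",
                      paste(bad, collapse = ", ")), call. = FALSE)
      ontology_filter <- setdiff(ontology_filter, bad)
    }
  }

  keep_member <- function(g) {
    sel <- rep.int(TRUE, nrow(g))
    if (!is.null(ontology_filter)) sel <- sel & g$ontology_id %in% ontology_filter
    if (!is.null(category_filter)) sel <- sel & g$category %in% category_filter
    g[sel, , drop = FALSE]
  }

  if (!is.null(ontology_filter) || !is.null(category_filter)) {
    members <- lapply(merged$members, keep_member)
    nz <- vapply(members, nrow, integer(1)) > 0L
    merged <- merged[nz, , drop = FALSE]
    members <- members[nz]
    if (nrow(merged)) {
      # members are already in best-first order within each group
      stat_cols <- setdiff(names(merged),
                           c("display_name", "ontology_count",
                             "best_ontology", "members"))
      for (i in seq_len(nrow(merged))) {
        best <- members[[i]][1L, , drop = FALSE]
        merged[i, stat_cols] <- best[, stat_cols]
        merged$best_ontology[i] <- best$ontology_id
        merged$ontology_count[i] <- length(unique(members[[i]]$ontology_id))
      }
      merged$members <- I(members)
    }
  }

  if (!is.null(keyword) && nzchar(keyword) && nrow(merged)) {
    merged <- merged[grepl(normalize_phrase(keyword), merged$display_name,
                           fixed = TRUE), , drop = FALSE]
  }
  if (nrow(merged)) {
    merged <- merged[order(merged$p_adjusted, merged$p_raw,
                           merged$best_ontology, merged$term_accession), ,
                     drop = FALSE]
  }
  rownames(merged) <- NULL
  class(merged) <- c("merged_result", "data.frame")
  merged
}

merged_table <- function(merged) {
  if (!nrow(merged)) {
    return(data.frame(display_name = character(0),
                      ontology_count = integer(0),
                      best_ontology = character(0),
                      term_accession = character(0), name = character(0),
                      n_t = integer(0), n = integer(0), m_t = integer(0),
                      m = integer(0), p_raw = character(0),
                      p_adjusted = character(0),
                      significance_score = character(0),
                      direction = character(0), significant = logical(0),
                      study_genes = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    display_name = merged$display_name,
    ontology_count = merged$ontology_count,
    best_ontology = merged$best_ontology,
    term_accession = merged$term_accession,
    name = merged$name,
    n_t = merged$n_t, n = merged$n, m_t = merged$m_t, m = merged$m,
    p_raw = sprintf("%.6e", merged$p_raw),
    p_adjusted = sprintf("%.6e", merged$p_adjusted),
    significance_score = sprintf("%.4f",
                                 as.numeric(significance_score(merged$p_adjusted))),
    direction = merged$direction,
    significant = merged$significant,
    study_genes = merged$study_genes,
    stringsAsFactors = FALSE
  )
}

#' Write merged results as TSV (and optionally JSON)
#'
#' @param merged a `"merged_result"`.
#' @param path TSV output path.
#' @param json_path optional JSON output path mirroring the TSV schema.
#' @return `path`, invisibly.
#' @export
write_results <- function(merged, path, json_path = NULL) {
  tab <- merged_table(merged)
  write_tsv(tab, path)
  if (!is.null(json_path)) {
    jsonlite::write_json(tab, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @export
print.merged_result <- function(x, n = 10L, ...) {
  cat(sprintf("<merged enrichment results: %d names, %d significant>\n",
              nrow(x), sum(x$significant %||% logical(0))))
  if (nrow(x)) {
    show <- utils::head(merged_table(x)[c("display_name", "ontology_count",
                                          "n_t", "m_t", "p_adjusted",
                                          "significant")], n)
    print(show, row.names = FALSE)
  }
  invisible(x)
}
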