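# Evaluation of automatic annotations against a gold standard:
# per-gene true/false positives, macro-averaged precision and recall per
# organism, and the harmonic-mean F-measure.

#' F-measure
#'
#' Harmonic mean of precision and recall, `2PR / (P + R)`; defined as 0
#' when both inputs are 0.
#'
#' @param precision,recall ratios in `[0, 1]` (vectorized).
#' @return numeric vector of F values.
#' @export
#' @examples
#' f_measure(0.678, 0.993)
f_measure <- function(precision, recall) {
  ok <- function(x) is.numeric(x) && !any(is.na(x)) && all(x >= 0 & x <= 1)
  if (!ok(precision) || !ok(recall)) {
    oe_stop("precision and recall must lie in [0, 1]", "oe_domain_error")
  }
  s <- precision + recall
  ifelse(s == 0, 0, 2 * precision * recall / s)
}

#' Precision and recall for one gene
#'
#' Compares the predicted term set of a gene with its gold-standard term
#' set: `tp = |predicted ∩ gold|`, `fp = |predicted \ gold|`,
#' `fn = |gold \ predicted|`.  Precision is 0 when nothing is predicted
#' (0/0 convention); genes with an empty gold set are not evaluable and
#' must be skipped upstream.
#'
#' @param predicted character vector of predicted term accessions.
#' @param gold nonempty character vector of gold-standard accessions.
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
evaluate_gene <- function(predicted, gold) {
  gold <- unique(as.character(gold))
  if (!length(gold)) {
    oe_stop("evaluate_gene() requires a nonempty gold-standard set")
  }
  predicted <- unique(as.character(predicted))
  tp <- length(intersect(predicted, gold))
  fp <- length(setdiff(predicted, gold))
  fn <- length(setdiff(gold, predicted))
  list(tp = tp, fp = fp, fn = fn,
       precision = if (tp + fp == 0) 0 else tp / (tp + fp),
       recall = tp / (tp + fn))
}

#' Evaluate a corpus-wide annotation set against a gold standard
#'
#' Restricts both sides to one ontology, evaluates every gene that has at
#' least one gold annotation there, and macro-averages: the organism-level
#' precision (recall) is the mean of per-gene precisions (recalls), and the
#' F-measure is the harmonic mean of those two averages.
#'
#' @param annotations an `"annotation_set"` with the automatic annotations.
#' @param gold an `"annotation_set"` or data.frame (`gene_id`,
#'   `ontology_id`, `term_accession`) holding the gold standard.
#' @param restrict_ontology ontology id to evaluate within.
#' @param species label carried into the report.
#' @param source_pair label of the annotation source / gold-standard pair.
#' @return an `"eval_report"`: list with `species`, `source_pair`,
#'   `avg_precision`, `avg_recall`, `f_measure`, `genes_evaluated` and a
#'   `per_gene` data.frame.
#' @export
evaluate_corpus <- function(annotations, gold, restrict_ontology,
                            species = "unspecified",
                            source_pair = "auto/gold") {
  stopifnot(inherits(annotations, "annotation_set"))
  gdf <- if (inherits(gold, "annotation_set")) gold$assignments else gold
  gdf <- gdf[gdf$ontology_id == restrict_ontology, , drop = FALSE]
  adf <- annotations$assignments
  adf <- adf[adf$ontology_id == restrict_ontology, , drop = FALSE]
  genes <- sort(unique(gdf$gene_id))
  if (!length(genes)) {
    oe_stop(sprintf("no gene has a gold annotation in ontology %s; nothing to evaluate",
                    restrict_ontology))
  }
  gold_by_gene <- split(gdf$term_accession, gdf$gene_id)
  pred_by_gene <- split(adf$term_accession, adf$gene_id)
  rows <- lapply(genes, function(g) {
    ev <- evaluate_gene(pred_by_gene[[g]] %||% character(0),
                        gold_by_gene[[g]])
    data.frame(gene_id = g, tp = ev$tp, fp = ev$fp, fn = ev$fn,
               precision = ev$precision, recall = ev$recall,
               stringsAsFactors = FALSE)
  })
  per_gene <- do.call(rbind, rows)
  avg_p <- mean(per_gene$precision)
  avg_r <- mean(per_gene$recall)
  structure(
    list(species = species, source_pair = source_pair,
         avg_precision = avg_p, avg_recall = avg_r,
         f_measure = f_measure(avg_p, avg_r),
         genes_evaluated = nrow(per_gene), per_gene = per_gene),
    class = "eval_report"
  )
}

#' One-row summary table of an evaluation report
#'
#' Recall, precision and F rounded to 3 decimals for display.
#'
#' @param report an `"eval_report"`.
#' @return one-row data.frame (`species`, `source_pair`, `recall`,
#'   `precision`, `f_measure`, `genes_evaluated`).
#' @export
eval_report_table <- function(report) {
  stopifnot(inherits(report, "eval_report"))
  data.frame(species = report$species,
             source_pair = report$source_pair,
             recall = round(report$avg_recall, 3),
             precision = round(report$avg_precision, 3),
             f_measure = round(report$f_measure, 3),
             genes_evaluated = report$genes_evaluated,
             stringsAsFactors = FALSE)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<evaluation %s (%s): recall %.3f, precision %.3f, F %.3f over %d genes>\n",
              x$species, x$source_pair, x$avg_recall, x$avg_precision,
              x$f_measure, x$genes_evaluated))
  invisible(x)
}
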