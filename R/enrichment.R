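# Per-ontology term enrichment / depletion testing.
#
# Counts follow the urn model: within one ontology, m is the number of
# background genes carrying at least one annotation in that ontology and n
# the number of such study genes; genes without any annotation in the
# ontology are ignored.  For a term t, m_t and n_t count background and
# study genes annotated to t.  The enrichment p-value is the upper tail of
# the hypergeometric distribution,
#
#   p(t) = sum_{k = n_t}^{min(m_t, n)} C(m_t, k) C(m - m_t, n - k) / C(m, n),
#
# i.e. the one-tailed Fisher exact test; depletion uses the symmetric lower
# tail.  Correction for multiple testing is applied per ontology over the
# family of terms with n_t >= 1, so results for one ontology never depend
# on which other ontologies are loaded.

check_counts <- function(n, m, n_t, m_t) {
  vals <- c(n = n, m = m, n_t = n_t, m_t = m_t)
  if (any(is.na(vals)) || any(vals < 0) || any(vals != floor(vals))) {
    oe_stop("counts must be nonnegative integers", "oe_domain_error")
  }
  if (n > m) oe_stop(sprintf("invalid counts: n <= m violated (n=%d, m=%d)",
                             n, m), "oe_domain_error")
  if (m_t > m) oe_stop(sprintf("invalid counts: m_t <= m violated (m_t=%d, m=%d)",
                               m_t, m), "oe_domain_error")
  if (n_t > n) oe_stop(sprintf("invalid counts: n_t <= n violated (n_t=%d, n=%d)",
                               n_t, n), "oe_domain_error")
  if (n_t > m_t) oe_stop(sprintf("invalid counts: n_t <= m_t violated (n_t=%d, m_t=%d)",
                                 n_t, m_t), "oe_domain_error")
  invisible(TRUE)
}

#' Hypergeometric upper-tail (enrichment) p-value
#'
#' Probability of observing at least `n_t` study genes annotated to a term,
#' given `n` annotated study genes drawn from `m` annotated background
#' genes of which `m_t` carry the term.  Computed with log-gamma binomial
#' coefficients summed via max-subtracted log-sum-exp, so large counts never
#' overflow; exact to better than 1e-12 relative error.
#'
#' @param n study genes with at least one annotation in the ontology.
#' @param m background genes with at least one annotation in the ontology.
#' @param n_t study genes annotated to the term.
#' @param m_t background genes annotated to the term.
#' @return the upper-tail probability.
#' @export
#' @examples
#' hypergeometric_pvalue(n = 5, m = 10, n_t = 3, m_t = 4)  # 66/252
hypergeometric_pvalue <- function(n, m, n_t, m_t) {
  check_counts(n, m, n_t, m_t)
  ks <- seq.int(n_t, min(m_t, n))
  lp <- lchoose(m_t, ks) + lchoose(m - m_t, n - ks) - lchoose(m, n)
  min(1, exp(logsumexp(lp)))
}

#' Hypergeometric lower-tail (depletion) p-value
#'
#' Probability of observing at most `n_t` study genes annotated to the
#' term; the symmetric counterpart of [hypergeometric_pvalue()] used when
#' scanning for depleted terms.
#'
#' @inheritParams hypergeometric_pvalue
#' @return the lower-tail probability.
#' @export
depletion_pvalue <- function(n, m, n_t, m_t) {
  check_counts(n, m, n_t, m_t)
  lo <- max(0L, n - (m - m_t))
  if (n_t < lo) {
    oe_stop(sprintf("invalid counts: n_t >= n - (m - m_t) violated (n_t=%d, bound=%d)",
                    n_t, lo), "oe_domain_error")
  }
  ks <- seq.int(lo, n_t)
  lp <- lchoose(m_t, ks) + lchoose(m - m_t, n - ks) - lchoose(m, n)
  min(1, exp(logsumexp(lp)))
}

#' Hypergeometric point probability
#'
#' @inheritParams hypergeometric_pvalue
#' @return probability of exactly `n_t` annotated study genes.
#' @export
hypergeometric_pmf <- function(n, m, n_t, m_t) {
  check_counts(n, m, n_t, m_t)
  exp(lchoose(m_t, n_t) + lchoose(m - m_t, n - n_t) - lchoose(m, n))
}

#' Multiple-testing correction
#'
#' Adjusts a family of raw p-values with Bonferroni, Holm's step-down or
#' the Benjamini-Hochberg step-up procedure (delegating to
#' [stats::p.adjust()]).  The family must be exactly the set of terms
#' tested within one ontology.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @param method one of `"benjamini_hochberg"` (alias `"bh"`), `"holm"`,
#'   `"bonferroni"`.
#' @return adjusted p-values in input order, capped at 1.
#' @export
adjust_pvalues <- function(p, method = c("benjamini_hochberg", "bh",
                                         "holm", "bonferroni")) {
  method <- match.arg(tolower(method[1]),
                      c("benjamini_hochberg", "bh", "holm", "bonferroni"))
  if (!is.numeric(p)) oe_stop("p-values must be numeric", "oe_domain_error")
  if (length(p) && (any(is.na(p)) || any(p < 0 | p > 1))) {
    oe_stop("p-values must lie in [0, 1]", "oe_domain_error")
  }
  stats::p.adjust(p, method = switch(method,
                                     benjamini_hochberg = "BH",
                                     bh = "BH",
                                     holm = "holm",
                                     bonferroni = "bonferroni"))
}

#' Significance score of an adjusted p-value
#'
#' The display score `-log10(p)`, so p = 0.01 maps to 2.  An adjusted
#' p-value of exactly zero (possible only through underflow) is capped at
#' `max_score` and flagged via the `"capped"` attribute.
#'
#' @param p numeric vector of adjusted p-values in `(0, 1]` (0 allowed,
#'   capped).
#' @param max_score score assigned to p = 0.
#' @return numeric vector of scores with a logical `"capped"` attribute.
#' @export
significance_score <- function(p, max_score = 350) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    oe_stop("significance_score() needs p-values in [0, 1]",
            "oe_domain_error")
  }
  s <- ifelse(p == 0, max_score, -log10(p))
  attr(s, "capped") <- p == 0
  s
}

enrichment_columns <- function() {
  c("ontology_id", "category", "term_accession", "name", "n_t", "n",
    "m_t", "m", "p_raw", "p_adjusted", "direction", "significant",
    "study_genes")
}

empty_enrichment_result <- function(ontology, direction = "enriched") {
  res <- data.frame(ontology_id = character(0), category = character(0),
                    term_accession = character(0), name = character(0),
                    n_t = integer(0), n = integer(0), m_t = integer(0),
                    m = integer(0), p_raw = numeric(0),
                    p_adjusted = numeric(0), direction = character(0),
                    significant = logical(0), study_genes = character(0),
                    stringsAsFactors = FALSE)
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Term enrichment within one ontology
#'
#' Restricts both study and background to genes with at least one
#' annotation in the ontology, tests every term with `n_t >= 1`, corrects
#' the p-values over exactly that family and flags a term significant when
#' its adjusted p-value is below `alpha` *and* at least `min_genes` study
#' genes are annotated to it.  Results are ordered by adjusted p, raw p,
#' then accession, which makes output byte-reproducible.
#'
#' @param study character vector of study gene ids (must be contained in
#'   the background; use [resolve_study()] first).
#' @param background a `"background_set"` or character vector of gene ids.
#' @param annotations an `"annotation_set"`.
#' @param ontology the `"ontology"` to test.
#' @param method correction method, see [adjust_pvalues()].
#' @param alpha significance threshold on the adjusted p-value.
#' @param min_genes minimum number of annotated study genes for a term to
#'   be reported as significant.
#' @param direction `"enriched"` (upper tail) or `"depleted"` (lower tail).
#' @return data.frame of class `"enrichment_result"`, one row per tested
#'   term.
#' @export
run_enrichment <- function(study, background, annotations, ontology,
                           method = "benjamini_hochberg", alpha = 0.05,
                           min_genes = 3L,
                           direction = c("enriched", "depleted")) {
  direction <- match.arg(direction)
  stopifnot(inherits(annotations, "annotation_set"),
            inherits(ontology, "ontology"))
  bg <- if (inherits(background, "background_set")) background$gene_ids
        else as.character(background)
  study <- unique(as.character(study))
  extra <- setdiff(study, bg)
  if (length(extra)) {
    oe_stop(sprintf("study contains %d identifier(s) absent from the background; run resolve_study() first",
                    length(extra)), "oe_usage_error")
  }

  ann <- annotations$assignments
  ann <- ann[ann$ontology_id == ontology$id & ann$gene_id %in% bg,
             c("gene_id", "term_accession"), drop = FALSE]
  live <- ontology$terms$accession[!ontology$terms$obsolete]
  ann <- ann[ann$term_accession %in% live, , drop = FALSE]
  ann <- ann[!duplicated(ann), , drop = FALSE]

  m <- length(unique(ann$gene_id))
  sann <- ann[ann$gene_id %in% study, , drop = FALSE]
  n <- length(unique(sann$gene_id))
  if (n == 0L) {
    message(sprintf("ontology %s: no study gene carries an annotation; nothing to test",
                    ontology$id))
    return(empty_enrichment_result(ontology, direction))
  }

  n_t_tab <- table(sann$term_accession)
  terms <- names(n_t_tab)
  m_t_tab <- table(factor(ann$term_accession, levels = terms))
  n_t <- as.integer(n_t_tab)
  m_t <- as.integer(m_t_tab)

  pfun <- if (direction == "enriched") hypergeometric_pvalue
          else depletion_pvalue
  p_raw <- vapply(seq_along(terms),
                  function(i) pfun(n, m, n_t[i], m_t[i]), numeric(1))
  p_adj <- adjust_pvalues(p_raw, method)

  genes_by_term <- split(sann$gene_id, sann$term_accession)
  study_genes <- vapply(genes_by_term[terms],
                        function(g) paste(sort(g), collapse = ","), "")
  name_of <- stats::setNames(ontology$terms$name, ontology$terms$accession)

  res <- data.frame(
    ontology_id = ontology$id,
    category = ontology$category,
    term_accession = terms,
    name = unname(name_of[terms]),
    n_t = n_t, n = n, m_t = m_t, m = m,
    p_raw = p_raw, p_adjusted = p_adj,
    direction = direction,
    significant = p_adj < alpha & n_t >= min_genes,
    study_genes = unname(study_genes),
    stringsAsFactors = FALSE
  )
  res <- res[order(res$p_adjusted, res$p_raw, res$term_accession), ,
             drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Term enrichment across a catalog
#'
#' Runs [run_enrichment()] independently for every ontology of the
#' catalog.  Because testing, correction and ordering are strictly
#' per-ontology, adding or removing ontologies from the catalog leaves
#' every other ontology's result table bit-identical.
#'
#' @inheritParams run_enrichment
#' @param catalog an `"ontology_catalog"`.
#' @return named list mapping ontology id to its `"enrichment_result"`.
#' @export
run_all_ontologies <- function(study, background, annotations, catalog,
                               method = "benjamini_hochberg", alpha = 0.05,
                               min_genes = 3L,
                               direction = c("enriched", "depleted")) {
  stopifnot(inherits(catalog, "ontology_catalog"))
  direction <- match.arg(direction)
  lapply(catalog$ontologies, function(ont) {
    run_enrichment(study, background, annotations, ont,
                   method = method, alpha = alpha,
                   min_genes = min_genes, direction = direction)
  })
}
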