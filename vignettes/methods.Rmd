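---
title: "Text-derived multi-ontology term enrichment: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Text-derived multi-ontology term enrichment: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontenrich)
```

## Overview

`ontenrich` implements a two-stage pipeline for hypothesis generation from
gene or protein lists:

1. **Annotation.** Curated descriptive text about each gene (summaries,
   GeneRIFs, publication titles, keywords) is scanned for exact occurrences
   of ontology term names and synonyms.  Each hit is propagated to every
   ancestor of the matched term along `is_a` edges (the true-path rule), and
   the deduplicated gene-to-term assignments are stored with provenance.
2. **Enrichment.** A study gene list is tested against a background set,
   separately within each ontology, with the hypergeometric test; p-values
   are corrected per ontology and results are merged by term name for
   display.

The two stages are deliberately decoupled: annotation can be run once over
a large corpus and written to a TSV, while enrichment is cheap enough to
run interactively against that table.

## The annotation model and its assumptions

Matching is **exact dictionary matching**: no stemming, no fuzzy matching,
no disambiguation.  Both lexicon phrases and input text are normalized the
same way (lower case, every run of non-alphanumeric characters collapsed to
one space), and a phrase only matches when it starts and ends at token
boundaries, so a term named *rat* can never fire inside *operation*.
Overlapping and nested matches are all reported, and a phrase owned by
several terms annotates all of them — ambiguity is preserved here and
handled at display time by name-based merging.

Assumptions this model makes:

* curated text mentions concepts by their ontology label or a known
  synonym — which holds remarkably often for curated summaries and titles,
  and is the reason recall against curated annotations is high;
* any concept mentioned in a gene's description is *about* that gene.  This
  is the model's main source of false positives (a database name appearing
  in every interaction record, an author's country in a seminal title), and
  two mitigations are built in: a description blocklist of interaction
  database names applied before matching (`default_blocklist()`), and the
  statistical filter itself — spurious annotations that are uniform across
  the background are not enriched in any particular study set.

Propagation follows `is_a` only.  Other OBO relationships (`part_of`,
`regulates`, ...) are parsed and discarded: their semantics do not license
the annotation inheritance that `is_a` does.  Obsolete terms are loaded and
flagged but excluded from the lexicon, from propagation targets and from
testing.

## The enrichment model

Within one ontology, let `m` be the number of background genes with at
least one annotation *in that ontology* and `n` the number of such study
genes.  For a term $t$ with `m_t` annotated background genes and `n_t`
annotated study genes, the enrichment p-value is the upper tail of the
hypergeometric distribution

$$ p(t) \;=\; \sum_{k=n_t}^{\min(m_t,\,n)}
   \frac{\binom{m_t}{k}\binom{m-m_t}{n-k}}{\binom{m}{n}}, $$

and depletion (a run-level mode, never mixed with enrichment in one
correction family) uses the symmetric lower tail.  Genes with no annotation
in the ontology carry no information about it and are excluded from both
`n` and `m`; this matters because ontology coverage varies enormously.

**The tested family** is exactly the set of terms with `n_t ≥ 1`, and
multiple-testing correction (Bonferroni, Holm, Benjamini–Hochberg) is
applied per ontology over that family.  The per-ontology scope is a
consistency guarantee: adding or removing ontologies from the catalog
leaves every other ontology's corrected results bit-identical, which the
test suite asserts on byte level.  The price is that the family-wise error
rate is controlled per ontology, not across the whole catalog — with $K$
ontologies the chance that *some* ontology reports a false positive grows
up to $K\alpha$.  The test suite measures this directly on null draws.

A term is flagged significant when `p_adjusted < alpha` **and**
`n_t ≥ min_genes`.  The gene floor counts *study* genes: a term carried by
one or two study genes is rarely an interpretable group property no matter
how small its p-value.

### Display merging

Many ontologies contain a term with the same name (e.g. a disease name
appearing in a dozen vocabularies).  After correction, results are grouped
by normalized name; each group reports its best member (minimal adjusted p,
ties broken by raw p, then ontology id, then accession — a total order, so
output is reproducible byte for byte) and the number of contributing
ontologies.  Merging is display-only: it never re-corrects, because members
were corrected in different families.  Conjunctive filters (ontology ids,
ontology categories such as the curated "Preferred" subset, and a keyword
substring on the name) restrict members and recompute the best member from
the survivors.

The reported significance score is $-\log_{10}(p_\mathrm{adjusted})$, so
$p = 0.01$ maps to 2; an adjusted p of exactly zero (possible only by
underflow) is capped at a configurable maximum and flagged.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `alpha` | 0.05 | threshold on the corrected p-value |
| `min_genes` | 3 | minimum annotated **study** genes for significance |
| `method` | Benjamini–Hochberg | also Holm, Bonferroni |
| `min_length` | 3 characters | shortest admissible lexicon phrase; suppresses one/two-letter symbol noise |
| `stopwords` | 24 function words | phrases consisting only of these never enter the lexicon |
| `synonym_scopes` | all four OBO scopes | restrict to `EXACT` for conservative matching; the inclusive default mirrors how annotator dictionaries are typically built |
| `blocklist` | five interaction-database names | removed from text before matching |

## Numerical choices

The hypergeometric tails are computed from log-gamma binomial coefficients
(`lchoose`) summed with max-subtracted log-sum-exp.  Naive factorials are
never formed, so counts in the tens of thousands are safe; on small
instances the implementation agrees with exhaustive subset enumeration to
better than $10^{-12}$ relative error (asserted for every valid
configuration with $m \le 12$), and with `stats::phyper` on large random
instances.  Correction delegates to `stats::p.adjust` and is checked in the
tests against an independently hand-rolled step-up/step-down reference.
Count invariants ($n \le m$, $n_t \le \min(n, m_t)$, $m_t \le m$) are
validated and violations name the violated inequality.  Degenerate inputs
have defined behaviour: an ontology in which no study gene is annotated
yields an empty result with a notice, not an error; `n_t = 0` gives an
upper-tail p of 1.

## What the synthetic fixtures emulate — and what they do not

The generator (`fixture_spec()`, `generate_catalog()`,
`generate_corpus()`, `generate_study()`) builds, deterministically from a
seed (Mersenne–Twister, set explicitly):

* random `is_a` DAGs whose parents are drawn only among earlier terms
  (acyclic by construction), with unique two-word names and one unique
  `EXACT` synonym per term;
* a corpus of typed text segments made of filler tokens and stopwords, in
  which catalog term names are embedded verbatim: one *planted* term at
  elevated frequency in the study pool (defaults: 20-gene study, 1000-gene
  background, 50% vs 1.5%), plus *ambient* uniform embeddings (rate 0.3
  per segment) so that every term has a realistic nonzero background
  frequency and null enrichment runs test a non-trivial family;
* a gold standard equal to the `is_a` closure of every embedding, and a
  study/background pair, the study written with mixed delimiters to
  exercise list parsing.

Names are embedded as atomic phrases (a later insertion can never split an
earlier one) and the filler vocabulary is disjoint from term labels, so
annotation recall and precision against the gold standard are exactly 1 by
construction.  Passing tests on these fixtures therefore demonstrate the
*mechanics* — matching, propagation, counting, correction, ranking — not
robustness to the noise of real corpora: real text has inflected and
partial mentions (missed by exact matching), ambiguous short labels, and
systematic co-mention biases, so real-world precision is substantially
below 1 even when recall of explicitly mentioned concepts stays high.
Occasionally an ancestor of the planted term outranks it in a replicate:
ambient embeddings can hand an ancestor an extra study carrier, and a
parent term then legitimately carries a stronger signal than its child.
The acceptance suite quantifies how often the planted term itself is the
top merged result across 100 seeded replicates.

Problem sizes used by the test suite (100–1000 genes, 3 × 40 terms, 1000
null draws, 100 end-to-end replicates) were chosen so the full suite runs
comfortably on a laptop in about a minute while keeping binomial sampling
error small relative to the asserted bounds.

## Evaluation protocol

`evaluate_corpus()` compares automatic annotations with a gold table
within one ontology.  Only genes with at least one gold annotation are
evaluable.  Per gene, precision is `tp / (tp + fp)` (0 when nothing is
predicted) and recall `tp / (tp + fn)`; the organism-level numbers are
**macro-averages** (means of per-gene ratios), and the F-measure is the
harmonic mean of those two averages.  Two conventions here were genuinely
open:

* *F from averages vs average of per-gene F*: the harmonic mean of the
  averaged precision and recall reproduces published per-organism summary
  tables of this kind to three decimals in almost all rows; residual
  last-digit differences are consistent with rounding of the inputs before
  the harmonic mean is formed.  Report tables round to 3 decimals.
* *Gold-side propagation*: the gold set is treated as closed under `is_a`
  (both sides of the comparison are closures).  Comparing a closed
  prediction against an unclosed gold would count every inherited ancestor
  as a false positive and make precision mostly a measure of term depth.

## Known limitations

* Exact matching cannot find inflected, abbreviated or paraphrased
  mentions, and has no word-sense disambiguation; short ambiguous labels
  are controlled only by the length/stopword filters and the statistics.
* Cross-ontology term mappings are deliberately out of scope; the same
  concept in two ontologies is reconciled only by name-based display
  merging.
* Per-ontology correction controls the error rate within, not across,
  ontologies (see above).
* The identifier model is deliberately thin: a case-sensitive string with
  an optional user-supplied alias table; no live ID-mapping service is
  consulted.
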