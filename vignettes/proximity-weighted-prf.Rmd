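---
title: "Proximity-weighted pseudo-relevance feedback: models and design"
author: "hroc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proximity-weighted pseudo-relevance feedback: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hroc)
```

## The problem

Pseudo-relevance feedback (PRF) assumes the top-ranked documents of a
first-pass retrieval are relevant, mines them for expansion terms, and
re-runs the query. Classic Rocchio expansion scores candidate terms by how
*frequent* (and discriminative) they are in the feedback set:

$$Q_1 = \alpha\,Q_0 + \beta \sum_{r \in R} \frac{r}{|R|}$$

where $Q_0$ is the original query vector, $R$ the feedback set, and $r$ a
feedback document's term-weight vector. Frequency alone, however, cannot
tell a term that co-occurs *near* the query terms from one that merely
shares a document with them. In clinical text this matters: a drug name
adjacent to a disease mention is strong evidence of topical relation; the
same two terms at opposite ends of a full-text article are not, and clinical
jargon often occurs only once, so frequency is a weak signal for exactly the
terms that matter.

This package scores candidate expansion terms with a second, proximity-based
component built on the Hyperspace Analogue to Language (HAL) model, and
mixes the two after normalization.

## The proximity component

HAL slides a window of size $D$ over the token stream. A co-occurrence of a
candidate term $t$ with a query term $q$ at token distance $l \le D$
contributes strength $w(l) = D - l + 1$: adjacent terms get the full $D$,
decaying linearly to $1$ at the window boundary. Per document,

$$\mathrm{HAL}(t, q) = \sum_{l=1}^{D} w(l)\, p(t, l, q)$$

where $p(t, l, q)$ counts co-occurrences at distance exactly $l$, over *all*
occurrence pairs, both directions. The per-document proximity weight of a
candidate then weights each query term by its inverse document frequency:

$$W_{\mathrm{HAL}}(t, Q_0) = \sum_{i=1}^{|Q_0|} \mathrm{HAL}(t, q_i)\,
\mathrm{IDF}(q_i)$$

The expanded query mixes the frequency and proximity components, each
normalized across the candidate axis:

$$Q' = (1-\alpha) Q_0 + \alpha \Big( (1-\beta)\,
\mathrm{Norm}\big(\textstyle\sum_{r \in R} \frac{r}{|R|}\big) + \beta\,
\mathrm{Norm}\big(\textstyle\sum_{r \in R} \frac{W_{\mathrm{HAL}}}{|R|}\big)
\Big)$$

Three normalizations give the three model variants: min–max scaling
(`norm1`, the hroc1 model), L2 scaling (`norm2`, hroc2) and division by the
maximum (`norm3`, hroc3). Normalization is essential: the raw proximity
sums are orders of magnitude larger than BM25 weights, so an unnormalized
mix would be dominated by whichever component happens to have the larger
scale.

### Choices the formulas do not pin down

Several details are under-determined by the model statement; the package
resolves them as follows, each behind an explicit argument where an
alternative reading is defensible.

* **Window directionality.** The classic HAL matrix is directional (rows
  count left-context). The expansion weight only ever consumes a combined
  count, so `hal_score()` uses a symmetric window; the directional matrix
  remains available through `hal_matrix(directional = TRUE)` for inspection.
* **Per-query-term weighting.** $W_{\mathrm{HAL}}$ sums
  $\mathrm{HAL}(t, q_i)\,\mathrm{IDF}(q_i)$ per query term $q_i$ — each
  query term's proximity profile scaled by that term's discriminativeness.
* **All pairs, not nearest neighbours.** Every occurrence pair within the
  window counts, consistent with reading the matrix entry as a weighted sum
  over all close occurrences.
* **IDF form.** The BM25-consistent
  $\log\frac{N - df + 0.5}{df + 0.5}$, floored at zero so terms in more than
  half the collection contribute nothing; `idf(scheme = "plain")` gives
  $\log N/df$.
* **Feedback term weight $r$.** The document-side BM25 factor times IDF,
  with no query-side saturation factor — a candidate term has no within-query
  frequency for that factor to act on.
* **Candidate pool and truncation.** All feedback-document terms minus the
  original query terms, ranked by the $\beta$-combined normalized score,
  truncated to `n_expansion_terms` *after* normalization, ties broken
  lexicographically so runs are reproducible byte for byte.
* **Second pass.** BM25 with the expansion weights as fractional within-query
  term frequencies — the same scorer as the strongest conventional PRF
  baseline, so first and second pass differ only in the query.
* **BM25 query factor.** The standard Okapi $(k_3+1)\,qtf/(k_3+qtf)$. A
  literal variant with $k_3 \cdot qtf$ in the denominator circulates in some
  write-ups but is constant in $qtf$; `bm25_params(as_printed = TRUE)`
  reproduces it for audits, and is never a default.

## Adaptive window sizing

A fixed $D$ must be tuned by sweeping, and one global value is a poor fit
when document lengths span two orders of magnitude. The adaptive variants
replace $D$ per feedback document with a function of its length $dl$ and the
collection mean $\overline{dl}$:

| variant | window size |
|---------|-------------|
| f1      | $dl$ |
| f2      | $dl\,(1 + dl/\overline{dl})$ |
| f3      | $(dl + \overline{dl}) / (1 + \log_2(dl/\overline{dl}))$ |

f3 is stated ambiguously in circulation; this package groups numerator and
denominator as shown (the literal left-to-right reading is available via
`adaptive_window(literal = TRUE)`). The f3 denominator is non-positive for
documents shorter than half the average length; such documents fall back to
f1 with a warning. Results are rounded to the nearest integer and floored
at 1. The adaptive size is computed per feedback document against the
whole-collection average length.

## Retrieval and evaluation machinery

First-pass models are Okapi BM25 ($k_1 = 1.2$, $k_3 = 8$, $b = 0.5$ by
default — $b$ is the conventional sweep's optimum on clinical full text,
$k_1$ and $k_3$ the usual constants) and a Dirichlet-smoothed
query-likelihood language model (default $\mu = 2000$). Documents scoring
zero under BM25 (no query term, or only clamped-IDF terms) are not ranked.
Query terms unseen in the collection contribute nothing under either model
rather than $-\infty$ under the language model.

Evaluation follows TREC conventions: MAP and recall at cutoff 1000, P@k for
$k \in \{5, 10, 20\}$, and F1 as the harmonic mean of precision and recall
computed at the same cutoff (the cutoff for F1 is a package choice; the
convention leaves it open). Unjudged documents count as non-relevant;
topics without relevant judgments are removed with a warning; graded
judgments are binarized at grade $> 0$. `grid_sweep()` is exhaustive with
first-in-grid tie-breaking, and `cv_sweep()` implements the two-fold
protocol that partitions topics by the parity of their numbers, selecting on
one fold and scoring once on the other. Paired t and Wilcoxon signed-rank
tests are both reported by `paired_significance()` because published
comparisons cite them interchangeably; neither is re-derived, both delegate
to `stats`.

## The analyzer

Tokenization lowercases and splits on non-alphanumeric runs; stemming is the
original Porter algorithm, implemented from the algorithm definition and
verified against its published reference vectors. Stopword removal is **off
by default**: proximity is measured on the analyzed token stream, so every
deleted token shortens distances and silently inflates HAL scores. Enable it
deliberately via `text_analyzer(stopwords = ...)` and treat swept $D$ values
as specific to that choice. Porter stemming is not idempotent on every word
(a stem ending in *s* loses it on a second pass), which is why analyzed
tokens — not raw text — are the unit all indices and distances are defined
on.

## What the synthetic generator emulates

`generate_collection()` builds collections in which proximity, and only
proximity, separates good expansion terms from bad ones. Per topic it
plants, inside filler text:

* **seed relevant** documents — query and designated expansion terms twice,
  at distance `relevant_gap` (default 2);
* **hidden relevant** documents — one planted block plus extra expansion-term
  occurrences: weak query-term evidence, retrievable mainly through good
  expansion;
* **distractors** — the *same* query and expansion terms but all
  query-to-expansion distances at least `nonrelevant_gap` (default 12, beyond
  any default window), plus a high-frequency block of *decoy* terms far from
  the query terms;
* **decoy-only** documents — the decoy block without query terms; and pure
  **filler** documents.

Decoys are the designed failure mode of frequency-only feedback: they are
the most frequent non-query terms in the feedback set, so Rocchio promotes
them and drags decoy-only documents up the second-pass ranking, while the
proximity component assigns them near-zero weight. Placement is
distance-exact rather than probabilistic, so the planted invariants (every
relevant document has a query-to-expansion distance within the relevant gap;
every distractor keeps them at least the non-relevant gap apart) hold
deterministically and are asserted by a post-hoc scan in the tests. All
randomness (filler tokens, document lengths) flows through one seed.

Defaults — 20 topics, 25 documents per topic (500 in all), lengths 60–100
tokens, 5 relevant per topic — keep a full twenty-seed comparison of two
PRF pipelines inside a minute on one core; these sizes are the scale the
directional test is designed for, and the test suite runs them as stated.

What passing these tests shows — and does not. The generator isolates the
proximity mechanism: on its collections the proximity-weighted expansion
reliably out-ranks frequency-only Rocchio, and planted expansion terms carry
higher HAL scores in relevant than in non-relevant documents. It does not
model real clinical language: no Zipfian vocabulary, no topic drift, no
graded relevance, and distractors that contain *all* query terms cap what
any proximity-blind second pass can achieve, so absolute MAP values on
synthetic collections say nothing about absolute performance on real
collections such as TREC CDS; only the *contrast between systems under
identical conditions* is meaningful here.

## Numerical and degenerate-input conventions

* Ranking ties (equal scores) break lexicographically by document id;
  candidate-term ties lexicographically by term. Two runs under one config
  are byte-identical.
* `norm1` on a constant vector would divide by zero; it returns all zeros
  with a warning. `norm2`/`norm3` on all-zero input return zeros.
* If every candidate's proximity component is zero (no candidate inside any
  window), expansion falls back to the frequency-only branch with a warning
  rather than mixing in a degenerate normalization.
* $\alpha = 0$ returns the original query object unchanged — the identity is
  exact, not approximate.
* Empty feedback sets are an error; a first pass that retrieves nothing
  yields the (empty) first-pass run unchanged.
* Run files print scores with six decimals; re-reading a written run
  reproduces the ranking exactly.

## Limitations

* The expansion engine holds feedback-document token streams in memory via
  the index; this is designed for desk-scale experimentation and method
  study, not for indexing millions of full-text articles.
* Only BM25 is offered as the second-pass scorer; proximity information
  influences *term selection and weighting*, not document scoring itself.
* The analyzer is English-only (Porter) and has no multi-field weighting;
  corpus ingestion expects pre-extracted plain text.
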