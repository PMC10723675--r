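---
title: "Piecewise document matching: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Piecewise document matching: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(docmatch)
```

## The problem

Regulatory document corpora pair long, heterogeneous "query" documents —
typified by European Public Assessment Reports (EPARs), the public dossiers
concluding a medicine's marketing authorisation — with a corpus of
"reference" documents such as CHMP scientific guidelines. A single
assessment report touches pharmaceutical quality, non-clinical pharmacology
and clinical evidence, so only a minority of guidelines are relevant to any
one report, and the relevant material may occupy a few pages of a
several-hundred-page document. Single-vector document representations
(TF-IDF, doc2vec, pooled embeddings) average this structure away; docmatch
instead compares documents piece by piece.

## The model

Every document is an ordered sequence of pages of word tokens. Three steps
produce a global distance between two documents $A$ and $B$:

1. **Chunking.** Each page is split into overlapping windows of at most
   $w = 200$ words with stride $s = 150$, so consecutive chunks within a
   page share exactly $w - s = 50$ words. Windows never cross a page break;
   chunking restarts on every page, and a page shorter than $w$ yields a
   single chunk.
2. **Embedding.** Each chunk is mapped to a unit-norm vector
   $x \in \mathbb{R}^d$ by an encoder satisfying a minimal contract: a pure
   function from text to a fixed-dimension vector, re-normalised
   defensively so that the cosine distance reduces to $1 - x^\top y$
   everywhere. The semantic distance between two chunks is
   $d(x, y) = 1 - x^\top y \in [0, 2]$; lower means more similar.
3. **Piecewise matching.** With $n_A$ and $n_B$ chunks, all
   $n_A \times n_B$ chunk distances are computed, and the global distance is
   $$D(A, B) = \operatorname{mean}\;\text{of the}\;N\;\text{lowest entries},
   \qquad N = \min(n_A, n_B).$$
   Selection is by value alone: a chunk contributes repeatedly when it
   matches several chunks of the other document well. $D$ is symmetric,
   zero for identical chunk sets, and — crucially — zero whenever the
   smaller document's chunks all occur in the larger one, which is the
   precise sense in which piecewise matching preserves granularity.

A **mean-pooling comparator** (`mean_pool_distance()`) averages each
document's chunk vectors, re-normalises, and takes one cosine distance. The
chunk-subset property above is the cleanest contrast: pooled means still
differ when piecewise distance is exactly zero, and on synthetic corpora
where a reference matches only a minority topic of a query, pooling
reliably overstates the distance.

### Aggregation of the N lowest distances

Both an arithmetic and a geometric mean of the $N$ selected distances are
provided, selectable via `aggregator`. The arithmetic mean is the default:
it is well-defined when exact-zero chunk distances occur (identical chunks
are common between revisions of related documents), whereas a geometric
mean must floor values — we use $10^{-12}$ — before taking logarithms. By
the AM–GM inequality the geometric aggregate never exceeds the arithmetic
one; both are exposed and tested, and corpus-level conclusions in our
synthetic experiments do not depend on the choice.

### Corpus-level scores

* **Query totals** (`score_query()`): each query's total distance is the
  arithmetic mean of its $k = \lceil f \cdot n_\text{ref} \rceil$ smallest
  reference distances, with $f = 0.05$ by default — reflecting that only a
  small fraction of references is applicable to one query. At a
  669-reference corpus this keeps $k = 34$; the ceiling (with a minimum of
  1) guarantees a non-empty selection at any corpus size. The best-match
  fraction is a plain parameter here; no signal-to-noise selection
  procedure is implemented.
* **Reference contributions** (`reference_contribution_scores()`): a
  reference is ranked by the mean of its distances to the queries in whose
  contributing set it appears. Averaging only over contributing queries is
  the default because the ranking is about contributions to the totals; a
  `mode = "all"` flag averages over every query instead.
* **Group specificity** (`group_specificity()`): for a group of queries
  (say, one ATC level-2 class), a reference's specificity is the global
  geometric-mean distance minus the within-group geometric mean; positive
  values mean the reference sits specifically close to that group. Both
  means use *all* queries, independent of the 5% cut — group affinity
  should not depend on whether a reference happens to clear the
  contribution threshold.

### Covariate analysis

`build_design()` + `fit_ols()` model the query totals as a linear function
of product covariates: product age (days from approval to a reference
date, defaulting to the latest approval in the data) and document word
count, both min–max scaled to $[0, 1]$; four regulatory boolean flags as
0/1; and category code (ATC level 2) and rapporteur country dummy-coded
against the *largest* subgroup as baseline. Scaling every covariate to
$[0, 1]$ makes coefficients directly comparable as effects over each
covariate's observed range; the response stays on its natural distance
scale. Inference is ordinary least squares with $t$-based two-sided
p-values and 95% intervals on $n - p$ degrees of freedom; raw p-values are
reported at $\alpha = 0.05$ with **no multiple-testing correction**, a
deliberate fidelity-over-stringency choice that users should keep in mind
when many dummies are in play.

Degenerate designs are handled in two distinct ways: covariate columns with
no variation (a flag never set in a small corpus) are dropped with a
message, since they carry no information and would alias the intercept,
while genuine collinearity among varying columns is an error naming the
offending columns. Categorical levels observed fewer than twice are pooled
into `"other"` before dummy coding to avoid spurious rank deficiency.

## The encoder contract and the mock encoder

Everything downstream of embedding depends only on the contract
*text → unit vector*. The shipped `mock_encoder(dim, seed)` encodes a chunk
as the normalised sum of per-token vectors, each distinct token mapping via
a seeded hash to a fixed pseudo-random unit vector. This gives exactly the
properties the pipeline needs from a semantic encoder in tests:

* determinism and purity (same text, same vector — across sessions);
* graded similarity monotone in token overlap, standing in for semantic
  overlap;
* near-orthogonality of disjoint vocabularies in high dimension.

What it does **not** model: synonymy, word order, polysemy, or any
language understanding — two paraphrases with disjoint vocabulary are
orthogonal under the mock but close under a sentence encoder. Passing tests
therefore demonstrate the correctness of the chunking/matching/scoring
machinery and the qualitative behaviour of the method, not retrieval
quality on real prose. `pretrained_encoder()` wraps an external
sentence-transformer (the 768-dimensional mpnet family is the intended
backend) through a python subprocess behind the same contract; it requires
the model to be installed and errors with a pointer to the mock encoder
otherwise.

## The synthetic corpus generator

`generate_corpus()` draws paged documents from per-document topic mixtures
over disjoint (optionally partially shared) topic vocabularies, so the full
path — tokenise, chunk, mock-embed, match — is exercised end to end. The
ground truth overlap of a pair is the dot product of their topic mixtures.
Defaults, chosen once as a realistic desk-scale miniature: 12 queries and
8 references, 2–4 pages of 120–280 words, 4 topics of 100 word types with
10% shared "boilerplate" vocabulary; references are single-topic,
queries two-topic mixtures. `generate_metadata()` samples the covariate
table (one dominant category level and rapporteur, Bernoulli flags,
uniform approval dates) and a latent distance
$0.33 + \sum_j \beta_j x_j + \varepsilon$, $\varepsilon \sim N(0, 0.01)$,
with planted effects mirroring the qualitative structure of real corpora:
negative product-age and length effects ($-0.0424$, $-0.0177$), a positive
additional-monitoring effect ($+0.0045$) and two negative category effects
(B02 $-0.0174$, J05 $-0.0069$), on a baseline distance scale of ~0.2–0.6.

What the generator does *not* emulate: real section structure, realistic
length distributions (actual assessment reports run to hundreds of pages),
regulatory vocabulary, or correlated covariates. All randomness flows from
a single spec seed through derived per-component seeds, and generation
restores the caller's RNG state.

## Numerical choices

* Cosine distances are clamped to $[0, 2]$ after the matrix product
  (floating-point can produce $-10^{-16}$).
* Geometric means floor their inputs at $10^{-12}$ before logs; exact-zero
  distances are legitimate inputs.
* N-lowest selection ties are irrelevant to the aggregate (equal values);
  determinism of reported contributing sets is ensured by ordering ties by
  reference id.
* A document whose chunk vectors cancel to a (near-)zero mean
  (norm $< 10^{-9}$) is a degenerate-document error in mean pooling rather
  than a silent division.
* The terminal chunk of a page stops exactly at the page end; if a
  parameterisation would generate a terminal span shorter than
  `min_tail = 25` words, it is merged backward into the previous chunk
  (which may then exceed the window by up to `min_tail - 1` words). With
  the default window/stride this situation cannot arise — the shortest
  possible terminal span is 51 words — but the rule matters for other
  settings and is fuzz-tested against a brute-force enumeration.

## Problem sizes used in validation

The test-suite and the acceptance script run entirely offline with the mock
encoder, at sizes chosen to make the checked properties sharp rather than
large: 1,000 random embedding-set pairs (up to 30 chunks, 16 dims) for the
brute-force agreement of the N-lowest selection; 1,000 fuzzed page lengths
for the chunker invariants; 200 random pairs for symmetry/identity; 200
Monte-Carlo replicates at $n = 500$ for OLS confidence-interval coverage
and planted-sign recovery; and 20 seeds for each end-to-end synthetic
experiment (date-aligned trend, overlap monotonicity, piecewise vs pooling
separation). The end-to-end regression demonstrations use a 40-query
corpus rather than the 12-query default because the covariate design has
about 15 columns and OLS needs $n > p$.

## Known limitations

* The built-in PDF reader handles simple, unencrypted text-layer PDFs with
  classic cross-reference tables and plain or Flate-compressed content
  streams (the dialect its companion writer produces); documents using
  object streams, CID fonts or scanned images need external conversion to
  the form-feed-delimited plain-text format.
* Word tokens are maximal non-whitespace runs after NFC normalisation;
  punctuation stays attached. This is a chunk-sizing device, not linguistic
  tokenisation — the encoder owns any subword handling.
* Chunking is purely positional; no sentence or section awareness.
* All-vs-all matching is exhaustive, $O(n_A n_B d)$ per pair. This is
  entirely feasible at the thousands-of-documents scale the method targets
  but offers no approximate-nearest-neighbour shortcut.
* Distance scores measure textual-semantic proximity between document
  corpora. They are not a measure of guideline adherence or of dossier
  quality, and regression findings on observational metadata are
  associations, not effects.
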