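---
title: "Quality-centred ranking for health search: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-centred ranking for health search: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qualrank)
```

## The model

Health-related search is evaluated here not by plain relevance but by
whether a system surfaces *helpful* content (supporting effective
treatments, dissuading from ineffective ones) above *harmful* content
(the reverse). `qualrank` implements a two-phase pipeline and the
compatibility metric used to score it.

### Preprocessing

Candidates for a topic come from Okapi BM25 over an in-memory inverted
index. For a query term $t$ and document $d$:

$$\mathrm{score}(d) = \sum_{t}
  \ln\!\Big(\frac{N - \mathrm{df}_t + 0.5}{\mathrm{df}_t + 0.5} + 1\Big)
  \cdot \frac{\mathrm{tf}_{t,d}\,(k_1 + 1)}
             {\mathrm{tf}_{t,d} + k_1 (1 - b + b\,|d|/\overline{|d|})}$$

The non-negative IDF form is used so scores never go negative and the
monotonicity properties asserted in the tests hold unconditionally. Query
terms are deduplicated (unit query weight); tokenization lowercases and
splits on non-alphanumerics, with no stemming or stopword removal — the
simplest reproducible choice, and pluggable via the `tokenizer` argument.

Two indices over the same corpus are searched per topic: one with the
standard parameters and one tuned by **known-item search**: silver topics
are generated from sampled documents (the built-in generators use top
TF-IDF keywords as the query and the first sentence as the description;
neural query/description generators are out of scope and replaced by this
text-to-text contract), and a grid search keeps the $(k_1, b)$ maximizing
the fraction of silver topics whose source document is retrieved at
rank 1. The two result lists are fused with reciprocal rank fusion (RRF)
and truncated to `n_docs` candidates, giving $H_P$. Only the topic's
*query* is consumed — never its stance, which would amount to an oracle in
the automatic-run setting.

### Multidimensional reranking

Each quality dimension reranks the candidate list in parallel and is then
RRF-fused with $H_P$:

* **Usefulness** ($H_U'$): an ensemble of scorers, each inducing a full
  reordering of the candidates; orderings are RRF-fused.
* **Supportiveness** ($H_S'$): each claim checker labels every candidate
  `supports` / `refutes` / `neutral`; the non-neutral labels in the top
  $k$ of the base ranking vote on the topic's stance (a fact is taken to
  be defined by the largest body of evidence). Candidates are then
  partitioned into stance-correct, neutral, and stance-incorrect tiers,
  preserving the base order within each tier. A tied or all-neutral vote
  leaves the base ranking unchanged: an automatic system must not
  fabricate a stance.
* **Credibility** ($H_C'$): a random forest over SMOG readability, CSS
  design-effort, and page-rank features yields a probability of
  credibility; a unitary bonus is added for URLs on a trusted-domain
  list, so a trusted page always outranks any untrusted page whose
  probability is below 1.

Combinations such as $H_U + H_S + H_C$ RRF-fuse the dimension runs. Two
further analyses are provided: *depth-restricted reranking* applies
$H_S'$ and $H_C'$ only to the top-$n$ prefix of a base run (the judgment
process is hierarchical — only useful documents were assessed for stance
and credibility — so reranking deep, non-useful candidates by stance or
credibility can promote useless pages), and a *weight sweep* varies one
model's weight over $[0, 2]$ in a min-max-normalized linear combination
while fixing the others at 0.33.

### Evaluation: help/harm compatibility

A run $R$ is compared with an ideal ranking $I$ by truncated rank-biased
overlap,

$$\mathrm{RBO}(R, I) = (1 - p) \sum_{d=1}^{K} p^{\,d-1}
  \frac{|R_{1:d} \cap I_{1:d}|}{d}, \qquad
  \mathrm{compatibility}(R, I) = \frac{\mathrm{RBO}(R, I)}{\mathrm{RBO}(I, I)}$$

with patience $p = 0.95$ and depth $K = 1000$, chosen so $p^{K-1}$ is
negligible. The normalization by the ideal's self-RBO accommodates short,
truncated ideal lists; an empty ideal yields 0 by convention. *Help* uses
the ideal of helpful documents, *harm* the ideal of harmful ones,
*help−harm* their difference; macro averages are unweighted topic means
over the helpful-topic, unhelpful-topic, and all-topic partitions. At
$K = 10$ the metric has a direct reading: placing a single ideal document
somewhere in an otherwise non-ideal top 10 yields help compatibility
averaging about 0.1 over its ten possible positions — roughly "one
helpful document ≈ ten points".

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k1`, `b` (default index) | 1.2, 0.75 | conventional Okapi settings |
| `tuned_k1`, `tuned_b` | 0.9, 0.5 | stand-in tuned settings; lower length normalization suits short, noisy web text. Set `tune = TRUE` to grid-search instead |
| `k1_grid`, `b_grid` | {0.6, 0.9, 1.2, 1.5, 1.8} × {0.3, 0.5, 0.75, 0.9} | tuning grid (ties resolved to the first row-major point) |
| `n_docs` | 10,000 | preprocessing candidate-list size |
| `rrf_k` | 60 | RRF constant, the canonical value of the method |
| `stance_k` | 10 | top-k size of the stance vote |
| `p`, `K` | 0.95, 1000 | compatibility patience and depth; `K = 10` for interpretation |
| `useful_min` | 1 | usefulness grade below which a document is "neither" |

The preference-label rule is a configurable lookup table over (topic
stance, document supportiveness), applied only to documents at or above
`useful_min`; the default encodes helpful = supportive-of-helpful or
dissuasive-of-unhelpful, harmful = the stance-opposing pair. Grade
vocabularies default to usefulness $\in \{0, 1, 2\}$, supportiveness
$\in$ {supportive, dissuasive, neutral, unjudged}, credibility
$\in \{0, 1\}$, with *unjudged* kept distinct from grade 0 throughout.

## The synthetic benchmark

`generate_benchmark()` is a pure function of (spec, seed). Its defaults
are the package's study conditions: 32 topics, 14 helpful and 18
unhelpful, 200 documents per topic. Each document is useful with
probability 0.15 (health queries have sparse relevant content: shallow
lists contain only one or two relevant documents among ten), very useful
with probability 0.4 given useful, stance-neutral with probability 0.2,
and — among stance-carrying useful documents — supportive with
probability 0.75 on helpful topics and 0.5 on unhelpful ones (web content
skews supportive of effective interventions and is roughly evenly split
on ineffective ones). Useful documents are credible with probability 0.6.
Document text mixes topic-signature tokens (denser with higher usefulness
grade, plus a 10% mention rate in non-useful documents as retrieval
noise) with a 2000-word filler vocabulary, so BM25 retrieves useful
documents above filler on average while stance and credibility stay
invisible to it; supportive/dissuasive documents also carry a marker
token. Mock scorers are configured with the planted judgments, a fidelity
$\varphi$, and a seed: with probability $\varphi$ (decided by a
per-(topic, document, seed) hash, independent of the global RNG) they
return the ground-truth grade or label, otherwise a uniform draw.

What this emulates — graded multidimensional judgments, stance-biased
content, sparse relevance, retrieval noise. What it does not — natural
medical prose, corpus-scale vocabulary statistics, correlated assessor
error, topic drift, or adversarial misinformation. Passing tests
therefore establish the correctness and internal consistency of the
pipeline machinery, not effectiveness on real web corpora.

## Numerical choices and degenerate inputs

* All orderings are deterministic: scores sort descending with ties
  broken by `doc_id` ascending, everywhere. Ranks are 1-based.
* `truncated_rbo` implements the plain finite sum with no extrapolation
  term; an extrapolated variant (residual mass $p^K$ at the depth-$K$
  overlap proportion) is exposed via `extrapolate = TRUE` on
  `compatibility()` rather than guessed to be the official convention.
* Ideal rankings order by usefulness grade, then credibility grade
  (unjudged last), then `doc_id` — an assumption, since no official
  ordering is published; topics with empty ideals score 0 and the caller
  chooses whether to exclude them.
* Within a stance tier, documents keep the base ranking's order (rather
  than, say, checker confidence); the vote uses pure label counts.
* Min-max normalization maps a constant score list to all ones; documents
  absent from a fused list contribute 0 from it rather than being
  dropped.
* SMOG uses the standard constants
  $3.1291 + 1.0430\sqrt{\text{poly} \cdot 30 / \text{sentences}}$ with a
  vowel-group ($\geq 3$) syllable heuristic and terminal-punctuation
  sentence splitting; both are deterministic and pluggable. CSS effort
  counts rule blocks in `<style>` elements plus inline `style` attributes
  plus linked stylesheets (each link counts 1), best-effort on malformed
  HTML.
* Credibility ratings on a 1–5 scale binarize as $\geq 4 \mapsto 1$. The
  manually rated web-page collection used by the original feature design
  is not redistributable, so the harness trains on any
  (features, rating) table; `synthetic_credibility_table()` provides a
  labelled stand-in.
* Oracle-equivalence tests compare to $10^{-12}$; formula fixtures to
  $10^{-6}$.

## Problem sizes in the test suite

The suite establishes oracle equivalence exhaustively on small universes
(all 120 permutations of 5 documents against all 86 ordered ideals of up
to 3), and statistical properties at the default benchmark scale: the
fidelity-monotonicity check runs 30 replicate benchmarks (32 × 200
documents) at $\varphi \in \{0, 0.5, 1\}$, comparing the full combination
against the BM25 baseline on macro help−harm compatibility. The
acceptance script averages five replicate benchmarks. These sizes keep
the whole suite in the low minutes on a single core while leaving the
binomial and chi-squared checks adequately powered.

## Known limitations

* Real transformer rerankers, claim checkers, and page-rank services are
  deliberately out of scope; the scorer/checker contracts are the
  integration surface, and the mocks only bound what the surrounding
  machinery can deliver given scorers of a known fidelity.
* The stance vote assumes evidence majority defines the fact; on topics
  where web content majority-supports an ineffective intervention, the
  tiering can promote harmful documents — visible in the unhelpful-topic
  partition of the reports.
* BM25 here is an in-memory reference implementation for corpora of
  thousands to hundreds of thousands of documents, not a
  production-scale engine.
* Registrable-domain matching is suffix-based and does not consult a
  public-suffix list; entries like `co.uk` would over-match.
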