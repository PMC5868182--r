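---
title: "Study-wise annotation models and semantic similarity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Study-wise annotation models and semantic similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(studysim)
```

## The problem

Databases such as the HPO and GO annotation files describe a disease or a
gene as a flat list of ontology classes.  That flat list throws away a piece
of structure that full-text disease descriptions and literature-derived GO
annotations actually have: each annotation came from *somewhere* — a
paragraph summarizing one clinical report, a PubMed article.  Annotations
originating from the same study tend to be topically coherent (one report
describes one presentation of the disease), and that coherence is
informative when comparing two items.

`studysim` represents an item as an ordered list of **studies**, each an
ordered list of ontology classes, and derives four annotation models from
this single representation:

* **merged** — the flat unique class set (the status quo);
* **weighted** — a multiset in which each class is counted once per study
  mentioning it;
* **study-wise** — the per-study structure itself;
* **study-wise (shuffled)** — a null control that keeps the number of
  studies and each study's size fixed while randomly exchanging classes
  between the studies of an item (1000 exchange iterations per item by
  default).

## Measures

All measures operate on a rooted `is_a` DAG.  Information content is
$IC(c) = -\log p_c$, with $p_c$ the fraction of annotated items carrying
$c$ directly or via a descendant (true-path rule).  Natural log by default;
the base is a parameter of `compute_ic()`.

For a query profile $Q$ and item profile $I$:

* **Resnik BMA**
  $\;\mathrm{sim}(Q,I) = \frac{1}{|Q|}\sum_{c_1\in Q}\max_{c_2\in I}
  IC(\mathrm{MICA}(c_1,c_2))$, where $|Q|$ counts multiplicity in the
  weighted model.  It is query-directed (normalized by $|Q|$ only); no
  symmetrized variant is offered.
* **Cosine** and **Jaccard** act on ancestor-propagated count vectors
  $q, i$: $\cos(q,i)= q\cdot i/(\lVert q\rVert\,\lVert i\rVert)$ and
  $J(q,i)=\sum_j\min(q_j,i_j)/\sum_j\max(q_j,i_j)$.

The **study-wise meta-measure** lifts any base measure $Sim$ to study lists
$Q_s, I_s$:
$$\mathrm{sim}(Q_s, I_s) = \frac{1}{|Q_s|}\sum_{s_q\in Q_s}
  \max_{s_i\in I_s} Sim(s_q, s_i),$$
i.e. each query study is matched against the best-fitting item study.
Study class lists enter the base measure as unweighted sets.

## Numerical and design choices

**Ancestor count rule.** "Ancestors are set to the corresponding count" is
ambiguous when one ancestor covers several annotated descendants with
different counts.  We assign every class in the closure the **maximum**
multiplicity over the annotated classes it subsumes.  This preserves
monotone coverage within a branch and degenerates exactly to the all-ones
vector in the unweighted case.  A sum rule is available
(`propagate(..., rule = "sum")`) but is not the default: summing makes an
ancestor's weight grow with the *number* of annotated descendants, which
double-counts the weighted model's study multiplicity.

**IC population.** IC is always computed from item-level presence (the
merged view), regardless of which model a similarity later uses: $p_c$ is
defined over items, not studies.  Frequencies use the true-path rule; the
propagated measures assume it, so the IC does too.

**MICA ties.** Among common ancestors with maximal IC we drop candidates
that are proper ancestors of another tied candidate (the most specific
tied class wins — this makes `mica(c, c)` return `c` itself when its parent
has equal IC, as it must), then take the lexicographically smallest id.
Deterministic by construction.

**Degenerate inputs.** Empty item profiles score 0 under every measure
(the benchmark's item filter removes such items before scoring, so the
convention only matters for direct API use); Resnik BMA and the study-wise
measure refuse an empty *query* because their normalization is undefined;
the Jaccard of two empty vectors warns and returns 0.

**Shuffle mechanics.** Each iteration draws two studies uniformly *with*
replacement and one position in each; drawing the same study twice is a
counted no-op.  A class may land in a study that already lists it — the
list keeps both slots so the per-study class count stays constant, and the
duplicate collapses only when a measure reads the study as a set.
Rejecting such swaps would change the null distribution in an unstated
way.  Items are processed in sorted id order under one seeded generator.

**Item filter.** The default policy keeps an item only if it has at least
5 merged annotations AND at least 4 studies.  The removal rule "remove
items with <5 annotations and <4 studies" also supports a literal reading
(remove only when both fail); it is available as `policy = "literal"` in
`filter_items()`.  The stricter reading is the default because the
evaluation's intent is to test the study-wise structure, which is vacuous
for items that fail either condition.

**Ranking and PR.** The query is excluded from its own candidate list.
Tied scores get the mean rank of their block (`tie = "worst"` for the
pessimistic policy).  (score, label) pairs are pooled globally over all
queries; the PR curve emits one point per distinct score threshold, and
AU-PRC is the trapezoid over those points with a leading point at recall 0
carrying the first block's precision.  Interpolation choice shifts AU-PRC
by a few points, which is why the construction is fixed and documented —
comparisons between models always use the same construction.

**Wilcoxon.** One-sided paired signed-rank ("less": first sample's ranks
are smaller).  Zero differences are dropped.  For n ≤ 25 the p-value comes
from exact enumeration of all $2^n$ sign assignments — implemented by
convolution over (possibly tied, average) ranks, so the exact branch also
covers tied absolute differences; above that, the normal approximation
with continuity and tie correction, numerically identical to
`wilcox.test(x, y, paired = TRUE, alternative = "less")` in the no-tie
and large-sample regimes.

**Concept recognition.** The original pipeline used a web-service
annotator; this package substitutes a deterministic longest-match
dictionary scanner over class names and exact synonyms (lowercased,
whitespace-normalized, forms under 3 characters dropped, non-overlapping
left-to-right on word boundaries).  No fuzzy matching, stemming, negation
handling or abbreviation expansion: the contribution under test is the
annotation model, not the NER engine, and an offline matcher is exactly
reproducible.  Mentions with classes outside the chosen sub-ontology are
filtered when the corpus is loaded, not at mention time.

## What the synthetic generator emulates — and what it does not

`generate_ontology()` builds a rooted DAG level by level (default 150
classes, depth 4, up to 4 children per class, 10% of classes get a second
parent so multi-parent MICA paths are exercised).  `generate_corpus()`
assigns each group a *topic block* — the descendant set of a depth-2 class,
broad enough to contain several related classes, specific enough that
MICA-based measures see them as related.  A group member's study is
topically coherent with probability `coherence` (classes drawn from the
topic block, each replaced by a random class with probability
`noise_rate = 0.1`); incoherent studies and all studies of background
items draw uniformly random classes.  Defaults: 4–8 studies per item and
2–6 classes per study, so that typical items survive the ≥5-annotation /
≥4-study filter, matching the order of magnitude of mined full-text
corpora (a handful of studies per item, a few classes per study).

This captures the mechanism the study-wise model exploits — per-study
topical purity shared within groups — but not several features of real
data: real study counts are heavy-tailed (a famous disease has hundreds of
paragraphs), annotation depth correlates with class depth, synonyms and
recognition errors correlate across paragraphs, and real groups overlap
hierarchically.  A green benchmark test therefore establishes that the
implementation ranks as the model predicts *under the stated mechanism*,
not that the effect size transfers to any particular real corpus.

One consequence, visible in the acceptance run: at coherence 0.9 almost
every study of a group member already draws from the same topic block, so
shuffling classes between an item's studies destroys little structure and
the study-wise vs. shuffled AU-PRC margin is thin (it still holds for the
majority of seeds).  The shuffled null separates much more clearly at
moderate coherence, where items mix on- and off-topic studies.

## Limitations

* Only `is_a` edges; no `part_of`, no OWL, no cross-ontology mappings.
* No alternative IC flavors (Lin, Jiang–Conrath, graph IC, simGIC) and no
  p-value calibration of similarity scores.
* The dense-matrix benchmark engine (`score_matrix()`) is sized for
  hundreds of items and classes — the scale of the synthetic evaluation —
  not for a full 17 000-class ontology; the per-pair functions have no such
  limit but are correspondingly slower in bulk.
* `wilcoxon_signed_rank()` is a two-branch implementation (exact /
  normal); it does not implement the Pratt treatment of zeros.
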