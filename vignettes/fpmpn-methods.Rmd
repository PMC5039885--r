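---
title: "Function prediction on multilayer protein networks: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Function prediction on multilayer protein networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpmpn)
```

## The model

`fpmpn` transfers GO annotations to an unannotated protein from its
neighbours in a three-layer network over a single protein universe. The
layers encode qualitatively different evidence that two proteins function
together:

* the **shared-complex layer (SCL)** connects proteins that are members of
  a common catalogued complex,
* the **shared-domain layer (SDL)** connects proteins sharing at least one
  domain type,
* the **physical-interaction layer (PIL)** carries the experimental PPI
  edges themselves.

Each layer is weighted by a squared-overlap similarity. For sets $X_i$,
$X_j$ (complex memberships or domain repertoires) the weight is
$|X_i \cap X_j|^2 / (|X_i| \cdot |X_j|)$; for the PIL the analogous edge
clustering coefficient
$|N_i \cap N_j|^2 / ((|N_i|-1)(|N_j|-1))$ is used, with $N_i$ the direct
neighbours of $v_i$, defined only when both endpoints have degree above one.
All three weights lie in $(0, 1]$ because
$|X \cap Y|^2 \le |X| \cdot |Y|$ and, for adjacent nodes,
$|N_i \cap N_j| \le \min(|N_i|-1, |N_j|-1)$. Pairs with weight zero are not
stored: a PIL edge with a degree-one endpoint or no common neighbour is
omitted from the layer, so such neighbours contribute nothing to scoring.
The PIL's support is therefore a subset of the experimental edge set, while
the SDL/SCL supports are the complete shared-domain and shared-complex pair
sets.

Scoring works on the row-normalized tensor view $A^{(1)}$: each protein's
row on each layer is divided by its row sum, so rows sum to exactly 1 (or
stay all-zero for proteins isolated on the layer). For a query $u$, a
candidate function $f$ scores
$S(f) = \sum_i W(u, p_i)\, t_{ij} \in [0, 1]$ on each layer, where $W$ is
the normalized weight and $t_{ij}$ indicates that neighbour $p_i$ carries
$f$. Layers are visited in a fixed access order and combined with geometric
importance coefficients $IC(i) = 2^{-i}$:
$\mathrm{Score}(f) = \sum_{i=1}^{L} IC(i)\, S_i(f)$. Since
$\sum_i IC(i) = 1 - 2^{-L} < 1$, every composite score lies in $[0, 1)$ and
can be read as a probability-like confidence. A function supported on
several layers accumulates all its contributions; traversal never stops
early, even if the first layer alone already yields enough candidates — an
explicitly resolved ambiguity, since stopping early would make the
composite score depend on the selection cap.

The number of functions finally assigned is not a free parameter. The
**anchor rule** caps it by the annotation count of the annotated neighbour
with the highest *raw* weight over all layers. Raw weights are used because
they are comparable across layers on a common $(0,1]$ scale, whereas row
normalization rescales every row to sum to one and destroys that
comparability (a behaviour switch to normalized weights exists for
sensitivity analysis). This neighbour-bounded cap follows from the observed
distribution of pairwise function-overlap scores
$OS(u,v) = |F_u \cap F_v|^2/(|F_u||F_v|)$ among annotated proteins (see
`overlap_histogram()`): once single-function proteins are excluded, most
co-annotated pairs overlap only partially, so adopting *all* functions of
the most similar protein would systematically over-assign; ranking a
candidate set pooled from all neighbours and cutting it at the anchor's
annotation count is the better-calibrated strategy.

### Normalization acts on the weighted adjacency

The tensor definition is stated on a binary adjacency in its original
formulation, while the layers carry fractional weights. This package
normalizes the *weighted* adjacency row-wise. That reading is forced by the
worked example: a single shared-complex neighbour must yield a layer score
of exactly 1, and two equally weighted physical neighbours must contribute
0.5 each — both of which hold only if fractional weights are divided by the
row sum. `fig5_fixture()` freezes that example; the fixture is specified at
the level of the printed per-layer scores and realizes them with one
concrete choice of raw edge weights (0.28/0.72 on the domain layer, equal
weights on the interaction layer), documented in its help page.

## Access order

The access order determines which layer receives the largest coefficient.
The default SCL → SDL → PIL reflects the standalone predictive power of the
layers, and `determine_layer_order()` re-derives an order from data: it
runs a leave-one-out neighbour-counting baseline (`nc_layer_baseline()`,
frequency ranking with the same anchor-bounded cap restricted to one layer)
on each layer independently, computes macro-averaged precision, recall and
F-measure, and sorts layers by F-measure (ties: annotated-protein count,
then layer id). Layers with no predictable protein go last. On shared-
complex evidence this ranking is typically stable because complex
co-membership is the most direct proxy for shared function, which is also
visible in the per-layer annotation bookkeeping of
`layer_annotation_stats()` (the fraction of proteins with neighbours that
carry at least one annotation).

## Evaluation conventions

Several reported quantities admit more than one convention; the package
fixes them as follows, with the reasoning:

* **Macro averaging.** Precision and recall are averaged per protein over
  proteins that received at least one prediction; the F-measure is the
  harmonic mean of those two averages (not the average of per-protein
  F-values). This convention is identified by checking the published
  layer-statistics arithmetic: an averaged precision of 0.3791 and recall
  of 0.1094 reproduce the printed F-measure 0.1697 only under the
  harmonic-mean-of-averages reading.
* **Unpredicted proteins** are excluded from the precision/recall averages
  but remain in the coverage-rate denominator; a flag
  (`include_unpredicted`) switches to zero-imputation for sensitivity
  checks. The coverage rate $CR = \sum_i |KF_i \cap PF_i| / \sum_i |KF_i|$
  is a micro-recall over the whole testing set.
* **Exact term matching.** A predicted term counts only if it equals a
  known term; no partial credit is given through the GO hierarchy, and
  annotations are not propagated up the DAG. Term filtering (default: keep
  terms annotating 10–200 proteins, inclusive) is applied per aspect after
  restriction to the protein universe.
* **Curves.** For each $K = 1, \dots, K_{\max}$ (default 50), each
  protein's top-$K$ ranked terms form its prediction; macro precision and
  recall give one PR point, and pooled TP/FP totals give one FP/TP point.
  The AUC uses the trapezoidal rule over recall-sorted points with
  duplicate recalls collapsed to their maximum precision. The "middle"
  FP/TP statistic is the median; cutoffs with zero pooled TP are excluded
  from the ratio statistics rather than treated as infinite.
* **Ties.** Ranked terms tie-break by ascending term identifier, anchor
  candidates by ascending protein identifier. Both choices make output
  bit-reproducible; nothing in the method constrains them otherwise.
* **Cross-validation.** Leave-one-out is deterministic; k-fold partitions
  annotated proteins uniformly at random under a mandatory seed into folds
  differing in size by at most one, and k-fold with $k = n$ reproduces
  leave-one-out bit-exactly (a tested invariant). Masked proteins remain
  network nodes — the layers are annotation-free, so masking cannot leak
  through the weights; leakage through the candidate sets is separately
  tested with a canary term.

## The synthetic generator

`random_mpn()` emulates the four inputs with a planted-signal model. Every
protein receives 1–3 terms from a small vocabulary; interactions, domain
groups and complexes are then drawn with an assortativity dial `p_share`:
with probability `p_share` a connection (or group) is planted on proteins
sharing a term, otherwise uniformly. The defaults (200 proteins, 20 terms,
interaction density 0.03, 60 domain groups of 2–4, 40 complexes of 2–5,
`p_share = 0.5`) give layer densities and annotation multiplicities in the
regime of a small curated PPI dataset while keeping leave-one-out
cross-validation fast. Generation is a pure function of the mandatory seed
(the caller's RNG state is saved and restored).

Two ends of the dial have provable behaviour used as end-to-end checks: at
`p_share = 0` the layers carry no functional signal and the cross-validated
F-measure sits in the label-permutation null band; at `p_share = 1` with a
single term per protein, every annotated neighbour carries the held-out
term, forcing recall 1 on predicted proteins. Between them the F-measure
rises monotonically in `p_share` (averaged over five seeds).

What the generator does *not* emulate: scale-free degree distributions,
correlated multi-domain architectures, GO-term hierarchy and co-annotation
correlation structure, or annotation incompleteness. Passing tests on this
generator therefore demonstrate correctness of the algorithmic pipeline and
its monotone response to planted signal — not expected performance levels
on real interactome data, where published full-scale runs require the
external DIP/Pfam/CYC2008/GO releases.

## Numerical and degenerate-input choices

* Row normalization uses exact division by the row sum; tests assert row
  sums within $10^{-12}$ of 1 (or exactly 0).
* Proteins with no annotated neighbour on any layer yield an empty
  prediction (`n_limit = 0`, no anchor) and are excluded from
  predicted-protein counts, matching the distinction between evaluated,
  predicted and matched proteins.
* Complexes reduced below two members after universe restriction are
  dropped with a message; unknown-protein records in domain/annotation
  files are skipped with a warning rather than erroring, to tolerate
  real-world identifier mismatch. Identifier matching is case-sensitive
  and exact; mapping between naming systems is the caller's job.
* Layer identifiers are open strings: a fourth layer (e.g. co-expression)
  can be assembled without code change; only the default order covers the
  three standard layers.

## Problem sizes in the test suite

The suite verifies the scoring path against a naive dense reimplementation
on 20-protein instances across 50 seeds, edge-clustering weights against
brute-force common-neighbour counting on 30-protein graphs, and the
signal-recovery property on 200-protein instances across 5 seeds — sizes
chosen so the full suite completes in well under a minute while covering
every code path; the oracle comparisons are tolerance $10^{-12}$, so larger
instances would add cost without adding discrimination.

## Known limitations

* No GO-DAG awareness: neither true-path propagation of input annotations
  nor ancestry-aware match credit.
* The anchor rule transfers the annotation *count*, not the annotations,
  of the closest neighbour; for proteins whose closest annotated neighbour
  is atypically sparsely or richly annotated the cap is miscalibrated.
* Composite scores are comparable within a query's ranking, but only
  loosely across queries with different neighbourhood sizes.
* The evaluation protocol scores a prediction only against the held-out
  protein's known terms; genuinely novel (unannotated) true functions are
  counted as false positives, as in all benchmark studies of this design.
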