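---
title: "Scoring disease-associated miRNAs by personalized recommendation: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring disease-associated miRNAs by personalized recommendation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirec)
```

## The model

`mirec` scores every disease–miRNA pair of a bipartite association
network by fusing three sources of evidence, each of which compensates a
weakness of the others.

**Semantic similarity of diseases.** Disease vocabularies (MeSH-style)
form a DAG whose ancestors are more general terms. Two diseases are
similar when their ancestor closures overlap heavily. We combine two
contribution models. The *decay* model assigns a disease's own term
contribution 1 and propagates contributions upward by
$D1_D(d) = \max\{\Delta \cdot D1_D(d')\}$ over children $d'$ of $d$
inside the closure $T(D)$; its weakness is that all terms at the same
depth contribute equally. The *frequency* model corrects this by weighting
a term by its rarity across the study diseases' DAGs,
$D2_D(d) = -\log(n_{dt}/n_d)$: an ancestor present in every disease's DAG
carries no information ($-\log 1 = 0$), a rare one carries much. Both
models normalize the shared-ancestor contribution sum by the two
semantic values, so similarities live in $[0, 1]$ with unit diagonal; the
disease similarity used downstream is their mean.

**Interaction-profile kernels.** The network itself defines a similarity:
entities with overlapping association profiles (rows or columns of $A$)
get Gaussian kernel similarity
$\exp(-\gamma\,\lVert IP_i - IP_j\rVert^2)$, with the bandwidth
normalized by the mean squared profile norm so that the kernel adapts to
network density. This is the only similarity available for entities
missing from the curated sources.

**Integration.** The integrated similarities $S_m$ and $S_d$ take the
curated value wherever evidence exists and the kernel value otherwise — a
hard switch, not a blend. "Evidence exists" means the pair appears in the
curated matrix with a value strictly above `similarity_threshold`
(default 0): a stored 0 in a curated functional-similarity export means
"no evidence", the same epistemic state as an absent pair, so it too
falls back to the kernel. The threshold is configurable for sensitivity
analysis.

**Recommendation scoring.** The rating side builds TF-IDF-like weights
$W_d(i,j) = n_{tal} \cdot \log(N_a/n_a)$ — how many of disease $i$'s
known miRNAs resemble miRNA $j$, discounted by how unspecific disease
$i$'s neighbourhood is — row-normalized into $Z_d$, with the exactly dual
construction on the miRNA side, and combined with Euclidean row norms.
The projection side smooths the adjacency by similarity on both margins,
$K_m = A S_m$, $K_d = S_d A$ (the only dimension-consistent operand
orders), again combined by row-normalized addition. The final score is
$R = K/\lVert K\rVert + Z/\lVert Z\rVert$ per row. Because $K_d$ needs no
known association for the scored disease, a disease with an empty row
still receives a finite, informative score row — this is what makes the
zero-knowledge protocol work.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `delta` | 0.5 | semantic decay per DAG edge, dimensionless in (0, 1); the value used throughout this literature lineage |
| `gamma_d`, `gamma_m` | 1 | raw kernel bandwidths before density normalization, the interaction-profile-kernel convention |
| `norm` | `"l2"` | row norm in all combination steps; `"l1"` provided for sensitivity checks |
| `log_base` | e | base of the specificity and frequency logarithms |
| `similarity_threshold` | 0 | strict cut defining "has similarity" in all counting rules |

The logarithm base deserves a note: in the frequency model the self term
is a fixed 1 while the $-\log$ terms scale with the base, so the base is
not a pure rescaling and must be pinned; natural log is the default. In
the rating weights the log factor is constant within a row and cancels in
normalization, so there the base only matters jointly with thresholding.

## Numerical choices

*Zero rows propagate as zeros.* Every normalization in the pipeline maps
an all-zero row to an all-zero row rather than NaN; degenerate inputs
(a disease with no associations, an empty rating side) degrade gracefully
to the surviving evidence path.

*Negative specificity factors.* When an entity has more
positive-similarity neighbours than the opposing dimension has entities
($n_a > N_a$), its log factor is negative. This is not an edge case: with
the strictly positive kernel fallback it happens for *every* miRNA
whenever there are more miRNAs than diseases, which is the normal state
of curated association databases. Since the factor is constant within a
row, the row normalization of the rating step cancels it exactly — each
nonzero row reduces to the non-negative neighbour-count profile
$n_{tal}/\sum n_{tal}$ and sums to 1. The package therefore normalizes
through (with a once-per-session warning) instead of refusing, which
would make the method unusable in exactly its intended regime.

*Ties.* Tied scores receive midranks everywhere (candidate rankings,
held-out ranks in cross-validation); display order breaks remaining ties
lexicographically by miRNA name. Tied scores are common in practice —
candidates with no curated information and identical kernel profiles
score identically — so the tie policy materially affects ranks and is
pinned.

*ROC construction.* Each LOOCV fold yields the midrank $r$ of the
held-out positive among its $c$ candidates plus itself. The ROC pools
thresholds across folds on the per-fold normalized rank scale
$x = (r-1)/c$: TPR$(x)$ is the fraction of folds with normalized rank at
most $x$, and the expected fraction of a fold's negatives inside the top
$x$ is $x$ itself, so FPR$(x) = x$. The trapezoidal area of this curve
equals $\mathrm{mean}\,(c+1-r)/c$ *exactly*, which is the within-fold
Mann–Whitney statistic (probability that the positive outranks a random
candidate negative, ties counted half). We chose this construction over
vertical averaging of per-fold step curves on a shared integer-rank grid
because the latter does not equal the mean within-fold AUC when candidate
counts differ across folds.

*Cross-validation semantics.* By default the kernels and integrated
similarities are recomputed in every fold on the modified network, so the
model never sees the held-out edge (removing one edge shifts both
bandwidth means globally, so no purely local update is exact). A
`static_kernels` option computes them once on the full network for
speed-accuracy comparisons. The candidate pool of a fold is defined on
the *original* network: the disease's other true positives are neither
candidates nor test items.

## Design choices where the design was open

- *Universe for frequency counts*: $n_{dt}$ is counted over the DAGs of
  the diseases in the association network (not the whole vocabulary), and
  $n_d$ is the number of network diseases. This makes the frequency model
  a property of the study, not of the vocabulary release.
- *Polyhierarchy*: a term carrying several tree numbers is merged into a
  single node whose closure unions all positions.
- *Diseases absent from the DAG* get zero semantic similarity off-diagonal
  (with a warning) and are scored through the kernel fallback.
- *Name matching* across files is exact after normalization (trim,
  lowercase, collapse internal whitespace); no fuzzy matching.
- *Orientation*: all rating/projection matrices are diseases × miRNAs;
  the miRNA-side rating submatrix is computed miRNAs × diseases and
  transposed before combination.

## The synthetic generator

`simulate_mda()` *is* the study design for all shipped tests: diseases
and miRNAs are partitioned into paired co-modules; associations are
Bernoulli(0.3) within and Bernoulli(0.02) between modules on a 40 × 60
network with 4 blocks; curated similarity is 0.7 within and 0.1 between
modules plus Gaussian noise (SD 0.1), clipped to $[0,1]$, with 70% of
pairs available — values chosen once as realistic for curated
functional-similarity exports (strong within-module similarity, weak
background, substantial but incomplete coverage). The DAG hangs one
random tree per block off a common root, so same-block diseases share
ancestors below the root. A degree-preserving checkerboard-swap rewiring
provides the null control.

What it emulates: modular guilt-by-association structure, curated-source
incompleteness, similarity noise, vocabulary hierarchy. What it does not:
the heavy-tailed degree distributions of real association databases,
literature bias (well-studied miRNAs accumulate associations across many
diseases), disease-dependent annotation depth, and name-reconciliation
noise between sources. Passing tests therefore demonstrate correctness of
the machinery and recoverability of modular signal, not field performance
on any particular database snapshot; for user-supplied HMDD-scale data the
expectation is an LOOCV AUC in roughly 0.80–0.86 under defaults.

Problem sizes used by the shipped tests: oracle equivalence on 20 random
15 × 20 networks; invariants on 200 random instances of 6–10 × 8–12;
structure recovery on 20 replicate 40 × 60 planted studies with full
LOOCV (a few thousand folds in total) against 20 shuffled controls —
sizes at which the whole suite completes in about a minute while the
binomial/hypergeometric checks retain power.

## Limitations

- The specificity weight mixes a miRNA count and a disease count inside
  one logarithm; it is implemented as published in this method family,
  and the normalization-cancellation above is what keeps it well-defined.
- With a strictly positive kernel fallback, all "has similarity" counts
  saturate ($n_a = n_d$, $n_{tal} = |RM_i|$) wherever the fallback
  applies; the `similarity_threshold` knob exists to explore sparser
  counting regimes.
- Scores are comparable within a disease row, not across diseases.
- The method is transductive: adding a new entity changes kernels and
  hence all scores; there is no incremental update path.
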