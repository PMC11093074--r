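---
title: "Fuzzy expression-level flows: model, parameters and design notes"
author: "FuzzyFlows authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy expression-level flows: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FuzzyFlows)
```

## The problem

Differential-expression lists answer "which genes changed between two
conditions", but many designs ask a path-shaped question instead: *which
genes move to a higher expression level in the final condition than in
every baseline condition, and do they do so in every cell subpopulation?*
A concrete instance is circulating neutrophils profiled by CITE-seq in
healthy donors, patients with sterile inflammation, and patients with
bacterial infection: the biological question is which transcripts are
switched on by infection specifically, above *both* baselines, across all
neutrophil substates.

FuzzyFlows answers this with a fuzzy-set formulation.  Instead of
thresholding genes into "up" and "down", each gene holds a *graded
membership* in a small ordered vocabulary of expression levels
(NotExpressed < Low < Medium < High) at every (cluster, condition) group.
A *flow* is one assignment of a level per condition across the ordered
condition series; every gene belongs to every flow with a membership
between 0 and 1, and the width of a flow — what an alluvial diagram draws —
is the sum of all gene memberships in it.  Pattern predicates select flows
(e.g. "final level above all prior levels, at least Medium"), and genes are
ranked by their combined membership in the selected set.

## The model, step by step

### Pseudobulk profiles

Counts are normalized per cell to a fixed total (default 10,000) followed
by `log1p` — the conventional single-cell scaling — and averaged within
each (cluster, condition) group; the fraction of cells with a nonzero raw
count is kept alongside (`pseudobulkProfile()`).  Fuzzification operates on
group summaries rather than single cells: levels describe what a
population of cells does, and group means at the cell numbers involved
(hundreds of cells per group) are stable.

### Triangular membership functions

A `FuzzySpec` fixes one anchor per level, \(a_0 = 0 < a_1 < \dots <
a_{L-1}\), on the normalized scale.  Level \(l\) has membership 1 at
\(a_l\), decaying linearly to 0 at the adjacent anchors; inputs at or below
\(a_0\) are fully NotExpressed and inputs at or beyond \(a_{L-1}\) fully
High.  For \(x \in [a_l, a_{l+1}]\):

\[
\mu_l(x) = \frac{a_{l+1}-x}{a_{l+1}-a_l}, \qquad
\mu_{l+1}(x) = \frac{x-a_l}{a_{l+1}-a_l},
\]

and all other levels are 0.  Triangular functions are chosen for the
*partition of unity*: memberships sum to exactly 1 for every input, which
is what makes flow widths conserved (below).  The membership family is a
design decision of this package; smoother families (e.g. Gaussian) lose
exact conservation.

Anchors are placed by `fitFuzzySpec()` at empirical quantiles of the
*positive* group means, pooled over all groups.  One spec is fitted per
dataset — levels must mean the same thing in every cluster and condition,
otherwise cross-cluster statements like "increased in all subsets" are
incoherent.  The default quantiles for four levels are (0.25, 0.5, 0.9):
the top anchor sits at the 90th percentile so that full High membership
marks the strongly expressed tail rather than merely above-median genes.
Genes detected in less than 1% of cells in every group are dropped before
fuzzification (`detectionGate`), so flows are not driven by noise-level
genes.

### Flows, weights and conservation

With \(L\) levels and \(T\) conditions there are \(L^T\) level paths.  A
gene's membership in path \(p = (l_1, \dots, l_T)\) within cluster \(c\)
combines per-condition memberships with a t-norm; the default is the
product

\[
m_{g,c}(p) = \prod_{t=1}^{T} \mu_{l_t}\!\big(x_{g,c,t}\big),
\]

with `min` available as an alternative.  The product is the default
because it factorizes: summed over all \(L^T\) paths it telescopes into
\(\prod_t \sum_l \mu_l = 1\) per gene, so flow widths
\(w_c(p) = \sum_g m_{g,c}(p)\) sum *exactly* to the number of genes — an
identity the test suite checks to \(10^{-9} G\), and which makes the
alluvial diagram an exact decomposition of the gene population.  It also
permits computing all path memberships by accumulating one condition at a
time instead of looping over paths; the suite verifies the factorized
computation against explicit path enumeration to \(10^{-12}\).

### Pattern selection and cluster scope

`FlowPattern` predicates operate on paths: `final_above_all_prior` keeps
paths whose final level strictly exceeds *every* earlier level.  This is a
deliberate formalization choice: "increased in the final condition
compared to both baselines" compares against each baseline separately and
does not require a monotone trend across the series (an infection response
need not pass through the sterile-inflammation level on the way).
`minFinalLevel` additionally requires the final level to reach a label
(e.g. Medium), which excludes genes that merely wobble at the bottom of
the scale.

Because the selected paths are disjoint, a gene's membership in the
selected set is the sum of its path memberships, and is at most 1 under
the product combiner.  Cluster scope then combines per-cluster values:
`all_clusters` takes the minimum (fuzzy AND — the gene must follow a
selected flow in *every* cluster), `any_cluster` the maximum.  The minimum
is the standard fuzzy conjunction and makes the "in all subsets" claim
conservative: one discordant cluster caps the gene's score.

Ranking (`topGenes()`) sorts by combined membership with deterministic
lexicographic tie-breaking.

### Enrichment

Two modes test gene sets against flow memberships.  The crisp mode
thresholds memberships (default 0.5, inclusive) and applies the one-sided
hypergeometric over-representation test via `stats::phyper`; the weighted
mode scores each set by the sum of member memberships and permutes the
membership vector over the universe (p = (1 + #{perm ≥ obs})/(1 + nPerm)).
Benjamini–Hochberg controls the FDR across sets in both modes.  The
universe is deliberately the genes that survived the expression gate, not
the full annotation, to avoid composition bias.  Depletion testing and
ontology-graph redundancy reduction are out of scope.

### Antibody-based cell calling and UMI filtering

Cell populations with little RNA (neutrophils are the canonical case) are
truncated by transcript-count filtering, so cells can instead be called
from surface antibody captures: a cell is kept when its count reaches a
threshold for *every* required antibody (e.g. CD45 plus MHC class I).
Thresholds are either explicit or the 99th percentile of a declared
background population; both are exposed because gate choices in published
data are rarely recoverable.  `umiFilter()` keeps cells at or above the
cutoff — the boundary is inclusive, a convention this package fixes
explicitly since "a cutoff of 100" does not by itself say which side the
boundary belongs to.  `downsampleAndPool()` caps each sample's
contribution (uniformly, without replacement, seeded) before pooling a
cohort, keeping undersized samples whole with a warning rather than
failing.

### Module scores

`moduleScore()` is the binned-control scheme: genes are placed in 24
equal-frequency bins of mean expression, each set gene draws 100 controls
from its bin excluding the set itself, and a cell's score is the mean
over set genes minus the mean over the pooled control multiset.  The
multiset matters: controls are pooled with multiplicity so that control
bins are weighted exactly as the set's bins are — collapsing to unique
controls would weight bins by coverage instead and biases the null
noticeably (the package's null-calibration test caught exactly this
during development).  Under a structureless null, per-set mean scores
scatter around zero with a spread of roughly the within-bin expression
spread divided by \(\sqrt{|S|}\), so small random sets fluctuate more than
module-scale (≥ 100 gene) sets.

## The synthetic cohort generator

`syntheticSpec()`/`simulateCiteSeq()` generate the ground-truth data every
quantitative claim in the package is tested against.  The defaults are
fixed once and describe the emulated study shape:

| parameter | default | rationale |
|---|---|---|
| genes | 5,000 | desk-scale transcriptome |
| clusters × conditions | 5 × (healthy → sterile inflammation → infection) | five cell substates over an ordered three-cohort series |
| cells | 2 samples/condition × 100 cells/(cluster, sample) → 200 per group | enough for stable group means |
| RNA counts | NB, dispersion 0.3, log-normal(−1, 1) baseline means | overdispersed counts with a realistic mean–variance spread |
| planted pattern | 50 genes × fold change 4, final condition, all clusters | the "switched on by infection everywhere" signal |
| planted gene pool | 25th–75th percentile of baseline means | a fold change on an unexpressed gene is undetectable and one on an already-maximal gene is not a level shift; moderately expressed genes are where the planted pattern is meaningful |
| antibodies | NB mixture, stained mean 100 vs background 2, dispersion 0.1 | well-separated staining, as for abundant surface epitopes |

Everything derives from one mandatory seed; identical specs are
byte-identical.  The generator deliberately omits batch effects, ambient
RNA, doublets and cell-cycle structure — passing tests therefore
demonstrate correctness of the method's algebra and its behavior under
idealized noise, not robustness to the artefacts of real droplet data.
Cluster labels are inputs throughout; the package neither clusters nor
corrects them.

## Numerical and degenerate-case choices

* Path enumeration refuses more than \(10^6\) paths (configurable) rather
  than silently thrashing; with four levels that admits up to nine
  conditions.
* `fitFuzzySpec()` rejects degenerate (non-increasing) anchors, which
  arise when the positive means are too concentrated for the requested
  level count, and says so.
* Cells with zero total counts normalize to zero rather than NaN.
* Permutation p-values use the add-one estimator, so they are never 0.
* All stochastic functions take an explicit seed and restore the caller's
  RNG state; nothing in the package touches global random state.
* Ties in gene rankings break lexicographically; ties in the equal
  frequency binning of gene means split by first occurrence.  Both are
  arbitrary but deterministic.

## Problem sizes used by the checks

The test suite and the acceptance script exercise: the full default cohort
(5,000 genes × 3,000 cells) for planted-pattern recovery; 200-gene random
tensors for conservation and brute-force equivalence; every hypergeometric
configuration with a universe up to 30 against a combinatorial oracle; 200
repeats × 5 sets for permutation type-I calibration; 1,000 stained +
background cells for antibody calling; and 2,000 structureless cells for
module-score nulls.  These sizes keep each property at the scale where its
guarantee is stated while running in seconds to a few minutes.

## Known limitations

* Anchors are data-derived quantiles, so level vocabulary is relative to
  the dataset at hand; comparing flows *across datasets* requires fixing a
  shared spec explicitly.
* Flow widths are descriptive; the package attaches no significance
  measure to a flow's width, and the enrichment layer tests gene sets, not
  flows.
* The product combiner treats conditions as independent evidence; strongly
  correlated group estimates (e.g. few cells shared across conditions) are
  not modeled.
* Per-cell fuzzification and learned membership functions are out of
  scope.
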