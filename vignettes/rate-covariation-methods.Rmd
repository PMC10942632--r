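---
title: "Evolutionary rate covariation: models, tests, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary rate covariation: models, tests, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ercovar)
```

# The problem

Two proteins whose functions are coupled tend to experience correlated
shifts in evolutionary rate: when selection relaxes or intensifies on the
shared function, both genes' branches lengthen or shorten together.
`ercovar` quantifies this as evolutionary rate covariation (ERC) and then
asks a finer-grained question: within a protein complex, do *physically
contacting* domains covary more than domains of the same proteins that do
not touch? Because complex members are co-functional by construction,
contrasting domain pairs *within* a complex controls for the co-functional
signal and isolates the contribution of physical contact.

The package assumes the standard input of this field: a master species tree
and one tree per gene (or per domain) whose topology equals the master
topology pruned to the species that gene retains, with branch lengths in
expected substitutions per site.

# Branch keys: matching branches across genes

Different genes miss different species, so "the same branch" must be defined
carefully. Every branch is identified by the set of master-tree species
descending from it. A pruned gene tree's branch, with pruned-descendant set
*D*, is matched to the **minimal** master branch whose descendant set,
restricted to the gene's species, equals *D*. When a path of master branches
collapses into one gene-tree branch (because intervening splits lost all
their other descendants), the merged length is thus attributed to the
leaf-most branch of the path. This rule is injective, reduces to the
identity when no species are missing, and is a package choice: with missing
taxa there is no canonical attribution of a merged path, and nothing
downstream depends on which end of the path receives it, only on the choice
being applied consistently to every gene.

# Relative evolutionary rates

For the branch-length matrix `L[g, b]` the genome-wide expectation `m_b` is
estimated in two passes: a provisional per-branch mean puts each gene on a
common scale (`s_g` = the gene's total length over its branches divided by
the provisional expectation of those branches), and the per-branch mean is
then recomputed from the rescaled lengths. One refinement pass is used,
deliberately fixed rather than iterated to convergence, so the estimate is
deterministic and reproducible; the alternation is already essentially at
its fixed point after one pass (exact for proportional gene families, as the
tests assert).

The default RER is the centred log-ratio

    RER[g, b] = log( L[g, b] / (s_g * m_b) ) - per-gene mean,

which satisfies three contract properties exactly: a gene proportional to
the expectation has RER ≡ 0; rescaling a gene's lengths changes nothing;
missing branches stay missing (no imputation). A second method
(`"residual"`) regresses `sqrt(L)` on `sqrt(s_g * m_b)` per gene and uses
the residuals divided by `sqrt(s_g)`. Classical descriptions of this family
of methods studentize such residuals; we deliberately normalize by scale
instead, because studentized residuals are scale-free and would *not*
shrink to zero as branch-length noise vanishes — they would break the
contract that both methods agree in the null. Zero-length branches are
floored at a pseudo-length of 1e-9, which keeps logarithms finite without
perturbing ordinary branches; because the floor only binds at zero, scale
invariance remains exact for positive lengths.

# ERC and the Fisher transform

For a gene pair, both RER vectors are restricted to the branches present in
both, each restricted vector is winsorized, and the Pearson correlation *r*
over the `n` shared branches is transformed to

    ftERC = atanh(r) * sqrt(n - 3).

Dividing the Fisher z by its null standard error makes pairs with different
branch counts directly comparable (null mean 0, variance ≈ 1, which the test
suite verifies empirically at n = 20, 50, 200). `r = ±1` is clamped at
1 − 1e-12 so the statistic stays finite while preserving order.

Winsorization condenses the three most extreme values in each tail to the
fourth, by value (ties at the boundary are treated alike wherever they sit).
It is applied per pair, to the vectors the correlation actually sees —
after restriction to shared branches — because an outlier branch matters
only on the branches entering the correlation. Three per tail (rather than
three overall) is the interpretation implemented; the depth is a parameter
(`winsor_k`) should a user want the other reading. Pairs sharing fewer than
15 species are filtered, not errored: the threshold is interpreted as shared
*species* (the shared *branch* count is what enters `sqrt(n - 3)`). Pairs
whose winsorized vector is constant are filtered with reason
`"zero_variance"`.

# Permutation tests and their conventions

All three permutation tests share one convention: with B replicates
(default 1000), `p = (1 + #{null >= observed}) / (1 + B)`. The add-one rule
never reports zero; at B = 1000 the floor is 1/1001, i.e. "< 0.001". Ties
between observed and null statistics count against significance, the
conservative direction.

* **Gene sets.** The observed statistic is the mean ftERC over unfiltered
  in-set pairs (optionally excluding a masked list of pairs, e.g. physically
  interacting pathway members). Null sets are drawn uniformly without
  replacement, size-matched, from *all* genes with computed RERs — not just
  annotated genes — and scored under identical filter and mask rules; a null
  replicate with zero usable pairs is redrawn and counted. Sets need more
  than four members after intersection with the dataset.
* **Complex ROC.** The ranked edge list is held fixed and the positive
  labels are reassigned to uniformly random positions. AUC is computed
  tie-aware (midpoint counting), which equals `U/(n0*n1)` and the
  trapezoidal area under the tie-aware curve. The study-wide test averages,
  per replicate, each complex's b-th permuted AUC.
* **Proportional rank.** Within one protein pair, the T inter-protein
  domain pairs are ranked by ftERC (average ranks on ties) and each physical
  pair scores `(T - rank)/(T - 1)`; multiple physical pairs are averaged.
  The complex statistic averages its protein pairs' scores; the nested null
  draws, per replicate, one random label placement per protein pair and
  averages. Protein pairs enter only if they share a physical interaction;
  pairs with T < 2 or with every pair physical are excluded (the statistic
  is undefined there) and logged.

The one-tailed Mann–Whitney test (alternative: physical pairs rank higher)
is delegated to `stats::wilcox.test`: exact enumeration when the two classes
total at most 12 tie-free values, otherwise the normal approximation with
tie and continuity corrections. The exact/approximate switch is validated
against an exhaustive arrangement-enumeration oracle in the tests.

Intra-protein domain pairs are excluded from the negative class by default:
domains of one protein share a gene tree's overall rate history, so their
ERC is trivially inflated and would dilute the contrast of interest. The
flag `include_intra_protein` restores them for sensitivity analysis.

# The synthetic-data generator

`simulate_study()` emulates the features of a real multi-species ortholog
dataset that the statistics respond to:

* a **Yule master tree** (default S = 40 species; at least 20, so the
  15-species filter is a live constraint). The pure-birth construction grows
  from 2 to S lineages and appends one final exponential epoch, giving
  E[total tree length] = S / birth rate — a closed form the tests check by
  Monte Carlo;
* **latent-factor RERs** with unit cell variance: domains in the same
  module share a per-branch factor with loading `sqrt(rho_mod)`, designated
  physical pairs share an extra factor with loading `sqrt(rho_phys)`, and
  the remainder is idiosyncratic. The population correlation of any two
  units is therefore exactly `rho_mod` (same module) plus `rho_phys`
  (physical pair) — the quantity ERC estimates — and is written to a truth
  table;
* **multiplicative log-normal noise**: branch lengths are
  `m_b * exp(sigma_noise * RER)` with `sigma_noise = 0.3` by default, a
  moderate rate dispersion at which RER recovery from emitted trees is
  nearly perfect (the suite requires per-gene correlation ≥ 0.95 with the
  truth at zero dropout);
* **i.i.d. taxon dropout** (default 10% per species per gene); draws
  leaving fewer than two species are redrawn. Clustered, phylogenetically
  structured missingness — which real ortholog detection produces — is
  *not* modelled, so calibration results here do not certify behaviour
  under systematically biased taxon sampling.

All randomness flows from one seed through derived per-component streams, so
a gene's tree does not depend on how many genes precede it. What passing
tests on these studies show is that the estimators recover known correlation
structure and that the permutation tests are calibrated under the model's
null; they cannot show robustness to misspecification real data may carry
(non-normal rate shifts, reference-tree error, correlated missingness).

# Numerical and degenerate-case policy

* Edge-list ties in ftERC: stable sort by (ftERC descending, domain_a,
  domain_b); average ranks for proportional rank; midpoint counting for AUC.
* Complexes without at least one physical and one non-physical edge with
  ERC values are degenerate: the ROC is undefined, the complex is skipped
  and listed in the run manifest.
* Filtered ERC pairs never silently disappear: edge lists carry an
  `n_dropped` attribute, the ERC table keeps a `filter_reason` per pair, and
  the manifest tallies the 15-species and zero-variance counts.

# Problem sizes used in validation

The shipped validation suite runs entirely on synthetic studies of desk
scale, chosen so the whole suite completes in a few minutes: null
calibration uses a 250-gene universe with 500 random sets (set test) and
200 complexes pooled from four independent studies (AUC permutation
uniformity, pooled so complexes do not all share one estimated master
tree); signal recovery uses 20 replicate studies per condition across
`rho_mod` ∈ {0, 0.3, 0.6, 0.9} and `rho_phys` ∈ {0, 0.2, 0.4, 0.6}. The
acceptance script's flagship study uses 30 species, 20 gene sets and 17
domain-resolved complexes, mirroring the shape (not the size) of a full
343-species study.

# Known limitations

* Trees are consumed as given: no re-rooting, no tree estimation, and no
  support for polytomies beyond those pruning creates.
* Under taxon dropout, a gene tree's collapsed path (a merged branch) shares
  a key with other genes' unmerged branch, so its length systematically
  exceeds the per-branch expectation; genes that happen to share missing
  taxa then share positive RER excursions at the same keys. This inflates
  the baseline ftERC of unrelated pairs by an amount that depends on the
  master tree's branch-length geometry. The permutation tests remain
  internally calibrated — observed and null statistics face the same
  inflation, which the null-calibration tests confirm at 10% dropout — but
  the detection power for modular signal at a fixed `rho_mod` degrades as
  dropout grows. An alternative (re-pruning both trees to each pair's
  common species set, as some classical pipelines do) trades this bias for
  a per-pair recomputation cost and is out of scope here.
* RERs are computed without phylogenetic covariance corrections; the
  log-ratio method is transparent and exactly testable but is not a
  reimplementation of any specific published RER software.
* ERC is plain (winsorized) Pearson correlation: no partial correlations
  or GLS corrections for shared tree structure.
* Per-complex p-values are reported raw, without multiple-testing
  correction; `binomial_tail()` is provided for count-level arguments
  across complexes.
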