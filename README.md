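# ercovar

Evolutionary rate covariation (ERC) analysis on phylogenies, from branch
lengths to complex-level statistics.

Proteins that work together tend to speed up and slow down their evolution
together: across the branches of a species phylogeny, their rates covary.
`ercovar` implements the full analysis chain used to ask a sharper question —
*does physical contact between two proteins (or two protein domains) add
covariation beyond what shared function already explains?* It is built for
datasets of per-gene (or per-domain) phylogenetic trees that all conform to
one master species topology, such as large yeast ortholog collections.

## The statistics

**Relative evolutionary rate (RER).** For gene *g* on branch *b*, with
branch length `l_gb`, genome-wide expected length `m_b`, and gene scale
`s_g` (the gene's total length relative to the expectation over its
branches):

    RER_gb = log( l_gb / (s_g * m_b) ),   centred per gene

so a gene proportional to the genome-wide tree has RER ≡ 0, and RERs are
invariant to the gene's overall rate. A square-root regression variant
(`method = "residual"`) is provided with the same contract.

**ERC.** For a gene pair, both RER vectors are restricted to branches
present in both trees, winsorized (the 3 most extreme values per tail
condensed to the 4th), Pearson-correlated, and Fisher-transformed:

    ftERC = atanh(r) * sqrt(n - 3)

with `n` the number of shared branches. ftERC has null mean 0 and variance
≈ 1, so pairs with different branch counts are directly comparable. Pairs
sharing fewer than 15 species are filtered out.

**Set, ROC, and rank tests.**

* mean ftERC of a complex/pathway vs. 1000 size-matched random gene sets
  (add-one permutation p-value; optional masking of physically interacting
  pairs);
* per-complex domain edge lists ranked by ftERC, scored by tie-aware
  ROC-AUC = U/(n0·n1), with a one-tailed Mann–Whitney test and a
  label-permutation null, plus a study-wide average-AUC permutation test;
* the proportional rank (T − rank)/(T − 1) of each physically interacting
  domain pair among the T domain pairs of its protein pair (1 = first,
  0 = last), averaged per complex with a nested permutation null.

A latent-factor simulator (`sim_config()`, `simulate_study()`) generates
complete synthetic studies — Yule master tree, taxon dropout, log-normal
branch noise, module factors (`rho_mod`) and physical-pair factors
(`rho_phys`) — with the population correlation of every unit pair recorded
in a truth table, so every stage can be validated quantitatively.

## Worked example

```r
library(ercovar)

study <- simulate_study(sim_config(
  S = 25, n_background_genes = 20, seed = 7,
  modules = tibble::tibble(module_id = "m1", kind = "complex",
                           n_members = 6, rho_mod = 0.6),
  complexes = tibble::tibble(complex_id = "cx1", n_proteins = 4,
                             n_physical_pairs = 3,
                             rho_mod = 0.2, rho_phys = 0.5)
))
run <- run_full_study(study, pipeline_params(B = 200, seed = 3))

run$set_results[, 1:7]
#> # A tibble: 1 × 7
#>   set_id kind    n_members mean_erc n_pairs_used     B       p
#>   <chr>  <chr>       <int>    <dbl>        <int> <dbl>   <dbl>
#> 1 m1     complex         6     5.86           15   200 0.00498

tidy(run)[, c("complex_id", "mean_erc", "mean_physical_erc", "auc", "p_mw", "prop_rank")]
#> # A tibble: 1 × 6
#>   complex_id mean_erc mean_physical_erc   auc   p_mw prop_rank
#>   <chr>         <dbl>             <dbl> <dbl>  <dbl>     <dbl>
#> 1 cx1            2.60              4.15 0.741 0.0945     0.622
```

The module simulated with `rho_mod = 0.6` shows a mean ftERC of 5.9 over
its 15 pairs, above all 200 size-matched random sets (p = 1/201 — the
add-one convention's floor, reported as "< 0.005" at this B). In the
domain-resolved complex, physically interacting pairs (`rho_phys = 0.5` on
top of the complex-wide 0.2) average a higher ftERC (4.15) than the complex
overall (2.60); the ROC analysis ranks them above non-physical pairs with
AUC 0.74 and the physically interacting domain pairs sit at a mean
proportional rank of 0.62 within their protein pairs.
`autoplot()` methods display ROC curves and permutation nulls; `tidy()` and
`glance()` return tibbles for every result object.

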