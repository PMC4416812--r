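# birw

Global prediction of phenotype–gene associations by bi-random walk on a
heterogeneous network, with the circular-bigraph statistics that motivate
it, comparison baselines, and an ab-initio evaluation protocol.

## The problem

Databases of disease phenotypes (OMIM) and model-organism phenotypes (MGI)
record which genes cause which phenotypes, but the recorded bipartite
association map is sparse and incomplete. Given a phenotype similarity
network *P* (m×m, weights in \[0,1\]), a gene interaction network *G*
(n×n), and the known associations *A* (m×n binary), the goal is to
reconstruct the complete score matrix *R* (m×n) at once — for every
phenotype simultaneously, not one query at a time. The package is aimed at
computational biologists benchmarking network-based disease-gene inference
and at anyone who needs the circular-bigraph coverage statistics of a
phenome–genome network.

## The method

The structural signal is the **circular bigraph (CBG)**: a phenotype path
and a gene path whose end pairs are joined by two associations. Most true
associations participate in CBGs of small path length, far above what
randomized associations produce, and the degree to which they do predicts
how recoverable they are.

**BiRW** exploits this by propagating the normalized association matrix on
both networks with a decay factor α and independent step caps:

    P̄ = D_P^{-1/2} P D_P^{-1/2},  Ḡ = D_G^{-1/2} G D_G^{-1/2},  Â = A / ΣA
    R₀ = Â
    for t = 1..max(l, r):
        left  (t ≤ l):  α P̄ R_{t-1} + (1-α) Â
        right (t ≤ r):  α R_{t-1} Ḡ + (1-α) Â
        R_t = average of the active updates

A cell's final score aggregates the CBGs linking it to known associations,
discounted geometrically in path length by α. Defaults carry the published
settings (human: α = 0.8, l = r = 4; mouse: α = 0.7, l = 5, r = 1).

The package also provides the balanced fixed-point variant and its
Kronecker regularization objective (for small-instance validation),
PRINCE / RWRH / CIPHER baselines, ab-initio cross-validation with
AUC-at-k-false-positives and recall metrics, disease-class bi-module
extraction, ontology-based phenotype-network construction (OBO parsing,
level selection, annotation roll-up, Jaccard similarity), and a synthetic
generator with planted CBG structure. See `vignettes/birw-methods.Rmd` for
the full account.

## Worked example

```r
library(birw)
library(dplyr)

# A synthetic heterogeneous network with planted CBG structure:
# 150 phenotypes, 200 genes, 20% of associated phenotypes held out ab initio.
sim <- generate_hetero(synthetic_config(seed = 1))
sim$net
#> <birw_heteronet> 150 phenotypes, 200 genes, 187 associations

# CBG coverage of the observed associations, against the randomized null
cov <- cbg_min_lengths(sim$net$P, sim$net$G, sim$net$A, L_max = 3)
cbg_coverage_curve(cov)
#>       L coverage
#> 1     1    0.465
#> 2     2    0.717
#> 3     3    0.802
null_coverage(sim$net$P, sim$net$G, k = nrow(sim$net$A$pairs),
              L_max = 3, reps = 50, seed = 2)
#>       L mean_coverage sd_coverage
#> 1     1         0.104      0.0282
#> 2     2         0.304      0.0479
#> 3     3         0.528      0.0490
```

72% of the observed associations close a CBG of length ≤ 2, versus
30% ± 5% for uniformly random associations — the locality signal BiRW
feeds on.

```r
# Reconstruct the association matrix and rank genes for a held-out phenotype
pred <- birw_predict(normalize_hetero(sim$net), birw_params(alpha = 0.8, l = 4, r = 4))
q <- sim$holdout_phenotypes[1]           # "p002": all its associations removed
head(rank_genes(pred, q), 5)
#>    rank gene     score
#> 1     1 g063  0.000340
#> 2     2 g062  0.000324
#> 3     3 g187  0.000311
#> 4     4 g021  0.000236
#> 5     5 g093  0.000233

# Recovery of the held-out truth over all masked phenotypes
aucs <- sapply(unique(sim$truth$pairs$phenotype), function(p)
  auc_at_fp(rank_genes(pred, p),
            sim$truth$pairs$gene[sim$truth$pairs$phenotype == p], Inf))
mean(aucs)
#> [1] 0.717
```

A mean full AUC of 0.72 for phenotypes whose every association was removed
before prediction, against ~0.5 for random scores: the genes are recovered
from network context alone. `tidy()`, `glance()` and `autoplot()` methods
are available on predictions, coverage objects and cross-validation results
(`run_cv()`).

A command-line front end over the same functions ships at
`inst/cli/birw-cli.R` (subcommands `simulate`, `predict`, `cbg`, `rank`,
`cv`, `module`).

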