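---
title: "Bi-random walk phenome-genome prediction: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bi-random walk phenome-genome prediction: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(birw)
library(dplyr)
```

## The problem

A heterogeneous phenotype–gene network consists of three parts: a phenotype
similarity network $P$ ($m \times m$, weights in $[0,1]$, e.g. text-mining
similarity between disease phenotype records or Jaccard similarity between
ontology terms), a gene interaction network $G$ ($n \times n$, e.g. a
protein–protein interaction network), and a bipartite set of known
phenotype–gene associations $A$ ($m \times n$, binary). Known associations
are sparse and incomplete; the task is to reconstruct the full association
matrix $R$ so that every cell $(i, u)$ carries a score for phenotype $i$
being associated with gene $u$. This is a *global* reconstruction: all
phenotypes are scored simultaneously, in contrast to per-query gene
prioritizers.

## Circular bigraphs

The structural assumption is that true associations rarely occur alone: an
association $(p, g)$ tends to have a partner association $(p', g')$ with $p'$
close to $p$ in the phenotype network and $g'$ close to $g$ in the gene
network. The closed structure — a phenotype path, a gene path, and the two
associations joining their endpoints — is a *circular bigraph* (CBG). Its
length is the larger of the two path lengths; degenerate paths of length 0
give the triangle cases (two phenotypes sharing a causal gene, or two
interacting genes causing the same phenotype), and length-1 paths give the
rectangle case (interacting genes associated with similar phenotypes).

`cbg_min_lengths()` reports, per known association, the smallest $L$ at which
a partner exists, using unweighted shortest-path (BFS) distances on the
binarized networks: "covered by a CBG of length up to $L$" is an existence
claim, and the shortest path witnesses it. The identical partner is
excluded; a partner may share the phenotype or the gene but not both.
Counting, as opposed to coverage, follows the matrix algebra of the method:
`cbg_count_matrix()` computes $P^l A G^r$ on binary adjacency, i.e. *walk*
counts, which is what repeated multiplication actually enumerates.
`null_coverage()` calibrates observed coverage against associations replaced
by uniform random pairs of the same count; the separation between the two is
what motivates using network proximity for prediction at all.

## The bi-random walk

Both networks are symmetrically degree-normalized,
$\bar P = D_P^{-1/2} P D_P^{-1/2}$ (likewise $\bar G$), which bounds their
spectral radius by 1; rows of zero-degree nodes are left at zero rather than
raising an error, because real interaction networks contain isolated
components. $A$ is normalized by its grand sum, $\hat A = A / \sum A$.
Starting from $R_0 = \hat A$, the walk iterates for $t = 1, \dots, \max(l, r)$:

$$R_t^{left} = \alpha \bar P R_{t-1} + (1 - \alpha)\hat A \quad (t \le l),
\qquad
R_t^{right} = \alpha R_{t-1} \bar G + (1 - \alpha)\hat A \quad (t \le r),$$

and $R_t$ is the average of whichever updates are active at step $t$. There
is no convergence test: the walk runs exactly $\max(l, r)$ steps. The two
caps matter because the phenotype and gene networks have different
topologies; the optimal number of steps need not be the same on both sides.
Unrolling the recursion shows each score aggregates CBGs with phenotype
paths up to length $l$ and gene paths up to length $r$, with a CBG of total
walk length $k$ discounted by roughly $\alpha^k$ — the decay factor
$\alpha \in (0, 1)$ penalizes long, weakly informative patterns.

Published settings carried as defaults: $\alpha = 0.8$, $l = r = 4$ for the
human OMIM/PPI setting and $\alpha = 0.7$, $l = 5$, $r = 1$ for the mouse
MP-ontology setting.

Two companion routines exist for validation rather than production use.
`birw_fixed_point()` iterates the balanced infinite-walk update
$R \leftarrow \tfrac{\alpha}{2}(\bar P R + R \bar G) + (1-\alpha)\hat A$ to a
fixed point; since $\|\bar P\|_2, \|\bar G\|_2 \le 1$ the update is a
contraction with factor at most $\alpha$ *in the spectral/Frobenius norm*
(note: not entrywise max norm — row sums of a symmetrically normalized
matrix can exceed 1), so convergence is geometric and the fixed point equals
the solution of the vectorized linear system
$(I - \tfrac{\alpha}{2}(\bar G^\top \otimes I + I \otimes \bar P))\,\hat R =
(1-\alpha)\hat A$, which the tests solve densely as an oracle.
`birw_objective()` evaluates the graph-regularization objective the balanced
walk minimizes,

$$\alpha \sum_{(i,u),(j,v)} (P \otimes G)_{(i,u),(j,v)} (R_{i,u} - R_{j,v})^2
+ (1 - \alpha) \sum_{i,u} (R_{i,u} - A_{i,u})^2,$$

whose smoothness term asks cells joined by a length-1 CBG to carry similar
scores. The sum runs over ordered index pairs, so the quadratic form is
$2\,\hat R^\top (D - P \otimes G)\hat R$ with $D$ the row-sum diagonal of the
Kronecker product — the factor 2 is checked against an explicit four-index
summation in the tests. The objective is stated on small instances only
(guarded at $mn \le 10^4$): forming $P \otimes G$ densely is quadratic in
$mn$ and is a validation device, not an algorithm. We do not assert the
algebraic equivalence between the *unbalanced* averaged update and this
Kronecker-product objective; each component is tested against its own
definition.

## Baselines

Three per-query prioritizers are re-implemented from their published
sketches, for comparison only:

* **PRINCE-style label propagation** — a prior over genes built from the
  causative genes of phenotypes similar to the query (logistic-weighted,
  each gene keeping its maximum, normalized to unit mass), propagated on the
  symmetric-normalized gene network by
  $F \leftarrow \alpha W F + (1-\alpha) Y$. The logistic curve
  $w(s) = 1/(1 + e^{cs + d})$ uses the published $c = -15$,
  $d = \ln 9999$ (configurable; this choice suppresses weak similarities).
* **RWRH** — random walk with restart on the combined $(m+n)$-node network;
  nodes incident to associations divert `jump_prob` of their transition
  mass across the bipartite edges, and the restart distribution splits
  `seed_balance` of its mass between the query phenotype and its known
  genes. The published triple $(0.5, 0.7, 0.5)$ is read as (jump, restart,
  seed balance) in that order — the source prints the triple without naming
  components, so the mapping is configurable.
* **CIPHER** (DN and SP) — scores a gene by the Pearson correlation between
  its closeness profile over phenotypes (sum of weights of its distances to
  each phenotype's causative genes; DN uses the self/adjacency indicator,
  SP the shortest-path length) and the query's similarity profile.
  Distances are mapped to similarities by $e^{-d}$ before the logistic
  weight, so an unreachable gene contributes $w(0) \approx 10^{-4} \approx 0$.
  Zero-variance profiles have no defined correlation and receive a $-\infty$
  sentinel, ranking last.

These are faithful implementations of the sketches, not certified clones of
the original tools.

## Evaluation protocol

Cross-validation is *ab initio*: phenotypes (not associations) are
partitioned into folds by a seeded shuffle dealt round-robin, and every
association of a test phenotype is removed before prediction, so the method
must recover a phenotype's genes with no residual anchor. Rankings over the
full gene universe are scored by:

* **AUC at $k$ false positives** (`auc_at_fp()`): the ROC step curve
  truncated after the $k$-th negative, each negative contributing a
  rectangle at the TPR attained just above it, normalized by $k$ so a
  perfect ranking scores 1. When the ranking holds fewer than $k$ negatives
  the curve is extended at TPR 1; with $k = $ number of negatives (or
  $k = \infty$) the measure reduces exactly to the Mann–Whitney AUC, which
  the tests verify by pair counting. The normalization rule (divide by $k$,
  rectangle integration) is applied uniformly to every method, which is
  what preserves comparability.
* **Recall at top $k$** (`recall_at_k()`).
* Paired $t$-tests compare methods per phenotype; a zero-variance nonzero
  difference returns the documented limit $t = \pm\infty$, $p = 0$.

Ties in scores are broken by ascending gene label before any metric is
computed, making every ranking and therefore every metric deterministic.

## The synthetic benchmark

Real inputs at their native scale are licensed database snapshots; the
package instead ships a generator (`generate_hetero()`) whose default
configuration defines the package's standard benchmark:

| parameter | default | meaning |
|---|---|---|
| `m`, `n` | 150, 200 | phenotype / gene counts |
| `pheno_knn` | 5 | kNN sparsification of the ring similarity |
| `gene_degree`, `rewire_prob` | 2, 0.05 | small-world gene network |
| `n_seed_assoc` | 120 | uniform seed associations |
| `expansion_prob` | 0.8 | chance a seed gets a planted partner |
| `partner_radius` | 2 | maximum CBG length of the planted partner |
| `noise_frac` | 0.1 | uniform random associations added |
| `holdout_frac` | 0.2 | phenotypes moved wholesale to the truth set |

Phenotypes sit on a ring with similarity decaying in ring distance (jittered
to break ties), so shortest-path structure is controlled; genes form a
Watts–Strogatz small world. For each seed association, with probability
`expansion_prob` a partner is planted: the CBG length is drawn uniformly
from $1..L$ and the partner uniformly among the cells at exactly that
length. Stratifying by length keeps short CBGs dominant, which is the
empirical signature of real association networks, and keeps coverage at $L$
tunable by `expansion_prob`. Two scale choices deserve a note: at
$n = 200$, radius-2 gene neighborhoods must stay small relative to the
network for locality to carry information at all, hence the sparsest
connected small world (mean degree 2 plus shortcuts); with a denser gene
network the radius-2 ball around the planted partners covers a large
fraction of the gene universe, the planted task becomes ill-posed, and no
scorer — not even one reading the true distances — can separate planted
genes from the crowd. Random numbers are consumed in a fixed documented
order (phenotype jitter, gene network, seeds, partners, noise, holdout), so
outputs are byte-identical across runs and adding features later cannot
silently shift old fixtures.

What the generator does *not* emulate: the heavy-tailed degree
distributions of curated interaction databases, study-bias correlation
between node degree and association count, and text-mining similarity
noise. Passing tests on this benchmark therefore demonstrate that the
implementation exploits planted local structure correctly — not that the
same margins would be observed on OMIM- or MGI-scale data.

## Ontology preparation

For ontology-derived phenotype networks, terms at a fixed depth are selected
(`term_levels()`: level = shortest `is_a` distance from the root, the root
counting as level 1, matching the convention under which annotation density
peaks at level 5 of the Mammalian Phenotype ontology), annotations are
rolled up from descendants (`propagate_annotations()`: a term is associated
with a gene iff it or any descendant is annotated), and terms are connected
by the Jaccard similarity of their propagated gene sets
(`jaccard_network()`). Only `is_a` edges are traversed; `part_of` is
ignored. The Jaccard-over-gene-sets reading is a design choice surfaced in
the interface — a structural (ontology-topology) similarity would be a
different, equally defensible choice.

## Bi-modules

`extract_bimodule()` condenses a prediction into a disease-class module: per
class phenotype, candidates are its known genes plus its top
$\lceil \text{top\_frac} \cdot n\rceil$ predicted genes (3% by default; with
a 2466-gene universe that ceiling is the published 74); genes supported by
at least `min_support` phenotypes (or all of them, for classes smaller than
the threshold) form the module. Known genes always count toward support.
The module depends only on the class's rows of $R$, and raising the support
threshold can only shrink it — both properties are tested.

## Numerical and degenerate-input choices

* Zero-degree nodes: all-zero normalized rows, never division errors.
* kNN sparsification: union symmetrization (an edge survives if either
  endpoint selects it), ties at the $k$-th weight all kept — deterministic
  and idempotent without arbitrary ordering.
* Phenotype edge weights are *kept* after kNN selection for the random walk
  (configurable by binarizing upstream); CBG statistics always binarize,
  since path length there is a hop count.
* All-zero association matrices are a hard error ("empty association set").
* `birw_predict` has no tolerance — it is an exact finite recursion;
  `birw_fixed_point` reports its last residual if the iteration cap is hit.
* Scores are written to TSV at 17 significant digits so write/read round
  trips are lossless.
* Seeds: every stochastic component takes an explicit seed and uses a local
  RNG scope, leaving the caller's RNG state untouched.

## Problem sizes

The test suite validates exact equivalences on instances up to $20 + 20$
nodes (where brute-force oracles are exact and fast) and runs the
end-to-end benchmark at the default configuration above: 5 replicate
datasets for recovery, 50 null replicates for coverage calibration, and 10
expansion levels for the coverage–predictability correlation. These sizes
were chosen so the planted effects are large relative to their Monte Carlo
error while the whole suite stays interactive.

## Known limitations

* Everything rests on network connectivity: phenotypes in components with
  no known associations are unreachable by propagation, and no prediction
  can be made for them.
* The CBG analysis uses BFS distances, not exact-length simple paths; a
  simple-path reading would be exponential in $L$ and is out of scope.
* The regularization objective is evaluable only on small instances.
* Baselines follow published sketches; parameter mappings noted above are
  explicit but not canonical.
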