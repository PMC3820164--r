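---
title: "Signature-regularized subtyping and driver prioritization: models and methods"
author: "subsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-regularized subtyping and driver prioritization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subsig)
```

## The problem

Expression-based cancer subtyping faces a chicken-and-egg problem: the
genes that delineate subtype boundaries are the subtype-specific
differentially expressed genes, but finding those genes requires knowing
the subtypes.  Unregularized clustering happily splits cohorts into many
clusters, some of which are driven by noise, copy-number load, or
cell-of-origin effects rather than by a distinct transcriptional program.
`subsig` operationalizes a definition of a subtype as *the smallest group
of tumor samples backed by a sizable set of genes dysregulated
specifically in that group* (against all other samples, including
normals), and iterates clustering and signature detection until that
definition is self-consistent.  A second stage ranks externally
pre-selected copy-number-aberration (CNA) candidate genes by their overall
correlation with each subtype's signature.

## Gene signatures

For a fixed partition of the tumor samples into clusters `1..K'`, a gene
belongs to the signature `S_k` of cluster `k` when two requirements hold.

**Statistical significance.**  The gene is differentially expressed in
`k` versus *all* other samples (the other tumor clusters and the normal
controls pooled).  The test is the empirical-Bayes moderated t: per-gene
pooled two-group variances are shrunk toward a common prior fitted by
moments (`limma::squeezeVar()`), the moderated statistic is referred to a
t distribution with augmented degrees of freedom, and p-values are
Benjamini–Hochberg adjusted across genes.  The package also exposes the
unmoderated pooled t (`prior = "none"`) so the moderation can be checked
against an external oracle.  The adjusted-p cutoff `alpha` defaults to
0.05; the moderated test is a standard choice for small per-group sample
sizes, where per-gene variance estimates are unstable.

**Subtype specificity.**  With `mu_k` the mean expression in cluster `k`
and `mu_l` the means of the other groups (other tumor clusters, plus the
normal samples as one additional group), define

    Delta_k  = min(|mu_k - min_{l != k} mu_l|, |mu_k - max_{l != k} mu_l|)
    Delta'_k = max_{l != k} mu_l - min_{l != k} mu_l
    FC_k     = Delta_k - Delta'_k

`Delta_k` measures how far the cluster sits outside the envelope of all
other groups; `Delta'_k` measures how spread out the other groups already
are.  A gene is specific to `k` only if its mean is *strictly* above (or
strictly below) every other group mean and `FC_k` strictly exceeds the
fold-change threshold `fct` (log2 units, default 1.0).  Treating the
normals as one of the "other groups" prevents calling a gene
subtype-specific when it is merely tumor-wide.  Ties in group means give
direction `none`: a tie means the data cannot distinguish which group the
gene marks.

The threshold `fct` is the key specificity dial.  At `fct = 0` any gene
strictly outside the others' envelope by more than their spread counts; at
`fct = 2` a gene must clear the envelope by two log2 units more than the
spread.  Raising `fct` can only shrink signatures (this monotonicity is
asserted in the test suite).

## The iterative loop

Starting from the top `gene_fraction = 10%` most variable genes (variance
over tumor samples only, since normals are never clustered):

1. build a dendrogram of tumor samples on the current gene set;
2. cut into `K` clusters; absorb singleton clusters into their nearest
   cluster by centroid distance (giving `K' <= K` *core clusters*, all of
   size >= 2);
3. detect signatures on the **original, full** matrix under the core
   labels;
4. form the union `Phi` of all signatures;
5. dissolve *bad clusters* — clusters holding fewer than `|Phi| / (4 K')`
   signature genes — re-assigning each of their samples to the nearest
   good cluster's centroid (giving `K'' <= K'`);
6. replace the clustering gene set by `Phi`;
7. set `K = K'' + delta_k` (default `delta_k = 1`) and repeat.

The loop stops when two consecutive iterations produce the same partition
with the same `K''`, or after `max_iter = 10` iterations.  Requiring the
identical partition (not merely an unchanged cluster count) is stricter
but removes a failure mode where the count stabilizes while samples keep
shuttling between clusters.  The `+ delta_k` term deliberately re-tests a
slightly larger `K` each round so the algorithm is never trapped below the
true number of subtypes; the bad-cluster rule provides the downward
pressure.  The default `k_init = 20` starts deliberately high: starting
above the truth costs little (surplus clusters dissolve), starting below
may merge distinct subtypes for an iteration but the `+ delta_k` growth
recovers them.

### Clustering choices

The dendrogram is built from a spectral embedding: similarity between
tumor samples is the shifted Pearson correlation `(1 + r) / 2` over the
current gene set, and the embedding uses the top `embed_dims = K`
non-trivial eigenvectors of the normalized affinity
`D^(-1/2) S D^(-1/2)`.  Two choices here are deliberate and worth
recording.

**Eigenvalue weighting.**  Each eigenvector is scaled by its eigenvalue
before the rows are normalized to unit length.  With `embed_dims = K` and
`K` well above the number of separable clusters, most retained
eigenvectors are noise directions whose entries are as large as the
informative ones; unweighted, they dominate row norms and blur the
cluster geometry.  The eigenvalues of the affinity operator decay sharply
past the informative directions (on the planted testbed below, from ~0.19
to ~0.01), so eigenvalue weighting suppresses the noise dimensions
smoothly and deterministically, without a hard eigengap cut.

**Density-robust agglomeration.**  The embedded points are agglomerated
by single linkage on the *mutual-reachability* distance
`d_mr(a, b) = max(core(a), core(b), d(a, b))`, where `core(x)` is the
distance from `x` to its `min_pts`-th nearest neighbor (default 3) — the
density-robust single-linkage hierarchy familiar from HDBSCAN.  The
reason is specific to this algorithm's update rule.  Because `K` is
always pushed to `K'' + delta_k`, the loop repeatedly cuts the dendrogram
into *more* clusters than the separable structure supports.  What the
surplus cut peels off decides everything downstream:

* if it peels an **outlier singleton**, step 2 absorbs it and the
  partition is unchanged — the loop converges;
* if it **bisects a cluster** into two siblings of near-equal means, the
  strict specificity rule annihilates *both* siblings' signatures (each
  sibling becomes the other's tying "other group" and `FC_k` collapses),
  both are dissolved into *other* clusters, and the next iteration
  rebuilds the correct partition from `Phi` — producing a permanent
  two-cycle that never converges.

Classical average (or complete) linkage bisects: within a homogeneous
cluster the last merges join two substantial halves.  Plain single
linkage is better but still peels multi-sample chains, because two
boundary samples close to each other merge early and then detach
together.  Mutual reachability prevents exactly those outlier–outlier
early merges (any pair of low-density points is pushed apart by their
core distances), so the top of each cluster's subtree peels individual
samples.  On the planted three-subtype testbed, full recovery across
`k_init = 2..20` holds for 0/10 seeds with average linkage, 6/10 with
plain single linkage, and 20/20 with mutual-reachability linkage.  Plain
linkages remain available (`linkage =` any `hclust` method,
`method = "cor_hclust"` for clustering directly on correlation distance).

"Closest cluster", both for singleton absorption and for bad-cluster
dissolution, means nearest cluster centroid (mean coordinate) in the
current embedding, applied per sample.

### Degenerate inputs

An empty `Phi` at any iteration stops with advice to lower `fct`; a
partition in which *every* cluster falls below the signature-size
threshold stops with a diagnostic (on pure-noise data this is the normal
outcome — the algorithm refuses to report structure it cannot back with
signatures, and the test suite asserts it).  Constant genes get zero
variance (never selected), undefined correlations are treated as zero
similarity, and all eigenvector signs are fixed by making the
largest-magnitude entry positive, so runs are deterministic and
seed-independent end to end (only the synthetic generators consume
randomness).

## Driver prioritization

Given a subtype `k` with signature `S_k` (J genes) and an externally
pre-selected list of L candidate CNA genes (e.g. genes in recurrent
GISTIC regions; producing this list is out of scope), the package forms
the between-set covariance `C_ab` (J x L) over the subtype's own samples
and projects it onto its first left singular vector:

    C_ab = U S V^T,   w_hat_b = C_ab^T u_1 = sigma_1 v_1

`w_hat_b[l]` — the *driver potential* — summarizes the overall
correlation of candidate `l` with the whole signature set; its sign says
whether the candidate tracks the signature positively or negatively.
This is the SVD shortcut to the canonical-correlation objective: it does
not maximize the CCA correlation itself, but finds the dominant
covariance direction, which is what the permutation test calibrates.
Covariances are computed over the subtype's samples only, because the
hypothesized dependency is subtype-specific; the gene-wise centering
inside the sample covariance provides the zero-mean precondition the
projection needs.  (Centering the *rows of `C_ab`* after the fact would
instead force the potentials to sum to zero and erase any common shift
shared by the candidates — precisely the signal a one-signed weight
regime plants — so the package deliberately does not do that.)

Significance comes from a permutation null: each of `n_permutations`
(default 1000) rounds draws `|S_k|` genes uniformly from all genes
*excluding the candidates* (so the null is never contaminated by planted
dependencies), recomputes the projection, and pools every null potential
into one empirical distribution.  The two-sided p-value of candidate `l`
is `(1 + #{|null| >= |w_hat_b[l]|}) / (1 + n_null)` — add-one, so p is
never zero, with both tails counted because strongly negative potentials
are as interpretable as positive ones.  Pooling all null entries (rather
than per-candidate nulls) gives a stable common reference distribution at
a fraction of the permutation cost.

## Synthetic testbeds

Two generators make every stage testable without external data.

**Driver testbed.**  `generate_driver_testbed()` draws an i.i.d. standard
Gaussian genes-by-cases matrix (defaults 10,000 x 100; the scaled variant
1,000 x 100 with 50 signature + 100 candidate genes keeps routine runs
fast).  The first block of genes acts as signature genes, the next as
candidates, the rest are NSNC (non-signature, non-candidate) genes used
as the empirical null.  Candidate `i` gets a weight `w_i` by regime
(`pos`: U[0,1], `neg`: U[-1,0], `zero`: 0, `mixed`: U[-1,1]) and each
signature gene `j` is updated with the candidates' *initialized* values:

    x_j <- sum_i w_i c_ij x_i + x_j,   c_ij ~ U(0, 1)

All regimes consume the same random-number stream, so for a fixed seed
they share initialization and `c` exactly.  Expected behavior, asserted
in the acceptance tests: one-signed regimes shift candidate potentials
above/below the NSNC null; `zero` shows no separation; `mixed` leaves the
means indistinguishable but fattens both tails.

**Subtype testbed.**  `generate_subtype_testbed()` plants `K` disjoint
signature blocks (default 3 blocks of 50 genes in 2,000) on a Gaussian
background: each subtype's block is shifted by `+shift` in half its genes
and `-shift` in the other half (default ±3, unit noise) in that subtype's
tumors only, with unshifted normal controls (default 3 x 20 tumors + 10
normals).  The defaults put the planted effect comfortably above the
noise so that failures indicate algorithmic defects, not borderline
power.

What these testbeds deliberately do **not** emulate: within-subtype
heterogeneity (samples are exchangeable inside a subtype), gene-gene
correlation beyond the planted dependencies, batch or platform effects
beyond two-moment shifts, and heavy-tailed microarray noise.  Passing
tests therefore demonstrate the machinery is correct under its own
assumptions; they do not certify performance on real cohorts, where the
separation is weaker and cluster shapes are irregular.

## Cross-dataset validation

Two cohorts are compared by restricting to common genes and transforming
each gene in each dataset to a common scale: mean `(m1 + m2) / 2` and
standard deviation `sqrt(s1^2/n1 + s2^2/n2)` (the standard error scale of
the between-cohort mean difference).  Labels are transferred by k-NN
(`k = 3`, Euclidean distance) on the *training* run's signature union
`Phi`, and scored against the test cohort's self-trained labels as a
confusion matrix.  Two points deserve emphasis:

* signatures and labels are always trained on each cohort's **original**
  scale — the two-moment transform compresses every gene's SD to roughly
  `s * sqrt(2/n)`, so a fold-change threshold calibrated in log2 units
  would be meaningless after normalization; the normalized matrices exist
  only to make distances comparable for the transfer;
* subtype integer labels are arbitrary per cohort, so before scoring, the
  test cohort's subtypes are matched to the training cohort's by greedy
  Jaccard overlap of signature gene sets (`match_subtype_labels()`); the
  matching is reported rather than hidden.

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `fct` | 1.0 | subtype-specific fold-change threshold (log2 units) |
| `alpha` | 0.05 | BH-adjusted significance cutoff |
| `k_init` | 20 | starting number of clusters |
| `delta_k` | 1 | K increment per iteration |
| `max_iter` | 10 | iteration cap |
| `gene_fraction` | 0.10 | initial top-variance gene fraction |
| `bad_cluster_factor` | 1/4 | bad-cluster threshold factor of `Phi/K'` |
| `embed_dims` | K | spectral embedding dimension |
| `min_pts` | 3 | core-distance neighbor order |
| `n_permutations` | 1000 | permutation-null size |
| `p_threshold` | 0.01 | driver significance cutoff |
| `k` (k-NN) | 3 | neighbors for label transfer |

## Problem sizes used in the checks

The automated checks run the full pipeline at the generator defaults
(2,000 genes, 60 tumors + 10 normals) across `k_init = 2..20` and 20
seeds, the scaled driver testbed (1,000 x 100, 50 + 100) for the four
weight regimes, 1,000 random matrices for the SVD identities, and 10,000
random mean vectors for the fold-change oracle; these sizes exercise
every code path while keeping a complete run in the minutes range.

## Known limitations

* The strict specificity rule makes sibling clusters with near-identical
  means annihilate each other's signatures.  The mutual-reachability
  dendrogram prevents the surplus-K cut from creating such siblings on
  clean data, but cohorts containing two *genuinely identical* expression
  subtypes of substantial size would still oscillate rather than
  converge; the iteration trace makes this visible.
* Bad-cluster samples are re-assigned to the nearest *good* cluster; if a
  true subtype is entirely dissolved in one iteration its samples
  transiently join wrong clusters, and recovery relies on the next
  iteration's re-clustering.
* The permutation null assumes candidate genes can be contrasted against
  a large pool of background genes; with very small matrices (pool close
  to the signature size) the null degenerates.
* k-NN transfer assumes the two cohorts share the signature genes; probe
  mapping and batch correction beyond two-moment matching are out of
  scope.
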