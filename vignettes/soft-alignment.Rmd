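---
title: "Soft alignment of t-SNE embeddings: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soft alignment of t-SNE embeddings: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(snealign)
library(dplyr)
```

## The model

Given samples $s = 1, \dots, S$, each a matrix of cells in a shared
$P$-dimensional PCA space with per-cell type annotations, the package
produces one 2-D t-SNE embedding per sample such that shared cell types
occupy matching positions across panels while each sample's own local
embedding structure is preserved. Feature/PCA space is never modified
beyond a per-sample similarity transform, which is what separates this
approach from data integration.

**Stage 1 — reference choice.** The *primary reference* is the sample with
the most distinct cell types (ties: more cells, then input order). If it
lacks some types, *secondary references* are added by greedy set cover
over the missing types until every type present anywhere is covered.

**Stage 2 — primary alignment.** For each non-reference sample, the
per-type centroid matrices (shared types only, identical row order) of the
sample and the reference are Procrustes-superimposed: both are centered
and Frobenius-normalized, the optimal orthogonal rotation is $UV^\top$
from the SVD of the cross-product, and the optimal scale is the sum of
singular values. The resulting similarity (translation, positive scale,
rotation — reflections allowed by default because PCA axes have arbitrary
sign) is applied to the sample's *full* PCA matrix. Being a similarity, it
changes no within-sample neighbor relation and therefore no t-SNE
affinity; its only downstream effect is on the embedding initialization.

**Stage 3 — embedding with center forces.** Each embedding is initialized
from the first two (aligned) PCA components, jointly rescaled so the first
column has standard deviation `init_std`. The reference is embedded with
plain exact t-SNE and its per-type centers $Y_{r,\mathrm{center}_i}$
recorded. Every other sample minimizes

$$L_\mathrm{total} = L_\mathrm{tsne} + \lambda \sum_{i=1}^{K} d_i, \qquad
  d_i = \lVert Y_{r,\mathrm{center}_i} - Y_{s,\mathrm{center}_i}\rVert^2,$$

with $K$ the number of types shared with the reference center set. The
force term is applied by alternation: after each t-SNE gradient step, each
shared type is rigidly translated by $\lambda$ times its center offset.
Two consequences follow directly from this update rule and are enforced by
tests: with the t-SNE gradient frozen, $j$ force steps scale
$\sum_i d_i$ by exactly $(1-\lambda)^{2j}$; and $\lambda = 0$ is
bit-identical to a plain run from the same initialization. Types with no
reference center receive no force. Secondary references are embedded in
cover order against the current center set, each contributing centers for
its not-yet-covered types, so the final center set is complete.

The per-cell gradient of $\lambda\sum_i d_i$ equals the rigid translation
direction scaled by $2/n_i$ for a type with $n_i$ cells; the translation
form was chosen so that $\lambda$ has a size-independent interpretation
($\lambda = 1$ closes the entire center gap in one step) rather than one
that weakens with cluster size.

## Evaluation metrics

*Alignment score.* Each embedding is normalized on its own — centered on
its grand centroid and divided by the root-mean-square cell distance from
it — and $d$ is the summed squared distance between matched normalized
type centers; the score is $1/(1+d) \in (0, 1]$. The normalization removes
the arbitrary origin and scale of a t-SNE run but deliberately **not** its
orientation: orientation is precisely what alignment is about. "Normalized
centers" is not pinned down further by the method's description; the
RMS-radius choice is one consistent reading, and any other
per-embedding similarity normalization would change scores monotonically
in the same direction.

*Locality preservation.* For each cell, the fraction of its $k$ nearest
neighbors (Euclidean, self excluded, ties broken by cell index for
determinism) in the independent embedding that remain among its $k$
nearest in the aligned embedding. Default $k = 30$, a neighborhood
comparable to the perplexity. The metric is invariant to isometries and
uniform scaling of either embedding.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lambda` | 0.1 | force weight per iteration; 0 disables forces, 1 snaps centers each step |
| `perplexity` | 30 | t-SNE effective neighbor count (must be `< n`) |
| `n_iter_main` | 750 | gradient-descent iterations |
| `n_iter_early` | 0 | optional early-exaggeration iterations (see below) |
| `exaggeration_early` | 12 | exaggeration factor when the phase is enabled |
| `learning_rate` | `"auto"` | 200, or `n/(4*exaggeration)` when exaggeration is on |
| `init_std` | 1e-4 | standard deviation of the rescaled initialization |
| `allow_reflection` | `TRUE` | permit determinant −1 Procrustes solutions |
| `fallback_k`, `representatives_per_cluster`, `mnn_neighbors` | 10, 20, 15 | annotation fallback: k-means clusters, representative cells per cluster, MNN neighborhood |

`lambda = 0.1` moves each shared center 10% of the way to its target per
iteration; over hundreds of iterations this dominates the residual center
drift while leaving within-cluster geometry to the t-SNE forces, and the
alignment/preservation trade-off it produces is measured, not assumed, by
the acceptance checks.

## Numerical design choices

**Exact gradient, no early exaggeration by default.** The t-SNE core is an
exact $O(n^2)$ gradient (Rcpp) with the canonical factor-4 KL gradient,
momentum (0.5 during an exaggerated phase, 0.8 otherwise) and the standard
adaptive per-coordinate gains. Early exaggeration exists to form a global
layout from a *random* start. Every embedding in this package starts from
an informative (aligned) PCA initialization — the method's premise is that
the initialization carries information — and an exaggerated phase at desk
scale measurably destroys it: with exaggeration 12 the exaggerated
attraction step sits far beyond its stability bound, trajectories become
chaotic (a 1e-6 perturbation of the initialization yields a completely
different cluster arrangement), and the alignment gained in PCA space is
forgotten. Established t-SNE implementations disable early exaggeration
when an initialization is supplied, and this package follows that
convention by default (`n_iter_early = 0`). When a user enables the phase,
the auto learning rate drops to $n/(4 \cdot \text{exaggeration})$ — the
stability bound of the exaggerated attraction step for a factor-4
gradient — and forces stay off until the phase ends.

**Determinism.** Runs are single-threaded and, given a seed, bit
reproducible: the only stochastic elements are the synthetic generator,
k-means restarts, and the Gaussian fallback initialization (used only for
a zero-variance first component, with a warning). Identical configuration
and seed reproduce identical coordinates.

**Degenerate inputs.** One shared type cannot determine a rotation
(error); collinear centroids trigger a warning and a non-unique but valid
rotation; k-means retries with shifted seeds on empty clusters; clusters
without mutual pairs during annotation transfer are flagged absent, with a
nearest-reference-centroid fallback when nothing seeds at all.

## The synthetic generator

`simulate_samples()` draws every sample from one Gaussian mixture over
cell types in PCA space and then applies a per-sample batch effect:
a planar rotation in components 1–2, a uniform scale, a translation, and
additive jitter. Type means are drawn with geometrically decaying
component-wise spread (factor 0.7 per component), mimicking how PCA
concentrates between-type separation in leading components — which is what
a PCA-derived initialization relies on — and are rescaled so the closest
pair of types sits exactly `separation * type_sd` apart (default 6 sd).

Default conditions: 3 samples × 1000 cells, 5 types, $P = 10$, jitter
0.3, rotations uniform on $(-\pi/4, \pi/4)$, scales on $(0.8, 1.25)$,
translations $N(0, 1)$ per component (norm ≈ 3, about half the type
separation). The batch effects are thus substantial but subdominant to the
biological structure; that is the regime in which cross-sample
mutual-nearest-neighbor correspondence in raw PCA space — the annotation
fallback this method prescribes — is meaningful at all. With translations
larger than the type separation the fallback degrades gracefully but can
no longer recover ground-truth types, which is a property of MNN in PCA
space, not of the implementation. The rotation is confined to components
1–2 so the ground-truth transform is exactly recoverable by the planar
Procrustes stage and visible in the initialization.

What the generator does **not** emulate: count noise and library-size
effects (cells are Gaussian around their type mean), unbalanced type
compositions across samples beyond dropout, continuous
differentiation trajectories, and non-rigid batch distortions. Passing
tests therefore demonstrate correctness of the algorithmic pipeline under
clean, well-separated conditions — they do not certify behavior on real
data with overlapping types or nonlinear batch effects, where the
Procrustes similarity can only partially align PCA space.

## Problem sizes used in the checks

The automated checks run the full pipeline on 3 × 1000-cell samples over
five seeds (plus a 1000-vs-100-cell unbalanced pair and an
annotation-withheld replicate), and verify unit-level properties on
instances of 20–300 cells where brute-force oracles (all-pairs kNN,
explicit group means, exhaustive set cover, dense rotation grids) are
exact. These sizes exercise every code path at desk scale; the exact
$O(n^2)$ core is comfortable to roughly $10^4$ cells per sample, beyond
which an approximate-gradient backend would be the natural extension.

## Known limitations

- The alternating translation step is one consistent reading of "alternate
  a t-SNE iteration with center-distance minimization"; a gradient-exact
  treatment of $\lambda \sum d_i$ would scale forces by type size.
- Forces act on type centers only: shape differences of a type between
  samples are preserved by design and not aligned.
- Alignment quality is bounded by how well a similarity transform can
  align PCA spaces; strongly nonlinear batch effects leave residual
  misalignment that the force term must absorb.
- The greedy secondary cover is optimal on dropout-style instances but is
  a heuristic in general (set cover is NP-hard); covers are always valid
  and irredundant.
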