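---
title: "Agent-attention multiple instance learning for continuous recurrence risk: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Agent-attention multiple instance learning for continuous recurrence risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmp)
```

## The problem

Genomic recurrence-risk assays such as MammaPrint return a continuous index
in $[-1, 1]$ for hormone-receptor-positive, HER2-negative breast cancer;
values $\le 0$ indicate high risk of distant metastasis and values $> 0$
low risk. The assay is destructive, slow and expensive, while the H&E
whole-slide image (WSI) is available for every case. `cpmp` implements a
weakly supervised route from the WSI to the continuous risk score: a slide
is represented as a *bag* of tile feature vectors (one embedding per
256-px tile, from any upstream extractor), and a single slide-level label
supervises the whole bag — classical multiple instance learning (MIL),
but as regression rather than classification, because binarizing a
continuous index discards information near the decision boundary.

## Model

### Agent attention

A slide can contain $10^4$–$10^5$ tiles, so full self-attention
($\Theta(n^2 d)$) is impractical. Agent attention interposes a small set
of $k$ agent tokens $A \in \mathbb{R}^{k\times d}$ between queries and
keys and stacks two ordinary softmax attentions:

$$V_{agent} = \mathrm{SAttn}(A, K, V) = \sigma\!\left(\tfrac{AK^\top}{\sqrt d}\right)V
\qquad\text{(aggregation)}$$
$$\mathrm{AAttn}(A,Q,K,V) = \mathrm{SAttn}(Q, A, V_{agent}) =
\sigma\!\left(\tfrac{QA^\top}{\sqrt d}\right)V_{agent}
\qquad\text{(broadcast)}$$

Both stages are exact softmax attentions — the construction is a
functional composition, not an approximation of the full attention
matrix. Counting multiply–accumulates, the two stages cost
$2nkd + 2knd$ against $2n^2d$ for full attention
(`attention_mac_count()`), a ratio of $2k/n$: linear in $n$ for fixed
$k$.

The effective token-to-token attention used for interpretation is the
rollout product
$M = \sigma(QA^\top/\sqrt d)\,\sigma(AK^\top/\sqrt d)$,
row-stochastic as a product of row-stochastic matrices. Its class-token
row, restricted to tile columns, is the per-tile importance vector behind
every heatmap in the package.

Two choices here were genuinely open:

* **Scaling.** The rollout definition is printed without a temperature;
  we apply the same $1/\sqrt d$ as the forward pass so the rollout is
  exactly the product of the matrices the model actually used.
* **Agent derivation.** How $A$ is obtained is not specified upstream;
  learnable agents and query pooling are both used in the agent-attention
  literature. We pool the queries by segment means ($k$ contiguous,
  near-equal segments; sizes differ by at most one), which makes $k = n$
  the exact identity and $k = 1$ the column mean, giving clean limiting
  cases for tests. Pooling is performed on the sequence in canonical
  row-major coordinate order, so the model is an exact set function of
  its tiles (tile order cannot leak into the prediction). No identity
  term is added inside the rollout; as printed it is a pure product.

### The slide-level network

One forward pass (`forward_bag()`) is:

1. linear projection of each tile embedding to 256 channels + ReLU;
2. 2D absolute sinusoidal positional encoding of the (column, row) tile
   grid coordinates, added to the projections — first 128 channels encode
   the column, last 128 the row, interleaved sin/cos at wavelengths
   $10000^{2i/128}$. Grid indices (not pixels) keep the wavelengths
   scale-free and match the HDF5 `coords` dataset;
3. concatenation of a learned class token (sequence length $n+1$);
4. one pre-norm transformer layer, 4 heads of width 64, agent attention
   with $k = 16$ agents per head, residual connections, feed-forward
   256→512→256. Pre-norm is our choice (the block diagram does not fix
   norm placement); it is the stabler layout at small data scale. The
   class token participates in both attention stages and in agent
   pooling like any other sequence element;
5. a LayerNorm → linear → sigmoid head on the class position, yielding a
   risk probability in $(0,1)$.

The rollout is computed per head and averaged (the rollout definition is
written single-head). No dropout is used anywhere: the forward pass is
deterministic, which the oracle tests rely on. Softmax rows are computed
with max-subtraction; LayerNorm uses $\varepsilon = 10^{-5}$.

Defaults ($k = 16$, width 256, 4 heads, FF 512) follow the reference
architecture; $k$ mainly trades compute for agent granularity and is
exposed in `model_config()`.

### Objective and training protocol

The loss on a batch of $B$ bags is the dual MSE

$$L = \frac1B \sum_{i=1}^{B} \Big[\lambda_1 (Y_i - \hat Y_i)^2 +
\lambda_2\, \mathbb{1}(Y_i > 0.5)\,(Y_i - \hat Y_i)^2\Big],$$

an ordinary MSE plus an extra penalty on cases above the 0.5 boundary
(on the normalized scale these are the low-risk cases, the clinically
actionable group). $\lambda_1 = \lambda_2 = 1$ by default; the reference
work does not give values, so they are exposed in `model_config()`.

Optimization (`train_model()`): Adam with momentum factor
$\beta_1 = 0.9$ ($\beta_2 = 0.999$, $\varepsilon = 10^{-8}$ are the
standard defaults), learning rate decaying linearly from $10^{-4}$ to
$10^{-5}$ at epoch 500 and constant thereafter, at most 1000 epochs,
early stopping after 50 epochs without strict validation improvement,
and gradient accumulation over 32 bags (each bag is a batch of one
forward; the accumulated gradient is divided by the number of bags in
the window, so partial windows at epoch end take an equivalent step).
All weights are initialized Kaiming-uniform; the parameters with the
lowest validation loss are returned. Labels are the raw scores mapped by
$(x+1)/2$; group boundaries are inclusive on the high side ($\le 0$ raw,
$\le 0.5$ normalized).

Cross-validation (`make_cv_plan()`) is patient-level: per repetition,
20% of patients are held out for testing and the rest split into five
near-equal folds; all slides of a patient travel together. When risk
groups are supplied the test split is stratified — our addition, to
stabilize AUROC at small cohort sizes.

## The synthetic cohort

Real cohorts (private clinical slides plus genomic assay results, with
foundation-model tile features) cannot ship with a package, so every
downstream stage is exercised on a generator with known ground truth
(`simulate_cohort()`):

* tiles live on a near-square grid; a fraction (default 0.2) form
  spatially contiguous disc-shaped "tumor" blobs at random centers
  (contiguity is what makes heatmap localization a meaningful test);
* background tiles are i.i.d. standard normal — the zero-information
  baseline that makes the no-signal null test exact and keeps the linear
  probe below closed-form;
* signal tiles add $s\,(Y - 0.5)\,u$ for a fixed unit direction $u$,
  label $Y \sim U(0,1)$ and strength $s$ (default 4). Uniform labels
  maximize identifiability for parameter-recovery tests; no attempt is
  made to match the empirical score distribution of any clinical cohort,
  which is not publicly stated;
* because the planted signal is linear, ordinary least squares of $Y$ on
  the bag-mean projection $\bar x^\top u$ is a closed-form oracle
  predictor: any trained model can be judged against it. At the study
  scale used throughout (200 bags of 200 tiles, 64 channels, $s = 4$)
  the probe reaches held-out Spearman $R > 0.9$.

Cell maps (`simulate_cellmap()`) plant the spatial-dispersion contrast
between risk groups: tumor cells follow a Thomas-like cluster process
(uniform parents, Gaussian offspring with dispersion $\sigma$ for the
low-risk group and $2\sigma$ for high-risk — high-risk tumors are more
dispersed), with torus wrap-around so edge clipping does not distort
spacing statistics; stromal and inflammatory cells are uniform. Because
tumor–stroma distances are stationary under tumor clustering, the
tumor–stroma comparison is an exact null while tumor–tumor spacing
carries the planted difference — mirroring the significant
tumor–tumor / null tumor–stroma pattern the method is meant to detect.

What the generator does *not* emulate: correlated tile features,
extractor-specific embedding geometry, staining and scanner variation,
label noise in the genomic assay, or cell-type co-location structure.
Tests passing on this cohort show the machinery is correct and can
recover a planted signal at realistic sizes; they say nothing about
clinical performance.

## Heatmaps and concordance

`tile_attention_scores()` min–max normalizes the rollout class-token
row; a constant row (e.g. a one-tile bag) maps to 0.5 everywhere — "no
salient region" must still render, and 0.5 is the documented convention.
`assemble_raster()` paints each tile's score over its pixel footprint at
stride $\text{tile} \times (1-\text{overlap})$ (inference tiling uses
overlap 0.1; training bags are non-overlapping, so overlap is a
parameter); overlapping pixels take the arithmetic mean — max-blending
was rejected because mean-blending keeps the raster linear in the
scores, which is itself a tested invariant. Uncovered pixels carry `NA`,
never a fake zero. `concordance()` compares raster and mask over covered
pixels only: pixelwise ROC AUC, plus recall, Dice and overlap ratio
after thresholding at 0.5.

## Phenotype discovery

`collect_top_tiles()` gathers each slide's top-100 attention tiles,
embeds each through the network as a singleton bag (the detached
class-token vector between the transformer and the head), and scores it
the same way. `cluster_embeddings()` builds a cosine kNN graph
(neighborhood size 50, symmetrized union of directed neighbor sets,
weights = cosine similarity mapped to $(0,1]$) and runs Leiden community
detection with the modularity objective.

The Leiden resolution default required a real decision. At resolution
1.0 the resolution limit of modularity fragments even a single
well-separated homogeneous cluster of a few hundred tiles into arbitrary
shards, which breaks the planted-partition contract (two 20-σ-separated
blobs must come back as exactly two clusters). The default is therefore
0.5, at which the test suite recovers planted partitions exactly across
two- and three-blob fixtures and 50 seeded replicates, while real
embedding tables still split into fine-grained subclusters; the
parameter remains exposed.

`classify_subclusters()` applies the strict 25% rule: a cluster is
retained in a risk group iff that group contributes *strictly more* than
25% of the cluster's tiles; retained in both → colocalized, in one →
high-/low-specific. Since the majority group always exceeds 25%, every
cluster is labeled. `composition_dendrogram()` averages per-type cell
counts over each cluster's tiles, min–max scales each cell-type column
across clusters (constant columns to zero), and runs Ward
variance-minimization linkage on Euclidean distances — verified in tests
against a from-scratch Lance–Williams recurrence.

## Cell graphs

The upstream graph construction is delegated to an external framework
whose exact neighbor rule is not restated in the reference; `cpmp`
documents its stand-in openly: Delaunay triangulation over the centroids
of the two cell types involved, keeping edges whose endpoints match the
pair class (tumor–tumor, tumor–stroma, tumor–inflammatory) and whose
length is at most `max_edge_um` (default 50 µm, exposed). Collinear or
sub-triangular inputs fall back to a nearest-neighbor chain; fewer than
three usable cells yields an edgeless graph with a warning flag, not an
error. Absolute MeanEdgeLength values from this construction are not
claimed to match any published distribution — only the group *contrast*
is the tested quantity.

`mean_edge_length()` averages each focus cell's incident edge lengths in
microns (conversion via `microns_per_px`, default 0.5 at 20×); degree-0
cells are excluded and counted rather than assigned 0, which would
distort the distribution tails. `tumor_cell_density()` is the neoplastic
count per mm². `compare_groups()` is a Mann–Whitney U test: exact by
full enumeration (midranks under ties, two-sided $p = 2\times$ the
smaller tail, capped at 1) when $\min(n_a,n_b) \le 8$ and
$n_a+n_b \le 12$, otherwise the normal approximation with tie and
continuity correction.

## Numerical conventions and degenerate inputs

* Softmax: max-subtraction per row; LayerNorm $\varepsilon = 10^{-5}$.
* Top-k tile ties: row-major coordinate order (row, then column), so
  selections are reproducible under tied attention.
* Min–max normalization of a constant vector: 0.5 for attention scores,
  0 for composition columns (each documented at its site).
* HDF5 features are single precision on disk; the generator snaps
  features to float32-representable values so write-then-read is an
  exact identity.
* Empty bags, duplicate coordinates, out-of-range labels, unknown cell
  types, non-positive areas and too-small clustering tables all fail
  fast with descriptive errors.

## Problem sizes used in the shipped experiments

The packaged tests and the acceptance script run a scaled-down study:
cohorts of 200 bags × 200 tiles × 64 channels for parameter recovery
(the closed-form linear probe gives $R > 0.9$ there and the trained
network reaches $R \approx 0.8$–$0.84$ held out), 500 tumor cells per
simulated region for the spatial statistics, and 100-seed replications
for the distributional claims. The scaled-down training protocol keeps
the reference optimizer and schedule but uses a gradient-accumulation
window of 8, so that the number of Adam steps at this cohort size is
comparable to the full-scale protocol's; sizes were chosen so a
complete run is comfortable on a single CPU.

### Attention localization under the planted-signal design

The synthetic generator plants its per-tile signal as
$s\,(Y - 0.5)\,u$ — *linear and sign-symmetric around the label
midpoint*. This has a consequence worth stating plainly: uniform
attention over tiles (the bag mean) is already statistically sufficient
to recover the label, and the per-bag gradient on the attention logits
points toward tiles whose values match that bag's $\mathrm{sign}(Y -
0.5)$, so the pressure to attend to signal tiles cancels across bags.
Empirically, trained models reach the regression target while their
rollout attention stays indistinguishable from uniform: across the
reference protocol run to 300 epochs, higher-learning-rate variants and
a 4×-step-count variant, attention-versus-mask AUC stays at $0.50 \pm
0.01$ while held-out Spearman reaches 0.81–0.84. A
magnitude-rectified attention solution exists in the architecture (the
ReLU projection can encode $|$shift$|$), but gradient descent does not
find it at this scale. On real slides, tumor tiles differ from stroma
*categorically* in embedding space — which is precisely what this
generator does not model — so heatmap localization on clinical data
cannot be inferred from, or refuted by, this synthetic design; the
localization tests in the suite document this gap rather than paper
over it.

## Known limitations

* One transformer layer only (as in the reference architecture); the
  rollout is correspondingly single-layer and no identity-augmented
  multi-layer rollout chain is implemented.
* Agent pooling by contiguous segments ties agents to the canonical
  coordinate ordering of the sequence; other pooling schemes (learned
  agents, spatial grid pooling) are not implemented.
* The Delaunay-with-cap cell graph is a documented substitute for the
  unpublished upstream construction.
* Checkpoints use R's native serialization (`saveRDS`); they are not
  interchangeable with other frameworks.
* The package consumes precomputed tile features; no image reading,
  tissue segmentation or feature extraction is included.
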