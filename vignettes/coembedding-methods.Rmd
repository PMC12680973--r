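---
title: "Methods: multi-modal protein co-embedding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-modal protein co-embedding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Proteomic technologies characterize protein organization at different scales
and with different coverage: affinity purification (AP-MS) and proximity
labeling (PL-MS) yield weighted interaction networks, co-fractionation
(SEC-MS) yields scored co-elution pairs, and fluorescence imaging yields
per-protein feature vectors. No single modality covers the whole proteome,
and their protein sets overlap only partially. `coembed` learns a single
latent coordinate for **every protein measured by at least one modality**,
so that downstream analyses (proximity networks, assembly detection, term
recovery) can work on one unified space instead of four incompatible ones.

## Model

Each modality $m$ contributes a feature matrix $x_{m,i}$ (networks are first
featurized by node2vec, see below). A per-modality encoder
$f_m$ maps features to a unit-norm latent vector $z_{m,i}$ of dimension 128:

    f_m: dropout -> linear(d_m, h1) -> ReLU -> dropout
         -> linear(h1, h2) -> ReLU -> linear(h2, 128) -> L2-normalize

and a decoder $g_m$ mirrors it back into feature space without a terminal
normalization (reconstructions must be comparable to raw inputs):

    g_m: dropout -> linear(128, h2) -> ReLU -> linear(h2, h1)
         -> ReLU -> linear(h1, d_m)

Hidden widths taper geometrically with a floor at the latent dimension:
$h_1 = \max(128, d_m/2)$, $h_2 = \max(128, d_m/4)$. The floor keeps small
inputs (e.g. 64-dimensional node2vec vectors) from collapsing below the
latent width.

Two losses are combined, $L = \lambda R + (1-\lambda) T$:

* **Cross-modal reconstruction** $R = \sum_{a \in M}\sum_{b \in M} R_{a,b}$
  with $R_{a,b} = \frac1n \sum_i D(x_{a,i},\, g_a(z_{b,i}))$, the mean
  cosine distance over proteins shared by $a$ and $b$. The double sum runs
  over *ordered* pairs including $a = b$, so self-reconstruction is part of
  the objective. Cross-decoding ($b$'s latent through $a$'s decoder) is the
  only dimensionally consistent reading when $d_a \neq d_b$; the
  `cross_decode` config flag records this interpretation.
* **Cross-modal triplet** $T = \sum_a T_a$: for each batch, each modality
  $a$ draws one partner $b \neq a$ uniformly; each anchor $z_{a,i}$ is
  pulled toward its positive $z_{b,i}$ (same protein) and pushed from a
  negative $z_{b,k}$ ($k \neq i$, resampled uniformly within the batch's
  shared set each batch) by margin $\varepsilon$:
  $T_a = \frac1N\sum_i \max(D(z_{a,i}, z_{b,i}) - D(z_{a,i}, z_{b,k}) +
  \varepsilon,\, 0)$.

Missing data needs no imputation: a batch is a chunk of the union universe,
and each modality's forward pass simply uses the covered subset. Pairs with
empty overlap in a batch contribute zero. After training, per-modality
latents are averaged per protein into the **unified embedding**; a protein
measured once keeps its single latent row exactly. The average is not
re-normalized (cosine proximities are scale-invariant; `renorm` is
available); note that exactly antipodal latents would cancel, which the
alignment objective makes vanishingly unlikely in practice.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `latent_dim` | 128 | shared latent dimension |
| `dropout` | 0.5 | rate for all dropout layers (train mode only) |
| `margin` | 0.2 | triplet margin on cosine distances (range 0–2) |
| `lambda` | 0.5 | weight of R vs T |
| `learning_rate` | 1e-4 | Adam step size |
| `batch_size` | 64 | proteins per optimizer step |
| `epochs` | 300 | passes over the union universe |

All but `epochs` follow the published training settings for this model
family. The epoch default is sized for the optimization budget, not the
data: with a few hundred proteins an epoch is ~5 Adam steps, and at a fixed
learning rate of 1e-4 the total parameter displacement scales with steps x
rate. Around 1,500 steps the benchmark fit is converged (ground-truth
AUROC plateaus; the loss log printed by `verbose = TRUE` makes this
visible), whereas 500 steps leave it mid-descent. On proteome-scale inputs
(thousands of proteins) far fewer epochs suffice because each epoch already
contains >100 steps.

Training is implemented in the package itself (analytic backprop for every
layer, Adam with standard moments). The test suite checks the analytic
gradients of the full combined loss against central finite differences.
All randomness — initialization, batch shuffling, partner choice, negative
sampling, dropout masks — derives from `config$seed` through independent
named substreams, so a fit is bit-reproducible and changing one consumer
(say, negative sampling) cannot perturb another (initialization).

## Network featurization

node2vec runs biased second-order walks (return parameter $p = 2$, in-out
$q = 1$, walk length 80, 10 walks per node) over the *filtered, unweighted*
graph — edge scores are used only by the confidence filters (strict
`> 0.75` precision, `< 0.01` BFDR, as appropriate per source), mirroring
the stated processing of the source networks; weighted walks are not
described there and are not implemented. The walk corpus is shuffled once,
then a skip-gram model with 5 negative samples, window 10, 5 corpus passes
and linearly decaying learning rate (initial 0.025) produces the embedding.
Walks and skip-gram run single-threaded on an internal splitmix64 generator:
a seed fully determines the embedding, at the cost of the multi-threaded
throughput a production word2vec would have.

## Evaluation statistics

* `top_fraction_pairs()`: the top 1% (or other fraction) most similar
  pairs. The count is `ceiling(fraction * n(n-1)/2)` — `ceiling` so the set
  is never empty — and ties at the cutoff break lexicographically, so
  results are deterministic.
* `pair_auroc()`: Mann–Whitney rank identity, ties counted 1/2. Negatives
  are *all* other unordered pairs within the restriction universe
  (defaulting to proteins present in both the embedding and the pair
  source). Invariant under monotone transforms of the proximity.
* `term_recovery()`: per term, one-sided Wilcoxon rank-sum of within-term
  pair proximities against pairs among root-only proteins, BH-corrected
  across terms, recovered at adjusted p < 1% FDR. `stats::wilcox.test`
  supplies the exact small-sample method (both sides < 50, untied) and the
  tie-corrected normal approximation otherwise.
* Baselines: feature concatenation (missing slots filled with a uniformly
  sampled existing row of that modality, seeded) and a standard
  autoencoder (per-modality linear+ReLU to 128, concatenate, linear to
  128, linear decoders, summed MSE objective, 50 epochs, Adam) trained
  only on fully covered proteins. MSE rather than cosine distance is used
  for the baseline's objective — it is the conventional choice for a plain
  autoencoder and keeps the baseline architecturally distinct from the
  co-embedding model.

## Hierarchy support

`threshold_networks()` produces the six proximity networks (top 0.2, 0.4,
0.6, 0.8, 1.0, 5.0% of pairs). Community detection itself is a pluggable
external stage: the published pan-resolution detector (HiDeF) is invoked
with persistence 10 and maxres 80 and its node/edge tables are parsed; a
deterministic stub exercises the parser contract in tests. Assemblies are
then scored two ways: hypergeometric overlap with known terms
(BH-corrected, flagged only when adjusted p < 0.01 **and** Jaccard > 0.2 —
the conjunction prevents large assemblies with tiny but significant
overlaps from being called known), and per-modality support (rank-sum of
within-assembly original-feature similarities against root-only pairs).
An assembly with < 2 covered proteins in a modality has *undefined* support
there — deliberately a third state so coverage gaps are never reported as
evidence against support.

## The synthetic world

The generator is the package's test bed: `plant_world()` assigns proteins
to communities (multinomial around balance, floor 2), `network_view()`
draws a stochastic block model (within-community probability `p_in`,
between `p_out`) over an independently coverage-sampled subset, and
`feature_view()` places community centroids uniformly on the unit sphere
and adds isotropic Gaussian noise (sd `sigma`). This is the minimal
generative family matching the model's assumption — modalities agree on
latent proximity and differ in noise and coverage.

The standing benchmark (`default_fixture()`): 300 proteins, 10 communities,
two SBM network views (`p_in = 0.3`, `p_out = 0.01`) featurized by node2vec
into 64 dimensions, one feature view (dim 64, `sigma = 0.3`), every view
covering an independent 70% sample, seed 7. Sizes were chosen so the whole
benchmark (generation, featurization, training, evaluation) runs in a few
minutes on one core.

What passing on this world does **not** show: real modalities disagree
systematically (a protein can have distinct localization and interaction
contexts), noise is not isotropic Gaussian, interaction networks have
degree heterogeneity and hub artifacts absent from an SBM, and coverage is
biased by protein abundance rather than independent. The benchmark
demonstrates correct mechanics and the integration benefit under the
model's own assumptions, not performance on laboratory data.

## Numerical choices and degenerate inputs

* Cosine distance errors on (near-)zero vectors rather than silently
  substituting an epsilon; likewise the encoder's L2 normalization errors
  on a zero pre-activation — a dead encoder should surface, not hide.
* Duplicate edges collapse to the maximum score (the usual convention for
  confidence scores); self-edges are dropped with a count.
* The protein universe is sorted lexicographically, making every downstream
  iteration order deterministic.
* The reconstruction total is the raw ordered-pair sum (not averaged over
  the number of pairs); with Adam the distinction only re-scales gradients.

## Known limitations

* **Type-I control of term recovery is approximate.** The published
  procedure treats within-term pairs as independent observations, but pairs
  sharing a protein are dependent. With strongly block-structured
  proximities and permuted (information-free) term labels, the realized
  recovery rate at nominal 1% FDR is ~5% on a 80-protein world, ~1.5% at
  the 300-protein benchmark scale, and shrinks further as the pair
  populations grow. With genuinely exchangeable pair values the
  implementation recovers ~0.1%, confirming the inflation comes from the
  dependence structure, not the machinery. Conclusions drawn near the FDR
  threshold on small universes deserve caution; a protein-level permutation
  test would control this exactly but is not the published procedure.
* Training cost scales with the number of ordered modality pairs (M^2
  decoder passes per batch); fine for a handful of modalities, not designed
  for dozens.
* The triplet loss needs at least one modality pair sharing >= 2 proteins;
  fully disjoint modalities cannot be aligned (training refuses, rather
  than silently fitting reconstruction only).
* Proximity matrices are dense n x n; around 20k proteins memory becomes
  the binding constraint.
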