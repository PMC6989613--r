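---
title: "Multi-task embedding of attributed networks: model, design and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task embedding of attributed networks: model, design and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Networks with node attributes are everywhere in biology: protein–protein
interaction graphs with expression or sequence-derived features, citation
graphs with bag-of-words vectors. Two analyses dominate: assigning class
labels to unlabeled nodes (node classification) and scoring unobserved node
pairs for missing interactions (link prediction). Embedding methods trained
for one of these tasks waste the supervision the other provides.

`mtgnn` trains one shared encoder against both. The encoder
`H = f(A, Z)` maps the adjacency `A` and feature matrix `Z` to embeddings;
two small heads consume `H`:

* a softmax classifier `P_v = softmax(W^T h_v + b)`, trained with
  cross-entropy over the labeled node set;
* a link decoder `S_ij = sigmoid(h_i^T M_sym h_j + b)` (bilinear, with
  `M_sym = (M + M^T)/2` so scores are symmetric in `i, j`), trained with
  binary cross-entropy against the training adjacency.

The joint objective is `L = L_NC + alpha * L_LP`. At `alpha = 0` the link
decoder receives no gradient at all and stays frozen at its random
initialization — a property the test suite checks bit-for-bit, and the basis
of the chance-level control recomputed by `scripts/acceptance.R`.

The protocol is transductive: every node's features and the training
adjacency are visible to the encoder; what is withheld is a fraction of
*labels* (classification test set) and a fraction of *edges* (link test set,
hidden from `A` before training and paired with an equal number of sampled
non-edges).

## Encoder choices

Two layer families implement `f`:

* **Attention (`gat`)** — per head, features are transformed by `W`, pairwise
  logits `e_ij = LeakyReLU(a . [Wh_i || Wh_j])` (negative slope 0.2) are
  softmax-normalized over each node's neighborhood, and neighbors are
  aggregated with those weights. The concatenation-plus-LeakyReLU form of the
  logit is the convention of the attention-network lineage this model
  follows; self-loops are added so every softmax is over a nonempty set and
  isolated nodes embed their own transformed features.
* **Convolution (`gcn`)** — `H' = sigma(D^{-1/2}(A + I)D^{-1/2} H W)`.

Defaults (all exposed in `encoder_config()`): two layers; hidden layer of
8 features per head with 8 heads concatenated; final layer `d = 64` with
heads averaged; ELU on the hidden layer, identity on the output layer. The
head count is the one piece fixed by the training recipe; the widths and
activations are the standard transductive conventions of this model family,
stated here as package defaults rather than facts about any one study.

Dropout (rate 0.1) is applied at the two standard attention-network sites —
each layer's input features and the normalized attention coefficients — and
only in training mode; evaluation passes are deterministic.

## Training recipe

`train_config()` defaults: Adam, fixed learning rate 0.005, 300 full-batch
epochs, `alpha = 1`, Glorot-uniform initialization, no early stopping. The
source recipe says only "gradient descent" with that rate; Adam is chosen
because it is the de-facto optimizer of this model family, and plain SGD is
selectable for literalists.

Both losses are implemented as **means** rather than raw sums: the
definitions are sums, but a mean makes the fixed learning rate independent
of graph size and label count; the difference is a constant factor that an
equivalent rate rescaling absorbs.

The link loss needs targets over node pairs. By default (`lp_mode = "auto"`)
graphs up to 3,000 nodes use the **exact mode**: every unordered non-self
pair contributes, with its target read from the training adjacency (hidden
evaluation edges therefore count as zeros — they are unknown to training by
construction). Larger graphs fall back to balanced sampling: each training
edge is paired with one freshly drawn non-edge per epoch.

The bilinear decoder is the default rather than the bare inner product
because only a decoder with its own parameters exhibits the documented
`alpha = 0` null behavior — held-out link AUC floating at its ~0.5 starting
value. An inner product applied to classification-trained embeddings is not
frozen at chance: class structure leaks into the scores. The inner-product
decoder remains available as `decoder = "inner"`.

All gradients — through both heads, the attention softmax, the dropout
masks, the ELU/LeakyReLU nonlinearities and the normalized adjacency — are
hand-written reverse-mode passes. The test suite compares them against
central finite differences at double precision (relative error below 1e-4 is
required; observed error is around 1e-8) and compares both layer forward
passes against independent dense-matrix reference implementations.

## Splits

`split_nodes()` stratifies by class with largest-remainder rounding, so even
a 10% labeled set keeps every class represented. `hide_edges()` removes
uniformly chosen edges (defaults: 5% validation, 10% test) and samples an
equal number of uniform non-edges of the original graph as negatives; the
training adjacency, hidden positives and their negatives are serializable
via `write_splits()`. Training-adjacency connectivity is deliberately *not*
enforced — isolated nodes still receive embeddings through their self-loops.

Because the recipe has no early stopping, validation edges play no role in
optimization; the evaluation protocol used by the acceptance runs and the
long-run tests therefore hides test edges only (`val_frac = 0`,
`test_frac = 0.10`), matching the chance-level control's stated setup. When
per-epoch monitoring is wanted, `eval_every` in `train_config()` records
held-out accuracy and validation-edge AUC into the history at that cadence.

## Metrics

* `roc_auc()` is the tie-aware Mann–Whitney estimator
  `(concordant + 0.5 * ties) / (n_pos * n_neg)` — exact, no threshold grid.
* `average_precision()` averages precision at the rank of each positive,
  with ties resolved by stable original order for determinism. The source
  description of AP is loose ("average accuracy score"); it is interpreted
  as the standard average precision of the ranked pair list.
* `accuracy()` breaks argmax ties toward the lowest class index.

Both ranking metrics are validated against brute-force pairwise/rank oracles
on hundreds of random instances, ties included.

## The synthetic benchmark

`make_synthetic_dataset()` draws a stochastic block model whose blocks double
as classes (round-robin assignment, so block sizes differ by at most one;
each unordered pair carries an edge with probability `p_in` within a block,
`p_out` across) and Gaussian node features: class centroids are mutually
orthogonal vectors scaled so pairwise centroid distance is exactly `mu`
(approximate when `F < classes`), plus isotropic noise `sigma_f`. Structure
and features draw from separate sub-seeds of the master seed, so tests can
vary one factor at a time. A `binarize` flag thresholds features at the
centroid midpoint for bag-of-words-style 0/1 data.

The reference conditions used by the acceptance runs are `n = 400`, four
blocks, `F = 16`, and two regimes: a *moderate* graph
(`p_in = 0.08, p_out = 0.01, mu = 1`) for the `alpha = 0` null control, and
a *separable* graph (`p_in = 0.10, p_out = 0.005, mu = 2`) for the
joint-learning check. These sizes keep a full 300-epoch run in the tens of
seconds on one CPU while leaving hundreds of hidden edges for evaluation.

What the generator emulates: community structure correlated with classes,
class-informative noisy features, sparse symmetric adjacency. What it does
not: degree heterogeneity, overlapping communities, binary high-dimensional
bag-of-words sparsity (unless binarized), and any dependence of edges beyond
block membership. The last point matters for interpreting results: in an
SBM, conditionally on blocks, a hidden edge is statistically identical to
any other within-block non-edge, so no method can rank hidden edges above
within-block non-edges. With the separable regime's densities the
Bayes-optimal link AUC is roughly 0.82; the trained model's 0.80–0.84 per
seed is at that ceiling, and passing tests certify correct mechanics and
calibration, not performance transferable to real graphs with richer
structure.

## Numerical choices

* Softmaxes (attention and classifier) subtract the per-row maximum before
  exponentiation.
* All `log` terms in losses clip their argument at `1e-12`; gradients use
  the unclipped sigmoid/softmax identities (the clip only guards evaluation
  of the reported loss at saturated scores).
* Attention on sparse graphs runs on a directed edge list with grouped
  softmax rather than dense `n x n` masks; a dense reference implementation
  lives in the tests and must agree to `1e-8`.
* Glorot-uniform bounds use `sqrt(6 / (fan_in + fan_out))`; attention
  vectors are treated as `fan_in = 2F', fan_out = 1`.
* Degenerate inputs are errors, not warnings: empty neighborhoods cannot
  occur (self-loops), empty masks and empty score sets are refused, edge
  splits on graphs with fewer than 5 edges are refused, and a non-finite
  training loss aborts with diagnostics rather than propagating `NaN`s.
* `lr = 0` is permitted and verifiably leaves parameters untouched, which
  pins the optimizer plumbing in tests.

## Open design points, resolved

* **Feature normalization** — whether input features should be row-normalized
  is data-dependent and unstated in the source recipe; exposed as
  `row_normalize` in `load_dataset()`, default off.
* **Hidden-edge fractions** — unstated; defaults 5%/10% follow common graph
  autoencoder evaluation practice and are arguments everywhere.
* **Internal indexing** — 1-based inside R (the language idiom); class labels
  remain 0-based integers, matching the on-disk convention of the citation
  benchmarks this layout mirrors.
* **Checkpoint format** — a single `.rds` holding the named parameter list
  plus config echo, written by the CLI next to a YAML manifest.

## Limitations

Pure-R full-batch training is comfortable at desk scale (hundreds to a few
thousand nodes) but is not engineered for `n` in the tens of thousands;
exact-mode link loss is quadratic in `n` by definition. The model is
transductive: unseen nodes require retraining. Multi-label classification,
weighted or heterogeneous graphs, and inductive neighbor-sampling
aggregation are out of scope.
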