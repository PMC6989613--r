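# mtgnn — multi-task representation learning on attributed networks

`mtgnn` learns node embeddings of an undirected attributed graph — a
protein–protein interaction network, a citation graph, any network with node
features — with a single shared graph neural encoder that is supervised by
**two tasks at once**: semi-supervised node classification and link
prediction. Embedding methods trained for one task alone ignore the signal
the other task carries; sharing the encoder lets the two tasks regularize
each other and yields representations that serve both.

## Model

Given a graph with symmetric binary adjacency `A` and node feature matrix
`Z`, a stacked encoder `f` produces embeddings

```
H = f(A, Z),    h_v ∈ R^d
```

where `f` is either a multi-head **graph attention** network (per head:
`e_ij = LeakyReLU(a · [W h_i ‖ W h_j])`, `α_ij = softmax_j(e_ij)` over the
neighborhood of `i`, `h'_i = σ(Σ_j α_ij W h_j)`; hidden layers concatenate
heads, the final layer averages them) or a **graph convolution** network
(`H' = σ(D^-1/2 (A+I) D^-1/2 H W)`).

Two heads sit on the shared embeddings:

* classification: `P_v = softmax(Wᵀ h_v + b)` with cross-entropy loss
  `L_NC = mean over labeled nodes of −log P_{v, y_v}`;
* link prediction: `S_ij = sigmoid(h_iᵀ M h_j + b)` (bilinear decoder, `M`
  symmetrized; a parameter-free inner-product decoder is available) with
  binary cross-entropy `L_LP` against the adjacency over node pairs.

Training minimizes the joint objective

```
L = L_NC + α · L_LP
```

full-batch with Adam (learning rate 0.005, 300 epochs, dropout 0.1 on layer
inputs and attention coefficients, 8 attention heads) in the transductive
setting: held-out *edges* are hidden from the adjacency before training, and
held-out *node labels* are masked from the classification loss, but all nodes
are visible to the encoder. All gradients are computed analytically by
hand-written reverse-mode passes and verified against finite differences in
the test suite.

## Worked example

A synthetic benchmark with known structure: a 4-block stochastic block model
(400 nodes, within-block edge probability 0.10, between 0.005) whose blocks
double as classes, with 16-dimensional Gaussian node features whose class
centroids sit at pairwise distance 2 against unit noise.

```r
library(mtgnn)

cfg <- sbm_config(n = 400, classes = 4, p_in = 0.10, p_out = 0.005,
                  F = 16, mu = 2.0, sigma_f = 1.0, seed = 1)
g <- make_synthetic_dataset(cfg)
g
#> attributed_graph: 400 nodes, 2268 undirected edges, 16 features, 4 classes (400 labeled)

ns <- split_nodes(g, train_ratio = 0.6, seed = 1)       # 60% of labels for training
es <- hide_edges(g, val_frac = 0, test_frac = 0.10, seed = 1)  # hide 10% of edges

f <- fit(g, ns, es, encoder_config("gat"), train_config(alpha = 1, seed = 1))
f
#> mtgnn_fit: gat encoder, 300 epochs, alpha = 1, final L = 0.0956

evaluate_model(f, g, ns, es)
#> accuracy = 0.9938 (n = 160)   link AUC = 0.8174   AP = 0.7740 (pos = 226, neg = 226)
```

The model classifies 99.4% of the 160 held-out nodes correctly, and ranks a
hidden true edge above a random non-edge 81.7% of the time (Mann–Whitney
AUC over 226 hidden positives vs 226 sampled negatives). In an SBM, edges
are independent given the blocks, so hidden edges are statistically
indistinguishable from other within-block non-edges; with these densities
the Bayes-optimal AUC is about 0.82 — the model is essentially at the
information ceiling.

The sensitivity drivers reproduce the standard experiments: `alpha_sweep()`
re-trains over `α = 0, 0.1, …, 1` (at `α = 0` the link decoder receives no
gradient and held-out link AUC stays at chance), and `ratio_sweep()` varies
the labeled-node training ratio from 10% to 90%, each with repeated
re-splits and mean ± sd reporting.

## Command line

The same drivers are exposed as a CLI (see `inst/scripts/mtgnn`):

```sh
mtgnn generate --n 400 --classes 4 --p-in 0.1 --p-out 0.005 --seed 1 --out data/
mtgnn train --edges data/edges.tsv --features data/features.tsv \
    --labels data/labels.tsv --encoder gat --alpha 1 --seed 1 --out run/
mtgnn sweep-alpha --synthetic default --repeats 10 --out sweep/
```

Every command writes a YAML manifest (config echo, seeds, versions) beside
its outputs.

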