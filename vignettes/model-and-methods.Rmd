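---
title: "Coupled graph autoencoders for bipartite association prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled graph autoencoders for bipartite association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vemlda)
```

## The problem

We observe a binary association matrix $Y \in \{0,1\}^{m \times n}$ between
$m$ lncRNAs and $n$ diseases, where $Y_{ij} = 1$ records an experimentally
supported association and $Y_{ij} = 0$ means *unknown*, not *absent*. The
task is to score every unknown pair so that true-but-unrecorded
associations rank highly. Two side sources of information are available:
continuous lncRNA features (k-mer skip-gram embeddings of nucleotide
sequences, 300-dimensional by default) and binary disease features
(indicator vectors of association with a gene panel). Known associations
are extremely sparse, so evaluation must be imbalance-aware (AUPR,
Matthews correlation, fixed-specificity operating points) rather than
accuracy-driven.

## Model

### Graphs

Each space (lncRNA, disease) gets its own graph. For node features
$X$, each node selects its $k = 10$ nearest other nodes under the
Euclidean metric; the adjacency keeps an edge only where the selection is
*mutual* and adds self-loops,
$\tilde A = C^\top \odot C + I$,
with $\odot$ the Hadamard product. Layers operate on the symmetric
normalization $\hat A = \tilde D^{-1/2} \tilde A \tilde D^{-1/2}$, whose
spectrum lies in $[-1, 1]$. Mutual selection can isolate a node (self-loop
only); this is legal and the normalization remains well-defined. Distance
ties are broken by ascending node index so graph construction is
reproducible across platforms; a node never selects itself, by index, so
duplicate feature rows are allowed.

### Two autoencoders per space

Every layer is a graph convolution
$H^{(l)} = \rho(\hat A H^{(l-1)} \Theta^{(l)})$ without bias terms.

* The **inference network** (per space) is a variational graph
  autoencoder: a shared ReLU encoder layer ($d \to 256$), parallel linear
  heads for the posterior mean $\mu$ and log standard deviation
  $\log\sigma$ ($256 \to 256$), and a two-layer decoder
  ($256 \to 256$ ReLU, $256 \to d$ sigmoid). Representations are sampled
  with the reparameterization trick $Z = \mu + \sigma \epsilon$,
  $\epsilon \sim \mathcal N(0, I)$. Parameterizing $\sigma = e^{\log\sigma}$
  keeps the optimization unconstrained and $\sigma > 0$ by construction.
* The **label network** (per space) is a plain graph autoencoder: one
  ReLU layer from the label matrix to the 256-dimensional representation
  $Z'$, and one sigmoid layer back to a score block $F$. The lncRNA-space
  network consumes $Y$; the disease-space network consumes $Y^\top$.

Sigmoid squashing is applied to decoder outputs only ($X'$ and $F$);
$\mu$, $\log\sigma$, $Z$ and $Z'$ are unsquashed. Dropout (rate 0.5)
regularizes the *inputs* of hidden-to-output layers during training;
representations are always the undropped layer outputs, mirroring the
convention of standard graph-autoencoder stacks. Weights are initialized
Glorot-uniform from the run seed.

### Losses

Per space, the inference loss is reconstruction plus KL divergence,
$L_q = L_{qr} + L_{KL}$, with

* Gaussian features (lncRNA embeddings, min-max scaled to $[0,1]$):
  $L_{qr} = \tfrac12 \lVert X - X' \rVert_F^2$;
* Bernoulli features (disease gene profiles): full binary cross entropy
  $L_{qr} = -\sum_{ij} [X_{ij} \log X'_{ij} + (1 - X_{ij}) \log(1 - X'_{ij})]$;
* $L_{KL} = -\sum_{ij} \tfrac12 (1 + 2\log\sigma_{ij} - \mu_{ij}^2 - \sigma_{ij}^2)$.

The label-network loss per space is cross entropy against the known
labels plus a **manifold loss** $L_m = \tfrac12 \lVert Z - Z' \rVert_F^2$
tying the label representation to the (frozen) inference representation.
A **co-training loss** $L_c = \tfrac12 \lVert Z_l Z_d^\top - Y \rVert_F^2$
ties the two spaces together through the labels. The label cross entropy
is likewise the *full* binary form: a positive-term-only cross entropy
has the all-ones output as a trivial global minimizer, so the two-sided
form is required for a well-posed objective. Losses are summed, not
averaged, and logs are clamped at $10^{-10}$ against saturated decoder
outputs. Totals are
$\mathcal L_q = \alpha L_{ql} + (1-\alpha) L_{qd} + \beta L_c$ and
$\mathcal L_p = \alpha L_{pl} + (1-\alpha) L_{pd}$ with each $L_p$
containing $\gamma L_m$.

### Variational EM

Training alternates once per epoch:

* **E-step** — one Adam update of both inference networks with all
  label-network weights frozen, minimizing $\mathcal L_q$; the
  reparameterization noise is redrawn every pass.
* **M-step** — one Adam update of both label networks with all
  inference-network weights frozen; the manifold targets are the
  posterior means $\mu$ recomputed from the just-updated inference
  networks (the noiseless representation gives a lower-variance coupling
  target than a fresh sample).

The coupling weights ramp as $\beta = \gamma = e / e_n$: early epochs let
each network find its own structure, late epochs enforce agreement.
"Until convergence" is realized as a fixed $e_n = 500$ epochs with no
early stopping. After training, the label networks run in eval mode
(dropout off) to produce $F_l$ ($m \times n$) and $F_d$ ($n \times m$),
fused as $F = \alpha F_l + (1-\alpha) F_d^\top$ and min-max rescaled to
$[0, 1]$. Both blocks pass through a 256-wide bottleneck, so each has
rank at most 256 and, by the rank-sum inequality, so does the fusion:
the output inherits the low-rank structure the association matrix is
assumed to have.

Two Adam instances are used (one per network group), each with learning
rate 0.01 and weight decay $10^{-5}$; one step per group per epoch. All
defaults live in `train_config()`.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.5 | lncRNA/disease space balance in both totals and the fusion (dimensionless, open interval) |
| `epochs` | 500 | E/M alternations; also the denominator of the coupling ramp |
| `learning_rate` | 0.01 | Adam step size |
| `weight_decay` | 1e-5 | L2 penalty added to gradients |
| `dropout` | 0.5 | drop probability on hidden-layer inputs during training |
| `hidden_dim` | 256 | representation width; also bounds the rank of each score block |
| `knn_k` | 10 | neighbours per node before the mutual intersection |
| `seed` | 1 | fixes initialization, dropout masks and sampling noise |

## Synthetic benchmark

`synthetic_lda()` generates a complete study triple. Row factors $U$
($m \times r$) and column factors $V$ ($n \times r$) are i.i.d. standard
normal; ground-truth propensities are $\mathrm{sigmoid}(U V^\top / \sqrt r)$
(the $\sqrt r$ keeps logits $O(1)$ at any rank), and $Y$ plants 1s at the
`n_positives` top-propensity cells — a deterministic choice that makes the
number of knowns exact and runs comparable across seeds. lncRNA features
are a random linear read-out of $U$ plus Gaussian noise, min-max scaled;
disease features are Bernoulli with probability
$\mathrm{sigmoid}(V W_d + \mathrm{logit}(\text{base rate}))$. Both feature
families are therefore informative of exactly the factors that generated
$Y$ — the structural assumption the model exploits. If a disease's binary
row comes out all-zero, its highest-probability entry is set to 1 so
every node remains featured.

The fixed benchmark (`benchmark_spec()`) uses $m = 60$, $n = 80$,
$r = 4$, 300 positives (prevalence 0.0625), 64 continuous features at
noise sd 0.3, and 120 binary features at base rate 0.05. These sizes keep
a full 5-fold cross-validation at the default 500 epochs within a few
minutes on one CPU while leaving the positives sparse enough that AUPR is
a demanding metric.

What the generator does *not* emulate: real lncRNA sequence composition
(features are linear factor read-outs, not embeddings of actual
sequences), ontology structure among diseases, publication bias in which
associations are recorded, and heavy-tailed degree distributions. Passing
the benchmark shows the optimization and coupling machinery recovers a
planted low-rank signal from feature-informed graphs; it does not certify
performance on any real database.

## Evaluation protocol

Cross-validation partitions the *known positives* into k folds (unknown
pairs are never masked — they are already 0). For each fold the model is
refit from scratch on the masked matrix; the evaluation set is the
held-out positives (label 1) plus all pairs unknown in the full matrix
(label 0), with training positives excluded. Metrics are reported per
fold and pooled over the concatenated fold scores; both conventions are
reported since pooling weighs folds by pair count while the per-fold mean
does not.

Numerical conventions: a pair is predicted positive iff its score is
$\ge$ the threshold; any metric with a vanishing denominator is defined
as 0; AUROC is the trapezoidal ROC integral (equal to the Mann-Whitney
statistic with ties counted one half); AUPR is non-interpolated average
precision with tied scores collapsed into a single threshold step (under
which an all-tied ranking scores exactly the prevalence, the correct
chance level); the fixed-specificity threshold is the smallest observed
score whose specificity reaches the requested level.

## Numerical choices and degenerate inputs

* Distance ties in neighbour selection: ascending node index.
* Constant fused score matrices map to all zeros (with a warning), as do
  constant feature matrices under min-max scaling.
* Cross-entropy logs are clamped at $10^{-10}$; the KL term needs no
  clamp because $\sigma = e^{\log\sigma}$.
* An all-zero association matrix is rejected: with no positives there is
  nothing to propagate.
* Training aborts with the epoch number if any loss goes non-finite.

## Problem sizes used in the tests

The unit suite runs on small instances (tens of nodes, 8–20 epochs,
16-wide hiddens) where finite-difference gradient checks and exhaustive
oracles are exact and fast. The acceptance-style checks run the full
benchmark at the default configuration: three generator seeds, 5-fold
cross-validation each, plus one full-data fit for the rank and output
contracts. Larger problems scale roughly linearly in epochs and
quadratically in nodes through the dense adjacency products; dense
representation is a deliberate choice for the few-thousand-node regime
this method targets.

## Known limitations

* The skip-gram embedder is a compact reimplementation (overlapping
  k-mers, negative sampling); it reproduces the protocol shape but not
  any specific pretrained embedding artifact.
* No cold-start evaluation: a disease or lncRNA with zero training
  positives can only be scored through its feature-graph neighbours, and
  the cross-validation protocol does not isolate that regime.
* One optimizer step per network group per epoch means "convergence" is
  governed entirely by the epoch budget and the coupling ramp.
* Dense matrices throughout; memory grows as $O(p^2)$ per graph.

## A short worked run

```{r example, eval = FALSE}
dat <- synthetic_lda(benchmark_spec(0))
fit <- vemlda(dat$Y, dat$X_l, dat$X_d, train_config(seed = 0))
summary(fit)
rep <- cross_validate(dat$Y, dat$X_l, dat$X_d, train_config(seed = 0),
                      k_folds = 5, seed = 0)
rep
```
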