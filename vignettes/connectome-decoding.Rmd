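---
title: "Decoding task states from functional connectomes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding task states from functional connectomes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conndecode)
```

`conndecode` implements a complete task-state decoding pipeline for
parcellated brain activity: synthetic multi-subject time series are turned
into weighted functional brain graphs, node-level features are attached, a
spectral graph convolutional network (GCN) classifies each run's task state,
and a statistical harness compares decoding performance between subject
groups. This vignette documents the model, the parameters, the design of the
synthetic generator, and the numerical choices, in that order.

## 1. The statistical model

A *run* is a $T \times N$ matrix of $N$ parcel time series. Functional
connectivity is the Pearson correlation matrix $R$ of those series; edge
strength is variance-stabilized with the Fisher z transform
$z = \operatorname{artanh}(r)$, and the graph is obtained by thresholding:

* **proportional** (default, level 0.10): keep the strongest fraction of the
  $N(N-1)/2$ possible edges (exactly
  $\lfloor \text{level} \cdot N(N-1)/2 + 0.5 \rfloor$ edges, ranked by signed
  or absolute weight);
* **absolute**: keep edges with $z$ strictly above a cutoff.

The result is a symmetric, hollow, weighted adjacency matrix $A$. Its
spectral structure is exposed through the combinatorial Laplacian $L = D - A$
and the symmetric normalized Laplacian
$L_{sym} = I - D^{-1/2} A D^{-1/2}$ (with $d^{-1/2} = 0$ for isolated
nodes), whose eigendecomposition defines the graph Fourier domain used by
the spectral-filter utilities (`graph_fourier()`, `spectral_filter_apply()`,
`chebyshev_filter()`).

Each node carries a feature vector: nine statistical time-series calculators
(`statistical_features()`: absolute sum of changes, Benford correlation,
c3 nonlinearity, CID-CE complexity, longest strike above the mean, variance,
standard deviation, skewness, 25% quantile) optionally concatenated with a
topological node embedding of the run's own graph
(`node_embedding()`: Node2Vec, Walklets, NetMF, RandNE — all implemented
from first principles in this package).

The classifier is a three-layer GCN. One layer computes

$$H^{(l+1)} = f\!\left(\tilde D^{-1/2} (I + A) \tilde D^{-1/2}\, H^{(l)}\, \Theta^{(l)}\right),$$

the renormalized propagation of Kipf-style graph convolution; the network
stacks three such layers of 92 units with batch normalization, ReLU and
dropout 0.65 after each, pools node representations with a global mean, and
applies a linear softmax head. Training uses Adam (learning rate 0.001,
weight decay 0), cross-entropy loss, 100 epochs, mini-batches of 16 (the
reference grid is 16/32/48/64), learning-rate halving after 10 epochs
without validation improvement, and the parameters snapshot with the best
validation loss is kept.

Evaluation follows a stratified 5-fold protocol (`stratified_cv_split()`):
each held-out fifth is split 60:40 into validation and test, features are
standardized with training-fold statistics only, and the metric suite
(`compute_metrics()`) reports accuracy, balanced accuracy, macro / micro /
weighted F1, macro precision and recall, and the multiclass Matthews
correlation coefficient in Gorodkin's $R_K$ form

$$\mathrm{MCC} = \frac{c\,s - \sum_k p_k t_k}{\sqrt{(s^2 - \sum_k p_k^2)(s^2 - \sum_k t_k^2)}},$$

with $c$ the number of correct predictions, $s$ the sample count and
$p_k, t_k$ the predicted / true counts of class $k$. Zero-variance
denominators follow the 0-convention. An L2-regularized multinomial
logistic regression on raw connectivity features (`logistic_baseline()`,
via glmnet with a CV-tuned penalty) serves as the linear baseline.

## 2. Design of the synthetic generator

No imaging data ships with the package; `simulate_dataset()` produces
labeled multi-subject data with a planted, recoverable class structure.

Each run is a stationary AR(1) process
$x_t = \phi\, x_{t-1} + \varepsilon_t$, $\varepsilon_t \sim N(0, \Sigma_c)$,
initialized from its stationary distribution, with $\phi$ = 0.3 by default.
The innovation covariance $\Sigma_c$ carries the class signal through a
fixed partition of the parcels into `n_blocks` communities of *unequal*
sizes (proportional to $1, 2, \dots, K$):

* all pairs share a weak baseline correlation (`rho_between`, default 0.05);
* every within-block pair gets a moderate boost of
  $0.5 \cdot \text{effect\_size}$;
* class $c$'s *designated block* gets the full boost `effect_size` on its
  correlations **and** an innovation amplitude scale of
  $1 + \text{effect\_size}$ on its parcels.

Per-subject heterogeneity enters as a small Gaussian jitter on the
correlation boosts (`subject_sd`), and the binary group attribute scales the
correlation boosts by $1 + \text{group\_effect} \cdot \text{group}$, so
`group_effect > 0` makes the class structure easier to decode in group 1.

**Why fixed unequal blocks?** An earlier design rotated the block partition
from class to class. That is provably undecodable for this architecture:
if class $c$'s distribution is a node permutation of class 1's, then a mean
pooled GCN readout — which is permutation invariant — assigns both classes
identical distributions of graph-level representations, so the classifier
is at chance *by construction* (measured: 27% accuracy on a 4-class problem
where a logistic regression on raw connectivity, which sees node identity,
scored 100%). With one fixed partition and per-class designated blocks of
different sizes, the class-conditional distributions are not related by
node permutations and the pooled representation separates them.

**Limits.** The generator is deliberately minimal: it is stationary,
Gaussian, and block-structured, with no hemodynamic response, head motion,
physiological noise, spatial autocorrelation, or realistic network topology.
It validates the pipeline's machinery (signal in → labels out), not its
neuroscientific performance; none of the headline numbers obtained on it
transfer to real acquisitions. A voxel-level wrapper
(`simulate_voxel_runs()` + `average_voxel_timeseries()`) exists to exercise
the parcel-averaging entry point.

```{r generator}
cfg <- sim_config(n_subjects = 4, n_parcels = 20, n_classes = 3,
                  n_timepoints = 120, effect_size = 0.8, seed = 42)
runs <- simulate_dataset(cfg)
length(runs)            # one run per subject x class
g <- functional_graph(runs[[1]]$series, method = "proportional", level = 0.25)
g
round(statistical_features(runs[[1]]$series[, 1]), 3)
```

## 3. Node embeddings: algorithms and numerical choices

All four embeddings are written from scratch (walks and skip-gram SGD in
C++ via Rcpp for speed; everything else in base R):

* **Node2Vec** (`node2vec_embed()`): second-order biased walks — from $v$
  with predecessor $t$, candidate $x$ is weighted by $w(v,x)$ times $1/p$
  if $x = t$, $1$ if $x \sim t$, else $1/q$ — feed a skip-gram model with
  negative sampling (noise distribution: unigram$^{3/4}$; linear
  learning-rate decay; center vectors returned).
* **Walklets** (`walklets_embed()`): first-order walks, but scale $k$ trains
  only on pairs at *exact* offset $k$; the per-scale blocks of dimension
  `dim / n_scales` are concatenated, so later blocks encode coarser
  structure.
* **NetMF** (`netmf_embed()`): the dense matrix DeepWalk implicitly
  factorizes, $M = \frac{\mathrm{vol}(G)}{bT} \left(\sum_{r=1}^{T}
  (D^{-1}A)^r\right) D^{-1}$, truncated as $M' = \log \max(M, 1)$, then a
  rank-`dim` SVD with embedding $U_d \sqrt{\Sigma_d}$. Deterministic; SVD
  sign ambiguity is fixed by forcing each column's largest-magnitude entry
  positive.
* **RandNE** (`randne_embed()`): iterated Gaussian random projection
  $U_0 = R$, $U_k = (D^{-1}A) U_{k-1}$, output $\sum_k \alpha_k U_k$ with
  $\alpha = (1, 10^2, 10^4)$ by default.

Two numerical points matter in the pipeline context:

1. **A shared coordinate system across runs.** A random-projection (or SVD)
   basis is arbitrary per graph; if every run draws its own projection, the
   embedding columns are not comparable features across runs and downstream
   accuracy is unstable. `build_run_representations()` therefore uses one
   embedding seed for the whole study, and RandNE draws its projection once
   at full node count, so all runs share one basis. NetMF's sign convention
   only partially mitigates the analogous SVD ambiguity — a known
   limitation.
2. **Isolated nodes.** Thresholding can isolate nodes, and $D^{-1}$ is then
   undefined; the pipeline embeds the non-isolated subgraph and gives
   isolated nodes zero embedding rows.

```{r embedding}
emb <- node_embedding(g, algorithm = "randne", dim = 8, seed = 1)
dim(emb)
```

## 4. GCN training internals

The network is hand-implemented in base R with analytic gradients (verified
against central finite differences to relative error below $10^{-7}$ in the
unit tests). Choices that affect reproducibility:

* Glorot-uniform initialization, seeded per fit.
* Batch normalization uses population statistics over all nodes of the
  mini-batch's graphs stacked row-wise ($\varepsilon = 10^{-5}$), with
  running statistics (momentum 0.1) used at prediction time.
* Dropout is inverted dropout (train-time scaling), applied after each
  Conv → BN → ReLU block.
* The plateau scheduler halves the learning rate (patience 10, floor
  $10^{-5}$), and `fit_gcn()` returns the parameter snapshot at the best
  validation loss, not the final epoch.
* Models serialize to plain JSON (`save_gcn()` / `load_gcn()`), keeping the
  repository text-only.

`fit_gcn()` returns a classed object with `print()`, `summary()`, `coef()`,
`predict()` and `plot()` methods in the classic R modelling idiom.

## 5. The repeated-run group comparison and its calibration

`repeated_run_comparison()` implements the protocol used for group
contrasts: train/evaluate a classifier `n_runs` times (default 35) on each
group's data with fresh seeds, collect the per-run MCCs, check both samples
with Shapiro–Wilk, and compare them with Welch's two-sided t-test at
$\alpha = 0.05$.

A subtlety: the protocol's repeated runs share one fixed dataset per group,
so run-level MCCs are *not* independent draws from a dataset-generating
distribution — a shared dataset-level component inflates the t-statistic
and makes the test anti-conservative if the per-run variance is small. The
package's cheap harness classifier (`connectivity_centroid_mcc()`, a
nearest-centroid classifier on Fisher-z connectivity) is therefore designed
so that run-level variance dominates: each run subsamples subjects
*without replacement* (an earlier bootstrap with replacement leaked
duplicated runs across the train/test split and was removed), draws a
random subset of connectivity features, and makes a fresh stratified half
split. With this design the measured null rejection rate over 200
replications of a no-difference comparison is 0.055 at $\alpha = 0.05$, and
a strongly planted group effect is detected in 10/10 replications (see
`tests/testthat/test-acceptance.R`). When the full GCN is the classifier
under study, `gcn_pipeline_mcc()` plugs into the same harness.

## 6. A full decoding study

The end-to-end study below (20 subjects, 4 classes, 30 parcels) is the one
exercised by the acceptance suite; it takes about a minute, so it is not
evaluated when this vignette builds.

```{r decode, eval = FALSE}
cfg <- sim_config(n_subjects = 20, n_parcels = 30, n_classes = 4,
                  n_timepoints = 120, effect_size = 0.8, seed = 11)
runs <- simulate_dataset(cfg)
decode_runs(runs, embedding = "randne", embedding_dim = 16,
            threshold_level = 0.25,
            config = gcn_config(batch_size = 16, seed = 2), seed = 5)
#> decode_result: 5-fold CV, embedding = randne, 4 classes
#>   mean accuracy 1.0000 | F1 macro 1.0000 | MCC 1.0000
```

Problem sizes throughout (parcel counts, subject counts, embedding
dimension 16, threshold 0.25) are desk-scale choices of this package so the
whole suite runs in minutes on one CPU; the architecture and training
protocol themselves are kept at their published values (3 × 92 units,
dropout 0.65, learning rate 0.001, 100 epochs).
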