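---
title: "Predicting circRNA-drug sensitivity associations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting circRNA-drug sensitivity associations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Circular RNAs (circRNAs) modulate the sensitivity of cells to drugs, and
experimentally testing circRNA-drug pairs is slow and expensive. Given a
small set of known associations between circRNAs and drug sensitivity,
together with circRNA host-gene sequences and drug structures, `cdaae`
scores unobserved pairs so that laboratory effort can be prioritized. The
task is bipartite link prediction: rows of a binary association matrix
$A \in \{0,1\}^{M \times N}$ are circRNAs, columns are drugs, and the model
must rank the zero entries by their probability of being true associations.

## Similarity representations

Four base similarity matrices are fused into one feature space per entity:

* **Sequence similarity (SSC).** CircRNAs are represented by their host-gene
  sequences; for sequences $c_i$, $c_j$ the similarity is the
  length-normalized Levenshtein complement
  $SSC_{ij} = 1 - \mathrm{lev}(c_i, c_j) / (|c_i| + |c_j|)$, which lies in
  $(0, 1]$ because an edit script never costs more than deleting one string
  and inserting the other. Edits have unit cost; characters outside
  `A/C/G/T` are kept and mismatch at unit cost.
* **Drug structure similarity (SSD).** Drugs are path-based (Daylight-style)
  topological binary fingerprints compared with the Tanimoto coefficient
  $|a \wedge b| / |a \vee b|$. Fingerprints can be supplied directly as 0/1
  vectors, or computed from SMILES with OpenBabel's FP2 fingerprinter (1024
  bits) when the ChemmineR/ChemmineOB packages are available. Two all-zero
  fingerprints compare as 1 with a warning; the ratio is otherwise 0/0.
* **Interaction-profile kernels (GSC, GSD).** The Gaussian
  interaction-profile kernel compares binary association profiles (rows of
  $A$ for circRNAs, columns for drugs):
  $GS_{ij} = \exp(-\eta \|IP_i - IP_j\|^2)$ with bandwidth
  $\eta = \eta' / \bigl(\tfrac1n \sum_k \|IP_k\|^2\bigr)$ and $\eta' = 1$.
  Profiles of entities with no associations would make the bandwidth
  degenerate, so the synthetic generator guarantees coverage and an
  all-zero matrix is rejected.
* **Fusion (SC, SD).** Elementwise, the fused similarity is the mean of the
  base and kernel values where the base similarity is nonzero, and the
  kernel value alone otherwise. The test is per entry, which keeps the rule
  meaningful (a matrix-level test would never trigger for sequence
  similarity, whose entries are strictly positive).

A pair $(c_i, d_j)$ is represented by row $i$ of SC concatenated
conceptually with row $j$ of SD — each row is an entity's similarity
profile against all entities of its kind.

### Label leakage

The interaction-profile kernels are functions of the labels being
predicted. During cross-validation the kernels are therefore recomputed per
fold from the association matrix with the test fold's positives zeroed
(`gip_leakage_guard`, on by default); the blind protocol masks the blind
positives the same way. Sequence and fingerprint similarities do not depend
on labels and are computed once.

## Multi-scale convolutional extractor

Each entity's similarity vector is processed by parallel 1-D convolutions
with kernel widths 3, 5 and 7 (three scales, the optimum of the scale-count
sweep), 16 filters per scale, stride 1 and "same" zero padding, followed by
ReLU. The three feature maps are concatenated and flattened
(channel-major), and a fully connected ReLU layer compresses them to
`fc_dim` (default 128) values per entity; the circRNA and drug branches
have separate parameters, and the pair representation is the concatenation
$x = [x_c \| x_d]$ of length `2 * fc_dim`. The ablation variant `no_mscnn`
replaces all of this with the raw concatenation of the two similarity
vectors.

Unstated architectural details (filter count, padding, pooling, the
interface between the convolutional output and the fully connected layer)
were fixed as: 16 filters per scale, same-padding, no pooling, flatten
before the fully connected layer. All are configurable.

## Adversarial autoencoder

The pair representation is compressed by an encoder (256-unit ReLU hidden
layer, linear 64-dimensional latent), reconstructed by a mirror decoder,
and regularized by a discriminator (64-unit hidden layer) trained to
distinguish standard-normal prior samples from encoder outputs. Training
alternates per minibatch:

1. **Reconstruction**: one RMSprop step on encoder+decoder minimizing mean
   squared reconstruction error (the Gaussian-likelihood reading of the
   negative log-likelihood objective).
2. **Regularization**: one discriminator step on the cross-entropy
   $-\log d(z_{prior}) - \log(1 - d(z_{post}))$, then generator (encoder)
   steps on the non-saturating loss $-\log d(z_{post})$. The
   encoder:discriminator training ratio $r$ (default 1:1) is implemented
   with a fractional accumulator: each iteration adds $r$ and runs
   $\lfloor\cdot\rfloor$ generator steps, so the long-run step ratio
   converges to $r$ for fractional settings such as 1.2:1 or 0.8:1.

**Latent standardization.** A deterministic encoder trained at the small
global learning rate (1e-4) cannot stop the adversarial game from drifting:
nothing bounds the latent code's location or scale, and the equally-paced
discriminator chases a moving target. The encoder output is
therefore passed through a non-affine batch standardization (running
statistics at evaluation time, re-estimated over the full training set
after the last update). This pins the latent code's per-dimension first
moments to the prior's and leaves the discriminator to shape
higher-order structure; it is the same stabilization commonly applied in
adversarial latent-matching models. With it, seeded training at ratio 1:1
ends with held-out discriminator accuracy indistinguishable from chance
(the equilibrium of the game).

The `no_discriminator` ablation skips the regularization phase entirely
(plain autoencoder); `no_encoder` removes the autoencoder and feeds the
extractor output directly to the classifier.

The classifier consumes the latent code $z$ by default. The alternative
reading — classifying the reconstruction $\hat x$ — is available as
`dnn_input = "reconstruction"`.

## Deep classifier and joint training

The classifier applies fully connected layers (default widths 128, 64)
with batch normalization, ReLU and dropout (rate 0.3), and a sigmoid output
$p = \sigma(W_{out} m_n + b_{out})$; pairs with $p \ge 0.5$ are called
positive (ties count as positive). The training loss is mean binary
cross-entropy with probabilities clipped to $[10^{-7}, 1-10^{-7}]$.

The whole stack is trained jointly: per minibatch, one RMSprop step on
BCE + reconstruction error (unit weights) through classifier, autoencoder
and extractor, then the adversarial phase. Adversarial gradients update the
encoder only, matching the formulation in which the generator objective is
a function of the encoder parameters. Optimization uses RMSprop with
learning rate 1e-4 and weight decay 1e-4 (applied to weight matrices, not
biases or normalization parameters) and Xavier initialization throughout.
Training epochs and batch size are not prescribed by the source method;
the defaults are 40 epochs at batch size 64 for the end-to-end model and
200 epochs for stand-alone autoencoder training, chosen as the point where
the loss traces flatten at the default problem sizes. All randomness flows
through explicit seeds, and two runs with the same configuration are
bit-identical.

## Evaluation protocols

Positives are all known associations; negatives are an equal number of
unobserved pairs drawn uniformly without replacement (balanced 1:1
sampling). Stratified $k$-fold cross-validation (5 or 10 folds) partitions
positives and negatives independently with per-class fold sizes differing
by at most one. The blind protocol isolates 20% of the pairs before any
training, trains on the remainder, evaluates once on the blind set, and
repeats with 5 different splits; blind pairs are provably absent from every
training fold. Metrics are exact-rank ROC AUC (Mann-Whitney with midrank
ties), average-precision AUPR, and the threshold metrics (precision,
recall, specificity, accuracy, F1) at 0.5, with zero-denominator cases
returning 0 with a warning. Negatives are drawn once per run before
folding; each blind repeat draws its own negatives.

## Synthetic benchmark

The generator plants the structure the similarity-fusion model assumes:
entities belong to latent clusters (round-robin assignment so every cluster
is populated on both axes); members of a cluster descend from an ancestral
sequence/fingerprint by point mutation (rate 0.05), so within-cluster
similarity exceeds between-cluster similarity; and associations are
Bernoulli draws at a higher within-cluster rate (0.35) than between
clusters (0.03). Defaults are 60 circRNAs, 50 drugs, 4 clusters, sequence
lengths 200-400, 256-bit fingerprints. Rows or columns left without any
association (likely at small sizes) receive one association drawn
proportional to their generating rates, so interaction profiles are never
all-zero. Identical seeds yield byte-identical files in the same formats
the real-data path consumes (FASTA, fingerprint TSV, edge-list TSV).

What the generator does not emulate: the extreme sparsity and size of real
association screens, realistic genomic sequence composition, chemical
fingerprint bit correlations, or dose-response-derived label noise. Tests
passing on this benchmark show the pipeline recovers a planted signal
end-to-end; they do not certify performance on real data.

**The information ceiling.** Given the cluster labels, each association is
an independent Bernoulli draw, so the best possible scorer — the
generating block rate, available via `planted_auc_ceiling()` — achieves
only about 0.79 AUC on balanced pairs at the default rates. Learned models
approach but cannot exceed this ceiling, and close to it the ablation
variants converge to similar scores: the planted benchmark separates a
working pipeline from a broken one, but compresses the margins between
architectural variants.

## Numerical choices and degenerate inputs

* Similarity matrices are validated (symmetry to 1e-9, range $[0,1]$, unit
  diagonal) and exactly symmetrized on construction; squared distances in
  the kernel computation are floored at 0.
* Probabilities are clipped in every log; batch normalization uses
  $\epsilon = 10^{-5}$ and momentum 0.9, with population statistics
  re-estimated after training.
* Prediction runs in eval mode (dropout off, normalization on fixed
  statistics) and is invariant to batch composition; rank ties are broken
  lexicographically by identifier.
* Training batches of size 1 are skipped (batch statistics undefined);
  divergence (loss above $10^6$) aborts with the trace attached.

## Known limitations

* The hand-written networks run on one CPU thread via BLAS matrix products;
  they are sized for the desk-scale benchmark (minutes per protocol), not
  for screens orders of magnitude larger.
* The latent standardization pins first moments by construction; the
  adversarial game is only responsible for higher-order structure.
* Blind-protocol model selection is a straight retrain on the development
  set: the package has no hyperparameter search to select (searching would
  be the place for the inner cross-validation loop).
* With `dnn_input = "reconstruction"` the classifier sees the decoder
  output; this reading is supported but not the default.
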