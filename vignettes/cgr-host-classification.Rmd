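---
title: "CGR feature tensors and CNN-based phage host classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CGR feature tensors and CNN-based phage host classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgrnet)
```

## The model

`cgrnet` predicts the bacterial host taxon of a phage from its genome alone.
The underlying assumption is compositional: phages infecting the same host
share k-mer usage, shaped by host-specific selection (codon adaptation,
restriction-site avoidance) and common ancestry. The package never aligns a
phage to a host genome; it learns to separate phage genomes whose k-mer
composition differs.

Each genome is encoded as a three-channel `2^k x 2^k` tensor built on the
Chaos Game Representation. The CGR iterates
`p_i = 0.5 * (p_{i-1} + corner(a_i))` from the centre `(0.5, 0.5)` of the
unit square, with corners `A=(0,0)`, `C=(0,1)`, `G=(1,1)`, `T=(1,0)` by
default. Because each step halves the distance to a corner, the last k
letters of the sequence confine the point to a unique `2^-k` sub-square, and
the unit square tiles into a grid of k-mer cells. The channels are

1. the count of each k-mer (frequency CGR),
2. the mean x coordinate of the trajectory points at which that k-mer ends,
3. the mean y coordinate of those points.

Channels 2 and 3 are what distinguish this representation from a plain
frequency CGR: two genomes can use a k-mer equally often but in different
genomic neighbourhoods, and the mean end-point position — which encodes the
distribution of the preceding sequence context — separates them. Words that
never occur are 0 in all three channels; since every real mean position is
strictly inside the open unit square, 0 is unambiguous as an absence marker.

Each channel is min-max rescaled to `[0, 1]` per sequence before
classification, putting counts (which grow with genome length) and
coordinates (already in the unit interval) on one scale.

The classifier is a compact CNN: two convolution blocks (5x5 kernels,
stride 1, padding 2, ReLU, then 2x2 max pooling with stride 2) with 64 and
128 output channels, a 512-unit fully connected layer with ReLU, and a
softmax output over host taxa. For k = 7 the shape chain is
`(3,128,128) -> (64,128,128) -> (64,64,64) -> (128,64,64) -> (128,32,32)`.
Training minimizes the categorical cross-entropy with Adam at learning rate
0.001. The network is implemented in base R: convolutions are evaluated as
im2col matrix products so the arithmetic runs in BLAS, and the
implementation is deterministic given the seed.

## Tunable parameters

* **`k`** (word length; grid side `2^k`). Default 7, the value at which
  host-classification accuracy peaks for real phage collections — large
  enough for specific signatures, small enough that a genome still populates
  the grid. The featurization cost and tensor size grow as `4^k`.
* **Corner assignment**. Configurable bijection from `{A,C,G,T}` to the four
  corners. It only reflects/permutes the grid and carries no information
  (the package's equivariance tests verify this); the default is the
  convention under which the package's exact worked-example fixtures hold.
* **`normalize`** (default on): per-channel min-max scaling. A constant
  channel maps to zeros rather than dividing by zero; this arises only for
  degenerate inputs (e.g. single-letter sequences).
* **Architecture** (`conv_channels = c(64, 128)`, `fc_units = 512`,
  5x5 kernels): the reference configuration. Two convolution blocks are the
  sweet spot between capacity and overfitting for this input size; the
  number of blocks is configurable, constrained to divide the grid side.
* **Training** (`learning_rate = 0.001`, `batch_size = 32`,
  `max_epochs = 100`, `patience = 10`, `validation = 0.1`, `seed`): Adam at
  0.001 is the reference setting; batch size, epoch budget and early
  stopping are this package's choices, all overridable. The validation
  split is used for model selection — the weights of the best-validation-
  accuracy epoch are kept — and training stops after `patience` epochs
  without improvement.
* **Dataset split**: `split_dataset()` partitions at 8:1:1
  (train/validation/test) with largest-remainder rounding, remainder ties
  going to the later subset, seeded and reproducible.

One model is trained per taxonomy level (species, genus or family); a
multi-level analysis is three independent fits. This matches how per-level
results are reported in practice and keeps the label space of each model
clean.

## Numerical and convention choices

* **Geometric binning.** A k-mer's grid cell is computed from its letters:
  the cell column is `sum(cx_i * 2^(i-1))` over letter positions i = 1..k
  (later letters dominate, since they were applied last), rows count from
  the top. Cell indices are 0-based in the API — row 0 is the top-left —
  and all exact tests key on per-word values through `kmer_cell_index()`,
  never on a particular printed matrix arrangement.
* **Ambiguity codes** (N, R, Y, ...): such residues emit no trajectory
  point, and any k-window containing one is discarded from the counts. This
  avoids fabricating coordinates while keeping the invariant that on
  ambiguity-free input the counts sum to `L - k + 1`.
* **Sequences shorter than k** are a hard error, not an empty tensor, to
  surface data problems early.
* **Exactness.** All CGR coordinates of short sequences are dyadic
  rationals, exact in double precision; the worked-example tests assert
  bit-identity, and the streaming featurizer is checked bit-for-bit against
  a brute-force oracle that re-iterates every prefix from scratch.
* **Ties.** Max pooling routes gradients to the first of equal entries in a
  fixed scan order; arg-max predictions and ranked outputs break probability
  ties by the lower class index. Both are documented determinism choices.
* **Cosine similarity** is computed as `sum(ab) / sqrt(sum(a^2) sum(b^2))`
  and clamped to `[-1, 1]`, so identical directions give exactly distance 0.
  Distances default to normalized tensors (the classifier's input scale); a
  raw-tensor variant is available by flattening unnormalized tensors into a
  matrix and calling `pairwise_distances()` on it. The flattening order —
  frequency channel, then mean-x, then mean-y, each row-major — is fixed so
  vectors are comparable across runs.
* **Macro metrics.** A per-class precision or recall with a zero denominator
  (class never predicted, or absent from the truth) contributes 0 to the
  macro mean. This is a documented convention, not an inference: sparse test
  sets with hundreds of host species routinely have classes with no
  predictions. By default the class set is the union of classes seen in
  either label vector; passing `labels =` to `confusion_matrix()` widens it.

## The synthetic generator

Real phage benchmark collections cannot ship with a package, so
`make_class_specs()` / `sample_sequences()` generate class-conditioned
sequences that carry exactly the signal the method exploits — and nothing
else. Each host class is an order-2 Markov chain over `{A,C,G,T}`: order 2
is the smallest order that induces non-trivial structure on 3-mers and
beyond while keeping the stationary distribution computable in closed form
(the package exposes `stationary_kmer_probs()`, and a test checks that
sampled sequences converge to it). A `separation` dial in `[0, 1]`
interpolates each class's transition rows between a shared random base table
(separation 0: all classes identical, no learnable signal) and a sharply
class-specific table with 85% of the mass on one preferred base per context
(separation 1: near-disjoint preferred k-mer sets). Default sequence length
is 2 kb — a desk-scale stand-in for phage genomes, which run from a few kb
(filamentous phages) to hundreds of kb.

What the generator does *not* emulate: genes and codon structure, repeats,
prophage insertions, horizontal transfer, class imbalance, uneven genome
lengths within a class, and sequencing artifacts. Passing the package's
end-to-end tests therefore demonstrates that the pipeline recovers
compositional class structure when it exists and degrades to chance when it
does not — it does not certify any particular accuracy on real phage data.

## Benchmark scale

The package's end-to-end acceptance property uses 5 classes, 50 sequences
per class, 2 kb per sequence, an 8:1:1 split, and k = 3 for the tensors.
k = 3 is the package's desk-scale choice for this benchmark: an order-2
generator concentrates its class signal in short words, so an `8 x 8` grid
already separates the classes cleanly, and the CNN trains in seconds per
epoch on one CPU. At separation 1 the held-out accuracy must reach at least
0.95; at separation 0 it must sit within three binomial standard errors of
chance (0.2). The k = 7 default remains the recommendation for real genomes,
where informative words are longer.

## Known limitations

* The CNN runs on the CPU in plain R; it is sized for desk-scale experiments
  and thousands of genomes, not for training on hundreds of thousands of
  sequences.
* Host assignment is closed-world: the model only ranks the taxa it was
  trained on and has no out-of-distribution rejection. The full softmax
  vector (and top-k lists) should be inspected when novel hosts are
  plausible.
* No reverse-complement canonicalization is applied; sequences are used as
  given, so strand conventions should be consistent between training and
  prediction data.
* Tree building itself is out of scope: the distance module exports PHYLIP /
  TSV matrices for external Neighbor-Joining tools.
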