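---
title: "Moment-based sequence features and neural classifiers for protein disorder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moment-based sequence features and neural classifiers for protein disorder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpmoments)
```

## The problem and the model

`idpmoments` addresses protein-level binary classification: given a primary
sequence, decide whether the protein belongs to the ordered or the
intrinsically disordered (lipid-binding) class. The method's premise is
that disorder leaves a signature in both the *composition* of a sequence
(which residues occur, and how often) and its *positional organization*
(where residues occur, and how residue types are placed relative to one
another). Both signals are captured in a fixed-width descriptor so that
standard feed-forward classifiers can be trained regardless of sequence
length.

The classification unit is the whole protein, not the individual residue:
the labels the pipeline consumes, and everything it reports, are
per-sequence. Per-residue windows would need positionally resolved labels,
which the protein-level benchmark design does not provide.

### The descriptor

Each validated sequence is reduced to 150 values in six blocks, in a fixed,
machine-readable layout (`feature_layout()`):

| block | width | content |
|---|---|---|
| FV | 20 | residue counts (raw, unnormalized) |
| PRIM moments | 30 | moment summary of the 20×20 position relative incidence matrix |
| RPRIM moments | 30 | the same on the reversed sequence |
| grid moments | 30 | moment summary of the ⌈√n⌉×⌈√n⌉ rank-encoded sequence grid |
| AAPIV | 20 | per-residue-type sums of 1-based positions |
| RAAPIV | 20 | the same on the reversed sequence |

Residues are indexed throughout by their rank in the fixed alphabetical
ordering `ACDEFGHIKLMNPQRSTVWY`. Any fixed bijection between residues and
ranks 1–20 would define an equivalent feature space; what matters is that
models, feature tables and checkpoints all share one ordering, so it is
pinned as a package constant rather than left configurable.

The PRIM entry for the ordered residue pair (x, y) is defined here as

$$R[x \to y] = \sum_{p\,:\,s_p = y} \big(p - \mathrm{firstpos}(x)\big),$$

the sum of the positions of all occurrences of *y* measured relative to
the first occurrence of *x*, with zero rows for residue types absent from
the sequence. "Relative position" admits several readings (relative to
every occurrence of *x*, to the nearest occurrence, …); the
first-occurrence rule is the one used in the feature-formulation lineage
this descriptor family comes from, it is computable in O(20·n), and its
entries may legitimately be negative (when *y* occurs before the first
*x*). The test suite checks this definition against an independent
brute-force enumeration, so the choice is pinned twice.

The reversed-sequence variants (RPRIM, RAAPIV) are defined *as* the forward
computation applied to the reversed residue string — the identities
`rprim(s) == prim(reverse(s))` and `raapiv(s) == aapiv(reverse(s))` are
tested properties, not coincidences.

The sequence grid uses k = ⌈√n⌉ with trailing zero padding, since √n is
not an integer for most lengths; ranks 1–20 encode residues so that cell
values stay small and the padding value 0 is not a valid residue code.

### Statistical moments

Every matrix (PRIM, RPRIM, grid) is summarized by 30 moments, 10 per
family, on the fixed order set {(0,0), (0,1), (1,0), (1,1), (0,2), (2,0),
(1,2), (2,1), (0,3), (3,0)} — all pairs of total order ≤ 3. Ten is the
natural cardinality of that set; descriptor families that list only nine
raw moments omit U01, which breaks the row/column symmetry of the set for
no reason, so the symmetric completion is used here.

* **Raw moments** U_ab = Σₑ Σ_f eᵃ fᵇ m_ef with 1-based indices.
* **Central moments** v_ab recentre the index grid on the mass centroid
  (x̄, ȳ) = (U10/U00, U01/U00); by construction v10 = v01 = 0 and
  v00 = U00, which the tests assert, and the values are invariant to
  translating matrix content within zero padding.
* **Hahn moments** project the matrix onto the orthonormal discrete Hahn
  polynomial basis on the support {0, …, Q−1}. The shape parameters are
  fixed at a = b = 0 (uniform weight — the discrete Chebyshev system);
  nothing in the descriptor design selects a particular asymmetric weight,
  and a = b = 0 is the canonical neutral choice. The basis is built by the
  standard three-term recurrence with per-order norm normalization rather
  than the hypergeometric closed form: the recurrence is numerically stable
  for every support size this package encounters (Q ≤ 20), and
  normalization makes the basis exactly orthonormal, hence the full
  transform invertible — a property the tests verify by reconstructing
  random matrices to ≤ 1e−6.

Numerical edge cases are resolved conservatively:

* **Degenerate centroid.** An all-zero matrix has U00 = 0 and no centroid;
  `centroid()` errors, while `central_moments()` substitutes the geometric
  grid centre, which yields all-zero central moments instead of NaNs
  propagating into feature vectors.
* **Tiny grids.** A length-1 sequence gives a 1×1 grid, which supports
  only the order-0 Hahn polynomial; moments whose order does not exist on
  the support are defined as 0.
* Moments are computed on the matrices as-is, with no rescaling of cell
  values; all standardization is deferred to the classifier pipeline,
  where it is learned from training data only.

## The classifier heads

Six architectures are provided over the 150-value input. Since the
descriptor design does not itself dictate network shapes, the package pins
small standard defaults:

* **CNN** — the vector as a length-150 single-channel 1-D signal:
  conv(32 filters, kernel 5, ReLU) → max-pool 2 → conv(64, kernel 3, ReLU)
  → global max-pool → dense 64 ReLU with dropout → sigmoid.
* **DNN** — dense 150→256→128→64→1, ReLU, dropout; **MLP** — dense
  150→64→32→1. The two differ only in depth and width, which is exactly
  how the two names are conventionally distinguished.
* **RNN / LSTM / GRU** — the vector reshaped to a 30-step × 5-feature
  sequence (the reshape is block-aligned with the feature layout), a single
  recurrent layer of width 64, and a sigmoid readout of the final hidden
  state. A fixed-width vector has no intrinsic time axis, so any recurrent
  treatment must impose one; 30×5 keeps steps short and homogeneous.

Training is minibatch Adam (learning rate 1e−3, batch 32) on binary
cross-entropy computed stably on logits, at most 100 epochs with early
stopping (patience 10) on an internal stratified 10% validation split, and
restoration of the best-epoch weights. Features are standardized per
column with statistics from the training rows only — the moment blocks
span many orders of magnitude (a PRIM U30 can exceed 1e9 while FV entries
are single digits), and unscaled optimization diverges. Dropout (rate 0.3)
regularizes the dense heads. All randomness — initialization, shuffling,
dropout, splits — derives from the explicit per-config seed, and R's
single-threaded BLAS arithmetic makes runs bit-reproducible, which the
tests assert.

The engine itself (dense, 1-D convolution via im2col, max-pooling with
first-index tie-breaking, recurrent cells with backpropagation through
time) is implemented in the package in plain R matrix algebra. Every
analytic gradient is verified against central-difference numerical
gradients in the test suite, for all six architectures; that check is the
load-bearing correctness argument for the engine.

## Evaluation protocols

* **Stratified k-fold cross-validation** (default k = 10). Folds are
  stratified so that each fold preserves the class balance of the design;
  the round-robin deal continues across classes, so fold sizes differ by
  at most one (1446 sequences → folds of 144–145). A fresh model,
  including its standardization, is fitted inside each training split. The
  pooled report over concatenated held-out predictions is primary;
  per-fold metrics are also returned since fold-averaged values are the
  other common convention and the two can differ slightly.
* **Independent test.** Default construction is a seeded stratified 80/20
  split performed before any training; an explicit external test FASTA
  pair can be supplied instead. Overlapping ids between train and test are
  refused as leakage.
* **Self-consistency** (resubstitution): train and evaluate on the same
  data. It upper-bounds the other protocols in expectation, a property the
  tests check across seeds.

Metrics are accuracy, sensitivity TP/(TP+FN), specificity TN/(TN+FP), MCC,
F1, and trapezoidal AUC-ROC. Sensitivity and specificity appear in some
descriptions of this metric panel in forms (TP/(TP+FP), TP/(FP+TN)) that
are inconsistent with the quantities those names denote and with the
near-symmetric values they take on balanced data; this package implements
the standard forms. MCC is defined as 0 whenever a denominator margin is
empty (the standard convention), and the confusion threshold is fixed at
0.5 while AUC remains threshold-free. The ROC/AUC implementation is
cross-checked in the tests against an independent library (pROC) to 1e−10.

The **decision-boundary map** standardizes the features, projects them onto
their first two principal components, retrains the configured head on the
2-D projection, and evaluates its probability on a lattice spanning the
points with a 10% margin. It is a visualization of how a head partitions
the projected space — red for the disordered subspace, blue for ordered —
not an evaluation protocol; the 2-D retraining necessarily discards most
of the descriptor's information.

## The synthetic generator: what it emulates and what it does not

`generator_spec()` defines two class emission models as first-order Markov
chains over the residue alphabet, an `effect` mixing weight between them,
and a length range. The defaults are fixed once: class 0 emits from the
uniform chain; class 1 is interpolated toward a chain with self-transition
mass 0.6 on the hydrophobic residues I, L, V, F — an arbitrary but fixed
bias that produces both compositional drift (stationary distribution
enriched in I/L/V/F) and local transition structure (runs), the latter
detectable only by the positional feature blocks. First-order emission
rather than i.i.d. draws is deliberate: it lets tests plant signal that
frequency counts alone cannot see, isolating what PRIM/RPRIM contribute.

`benchmark_like()` reproduces the *shape* of the curated disorder
benchmark the package targets — 1446 sequences, 723 per class, lengths
50–400 — with a moderate effect size of 0.3, so the cross-validation
protocols can be exercised at realistic scale offline. `separable_spec()`
gives the opposite extreme: disjoint residue alphabets per class, hence a
dataset any functioning head must classify almost perfectly.

What the generator does **not** emulate: real amino-acid background
frequencies, homology structure between sequences, actual
disorder-associated compositional biases (low aromatic content, high
charge), or any lipid-binding biology. Passing tests on synthetic data
therefore demonstrate that the pipeline is *correct* (features computed as
defined, models able to learn planted signal, protocols leak-free), not
that any particular accuracy will be achieved on curated biological data.
Published headline numbers for this method family on the real benchmark
require the external download and a training setup whose details are not
recoverable; the acceptance script reports what this implementation
achieves on the synthetic stand-in instead, and makes no claim of
equivalence.

## Problem sizes and runtime choices

The test suite and acceptance script run on sizes chosen to exercise every
code path at desk scale: separable-signal checks use the generator default
of 200 sequences per class with the default training configuration; the
null (effect 0) check uses 400 per class so the held-out AUC estimate has
standard error ≈ 0.04 against its ±0.1 acceptance band; the effect-size
monotonicity check uses 200 per class × 3 seeds × 4 effect levels with the
MLP head (the fastest); protocol-integrity checks run 10-fold CV at 100
sequences per class over 5 seeds. The full benchmark-shaped dataset (1446
sequences) is used where only featurization and fold bookkeeping are
exercised, and for the MLP-based protocol runs in the acceptance script.

## Known limitations

* The six architectures are small fixed defaults, not tuned; no
  hyperparameter search is provided. On weakly separated data the heads
  differ noticeably — the global-max-pooled CNN, which is deliberately
  position-agnostic along the descriptor axis, can need more data or
  epochs than the dense heads to reach its ceiling, and on
  weak-signal synthetic sets may not beat them.
* Training is plain R; a benchmark-scale 10-fold CV with the CNN head is
  minutes, not seconds. The dense heads are near-interactive.
* Only the 20 canonical residues are modeled. Ambiguity codes are
  rejected, dropped, or mapped (B→D, Z→E, U→C) per an explicit policy;
  the strict default refuses silent mutation because every positional
  feature depends on exact residue placement.
* The reported protocols assume a curated, deduplicated input; no
  redundancy filtering is performed in-package (sequence clustering is an
  upstream, external step).
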