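---
title: "Methods: sequence features, the pair classifier, and the planted-motif benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence features, the pair classifier, and the planted-motif benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppitriad)
```

## The prediction problem

`ppitriad` treats protein–protein interaction (PPI) prediction as
binary classification over pairs of amino-acid sequences: a mapping
`f(P1, P2) → y` with `y = 1` for interacting pairs. Everything the
model sees is derived from primary sequence — no structures, no
interaction networks, no alignments against external databases. This
keeps the pipeline applicable to any protein with a known sequence, at
the cost that all interaction-relevant information must be squeezed
into sequence-derived features.

## Feature encoders

Each protein is encoded independently; a pair vector is the
concatenation `[features(A) | features(B)]`. The blocks, in fixed
order:

**Conjoint triads (CT).** The 20 residues are collapsed into 7 classes
by dipole moment and side-chain volume — {A,G,V}, {I,L,F,P}, {Y,M,T,S},
{H,N,Q,W}, {R,K}, {D,E}, {C} — and every overlapping class triplet at
positions `(i, i+1, i+2)` is counted, giving 7³ = 343 frequencies with
denominator `n − 2` (the number of windows). Triads touching an `X`
are skipped *and excluded from the denominator*, so the vector still
sums to 1 whenever at least one window is valid; a sequence whose every
window contains `X` is a degenerate input and raises an error rather
than returning an all-zero vector.

**Spaced conjoint triads (SCT).** A width-5 window slides along the
sequence and its first, third and fifth residues form the spaced triad
`(i, i+2, i+4)` — in `MVICL`, the triad `MIL`. With no skips the
denominator `n − 4` equals `n − 2 − g` for total gap `g = 2`. Two
alphabets are supported: the raw 20 letters (20³ = 8000 features,
the default, since the motif `MIL` is a raw-residue statement) and the
7 conjoint classes (343 features). The geometry is fixed at one-gap
spacing; a variable-gap union of patterns would change the denominator
semantics and is deliberately out of scope.

**Dataset-level PSSM.** The package builds a positional scoring matrix
directly from a sequence collection — the positional stack of the
dataset's sequences, not a multiple alignment. With `N_j` sequences of
length ≥ j and pseudocount α (default 1),

`P(a at j) = (count_aj + α) / (N_j + 20α)`, `P(a)` the overall residue
frequency under the same smoothing, and `score(a, j) = ln P(a at j) / P(a)`.

With α = 0 a zero count would give `−∞`; such scores are floored at a
configurable value (default −20) so outputs are always finite.
Positions beyond every sequence's length carry score 0. Each protein's
block is, by default, the score of its *observed* residue at each of
`L_max` positions (default 500), zero-padded beyond the sequence end
and at `X` positions; a `full20` mode emitting all 20 scores per
position is available. Note that in `full20` mode the emitted scores
depend only on position, not on the protein's own residues — it is the
literal "record every score, flatten" reading — which is why
`observed_residue` is the default. Because the PSSM is fitted on a
*collection*, cross-validation refits it per fold on the training
pairs' sequences only; a global-fit option exists for compatibility
with pipelines that fit once per dataset, at the price of mild
information leakage.

**AAindex means.** Every complete index of an AAindex1 flat file (20
finite values; indices with `NA` entries are excluded and reported)
contributes the mean of its per-residue values over the sequence's
non-`X` positions. The residue order of the flat file
(`A R N D C Q E G H I / L K M F P S T W Y V`) is pinned by the format.
How many indices to use is data-dependent; the bundled sample file
carries three well-known ones (Kyte–Doolittle hydropathy, Hopp–Woods
hydrophilicity, residue molecular weight) plus a deliberately
incomplete synthetic entry exercising the exclusion rule.

**Hydropathy.** Mean hydrophobicity (Kyte–Doolittle) and mean
hydrophilicity (Hopp–Woods) — `Σ (1/s)·scale(A_i)` over non-`X`
positions. Both scales are configurable 20-vectors.

**Amino-acid pairwise distance (AAPD).** For each residue type, every
unordered pair of its occurrences contributes `|p_i − p_j|`; the
feature is the pooled mean over all `C` such pairs. It is a positional
dispersion summary (identical under sequence reversal), *not* a 3-D
distance. When no residue repeats, `C = 0` and the value is defined as
0, since the mean is otherwise undefined.

`X` handling is block-specific by design: frequency blocks skip
windows containing `X` (keeping denominators interpretable), averaging
blocks simply omit `X` positions, and the PSSM treats `X` as
contributing no evidence.

## The classifier

The pair vector feeds a fully connected network: for each hidden width
`h` (default 512/256/128/64), `dense(h) → batch normalization →
LeakyReLU(α = 0.1) → dropout(rate 0.3)`, then `dense(1) → sigmoid`.
Training minimizes binary cross-entropy with Adam. Features are
standardized with mean and population standard deviation fitted on the
training rows only (standard deviations floored at 1e−8, so constant
columns map to exactly 0); held-out rows are transformed with training
statistics. A stratified fraction (default 10%) of the training rows
monitors validation loss every epoch: the best weights are
checkpointed and restored at the end, the learning rate is halved
after 10 stagnant epochs, and training stops after 20 stagnant epochs
or 200 epochs total. Optimizer settings the architecture leaves open —
initial learning rate 1e−3, batch size 64, the patiences and the
validation fraction — are implementation defaults, all exposed in
`model_config()`. The classification threshold is 0.5 with ties going
to the positive class. A single integer seed drives weight
initialization, shuffling, the validation split and dropout, making
training bit-reproducible; batch normalization uses batch statistics
during training and frozen running statistics at inference.

Numerical choices: probabilities are clipped to `[1e−7, 1 − 1e−7]`
inside the loss; a trailing minibatch of size 1 is merged into its
predecessor because batch statistics need at least two rows; the MCC
is computed with factored square roots to avoid integer overflow and
clamped to `[−1, 1]` against floating-point spill; any metric with a
zero denominator is reported as 0 and flagged rather than `NaN`.

## Evaluation

`stratified_folds()` keeps per-class fold sizes within one of exact
proportionality and additionally spreads the per-class remainders
cyclically over a seeded random fold order, so *total* fold sizes also
differ by at most one (a balanced 2 × 1,458-pair dataset at k = 10
yields folds of 291 or 292 with class counts within one). For each
fold, the standardizer — and the PSSM, unless globally fitted — is
estimated on the 90% training portion only. Reports carry per-fold
metrics, fold-mean ± sd aggregates (the headline numbers) and the
metrics of the pooled confusion matrix; for balanced classes, accuracy
equals `(recall + specificity)/2` exactly. FPR and FNR are emitted via
the identities `1 − specificity` and `1 − recall`. The MCC uses the
standard four-factor denominator
`√((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.

## The synthetic planted-motif benchmark

The generator emulates the one structural claim the feature set is
built around: that spaced, non-adjacent residue motifs carry
interaction information. Sequences are i.i.d. draws from a
configurable background (uniform by default; a natural-composition
preset exists). With probability `signal_strength`, an interacting
pair receives motif A in protein A and motif B in protein B, written
in the same `(i, i+2, i+4)` geometry the SCT encoder reads, at a
uniform random valid position, with the pair's residues drawn from a
composition tilted toward hydrophobic residues
(`background × exp(shift · KD/4.5)`, default shift 0.25); with the
same probability a non-interacting pair is scrubbed so the planted
patterns never occur in it. Labels are exactly balanced and the whole
dataset is reproducible from one seed.

Defaults are calibrated so the planted signal is *recoverable at the
default benchmark size* (600 pairs): the motifs `C-W-C` and `W-C-W`
are built from the two rarest conjoint classes (the cysteine singleton
and the H/N/Q/W class), so the corresponding spaced class-triads occur
in only ~3% of background sequences and the planted signal is nearly
noise-free under either SCT alphabet. With common motifs the signal
would still be present in the features (a two-feature rule separates
the classes almost perfectly) but a 540-row training set does not let
the network find it among thousands of sparse, heavy-tailed k-mer
columns — an instructive failure mode of
standardize-then-train pipelines on rare-feature data, and the reason
the reference study configuration below reads the SCT block in class
space.

`synthetic_study_configs()` records the configuration used by the
package's signal-recovery and ablation experiments: encoder = SCT in
the class-7 alphabet plus hydropathy and AAPD (a 346-feature protein
vector whose columns are dense enough to estimate from 540 training
pairs; CT, PSSM and AAindex blocks are off because at this sample size
they add mostly-redundant dimensions), model = hidden layers 32/16,
dropout 0.6, learning rate 3e−3, batch 64, at most 100 epochs with
patience 15. These are study-scale choices, not new defaults: the
shipped default architecture remains 512/256/128/64 with dropout 0.3.

At these settings (600 pairs, 10 folds, seeds 1–3) mean accuracy is
≈ 0.92 with the full planted signal, ≈ 0.49 with `signal_strength = 0`
(no information is planted, so chance is correct behavior), increases
monotonically over signal strengths 0 → 0.5 → 1, and drops by ≈ 0.3
when the SCT block is ablated on motif-only data (hydropathy shift 0,
isolating the spaced-motif channel) — the qualitative ablation result
the feature set predicts. The acceptance script reruns all of these
from scratch at any seed.

What passing these tests does **not** show: real interactomes are not
i.i.d. sequences with a single planted motif pair. Real signal is
distributed across many weak determinants, sequence composition is
far from uniform, the pair graph has hubs (the generator draws two
fresh proteins per pair, so no protein recurs), and negative sets are
constructed, not sampled from ground truth. The synthetic benchmark
validates the *machinery* — encoders, leakage-free cross-validation,
training dynamics — not biological generalization.

## Known limitations

* The dataset-level PSSM is a composition/position summary, not an
  evolutionary profile; it carries far less information than
  PSI-BLAST-style profiles and, in its `full20` mode, reduces to a
  position-only encoding.
* Dense networks on tens of thousands of standardized k-mer features
  need thousands of training pairs; below that, the class-7 SCT
  alphabet or feature-block ablation is advisable (see above).
* Training the published 512/256/128/64 architecture on
  38k-dimensional vectors is CPU-feasible but slow in pure R; the
  implementation leans on BLAS matrix products and is practical up to
  a few thousand pairs on one core.
* Pair order is kept as given (symmetric augmentation is available but
  off by default); the model is therefore not guaranteed to be exactly
  symmetric in (A, B).
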