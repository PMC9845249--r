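---
title: "Predicting TCR-peptide binding with a hybrid gMLP: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting TCR-peptide binding with a hybrid gMLP: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

T cells recognize infected or malignant cells when their T-cell receptor
(TCR) binds a peptide presented by an MHC molecule. The third
complementarity-determining region (CDR3) of the TCR alpha and beta chains is
the most variable part of the receptor and the dominant determinant of which
peptide a TCR recognizes. `tcrgmlp` trains a classifier that, given a CDR3
beta sequence (optionally paired with CDR3 alpha) and a 9-mer peptide,
predicts the probability that the receptor binds that peptide. Around the
classifier the package provides the full experimental machinery needed to
evaluate such a model honestly: substitution-matrix encoding, negative-pair
generation by cognate-target mispairing, sequence-identity-clustered
cross-validation partitions, a kernel similarity baseline, per-peptide AUC
reporting, and a rank-based cognate-target assignment experiment. Because the
public paired-chain data this family of models is trained on cannot be
redistributed, the package ships a synthetic repertoire generator that
reproduces the *structure* of such data, so every claim the package makes is
testable end to end on generated inputs.

## Encoding

Each amino acid is represented by its row of the BLOSUM50 substitution
matrix: the score for substituting it with each of the 20 canonical residues.
A sequence of length $l$ thus becomes an $l \times 20$ matrix. CDR3s are
right-padded with all-zero rows to 18 positions (the upper bound of the
length filter) and peptides occupy exactly 9 positions; a boolean mask
records which rows are real. The padding value and side are not dictated by
the encoding itself; zeros with right padding were chosen because zeros are
neutral under the network's linear projections and the mask carries all
length information. Non-canonical residues are rejected rather than imputed:
the data this mirrors is restricted to canonical sequences, and silent
imputation would hide upstream data bugs. The 20 feature columns are fixed in
alphabetical one-letter order; the bundled matrix resource
(`inst/extdata/blosum50.txt`) is a plain-text transcription of the published
table in the standard NCBI layout and is cross-checked against an independent
copy in the test suite.

## The network

Three input streams (CDR3 alpha, CDR3 beta, peptide; which exist depends on
`chain_mode`) each pass through their own stack of three identical gMLP
blocks operating at width $d_\mathrm{model} = 20$, the encoding width, so
encodings feed the blocks directly. A block computes

$$Z = \sigma(\mathrm{LN}(X)\,U), \qquad \tilde{Z} = s(Z), \qquad
Y = X + \tilde{Z}\,V,$$

where $\sigma$ is the exact GELU $x\,\Phi(x)$, $U$ and $V$ are channel
projections ($d_\mathrm{ffn} = 32$ by default), LN is layer normalization,
and $s$ is the spatial gating unit (SGU). The SGU splits $Z$ into two channel
halves $(z_1, z_2)$, layer-normalizes $z_2$, applies a learned $L \times L$
projection $W$ over the *token* axis plus a per-token bias $b$, and gates:
$z_1 \odot (W\,\mathrm{norm}(z_2) + b)$. At initialization every entry of $W$
is drawn uniformly from $[-0.01, 0.01]$ and $b$ is set to 1, so each block
starts out behaving like a plain position-wise FFN and learns cross-token
mixing gradually; the test suite asserts this identity exactly at $W = 0$ and
within an analytic bound at the sampled initialization. Padded token rows are
zeroed before the spatial projection so learned mixing can never read
padding; because all other block operations are position-wise and attention
masks padded keys, the model output is bitwise independent of padding
content.

The inner normalization of $z_2$ follows the stabilized SGU design and is
exposed as a config switch (`sgu_norm`, default on). Two design points the
architecture description leaves open were resolved as follows and are
ablatable via `model_config()`:

* **Fusion of the attention paths.** Full multi-head attention and windowed
  local attention both run *in parallel* on the same (peptide query,
  chain key/value) pair, and their outputs are concatenated channel-wise.
  Parallel concatenation is the least-assuming composition of the two paths.
* **Per-stream parameters.** The peptide stream does not share gMLP weights
  with the chain streams; sharing is an untested assumption and separate
  stacks are the safer default.

After the gMLP stacks, the alpha and beta token sequences are concatenated on
the token axis (alpha first; the order is fixed purely for reproducibility)
and serve as keys and values. The peptide features are the queries. The
global path is standard scaled dot-product attention (default a single head
of width 32, within the "size up to 128" regime this hybrid family uses).
The local path first passes the peptide features through a learned
$9 \times 9$ spatial map and layer normalization, then attends within
consecutive non-overlapping key windows of size 2, superimposes (sums) the
per-window outputs, and applies a final spatial map plus layer normalization.
Summing per-window softmax outputs is algebraically a single weighted sum
under block-normalized weights, which is how it is computed; a window whose
keys are all padding contributes nothing. The two attention outputs are
concatenated, mean-pooled over the 9 peptide query positions (mean pooling is
mask-aware and length-invariant), and passed through a dense/GELU head
(hidden sizes 32 and 16 by default) ending in a single sigmoid unit.

## Training

The loss is mean binary cross-entropy with probabilities clamped to
$[10^{-7}, 1 - 10^{-7}]$; the optimizer is Adam (learning rate $2 \times
10^{-3}$, batch size 256). An internal validation split holds out 10% of
TCRs — all records of a receptor stay on one side — and early stopping
monitors validation AUC with patience 2, returning the best epoch's
parameters. Forward and backward passes for every layer are implemented in
the package (batched over examples via BLAS, with small compiled kernels for
GELU and layer normalization); gradients are verified against central finite
differences, and each layer against an independently coded brute-force
implementation, in the test suite. Training is exactly reproducible given
the seed under single-threaded BLAS.

The untrained network scores essentially at chance (AUC about 0.5), because
random head weights applied to pooled features produce scores unrelated to
the label; this chance floor is asserted in the tests together with a
label-permuted training run.

## Data pipeline

**Length filters.** Records are kept when the CDR3 (beta, and alpha when
present) is 8-18 residues and the peptide exactly 9; every rejection carries
a machine-readable reason.

**Negatives by mispairing.** The peptide target list is extracted from the
positives *with multiplicity* (a peptide bound by many TCRs appears many
times), and each positive TCR is paired with `ratio` draws from that list
excluding its own cognate target(s). Negatives therefore have exactly the
TCR sequence distribution of the positives — the classifier must learn
TCR-peptide *compatibility*, not TCR realism. The default ratio is 5:1
(configurable; the source experiments do not state theirs). Duplicate
positives are collapsed first, keeping the first source tag.

**Leakage-safe partitions.** TCRs with more than 90% sequence identity must
not straddle a train/test boundary. Identity is computed from a global
Needleman-Wunsch alignment with BLOSUM50 scores and affine gaps (open 10,
extend 1), as identical positions over alignment length; for paired chains
the alpha and beta identities are averaged. Clustering is single-linkage:
connected components of the graph whose edges are pairs with identity
strictly above the threshold (the strictness choice is ours; presets 0.90,
0.92, 0.94, 0.95, 0.99, 1.00 mirror the usual sweeps). Two exact pruning
bounds make the all-pairs computation fast at repertoire scale without
approximation: identity can never exceed $\min(l_a, l_b)/\max(l_a, l_b)$,
and because identical aligned columns form a common subsequence, identity
$> t$ implies Levenshtein distance $< l_a + l_b - 2t\max(l_a, l_b)$.
Surviving pairs are aligned exactly in one vectorized call. Clusters are
assigned to five folds greedily (largest first onto the currently smallest
fold after a seeded shuffle), so fold sizes differ by at most the largest
cluster.

## The similarity baseline

The baseline scores a query TCR for a peptide as its best kernel similarity
to the known positive TCRs of that peptide (training folds only, so a query
never meets itself); for paired chains the alpha and beta similarities to
each database TCR are averaged first and the maximum of the averages is
taken (max-of-averages keeps the two chains of a database receptor
together). The kernel is an alignment-free k-mer string kernel with $k = 3$:
every k-mer pair is scored as the product over positions of the BLOSUM50
odds ratio $2^{s/2}$ (the log-odds matrix mapped out of log space), summed
over all pairs, and normalized by $K(a,b)/\sqrt{K(a,a)K(b,b)}$ so identical
sequences score exactly 1. The multiplicative form is essential: summing raw
log-odds scores over k-mer pairs yields *negative* self-similarities for
most random CDR3s (measured on uniform sequences), which would make the
normalization undefined; in odds space the kernel is strictly positive, and
this matches the positive substitution-kernel form of the published baseline
lineage this mirrors. No gap handling is included — k-mer kernels are
alignment-free by construction.

## Evaluation and the cognate-target experiment

AUC is the Mann-Whitney pair statistic (ties get half credit), equal to
rank-sum computation and asserted against exhaustive pair counting. Pooled
AUC is computed over concatenated held-out scores; per-fold and per-peptide
AUCs are also reported, with single-class peptides flagged undefined rather
than dropped.

For the target-assignment experiment, every held-out positive TCR is scored
against each of the three dominant peptides; each score is converted to a
percentile rank (fraction of a background score distribution strictly above
it, half credit for ties), and the lowest-rank peptide is the predicted
target. The background population is not pinned down by the source
description; we use the held-out fold's mispaired-negative scores for that
peptide, which avoids any leakage and requires no extra data. Rank ties are
broken lexicographically and flagged. Chance level with three candidates is
exactly 1/3 by construction.

## The synthetic generator

The generator emulates the statistical structure of the public repertoire
data this model family is trained on: three dominant 9-mer peptides with
strongly skewed abundance (defaults 0.6/0.3/0.1), CDR3 lengths 8-18 with a
peak near 14 and CASS/CAV-style anchor prefixes, and negatives produced by
the same cognate-swap procedure as the real pipeline. Binding signal is
planted as short peptide-specific motifs (3 residues by default) inserted at
a random admissible position and corrupted per position with probability
`mutation_rate`. The default scenario — 2,000 positives, ratio 5, mutation
rate 0.1, fixed seed — was chosen once as a realistic difficulty level:
separable but noisy, and small enough to cross-validate on a single CPU in a
few minutes. The split-signal variant plants motifs so that each single
chain leaves two peptides ambiguous while the (alpha, beta) combination is
decisive, reproducing the qualitative paired > single-chain ordering; its
default size (600 positives, ratio 1, mutation rate 0.05) keeps the
15 training runs of that comparison affordable.

What the generator deliberately does **not** model: V/J recombination
statistics, position-dependent residue usage, peptide sequence/motif
chemistry (motifs are arbitrary strings), shared motifs between peptides
(except in the split-signal variant), or batch effects between data sources.
Passing tests therefore demonstrate that the implementation learns planted
compatibility signal under realistic skew and leakage controls — not that
the architecture attains any particular accuracy on real repertoires.

## Numerical choices and degenerate inputs

* Layer-norm epsilon $10^{-5}$; probabilities clamped at $10^{-7}$ in the
  loss; attention scores stabilized by per-row (per-window) max subtraction.
* An example whose attention keys are all masked is refused
  ("degenerate attention") rather than silently zeroed; fully masked *local*
  windows, which are routine (padding tail), contribute zero.
* Empty sequences encode to all-zero matrices with all-false masks; the
  pipeline's length filter excludes them from modeling.
* A TCR whose cognate set covers every peptide cannot receive a negative and
  is skipped with a warning, counted in the generation report.
* Single-class folds, unknown peptides, and missing backgrounds raise errors
  naming the offending fold/peptide/candidate.
* AUC on a single-class input is an error, but a single-class *peptide* in
  per-peptide reporting is data (`NA`), not failure.

## Problem sizes used in the shipped checks

The bundled tests cross-validate the full default scenario (12,000 records)
once and reuse it for both the learnability and target-assignment claims;
the paired-versus-single comparison runs 15 scaled-down trainings (5 seeds,
3 chain modes, 1,200 records each); layer oracles run on 100 random small
instances per layer. These sizes were chosen so the whole suite documents
the package's claims at desk scale.

## Known limitations

* Only HLA-A*02:01-style single-allele data is modeled; the MHC allele is
  metadata, not a model input.
* The model scores only peptides seen in training; it does not generalize to
  unseen peptides, matching the scope of the architecture it reimplements.
* The aligner settings behind the identity threshold (BLOSUM50, open 10,
  extend 1) are pinned defaults, not a reconstruction of any particular
  BLASTP configuration.
* Training reproducibility is exact only under single-threaded BLAS.
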