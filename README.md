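# tcrgmlp

Predicting TCR–peptide binding with a hybrid gMLP network.

Which peptide–MHC complex a T cell recognizes is determined mostly by the
CDR3 loops of its receptor's α and β chains. `tcrgmlp` implements a
sequence-based binding classifier for HLA-A\*02:01-style 9-mer peptides plus
the complete evaluation machinery this problem needs, for immunoinformatics
researchers who want a transparent, fully testable R implementation:

* **Model** — per-stream stacks of three gMLP blocks
  (`Z = σ(LN(X)U)`, `Z̃ = s(Z)`, `Y = X + Z̃V`) whose Spatial Gating Unit
  splits channels in half and gates one half with a learned token-axis
  projection of the other (`z₁ ⊙ (W·norm(z₂) + b)`, initialized with
  `W ∈ [−0.01, 0.01]`, `b = 1` so blocks start as plain FFNs); peptide
  features then query the concatenated α/β features through parallel
  multi-head attention and window-2 local attention, followed by a
  dense/GELU head with a sigmoid output. Forward *and* backward passes are
  implemented in the package and verified against brute-force oracles and
  finite differences.
* **Encoding** — BLOSUM50 rows per residue (`l × 20` matrices), zero-padded
  with masks; the matrix ships as a plain-text NCBI-layout resource.
* **Data pipeline** — the 8–18 CDR3 / 9-mer length filters, negatives by
  mispairing TCRs with non-cognate peptides drawn from the positives'
  peptide multiset, and leakage-safe 5-fold partitions from single-linkage
  clustering at >90% global-alignment identity (BLOSUM50, affine gaps).
* **Baseline** — a normalized BLOSUM50 3-mer string kernel; a query scores
  the maximum similarity against the training folds' positive database
  (max-of-averages over α/β for paired chains).
* **Evaluation** — Mann-Whitney AUC (overall, per fold, per peptide),
  percentile ranks, and the cognate-target experiment: assign each held-out
  TCR the candidate peptide with the lowest percentile rank.
* **Synthetic repertoires** — a generator planting peptide-specific CDR3
  motifs under realistic abundance skew (0.6/0.3/0.1 over three dominant
  peptides), so every claim is testable without restricted data downloads.

## Worked example

Generate a small synthetic repertoire, build identity-clustered folds, and
cross-validate the model and the similarity baseline:

```r
library(tcrgmlp)

d    <- generate_dataset(generator_config(n_positives = 400,
                                          negative_ratio = 2, seed = 7))
recs <- make_folds(d$records, threshold = 0.9, k = 5, seed = 7)
rep  <- cross_validate(recs, model_config(),
                       train_hyper(epochs = 6, batch_size = 128, seed = 7))
rep
#> cross-validation over 5 folds, 1200 records (400 positive)
#>   pooled AUC 0.902 (folds: 0.931, 0.948, 0.813, 0.942, 0.860)
#>   per peptide: GILGFVFTL=0.925, GLCTLVAML=0.736, NLVPMVATV=0.897

base <- cross_validate_baseline(recs, paired = TRUE)
roc_auc(base$score, base$label)
#> [1] 0.937
```

The pooled AUC is the probability that a random held-out binding pair
outscores a random mispaired one; per-peptide AUCs show the rarest peptide
(GLCTLVAML, 10% abundance) is hardest, mirroring the few-shot behaviour of
the real task. At this small demo scale the alignment-free kernel baseline
is still competitive with the network; with the default scenario's 12,000
records the network pulls clearly ahead (pooled AUC ≈ 0.99 — the ordering
asserted in the test suite).

A thin command-line front end over the same functions lives at
`inst/cli/tcr-gmlp.R` (`simulate`, `folds`, `eval`, `baseline`,
`predict-target` subcommands).

## Documentation

The methods vignette (`vignettes/tcrgmlp-methods.Rmd`) describes the model,
its initialization and training, the leakage controls, the kernel baseline,
the rank-based target assignment, what the synthetic generator does and does
not emulate, and the package's numerical choices and limitations.
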