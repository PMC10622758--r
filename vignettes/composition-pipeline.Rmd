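---
title: "Composition-based allergen classification: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composition-based allergen classification: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allerfuse)
```

## The problem and the model

Allergenic proteins elicit IgE-mediated hypersensitivity; telling them
apart from innocuous proteins using only the amino-acid sequence is a
binary classification task. `allerfuse` follows the composition-fusion
approach: the sequence is summarised by residue-level count statistics at
three granularities, the statistics are concatenated, and a random forest
learns the class boundary in a reduced coordinate system.

For a sequence of length $L$ over the 20 standard residues:

* **AAC** — $f_i = A_i / L$, the frequency of residue type $i$
  (20 features). Invariant to any permutation of the sequence.
* **DPC** — $F_i = D_i / (L - 1)$, the frequency of ordered dipeptide $i$
  among the $L-1$ overlapping 2-mers (400 features). Sees local order.
* **CKSAAP** — for each gap $k \in \{1,2,3\}$, the frequency of each
  ordered residue pair occupying positions $(i, i+k+1)$ among the
  $N_k = L - k - 1$ such positions (400 features per gap, 1200 total).
  "$k$-spaced" means exactly $k$ intervening residues; gap 0 is excluded
  because it would duplicate DPC. Sequences exactly at the minimum length
  $k + 2$ are accepted ($N_k = 1$).

Every encoder row is a normalised frequency vector (rows sum to 1; each
per-gap CKSAAP block sums to 1), all columns follow the fixed alphabetical
residue order `A, C, D, ..., Y`, and feature names carry their encoder
prefix (`AAC:`, `DPC:`, `CKSAAP:k1:`) so the fused 1620-column matrix
remains auditable.

## Selection, shrinkage, classifier

Fused composition features are strongly redundant (AAC is a marginal of
DPC; CKSAAP blocks correlate across gaps), so the pipeline prunes before
fitting:

1. **PCC ranking.** Each feature is scored by its Pearson correlation with
   the 0/1 label — for a binary label this is the point-biserial
   correlation, so no special casing is needed. Features are ordered by
   $|r|$: ranking by the signed value would discard perfectly informative
   negatively-correlated features. The signed score is kept for reporting.
   Constant columns (score undefined) are assigned 0 with a warning. Ties
   break by original column index, keeping the order deterministic.
2. **Top-$n$ selection**, default $n = 200$. `ifs_scan()` generalises the
   fixed choice: it evaluates nested top-$n$ subsets by cross-validated
   accuracy and returns the argmax (ties to the smaller $n$). The scan
   takes the labelled matrix directly rather than a precomputed ranking,
   because the ranking must be re-fitted inside each training fold — a
   global ranking argument would either be ignored or leak.
3. **PCA**, default $q = 100$ components. Columns are centred by training
   means but *not* rescaled to unit variance: all features already share
   the $[0,1]$ frequency scale, and rescaling would inflate near-constant
   noise columns into principal directions. A `scale.` flag exists for
   data that violates this assumption. `fit_pca()` delegates to the QR/SVD
   path of `stats::prcomp`; the test suite checks its explained variances
   against a direct eigendecomposition of the covariance matrix.
4. **Random forest**, default 200 trees: bootstrap samples of the training
   size, $\sqrt{p}$ candidate features per split, Gini impurity, unlimited
   depth — standard forest defaults; only the tree count is treated as a
   tuned quantity (`tree_count_sweep()` reproduces the 100–500 sweep).
   Scores are averaged tree probabilities (soft voting), which gives
   smoother ROC curves than counting hard votes; calls use an inclusive
   threshold, `score >= 0.5`.

When defaults are insufficient, LR, RBF-SVM and KNN baselines share the
same score/call contract. The SVM defaults are `cost = 2^15` and
`gamma = 2^-16`; a printed value of $2^{16}$ for this configuration
circulates but is implausibly large for an RBF bandwidth on $[0,1]$
frequency features (the kernel matrix degenerates to the identity), so the
small value is the default and the large one remains reachable through
the `gamma` argument rather than being guessed silently.

## Evaluation protocol and leakage policy

`holdout_protocol()` makes a seeded stratified 4:1 split, cross-validates
on the training portion (stratified 5-fold), then fits the final pipeline
on the whole training portion and scores the untouched validation portion
once. Stratification is used even though plain "5-fold" would suffice,
because balanced folds stabilise Sn/Sp at these sample sizes.

Inside `cross_validate()` the *entire* transform stack — ranking,
selection, PCA — is re-fitted on each training fold by default. Fitting
transforms on the full data before splitting is a known source of
optimistic bias; because some published composition pipelines are
ambiguous on this point, the leakier variant is available explicitly as
`refit_per_fold = FALSE` for comparison, and the per-fold selected feature
subsets are exposed in the report (`$fold_features`) so the refitting is
verifiable by construction. The pooled report concatenates out-of-fold
scores (per-fold curves are also kept), which weights every sample equally
rather than averaging fold curves.

Metric conventions: zero-denominator metrics (precision with no positive
calls, MCC with an empty factor) return 0 with a warning instead of NaN,
keeping report tables numeric. ROC curves sweep distinct score values with
ties grouped, so the trapezoid AUC equals the Mann–Whitney concordance
probability with the 0.5 tie convention; AUPRC uses step-wise average
precision because trapezoid interpolation on PR points is optimistic.
Report tables round percentages to one decimal; the report objects retain
full precision.

## The synthetic generator: what it emulates and what it does not

Benchmarks of curated allergens require an external download, so the
package carries its own study conditions. `synthetic_spec()` defines an
i.i.d. residue model: negatives draw each residue from a Swiss-Prot-like
background composition; positives draw from the same vector with a chosen
residue subset multiplied by `1 + effect_size` and renormalised. Defaults
— 200 sequences per class, lengths uniform on 50–300, `effect_size = 1`
on residues A and C (doubling their frequency) — give a strong but not
saturated compositional signal: pooled 5-fold CV AUC is about 0.96 at
these settings, while `effect_size = 0` yields exchangeable classes and
chance-level AUC. An optional dipeptide motif channel overwrites
Poisson-many positions of positive sequences with a fixed motif, creating
pair-level signal that DPC/CKSAAP can see but AAC (by permutation
invariance) cannot — this is what the encoder-contrast tests exercise.

The i.i.d. model deliberately lacks everything else that makes real
protein data hard: domain structure, homology between train and test
sequences (real benchmarks need redundancy removal), length–class
correlations, and physicochemical constraints. Passing tests on synthetic
data therefore demonstrate that the machinery is correct and leakage-free,
not that the reported numbers transfer to any particular curated allergen
benchmark.

## Numerical and interface choices

* Problem sizes: the test suite and the acceptance script use 400-sequence
  datasets and 5 folds, which the pipeline processes in seconds while
  leaving the binomial noise on AUC around ±0.02.
* Non-standard residues (B, J, O, U, X, Z, gaps) are stripped by default
  with a warning — this preserves dataset size while keeping the encoder
  domain exact; a `"reject"` policy is available when silent edits are
  unacceptable. The choice is this package's own; curation practice
  varies.
* All stochastic steps (generation, folds, splits, forests) take explicit
  seeds; identical seeds reproduce datasets, models and reports bitwise at
  the serialised level.
* Model bundles embed a format version, the seed, hyperparameters and the
  full ordered feature contract; prediction refuses inputs whose feature
  names or order deviate, and loading refuses unknown bundle versions
  rather than risking silent misprediction.
* The functions, scripts and this vignette are the package's interface;
  `inst/cli/allerfuse.R` wires them into shell subcommands for users who
  prefer a command line.

## Known limitations

Only composition-level information is used — no physicochemical scales,
no evolutionary profiles, no structure. The PCC ranking is univariate and
linear, so purely interactive or non-linear marginal signals rank poorly.
The IFS scan refits one forest per grid point per fold and is the most
expensive operation in the package. Finally, synthetic validation bounds
what the tests can promise about real allergen data, as discussed above.
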