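---
title: "Methods: prioritizing disease-associated lncRNAs by knowledge transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prioritizing disease-associated lncRNAs by knowledge transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Problem and model

Risk genes for neurodevelopmental disorders are discovered almost
exclusively among protein-coding genes, where rare-variant burden tests
have power. lncRNAs lack that evidence channel. `lncprior` transfers
knowledge from the coding risk-gene set: classifiers learn to separate
known risk genes (positives) from genes with evidence of non-association
(negatives) using only features that are equally defined for lncRNAs —
developmental brain expression and primary transcript sequence — and then
score unlabeled lncRNAs with the trained models.

### Expression block

Expression values (RPKM) are transformed as $\log_2(\mathrm{RPKM}+1)$.
Each gene's profile $x_g \in \mathbb{R}^S$ across the $S$ brain samples is
compressed by a single-hidden-layer autoencoder,

$$z_g = \mathrm{ReLU}(x_g W_1 + b_1), \qquad
  \hat{x}_g = \mathrm{ReLU}(z_g W_2 + b_2),$$

trained to minimize mean squared reconstruction error
$\frac{1}{nS}\sum_g \lVert \hat{x}_g - x_g \rVert^2$ with RMSprop
(decay 0.9, $\epsilon = 10^{-8}$, learning rate $10^{-3}$) for 100 epochs
on shuffled mini-batches of 64. The optimizer and backpropagation are
implemented directly in base R matrix algebra; gradients are the analytic
derivatives of the loss through the two ReLU layers. The code $z_g$ is the
expression feature vector.

Two initialization choices matter on this data and are deliberate:

- **Decoder bias at the column means**, $b_2 = \overline{x}$, so training
  starts from the best constant reconstruction instead of from zero.
- **Dead-ReLU guard.** All inputs are non-negative, so a hidden unit whose
  initial pre-activation is negative at typical inputs receives no
  gradient and stays dead; with small code sizes it is easy for *every*
  unit to start dead, leaving an all-zero code forever. The encoder bias
  is therefore initialized as
  $b_1 = \max(0, -\overline{x} W_1) + 0.01$, which guarantees every code
  unit is active at the mean input.

The autoencoder is fit once on the full gene set (labeled and unlabeled)
rather than refit inside each cross-validation fold. This mirrors the
workflow of choosing a single encoding and is required anyway to encode
the unlabeled lncRNAs, but it is transductive: the encoder has seen the
(unlabeled) expression values of genes later used as CV test cases. Label
information never leaks — the autoencoder is unsupervised — but users
comparing absolute AUCs across studies should note the caveat.

### Sequence block

Transcripts are summarized by length-normalized k-mer frequencies for
$k \in \{3, 4\}$: $4^3 + 4^4 = 320$ features, each window count divided by
the full sequence length $L$ (not by the window count $L-k+1$; the two
normalizations differ by a factor $(L-k+1)/L$ and the package documents
its choice). Counting is done with `Biostrings::oligonucleotideFrequency`,
which skips windows containing ambiguous bases.

k-mers are ranked by random-forest impurity importance: 10 independent
forests (by default) are fit to the labeled genes with class-weighted
bootstrap, each fit's importances are normalized to sum to one, and the
normalized importances are averaged. The top $m = 25$ k-mers enter the
final feature set; `select_top_kmers()` can pick $m$ from a grid by
cross-validated AUC instead.

### Classifiers, class weights, evaluation

Logistic regression, an RBF support-vector machine, and a random forest
are trained on the concatenated (min-max scaled) features with class
weights $w_{\mathrm{neg}} = 1$,
$w_{\mathrm{pos}} = |\mathcal{N}| / |\mathcal{P}|$ — 2.6391 for the
604/1,594 split of the motivating study. Min-max scaling statistics are
fit on the training rows of each fold and applied to the held-out rows, so
held-out values can fall outside $[0,1]$; no test-fold information reaches
the fit.

Repeated stratified 10-fold cross-validation reports accuracy,
sensitivity, specificity, precision, and Matthews correlation at the 0.5
threshold plus ROC and PR AUC. The ROC curve sweeps all observed score
thresholds, moves tied scores simultaneously, and integrates by trapezoid —
making the AUC exactly the Mann–Whitney statistic with ties counted ½
(verified to $10^{-12}$ in the tests). PR AUC uses the step-wise
right-continuous precision; a constant scorer gets the class prevalence,
which is also the curve's random baseline.

### Hypothetical-locus validation

For each known risk gene $t$, the model is refit without $t$, and $t$ is
embedded in a window of its $N-1$ nearest protein-coding neighbors on the
chromosome. Its percentile rank is

$$\mathrm{rank}(t) = \frac{L}{N} \times 100,$$

where $L$ counts locus members with predicted probability **strictly
less** than $t$'s — ties do not credit the target, so the statistic is
conservative and, for a random ranker, has expectation
$\frac{N-1}{2N} \times 100$ (48.8 for $N = 41$), not exactly 50.

### Prioritization

Unlabeled lncRNAs with probability > 0.5 are called per model; candidates
are ranked by mean probability with the three-model consensus flagged.
Calls are annotated with (a) protein-coding risk genes whose expression
correlates at Pearson $r > 0.95$ and (b) genomic-locus relationships:
`same_locus` for a strand-matched interval overlap with a risk gene,
`antisense` for an opposite-strand overlap.

## Parameter defaults and rationale

| Parameter | Default | Rationale |
|---|---|---|
| `code_dim` | 16 (pipeline preset) | Scaled to the 60-sample synthetic preset; for real data with hundreds of samples, grid-select via `select_code_dimension()` (the motivating study used 48 for 524 samples). |
| `epochs`, `batch_size` | 100, 64 | Standard protocol; the loss trace is returned so convergence can be inspected. |
| `ks` | {3, 4} | 320 features — rich enough to carry motif signal, small enough for RF importance to be stable. |
| `top_m` | 25 | The grid optimum of the motivating study; configurable via `select_top_kmers()`. |
| `rf_repetitions` | 10 | Averaging stabilizes impurity importances; ranking is deterministic given the seed with lexicographic tie-breaks. |
| `folds`, `repetitions` | 10, 3 | 10-fold stratified CV; 3 repetitions keep test runtime small (raise to 50 for publication-grade error bars). |
| `N_list` | 41 | Loci of 41 genes fit within the synthetic chromosomes (50 genes each); with genome-scale annotation use 101/201/401. |
| `threshold` | 0.5 | Candidate call threshold. |
| `pcc_threshold` | 0.95 | Only near-perfect co-expression is reported as a partner. |

### Synthetic generator

The generator plants known signal so every stage has a ground-truth
oracle. Defaults: 150 positives / 396 negatives (preserving the ≈1:2.64
class ratio at reduced scale), 60 unlabeled lncRNAs of which
`n_unlabeled_pos = 10` carry the positive-class signal, 60 samples (30
"signal" columns), log2-scale baseline mean `mu_base = 3` with noise SD
0.5, expression effect +2.0 for positives in signal columns, five planted
k-mers at 5× background, and 50 genes per chromosome with a 10% antisense
fraction of lncRNAs nested inside positive genes. The `real_shape` preset
(604/1,594/524) reproduces the motivating study's dimensions.

## Caveats

- **Selection optimism.** Ranking k-mers by importance on the full labeled
  set and then cross-validating on the selected 25 biases AUC upward; on
  pure-noise data this alone lifts apparent AUC to ≈ 0.64. The null
  calibration in the acceptance suite therefore evaluates the classifiers
  on the unselected feature set, and any absolute AUC quoted after
  selection should be treated as optimistic unless selection is nested in
  the CV loop.
- **Transductive autoencoder** (see above): unsupervised, but fit on all
  genes including later test folds.
- **Strict tie handling** in the percentile rank makes the random-ranker
  expectation $\frac{N-1}{2N}\times 100$, slightly below 50.
- The expression simulator clips RPKM at zero
  ($\mathrm{RPKM} = \max(2^y - 1, 0)$), which introduces a small downward
  bias in recovering the planted log2 effect; the tests allow for it
  explicitly.
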