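---
title: "Modular neural networks over functional hierarchies: model, training and explanation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular neural networks over functional hierarchies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xmodnn)
```

## The model

`xmodnn` classifies samples from a gene-by-sample expression matrix with a
neural network whose wiring diagram *is* a functional gene hierarchy. The
hierarchy is a levelled DAG: genes at level D, pathways at level C, pathway
groups at level B, top categories at level A, and one output node O — the
layering used by KEGG-BRITE-style catalogues. Edges connect adjacent levels
only; multi-membership (a gene in several pathways, a pathway in several
groups) is allowed and preserved, with the module's output fanning out to
every parent.

Every C/B/A/O node is realised as a small module: three internal layers of
three neurons by default, tanh on the first two, identity on the last. The
module's first internal layer (the *module-input layer*) reads the
concatenation of its children's outputs — one scalar per gene child, the
three last-layer neurons per module child. Each module additionally carries
a linear classifier head that predicts the global class label from the
module's own last layer; heads feed nothing forward. Bias terms are
disabled on the module-input layer and on the heads (this keeps the
inter-module connections sparse-friendly and improves the quality of the
relevance propagation); the middle internal layer carries a bias, and the
identity-activated last layer is bias-free as well, since any offset there
would be absorbed by the head weights. All of this is configurable through
`module_spec()`.

Weights start from normalized-Xavier initialisation (uniform on
±sqrt(6/(fan_in+fan_out))); enabled biases start at zero; identical seeds
give bit-identical parameters.

## Weighted multi-loss progressive training

Each module's head yields a class-weighted cross-entropy loss
(`class_weights()` uses the balanced heuristic w_c = n/(K·n_c), so a 50/50
two-class problem reduces to unweighted cross-entropy). The training
objective at epoch *e* is

total(e) = Σ over active levels l of w_l · Σ over modules m at level l of
CE_w(m) + L1,

with default level weights C:1.3, B:1.2, A:1.1, O:1.0 and level inclusion
epochs C:1, B:2, A:4, O:6 (1-indexed). Modules whose level is not yet
included are *fully frozen*: they receive no gradient from any source — not
from their own heads, not from parents, not from the penalty — so their
parameters are bit-identical to initialisation until their inclusion epoch
(this is tested by exact comparison). The L1 penalty uses 0.1 on
module-input-layer weight blocks and 0.01 on every other weight block,
heads included; these multipliers are alternatives, not additive, and
biases are never penalised. Within a level, module losses are summed by
default; `layer_reduce = "mean"` divides by the module count instead, which
preserves the intended C-to-O priority when level sizes are very unequal.

The optimizer is Adam at learning rate 0.01 (mini-batch 32); plain SGD is
available. The optimizer itself is a free design choice — only the learning
rate is pinned down by the tuned hyperparameter set — so it is exposed in
`train_config()` rather than hidden. Training runs for a fixed
`max_epochs` (default 30) with no early stopping; afterwards
`select_best()` restores the epoch with the lowest validation loss, ties
going to the earliest epoch. The validation loss is always computed with
*all* levels active (plus the full L1 term), so values are comparable
across epochs of the progressive schedule; the per-epoch log also records
per-level training losses and the validation macro-F1 of the output head.

## Cross-validation

`run_crossval()` implements a stratified k-fold harness (k = 10 by
default). Within each class, samples are shuffled and dealt into chunks of
size ⌈n_c/k⌉ or ⌊n_c/k⌋, larger chunks to the lowest-index folds; per-class
fold counts therefore differ by at most one. For a 434/555 two-class cohort
this yields fold sizes of five 98s, one 99 and four 100s. Per split, one
fold is the test set, two seeded-random folds are the validation set, and
the remaining k−3 train; over the k splits every sample is predicted
exactly once. Note that the deterministic "remainders to lowest folds" rule
means extreme settings such as k = n do not produce a leave-one-out
partition — per-class singleton chunks stack on the first folds — which we
accept as the price of reproducing the documented fold-size multiset.

Per-gene mean centering is computed on the training folds only and applied
to validation and test folds (`center = "train_only"`), because global
centering leaks held-out information; `center = "global"` is available when
fidelity to a globally centered preprocessing matters. Centering is per
gene (per row): it removes the baseline expression level of each gene,
which is what inflates relevance absorption at the input layer.

Metrics: per-class precision and recall, macro-averaged F1, balanced
accuracy (mean per-class recall) and the Matthews correlation coefficient
(multiclass form, reducing to the textbook binary formula); summaries
report median/mean/sd/min/max across splits, plus pooled-test-set metrics.

## Relevance propagation and biomarkers

Explanations use the epsilon rule of layer-wise relevance propagation. For
a linear layer z_k = Σ_j a_j w_jk + b_k, upper relevance R_k is
redistributed as R_j = Σ_j a_j w_jk/(z_k + ε·sign(z_k))·R_k, with sign(0)
treated as +1; tanh activations pass relevance through unchanged.
Propagation is seeded with the raw (pre-softmax) output-head score of a
start class — by default each sample's predicted class — and runs along the
forward wiring only: the auxiliary heads of C/B/A modules are never on the
backward path. At fan-outs, relevance arriving from multiple parents is
summed. A module's scalar relevance is the sum over its last internal
layer; gene relevance is read at the input layer.

With ε = 0 and no biases the redistribution is conservative: the gene
relevances sum to the seeded score (checked to 1e-6 relative tolerance over
100 random networks). A positive ε absorbs relevance near zero
pre-activations; the default ε = 1e-6 is a pure numerical guard, and the
absorbed amount grows monotonically with ε. Bias relevance, where biases
exist, is absorbed rather than redistributed — the standard epsilon-rule
convention — which is why conservation tests use bias-free configurations.

Per sample, relevance is normalized within each hierarchy level (genes are
one level, C, B, A each one level) by the level's absolute sum, making
values comparable across cross-validation splits; normalization is applied
uniformly to all levels, the gene level included. Pooled over all test
predictions, `aggregate_global()` records per-node median/mean/sd (plus
per-class medians), and `threshold_biomarkers()` flags nodes whose median
strictly exceeds the level-wise mean + sd of all pooled (node, prediction)
values and is positive. The positivity guard matches the convention that
positive relevance carries the evidence *for* the predicted label. A
per-node variant (median_g > mean_g + sd_g) is available via
`threshold_mode`; the pooled-per-level rule is the default because the
threshold is then a single calibrated bar per level rather than 8000
gene-specific bars.

## The synthetic generator

`synthetic_spec()` describes a two-class study with known ground truth:
log-scale background expression i.i.d. Normal(0, σ²) (optionally AR(1)
correlated within pathways), and a set of planted genes shifted by +δσ in
the second class. Defaults — 200 genes, 20 pathways, 6 groups, 2
categories, 10 planted genes, δ = 3, σ = 1, 100 samples per class — model a
compact expression panel with about ten genes per pathway and a clearly
detectable but redundant signal. Class imbalance is supported via
`n_per_class` (e.g. 86/14 to emulate a skewed cohort).

What the generator does *not* emulate: probe-level artefacts, count
overdispersion, batch effects, or realistic gene-gene correlation beyond
the optional AR(1) block structure. Passing the recovery tests therefore
demonstrates that the machinery is correct and that the pipeline can
isolate planted signal from Gaussian noise — not that it will rank real
pathway biology the way a cohort study would.

Two properties anchor the end-to-end behaviour. With δ = 3σ the pipeline's
pooled balanced accuracy exceeds 0.95, all or nearly all flagged biomarkers
are planted genes, and at least one pathway containing planted genes ranks
in the top decile of pathway relevance. With δ = 0 the pooled MCC
concentrates near zero and the flagged set is (near-)empty. A subtlety
worth knowing: because the ten planted genes are mutually redundant, the L1
penalty lets each split's model lean on a different subset, so the flagged
set is typically a handful of planted genes rather than all ten — the same
behaviour that produces very small biomarker sets on real cohorts.

## Numerical and scale choices

* Problem sizes in the test suite are kept at the defaults above; the
  cross-validation experiments run 12 epochs (the progressive schedule
  completes at epoch 6, and validation-loss selection rarely chooses later
  epochs), and the separability check trains on ~90 samples for 15 epochs.
* Epoch indexing is 1-based: "B: 2" means level B joins in the second
  epoch, so the first epoch optimises level C alone.
* Degenerate inputs fail loudly: non-numeric expression cells, ragged rows,
  NaN/Inf inputs to the forward pass, non-finite losses, hierarchies
  without an output node or with skip-level edges are all errors naming the
  offending element.
* All randomness (initialisation, batch shuffling, fold assignment,
  validation-fold draws, the generator) is seeded; single-threaded runs are
  bit-reproducible, and per-split seeds are derived as base + 1000·split.
* Checkpoints serialise to JSON at 15 significant digits; forward passes
  of a reloaded network match to ~1e-12.

## Known limitations

* Two-class problems are the tested path; the code supports K ≥ 2 classes
  (softmax heads, multiclass MCC) but multiclass behaviour has only unit
  coverage.
* Only the epsilon LRP rule is implemented; αβ/γ variants are out of scope.
* The hierarchy must be a levelled five-layer DAG; deeper or ragged
  hierarchies (genes attached directly to B, variable depth) are rejected
  by validation rather than adapted to.
* Training is single-threaded CPU; the model sizes targeted here (hundreds
  of genes to a few thousand) train in seconds to minutes, but nothing is
  tuned for very large hierarchies.
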