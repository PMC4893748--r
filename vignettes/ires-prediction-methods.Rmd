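---
title: "Predicting internal ribosome entry sites from 5'UTR features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting internal ribosome entry sites from 5'UTR features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Most cellular mRNAs are translated cap-dependently. A minority of cellular
and many viral transcripts instead initiate translation at an internal
ribosome entry site (IRES), a structured RNA element in the 5'
untranslated region (UTR). Experimental demonstration of IRES activity is
laborious, and sequence or structure conservation is too weak — especially
among cellular IRESs — to support prediction by homology or structure
comparison. `irespred` implements a supervised alternative: represent each
candidate UTR by a fixed vector of sequence, structure and
ribosome-interaction features and classify it as IRES-positive (IP) or
IRES-negative (IN) with a support vector machine.

## The 35-feature representation

Each sequence is described by 35 ordered features (see `feature_names()`):

1. **Eight general features**: length in bases; the number of upstream AUG
   trinucleotides (every AUG in a 5'UTR is upstream of the main start, so
   all occurrences in all frames count, and windows containing N never
   match); the hairpin-, external-, internal-, multibranch- and total-loop
   counts of the predicted minimum-free-energy secondary structure; and the
   folding energy of that structure in kcal/mol.
2. **27 interaction features**: predicted probabilities that the UTR
   interacts with each protein of an ordered panel of 27 small-subunit
   (40S) ribosomal proteins (SSRPs). IRES function requires recruiting the
   40S subunit without the cap-binding machinery, which is why these
   partner-specific interaction probabilities carry signal that the general
   features alone do not.

The panel order is fixed and recorded inside every trained model; features
computed under different panels (or folding engines, below) are refused at
prediction time rather than silently mixed.

## Secondary structure and loop decomposition

Folding goes through a one-sequence-in, dot-bracket-plus-energy-out
adapter (`fold()`):

* `engine = "vienna"` calls an external Vienna-compatible MFE folder
  (`RNAfold` on the PATH by default). Engine defaults (37 °C, standard
  parameters) are used.
* `engine = "fallback"` is a built-in deterministic maximum-base-pairing
  dynamic program (Watson–Crick plus G·U wobble pairs, minimum hairpin
  size 3). Its traceback prefers leaving the 3' position unpaired and
  otherwise pairs it with the smallest admissible partner, making the
  structure a pure function of the sequence. It reports a pseudo-energy of
  −(number of pairs). It exists so that the complete pipeline, including
  tests, runs with no external binary; its features live on a different
  scale than true MFE energies, which is exactly why the engine tag is
  enforced end to end.

Loop counts use the canonical nested decomposition (`decompose_loops()`):
for each base pair, count the helices *b* and unpaired bases *u* directly
accessible inside it; *b* = 0 is a hairpin, *b* = 1 with *u* ≥ 1 an
internal loop (bulges included), *b* ≥ 2 a multibranch loop, and *b* = 1
with *u* = 0 a stacked pair, which is **not** counted as a loop — counting
stacks would make the internal-loop count track the pair count and destroy
its value as a complexity measure. The external loop is counted exactly
once whenever at least one pair exists; a pairless structure has zero
loops of every kind. "Total loops" is defined as the sum of the four
counts. The test suite checks this decomposition exhaustively against an
independent brute-force enumerator on every balanced dot-bracket string up
to length 12.

## The interaction surrogate

The original interaction probabilities came from a pre-trained external
predictor whose weights are not redistributable. This package therefore
implements the same sequence encodings with a locally trainable
classifier, plus a precomputed-table path (`read_interaction_table()`)
that reproduces exact upstream values when the user has them:

* proteins: conjoint-triad frequencies — residues mapped to 7
  physicochemical classes ({AGV}, {ILFP}, {YMTS}, {HNQW}, {RK}, {DE},
  {C}), all overlapping class-triples counted and normalized (343
  features). Windows containing residues outside the alphabet (X, Sec,
  B, Z) are dropped rather than erroring.
* RNA: overlapping 4-mer frequencies over {A,C,G,U}, N-containing windows
  dropped (256 features). Sense strand only; no reverse complementing.

The classifier over the concatenated 599-dimensional encoding is a seeded
random forest (the variant reported best for this encoding family), 200
trees by default. The bundled SSRP panel
(`inst/extdata/ssrp_panel_synthetic.fasta`) is synthetic — random
sequences with stable ids — because the real panel identities live in
supplementary material that is not redistributed here; it makes the
pipeline runnable, and users supply a FASTA of the 27 real human 40S
proteins for biological use.

## Scaling and the SVM

Features are scaled per feature to [−1, +1] by x' = 2(x − min)/(max −
min) − 1, with min/max learned **on the training rows only** and stored in
the model (the svm-scale convention; the alternative [0, 1] range differs
only by an affine map the SVM kernel absorbs). Test values extrapolate
linearly without clipping; constant features scale to 0.

The SVM follows the LibSVM parameter coding: type s (0 = C-SVC, 1 =
ν-SVC, 2 = one-class), kernel t (0 linear, 1 polynomial, 2 RBF, 3
sigmoid), degree d, gamma g, cost c (read as ν for s ≥ 1, hence
constrained to (0, 1)). A one-class configuration on a labeled two-class
set is rejected with a diagnostic unless explicitly allowed, in which case
training uses the IP rows only and classifies by the sign of the one-class
decision value — both behaviors are reachable, neither silently. The
decision threshold is 0 on the signed decision value, with the degenerate
value 0 called IP.

Hyperparameters are searched by a seeded global-best particle swarm over
(s, t, d, log2 g, log2 c) — swarm 20, 50 iterations, inertia 0.729,
acceleration constants 1.49445, discrete coordinates snapped to their
candidate sets — with stratified k-fold cross-validation accuracy (k = 10
by default) as the objective; a deterministic grid search is available as
the exhaustive fallback. Ties break to the first configuration found.
Cross-validation folds are assigned per class on id-sorted records from a
seeded permutation, so the reported accuracy is invariant to row order;
when k exceeds a class size the empty folds are skipped and the mean is
over non-empty folds.

## Evaluation protocol

`run_protocol()` mirrors the original model-building strategy: five
independent seeded stratified splits, 50% of each class to training (odd
class counts give training the extra record); per split, scaling is
fitted on the training rows, the hyperparameter search runs on the
training rows, and the trained model is evaluated on the held-out rows.
Performance is reported as accuracy, sensitivity, specificity, precision
(all percent) and the Matthews correlation coefficient, computed from
TP/TN/FP/FN. A measure with a zero denominator is reported as NA with a
recorded reason, never as 0 — silent zeros would corrupt model selection.
The final model is selected by test accuracy, ties broken by higher MCC
and then lower split index (the original description says only "optimum
performance"; this rule makes the choice deterministic). Each split draws
its own sub-seed (seed + k − 1), so splits are independent but the whole
protocol replays byte-identically from one seed.

## Synthetic data: what it emulates and what it does not

The generators exist so every stage is testable without downloads. They
encode the *direction* of the contrasts the method exploits — IP UTRs
longer (150–600 vs 50–300 bases), AUG-enriched (1.2 vs 0.3 expected AUGs
per 100 bases), GC-richer (0.55 vs 0.45) and seeded with GC-rich stem-loop
insertion blocks (1.0 vs 0.1 per 100 bases) so they fold into more complex,
lower-energy structures — at class sizes (189 + 189) matching the curated
corpus the method was developed on. The magnitudes are the package's own
choices: real IRESs have no usable sequence or structure conservation, and
no attempt is made to simulate actual IRES motifs. Passing tests on this
material demonstrates that the pipeline recovers a learnable signal of the
assumed form; it says nothing about accuracy on real UTRs, which depends
on the curated training data and real interaction probabilities. The
interaction-pair generator plants a 4-mer RNA motif and a single-class
protein word whose conjunction defines the positive class, guaranteeing
separability in the encoding space; negatives carry at most one of the two
signals.

## Numerical and degenerate-input choices

* Ambiguity codes (R, Y, ...) normalize to N rather than erroring,
  mirroring how folding engines treat unknown bases; N never pairs, never
  matches AUG, and drops from k-mer windows.
* The 15–7500 base bounds and 10-sequence batch limit reproduce the
  published service's input contract; the batch limit is enforced only by
  the strict `predict` path because it is a per-request resource policy,
  not part of the method.
* Encoding of a sequence with no countable window (all-N) is the zero
  vector, not an error.
* Model files carry a format version; files from a newer format fail to
  load cleanly.

## Problem sizes used in the tests and acceptance script

The suite exercises the pipeline at deliberately small scale: 16 synthetic
UTRs of 40–160 bases for feature-level checks, 220 interaction pairs for
the surrogate, exhaustive structure checks to length 12, and n = 400
feature-table classification runs. The acceptance script
(`scripts/acceptance.R`) runs the surrogate at 500 pairs and the full
5-split protocol on the default 189 + 189 synthetic corpus with a
6-particle, 6-iteration swarm. These sizes are the package's chosen
trade-off between statistical resolution and quick, deterministic runs.

## Known limitations

* The interaction surrogate reproduces the published feature *definitions*
  but not the original predictor's trained weights; absolute probability
  values differ from the original service unless precomputed tables are
  supplied.
* The bundled SSRP panel is synthetic; biological predictions require the
  real 27-protein FASTA.
* The fallback engine maximizes pair count, not free energy; its features
  are internally consistent but not thermodynamic.
* Only nested structures are considered (no pseudoknots), and folding uses
  default engine parameters.
* Published performance values (e.g. 75.51% blind-test accuracy) depend on
  the original curated sequence sets and original interaction
  probabilities and are not reproduced by the synthetic pipeline.
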