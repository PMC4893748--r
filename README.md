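# irespred

Prediction of internal ribosome entry sites (IRES) in 5' untranslated
regions.

Some viral and cellular mRNAs initiate translation cap-independently
through an IRES — a structured RNA element in the 5'UTR. Because IRESs,
cellular ones in particular, lack usable sequence or structure
conservation, homology- and structure-comparison approaches fail on them.
`irespred` takes the supervised route: every candidate sequence is mapped
to an ordered vector of 35 features and classified as IRES-positive (IP)
or IRES-negative (IN) by a support vector machine.

The 35 features are

* **8 general properties** — length; number of upstream AUGs; counts of
  hairpin, external, internal, multibranch and total loops in the
  predicted minimum-free-energy secondary structure; and its folding
  energy ΔG (kcal/mol);
* **27 interaction probabilities** P(UTR binds SSRP_k) against an ordered
  panel of 27 small-subunit (40S) ribosomal proteins, predicted from
  conjoint-triad (343-dim) protein and 4-mer (256-dim) RNA sequence
  encodings by a trainable classifier, or taken from precomputed tables.

Features are scaled per feature to [−1, +1] with training-set min/max,
and the SVM (LibSVM parameter coding: type *s*, kernel *t*, degree *d*,
gamma *g*, cost *c*) is tuned by seeded particle-swarm or grid search
under stratified 10-fold cross-validation. Model evaluation follows a
5-fold repeated stratified 50/50 split/train/test protocol reporting

    Acc = (TP+TN)/(TP+TN+FP+FN)      Sn = TP/(TP+FN)     Sp = TN/(TN+FP)
    Pr  = TP/(TP+FP)                 MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN))

A seeded synthetic-data module generates labeled UTR corpora,
motif-linked RNA–protein interaction pairs and direct feature tables, so
the complete pipeline runs and is tested without any external downloads.

This is a research re-implementation intended for method study and for
retraining on user-supplied curated data; it does not ship the original
curated training corpus or the original interaction predictor's weights.

## Worked example

```r
library(irespred)

# interaction surrogate trained on synthetic motif-linked pairs
pairs <- generate_interaction_pairs(300, seed = 7)
rpi   <- train_interaction_model(pairs, seed = 7)

# a small labeled synthetic UTR corpus and its 35-feature matrix
utrs  <- generate_labeled_utrs(synthetic_spec(n_pos = 40, n_neg = 40,
                                              len_range_pos = c(100, 300),
                                              len_range_neg = c(50, 200),
                                              seed = 11))
panel <- load_ssrp_panel()           # bundled synthetic 27-protein panel
X <- extract_feature_matrix(utrs, panel, rpi, engine = "fallback")
round(X[1, 1:8], 2)
#>         length         n_uaug      n_hairpin     n_external     n_internal
#>            133              4              4              1             11
#>        n_multi        n_total folding_energy
#>              3             19            -52

# the 5-split train/evaluate protocol with a small grid search
res <- run_protocol(utrs, panel, rpi,
                    spec = search_spec(strategy = "grid", t_values = c(0L, 2L),
                                       d_values = 1L, grid_points = 3,
                                       k = 5, seed = 11),
                    n_splits = 5, seed = 11, features = X)
res
#> Split/train/evaluate protocol (5 splits)
#>  Model s t d        g         c   CV  Acc Sn Sp    Pr    MCC
#>      1 0 0 1 0.003906   2.82843 72.5 70.0 80 60 66.67 0.4082
#>      2 0 0 1 0.003906   2.82843 80.0 67.5 50 85 76.92 0.3736
#>      3 0 0 1 0.003906 256.00000 70.0 70.0 65 75 72.22 0.4020
#>      4 0 0 1 0.003906   0.03125 70.0 67.5 75 60 65.22 0.3540
#>      5 0 2 1 0.176777   0.03125 70.0 77.5 90 65 72.00 0.5680
#> Selected model: split 5
```

Each report row is one stratified 50/50 split: the selected LibSVM-style
parameters, the 5-fold cross-validation accuracy on the training half,
and held-out accuracy, sensitivity, specificity, precision (percent) and
MCC on the test half. The selected model (best test accuracy, MCC
tie-break) can be saved with `save_model()` and applied with `predict()`.

Structure features come from the folding layer directly if wanted:

```r
st <- fold("GGGGCAAAAGCCCC", engine = "fallback")
st
#> GGGGCAAAAGCCCC
#> (((((....))))) (-5.00)  [fallback-maxpair]
decompose_loops(st$db)
#>  hairpin external internal    multi    total
#>        1        1        0        0        2
```

## Command line

A thin CLI over the same functions mirrors the published server's process
flow (validate batch of ≤ 10 sequences of 15–7500 bases → compute 35
features → classify IP/IN), plus training, evaluation and simulation
subcommands:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","irespred.R",package="irespred"))')" \
    simulate --out-dir fixtures --n-pos 40 --n-neg 40 --seed 11
# ... train --fasta fixtures/synthetic_utrs.fasta --labels fixtures/synthetic_labels.tsv --out model.rds
# ... predict --fasta query.fasta --model model.rds --out predictions.tsv
```

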