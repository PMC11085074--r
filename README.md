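# grnhist

Genome-scale inference of transcription-factor (TF) regulatory networks
from the **joint expression histogram** of gene pairs, combining bulk
RNA-Seq (expression diversity across samples or accessions) with
single-cell RNA-Seq (diversity across cells), for systems biologists who
want supervised TF–target prediction without hand-crafted co-expression
statistics.

## The method

For a candidate pair (TF *a*, gene *b*), the paired expression values
across all samples are binned into a 32 × 32 2D histogram (TF on the
first axis); the bulk and single-cell histograms are stacked into a
64 × 32 image. A convolutional network — six 3 × 3 convolutional layers
with 2 × 2 max pooling after layers 2, 4 and 6, a flatten, two dense
layers (128/64) and a sigmoid output — maps the image to a score
*s* ∈ [0, 1], trained with binary cross-entropy on a gold standard of
labeled pairs (1 = *a* regulates *b*, 0 = no interaction). Scanning all
TF × candidate pairs and keeping the top fraction (default 10%, with the
implied score cutoff reported) or all scores > 0.5 yields a directed
network. The package also ships:

* a paired bulk (log-normal) + single-cell (negative binomial with
  Bernoulli dropout) simulator with planted TF→target structure, so the
  whole pipeline is testable without any accession downloads;
* permutation validation against experimental reference networks
  (degree-preserving null: expected overlap, fold enrichment
  = observed/expected, empirical p over 10,000 permutations);
* per-TF hypergeometric target-set overlap with Benjamini–Hochberg
  adjustment;
* GO-based TF function inference (hypergeometric enrichment of predicted
  targets, root-term exclusion, recovery rates of known annotations, and
  novel-function candidates).

Classification metrics follow the standard confusion-count definitions:
TPR = TP/(TP+FN), FPR = FP/(FP+TN), precision = TP/(TP+FP),
recall = TPR, F1 = 2·precision·recall/(precision+recall), and AUROC via
the Mann–Whitney rank formulation (ties counted ½).

The CNN engine is implemented inside the package (im2col convolutions on
BLAS, explicit backpropagation, Adam) and is fully deterministic under a
single integer seed. See `vignettes/joint-histogram-grn.Rmd` for the
modeling choices and their rationale.

## Worked example

Simulate the default study conditions (40 TFs × 5 targets + 200 decoys;
200 bulk samples, 500 cells; 400 labeled pairs), train on 70%, and
evaluate on the held-out 30%:

```r
library(grnhist)

sim   <- simulate_paired_dataset(simulation_config(seed = 1))
al    <- align_gene_universe(log_transform(sim$bulk), log_transform(sim$sc))
split <- split_train_test(sim$pairs, 0.7, seed = 11)

hc <- histogram_config(bins = 32)                    # stacked 64 x 32 images
tr <- build_image_corpus(split$train, al$bulk, al$sc, hc)
te <- build_image_corpus(split$test,  al$bulk, al$sc, hc)

model <- train_model(build_model(model_config(max_epochs = 10,
                                              early_stop_patience = 3,
                                              seed = 5)), tr)
scores <- predict_scores(model, te)
auroc(scores, te$labels)
compute_metrics(confusion_at_threshold(scores, te$labels, 0.5))
```

Output from this exact run:

```
epoch   1  loss 2.4592  val_auroc 1.0000
epoch   2  loss 0.1944  val_auroc 1.0000
epoch   3  loss 0.0036  val_auroc 1.0000
epoch   4  loss 0.0002  val_auroc 1.0000
[1] 1
  tpr  fpr precision recall        f1
1   1 0.05  0.952381      1 0.9756098
```

Held-out AUROC is 1 and F1 at the default 0.5 cutoff is 0.98: the
planted regulation (log-scale slope 2 shared by both modalities) is
deliberately strong, so this run demonstrates the machinery, not
real-data difficulty. Thresholding a scan and validating it against the
planted network:

```r
tfs   <- sprintf("TF%03d", 1:10)
truth <- sim$pairs[sim$pairs$label == 1 & sim$pairs$tf_id %in% tfs, ]
cands <- c(unique(truth$target_id), grep("^DC", al$shared_genes, value = TRUE)[1:100])
edges <- scan_all_pairs(model, tfs, cands, al$bulk, al$sc, hc)
top   <- threshold_top_fraction(edges, 0.10)
perm  <- permutation_expected_overlap(top$edges,
          reference_network(truth[, c("tf_id", "target_id")]),
          cands, n_permutations = 10000, seed = 2)
perm
```

```
overlap 50 (expected 5.0, range 0-14), fold enrichment 9.94, p < 0.0001 (10000 permutations)
```

All 50 planted edges of the scanned TFs land in the top decile of the
1500 scored pairs; a degree-preserving random network would share only
5 edges on average — a 10-fold enrichment never reached in 10,000
permutations.

The same pipeline is available from the shell via the thin CLI at
`inst/cli/grnhist` (subcommands `simulate`, `train`, `evaluate`, `cv`,
`scan`, `threshold`, `validate`, `annotate`; YAML config files with
flag-over-file precedence; every run writes a JSON manifest).

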