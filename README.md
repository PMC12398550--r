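# oligomatch

**Cell-identity transfer, species demultiplexing and myelin morphometry for
stem-cell-derived oligodendroglia.**

Human stem-cell-derived oligodendrocyte progenitors and oligodendrocytes —
grown in monolayer, in organoids, or transplanted into myelin-deficient
mouse brain as chimeras — are only useful as models of the adult human brain
if they actually resemble adult oligodendroglia. `oligomatch` is an R
toolkit for making that judgement quantitatively and for measuring a
treatment effect on top of it. It is aimed at computational biologists
working with single-cell RNA-seq of in vitro or xenograft oligodendroglia
together with electron-microscopy and in situ hybridisation readouts.

## What it implements

**Binarized-expression ensemble label transfer.** The core method trains an
ensemble of small neural networks to carry cell-type labels from a reference
atlas (source) to a new dataset (target). The feature space is the union of
the variable genes of both datasets, and every gene *g* in cell *c* is
encoded as a detection indicator

> x₍cg₎ = 1 if UMI count > 0, else 0,

which is robust to depth and batch shifts between domains. Each network is a
multilayer perceptron F → 64 → 32 → K (ReLU hidden layers with L1 penalty
λ = 0.001 on their weights, softmax output over the K source labels),
trained with RMSprop on cross-entropy over class-balanced minibatches
(16 examples per class per step) under a label-stratified k-fold split
(k = 5 or 3); target cells are labelled by plurality vote across the k
members, with softmax-probability tie-breaking. Performance is reported as
balanced accuracy (mean per-class recall) plus macro precision/recall.

**Species demultiplexing** of chimera count matrices: each cell is allocated
to human or mouse when at least 70% of its species-assignable signal maps to
that genome (inclusive boundary), otherwise held out as ambiguous, and the
matrix is split per species.

**Cosine-similarity cluster matching**: per-cluster mean expression profiles
over the classifier's feature space, compared across datasets by
S(i,j) = aᵢ·bⱼ / (‖aᵢ‖‖bⱼ‖), plus per-cluster compositional tests between
conditions.

**Hurdle differential expression** (the MAST model class): a logistic model
of detection and a Gaussian model of expression among detected cells, with
the group likelihood-ratio statistics summed and referred to a chi-square;
marker screening at log2FC > 0.25, detection ≥ 20% in / < 60% out;
condition contrasts thresholded at |log2FC| ≥ 0.5 and BH-adjusted p < 0.05.

**Morphometry**: g-ratio = √(axon area / (axon+myelin) area) under
circularity, strict exclusion of axons below 0.4 μm diameter,
myelinated-axon percentages and mitochondrial area fractions summarised per
animal, RNAscope composite score = (fraction OLIG2⁺ cells) × (mean puncta),
and normality-gated t / Mann-Whitney group comparisons.

A synthetic-data module generates every pipeline input with known ground
truth (negative-binomial counts with logistic dropout, log-normal domain
shift, species mixtures with contamination, planted DE genes, axon geometry
with known g-ratios), so the whole pipeline is testable end to end. See the
methods vignette (`vignettes/oligomatch-methods.Rmd`) for the models,
assumptions and parameter choices.

## Worked example

Simulate a labelled 8-class reference atlas and a domain-shifted unlabelled
target, then transfer labels with the binarized ensemble:

```r
library(oligomatch)

cfg <- simulation_config(n_classes = 8, n_genes = 500, cells_per_class = 200,
                         domain_shift_sd = 0.3, seed = 1)
ref <- simulate_reference(cfg)
tgt <- simulate_target(cfg, ref$truth)

nm_src <- normalize_counts(filter_genes(ref$counts, 10))
nm_tgt <- normalize_counts(filter_genes(tgt$counts, 10))
fs <- build_feature_space(select_variable_genes(nm_src, 300),
                          select_variable_genes(nm_tgt, 300))
cat("feature space size:", length(fs), "\n")
#> feature space size: 398

ens <- train_ensemble(binarize(ref$counts, fs), ref$truth$cells$label,
                      ann_config(), training_config(n_folds = 5, epochs = 100,
                                                    steps_per_epoch = 64,
                                                    seed = 1), fs = fs)
round(ens$mean_validation, 3)
#> balanced_accuracy   macro_precision      macro_recall
#>             0.993             0.993             0.993

pred <- ensemble_predict(ens, binarize(tgt$counts, fs))
ev <- evaluate_transfer(pred$table$label, tgt$truth$cells$label, ens$levels)
cat("target balanced accuracy:", round(ev$balanced_accuracy, 3), "\n")
#> target balanced accuracy: 0.979

head(pred$table, 3)
#>     barcode    label mean_max_p tie_broken
#> 1 tgt_00001 class_01  0.9890738      FALSE
#> 2 tgt_00002 class_01  0.9998800      FALSE
#> 3 tgt_00003 class_01  0.9999986      FALSE
```

The cross-validated source accuracy (0.993) says the atlas classes are
learnable from detection patterns alone; the target balanced accuracy
(0.979 against the withheld ground truth) says the transfer survives the
simulated batch shift. `mean_max_p` is the ensemble-mean softmax probability
of the winning label — low values mark cells whose identity the ensemble is
unsure about.

The same workflow runs end to end from a shell:

```sh
Rscript inst/cli/oligomatch.R run-all --seed 1 --out-dir results/run1
```

which writes count matrices, species calls, cluster labels, predictions,
similarity matrices, DE tables and morphometry summaries under
`results/run1/`.

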