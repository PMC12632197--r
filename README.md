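# scspot

Spatial transcriptomics measures a multi-gene expression profile at each
barcoded spot of a tissue section, paired with the H&E image around that
spot. `scspot` predicts those spot-level profiles directly from the image
patches, so that archived H&E slides — which vastly outnumber sequenced
sections — can be turned into approximate spatial expression maps.

The core idea is a biologically informed prior. A nucleus segmenter
counts the five coarse cell classes (neoplastic, inflammatory,
connective, non-neoplastic epithelial, dead) in each 224×224 patch. With
count fractions *π<sub>i</sub>* over the non-dead classes and a canonical
log-expression vector *Ref<sub>i</sub>* per class built from a labelled
single-cell reference of the same tumour type, each spot gets an
**initial expression**

> Expr = Σ<sub>i</sub> π<sub>i</sub> · Ref<sub>i</sub>,

which conditions a prompt-style network: an expression encoder embeds the
prior into one token, an attention-augmented CNN encodes the patch into
spatial tokens (49 tokens of width 512 for the full-scale 34-layer
residual backbone), and a two-way cross-attention decoder fuses the two
streams over two rounds before a linear head emits the per-gene
prediction. Training is Adam on mean-squared error against
library-size-normalized, log1p-transformed counts; evaluation is
leave-one-section-out per-gene Pearson correlation (PCC) with paired
Wilcoxon model comparisons and BH-adjusted positive-correlation gene
ranking.

The package contains the complete pipeline — preprocessing, reference
construction, prior composition, the model with its ablation variants
(random prior, perturbed cell ratios, plain CNN, concatenation decoder,
three decoder rounds, zeroed cross-attention gates, scrambled
keys/values), training/evaluation, robustness noise injections — plus a
self-contained synthetic study generator with nucleus-rendered patches
and known ground truth, so everything is testable offline. The neural
engine (attention, convolution, Adam, full backpropagation) is built into
the package with Rcpp/RcppArmadillo kernels; no deep-learning runtime is
required.

## A worked example

Simulate a small study (3 sections × 200 spots, 60 genes, 64-px patches),
train the model with leave-one-section-out cross-validation, and compare
it with the random-prior ablation:

```r
library(scspot)

study <- generate_study(sim_config(patch_size = 64, seed = 101))
ds <- study$dataset
ds
#> <spot_dataset> 600 spots, 3 sections, 60 genes, 64px patches

cfg <- small_model_config(n_genes = length(ds$panel), seed = 101)
fit <- run_loso(ds, cfg, desk_train_config(seed = 101))
tidy(fit)
#> # A tibble: 3 × 4
#>   section_id mean_pcc median_pcc n_undefined
#>   <chr>         <dbl>      <dbl>       <int>
#> 1 section01     0.595      0.615           0
#> 2 section02     0.608      0.676           0
#> 3 section03     0.610      0.657           0

cfg_rnd <- small_model_config(n_genes = length(ds$panel),
                              variant = "random_ie", seed = 101)
fit_rnd <- run_loso(ds, cfg_rnd, desk_train_config(seed = 101))
glance(fit_rnd)$mean_pcc
#> [1] 0.111
```

Held-out mean PCC around 0.6 for the full model versus about 0.1 when the
single-cell prior is replaced by noise: on this synthetic study most of
the predictable signal enters through the prior, and the image adds the
cellularity-linked remainder. `autoplot()` methods plot loss curves,
per-gene PCC histograms and per-section bars; `geneset_spatial_map()` and
`pseudo_bulk()` aggregate predictions for spatial maps and bulk
comparisons.

A thin command-line front end (`exec/scspot`) exposes the same pipeline
as `simulate`, `preprocess`, `build-reference`, `build-ie`, `train` and
`evaluate` subcommands over TSV/matrix-market/PNG files.

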