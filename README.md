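# mlsom — multi-layer SOM transcriptome portrayal for drug repositioning

`mlsom` asks a concrete question of expression data: *does this drug undo,
at the level of co-regulated gene modules, what this disease does?*  It is
aimed at computational biologists who have several already-normalized
case–control transcriptome studies — a drug-treatment study (treated vs.
baseline/placebo) and one or more disease studies (disease vs. healthy) —
and want a transcriptome-wide, module-level comparison rather than a
signature-overlap score.  The approach is designed with biologics in mind,
where structure-based repositioning is not an option.

## The method

Each study is one **layer**, a genes × samples log2 matrix with a
target/reference assignment per sample.  All layers are trained jointly:

1. **Preprocess** — quantile-normalize each layer independently, center
   every gene over *all* samples of *all* layers (the Δe scale), and
   harmonize the layers so each contributes equally to the training
   metric.
2. **Joint SOM** — genes are objects, their Δe profiles across the
   concatenated samples are features.  Batch Kohonen training on a
   K × K grid (45 × 45 in production) clusters co-expressed genes into
   prototype vectors ("metagenes").  Because the gene → metagene map is
   shared, every layer is portrayed in the same coordinate system.
3. **Spots** — the overexpression summary map (pixelwise max over group
   portraits) is thresholded at its 95th percentile; connected components
   become labelled spots, the units of all downstream analysis.
4. **Differential spot calling** — per layer, each spot receives a
   presence/absence vote (group-mean difference beyond ±1 SD of the
   layer's metagene expression) and a t-test vote (Welch *t* on
   per-sample spot means, *p* < 0.05 and linear fold change > 1.5),
   combined by a conservative AND into the spot-perturbation matrix.
5. **Verdict** — a drug is a repositioning **candidate** for a disease
   iff some spot is antagonistically regulated: up in the disease and
   down under the drug (or vice versa).

Gene-set Z scores (GSZ) per sample, Fisher exact spot annotation with BH
FDR, and Pathway Signal Flow (PSF, fold-change propagation through signed
pathway topologies) provide the functional context.  The methods vignette
(`vignettes/mlsom-methods.Rmd`) documents every numerical choice.

## Worked example

A synthetic four-layer study: two diseases share an upregulated 100-gene
module, a third disease does not, and the drug layer reverses it.

```r
library(mlsom)
sim   <- simulate_repositioning_study(seed = 1)
joint <- preprocess_dataset(sim$dataset, quiet = TRUE)
model <- train_som(joint, ml_config(grid_size = 20))
model
#> SOMModel: 20 x 20 metagenes, 2000 genes, 80 samples over 4 layer(s); final QE 3.103

spots <- segment_spots(group_portraits(model), model)
spots
#> SpotSet: 2 spot(s) on a 20 x 20 grid (connectivity 8)
#>   A: 19 units, 100 genes
#>   B: 1 units, 2 genes

pm <- perturbation_matrix(spots, model, enumerate_contrasts(model),
                          ml_config(grid_size = 20))
subset(as.data.frame(pm), direction != "none")[,
       c("spot", "contrast", "direction", "p_value", "linear_fc")]
#>  spot                     contrast direction  p_value linear_fc
#>     A disease1:target_vs_reference        up 0.000073     1.811
#>     A disease2:target_vs_reference        up 0.000181     1.793
#>     A     drug:target_vs_reference      down 0.000107     0.563
```

Spot A is exactly the planted module (100/100 genes, one connected
19-unit patch): upregulated in both diseases that carry it
(linear fold change ≈ 1.8), reversed by the drug (≈ 0.56 ≈ 1/1.8), and
silent everywhere else.  The verdicts follow:

```r
repositioning_call(pm, "drug:target_vs_reference",
                   "disease1:target_vs_reference")
#> Repositioning verdict: candidate
#>   drug:    drug:target_vs_reference
#>   disease: disease1:target_vs_reference
#>   antagonistic spot(s):
#>     A: disease up, drug down

repositioning_call(pm, "drug:target_vs_reference",
                   "disease3:target_vs_reference")
#> Repositioning verdict: not_supported
#>   drug:    drug:target_vs_reference
#>   disease: disease3:target_vs_reference
```

The same analysis runs from the shell against TSV matrices, a sample
sheet and a YAML config (`exec/mlsom run --config study.yaml --outdir
out/`), writing portraits, spot tables, the perturbation matrix,
enrichment/GSZ/PSF tables, verdict JSON and a run manifest;
`exec/mlsom simulate` writes a synthetic study in exactly those input
formats.

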