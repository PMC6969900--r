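---
title: "Multi-layer SOM portrayal for drug repositioning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-layer SOM portrayal for drug repositioning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlsom)
```

## The method in one page

`mlsom` implements transcriptome portrayal with multi-layer self-organizing
maps for signature-reversal drug repositioning.  The inputs are several
case--control expression studies ("layers"): at least one drug-treatment
layer (treated vs. baseline/placebo) and one or more disease layers
(disease vs. healthy).  All layers are projected into **one** shared SOM
space:

1. **Preprocessing** — each layer is quantile-normalized independently,
   every gene is centered to zero mean over *all* samples of *all* layers
   (the $\Delta e$ scale), and the layers are harmonized so that no layer
   dominates the Euclidean distances used in training.
2. **Joint SOM training** — genes are the objects, their $\Delta e$
   profiles across the concatenated samples are the features.  Batch
   Kohonen training arranges them on a $K \times K$ grid of prototype
   vectors ("metagenes"); co-expressed genes end up in the same or
   neighbouring units.  Because the features span all layers, the gene →
   unit assignment is common to every layer, which is what makes layers
   directly comparable.
3. **Portraits and spots** — a sample's portrait is the grid image of its
   prototype entries; a group portrait is the mean over its members.  The
   overexpression summary map (pixelwise maximum over the group portraits)
   is thresholded at its 95th percentile and its connected components
   become labelled **spots** — clusters of co-regulated metagenes
   overexpressed somewhere in the study.
4. **Differential spot calling** — per layer and contrast, each spot gets
   a *presence/absence* vote (group-mean difference of spot expression
   against $\pm$ one SD of metagene expression in that layer) and a
   *t-test* vote (Welch $t$ on per-sample spot means, gated by $p < 0.05$
   and linear fold change $> 1.5$).  The joint vote is their conservative
   AND.
5. **Repositioning verdict** — a drug is a *candidate* for a disease iff
   at least one spot is antagonistically regulated: up in the disease
   contrast and down under the drug, or vice versa.

Sample-wise gene-set Z scores (GSZ), Fisher exact spot annotation, and
Pathway Signal Flow (PSF) provide the functional readouts around the core.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `grid_size` | 45 | metagene grid; production analyses use 45×45, all shipped tests use 20×20 (see *Problem sizes*) |
| `overexpression_quantile` | 0.95 | portrait quantile above which a metagene is flagged (strict, type-7 interpolation) |
| `sd_multiplier` | 1.0 | presence/absence threshold in units of layer metagene SD |
| `ttest_alpha` | 0.05 | t-vote significance level (raw p; BH-adjusted p reported alongside) |
| `fc_threshold` | 1.5 | linear fold-change gate, two-sided (>1.5 or <1/1.5) |
| `connectivity` | 8 | spot segmentation connectivity (spots are smooth blobs; diagonal contact is common) |
| `vote` | `"both"` | joint vote: AND (`both`) or OR-unless-contradictory (`any`) |
| `rough_epochs`, `fine_epochs` | 20, 30 | training schedule (below) |

All log2-scale quantities are dimensionless log2 intensity differences;
fold changes are linear-scale ratios ($2^{\Delta \log_2}$).

## Numerical and algorithmic choices

**Quantile convention.** Every quantile in the package (overexpression
threshold, summary-map threshold) uses linear interpolation between order
statistics (the "type 7" convention) — one convention, stated once,
testable.

**Quantile normalization ties.** Tied values within a column receive the
mean of the reference values over the ranks they occupy.  This is
symmetric and independent of input order; it differs from
interpolation-at-average-rank implementations only for tie groups of odd
size ≥ 3.

**Harmonization statistic.** Each layer's block is rescaled by a single
scalar so that its mean per-gene SD equals the across-layer *median* of
those means, then rows are re-centered.  The median target makes the
operation idempotent and equalizes each layer's contribution to the
Euclidean metric, which is its purpose.  A single scalar (not per-gene
scaling) preserves within-layer co-expression structure.

**SOM training.** Batch (not online) Kohonen updates with PCA-plane
initialization: units start on the plane of the first two principal
components of the gene cloud (longer grid axis along PC1, component signs
fixed deterministically), so training is deterministic given the input —
there is no run-to-run jitter to average away.  The neighbourhood is a
smooth Gaussian of width $\sigma = r/2$ where the radius $r$ anneals
linearly from $\max(K)/2$ to 3 over 20 rough epochs and from 3 to 0.5
over 30 fine epochs.  A smooth (untruncated) kernel is used deliberately:
hard cutoffs make the neighbour set change discretely between epochs,
which visibly zig-zags the quantization error; with the smooth kernel the
fine-phase quantization error is non-increasing in practice, and at
$r = 0.5$ the nearest-neighbour weight is $e^{-8}$, so the final epochs
are k-means (Lloyd) steps for all practical purposes — a 2×1 grid on two
well-separated clusters recovers the 2-means solution.  Empty units keep
their (interpolated) prototypes and may still join spots; the population
support map exposes them.

**Spot segmentation.** Spots are *re-detected on the summary map*: the
pixelwise maximum over all group portraits is thresholded at the
overexpression quantile, and connected components (8-connectivity by
default) become spots, labelled A, B, … in row-major order of their
centroids.  Re-detection keeps the segmentation support at ~5% of the
grid regardless of how many group portraits the study has.  The
alternative — unioning every group portrait's own top-5% flags — grows
linearly with the number of groups; with 8 group portraits on a 20×20
grid it covers ~40% of the map, which is the site-percolation threshold
for 8-connectivity: spots then coalesce into sprawling components whose
profiles dilute every planted signal (we measured spot purities down to
0.2 under that rule).  Segmenting an explicit logical mask (or list of
masks, combined by union) remains available for direct use.

**Presence/absence call.** The vote thresholds the *difference* of
group-mean spot expression at $\pm$ `sd_multiplier` × σ.  A
difference rule is used because it is symmetric — swapping target and
reference flips up and down, which any directional call should satisfy —
and matches the idea of detecting a presence/absence *difference* at a
±1 SD threshold.  σ defaults to the SD of all metagene entries over the
layer's samples (`sigma_scope = "layer"`): the layer's typical metagene
variability.  Restricting σ to the spot's own entries
(`sigma_scope = "spot"`) is available but not the default, because the
spot's own between-group signal then inflates the threshold that is
supposed to detect it — a spot with a clean 1.0 log2 group difference
contributes 0.5 to its own σ and can fail its own call.

**t-test call.** Welch's unequal-variance form is the default ("t-test"
alone does not promise equal group variances; `welch = FALSE` gives the
pooled form).  The fold-change gate is two-sided.  Contrasts with fewer
than two samples on a side abstain with a warning.  No multiple-testing
correction is applied to the vote itself (the calling rule is raw
$p < \alpha$); BH-adjusted p-values across spots within each contrast are
reported alongside for transparency.

**Joint vote.** `both` (agreement required) is the default; with two
largely independent error modes the AND keeps the fraction of called
spots small, which matches how sparsely real perturbation maps are
populated.  `--vote any` is available.

**GSZ.** The simplified standardized-mean form
$z = \sqrt{n_S}\,(\bar{\Delta e}_S - \bar{\Delta e}) / \mathrm{sd}(\Delta e)$
per sample.  This omits the hypergeometric variance correction of the
full GSZ statistic; the simplification is flagged here and in the
function documentation.  On null data it is approximately standard
normal for sets of ≥ 20 genes (finite-population effects shrink the SD by
$\sqrt{(N - n_S)/(N-1)}$, well inside the tested tolerance).

**PSF.** Input nodes carry their own linear fold change; an activation
edge contributes the parent's signal, an inhibition edge its reciprocal;
a node multiplies its own fold change by the *product* of parent
contributions (the minimal extension of pairwise multiply/reduce to
multiple parents; `combination = "mean"` is available).  Acyclic graphs
are evaluated in topological order.  Cycles are iterated from the all-fc
initialization with damped (log-mean) updates until the log-signal
changes by < 1e-6 or 100 iterations — undamped updates oscillate on
marginally stable loops.  All-ones fold changes propagate to all-ones
signals on any acyclic topology.

## What the synthetic generator emulates — and what it does not

`simulate_study()` produces per-layer log2 matrices:
baseline$_g$ + planted effect + module factor + noise, with

- per-gene baselines drawn once from Normal(7, 1.5), mimicking
  RMA-normalized intensity ranges;
- planted modules: disjoint gene sets with a log2 effect added to the
  target group of the layers named in their direction pattern;
- a shared per-sample factor for each module with standardized loading
  0.8 — module-gene noise splits into $0.8\,\sigma_n f_s$ plus residual,
  keeping the total per-gene noise SD at `noise_sd` and giving pairwise
  correlations of ≈ 0.64, so module genes co-cluster on the SOM through
  correlated profiles rather than only through mean shifts;
- the factor is centered within each sample group, so the realized
  group-mean differential effect equals the declared effect size — the
  generator's truth labels describe the data it makes.  (An uncentered
  factor would add $\pm 0.18$ log2 of group-mean luck to every "1.0"
  effect.)

`simulate_repositioning_study()` is the showcase design: four layers
(two diseases sharing an upregulated module, one unrelated disease, one
drug layer reversing the module), 2000 genes, n = 10 per group, noise SD
0.5 — plus seven co-regulated but non-differential background modules.
Real transcriptomes are organized into co-expression programs everywhere,
not only where the disease signal is; with a purely i.i.d. background
every portrait's top-5% flags are idiosyncratic scatter, a pattern no
real dataset shows.

Passing tests on these data demonstrate that the pipeline recovers
planted, correlated, differentially regulated modules at realistic
effect/noise ratios.  They do **not** demonstrate robustness to
platform-specific artifacts, probe-level noise, outlier samples,
unbalanced group sizes, or confounded batch structure — none of which the
generator emulates — and gene-level verdicts on real data still require
the biological validation steps that are outside this package's scope.

## Problem sizes

Production analyses mirror the published setting: a 45×45 grid on
genome-scale matrices.  Every shipped test and the acceptance script run
on a 20×20 grid with 2000 genes and 10 samples per group — large enough
that segmentation, calling, and the repositioning logic operate in their
realistic regime, small enough that the whole suite (including two
100-seed recovery studies) completes in minutes.

## Known limitations

- Only overexpression spots are segmented by default; the mirrored
  underexpression criterion exists (`overexpression_mask(...,
  underexpression = TRUE)`) but is off by default, and downregulated
  programs are seen through spots that are overexpressed elsewhere in the
  assembly.
- Spot profiles are means over spot *units* (prototype entries), not over
  member genes; for very small spots the two can differ noticeably.
- The harmonization scalar assumes layers share a broadly similar
  variance structure; a layer whose variance is dominated by a single
  huge program will still be down-weighted as a whole.
- PSF ignores edge weights and rule-based (AND/OR) gate semantics;
  KGML/KEGG parsing is out of scope — topologies come in as signed edge
  lists.
- Probe-to-gene collapsing, RMA, and GEO retrieval are upstream of this
  package: inputs are already-normalized gene-level matrices.
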