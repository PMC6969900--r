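# Synthetic multi-layer case/control generator with planted co-regulated,
# differentially regulated gene modules.  Module genes share a latent
# per-sample factor so that they co-cluster on the SOM through correlated
# profiles, not only through their mean shifts; the factor model keeps the
# total per-gene noise SD at noise_sd (shared variance fraction =
# factor_loading^2).

#' Describe a planted module
#'
#' @param n_genes Number of member genes (ignored when `genes` is given).
#' @param effect Log2 effect size (>= 0) added to the target group of every
#'   layer where the module is directional.
#' @param pattern Named character vector layer id -> `"up"`, `"down"` or
#'   `"none"`.
#' @param genes Optional explicit gene identifiers.
#' @return A list describing the module.
#' @export
synthetic_module <- function(n_genes = 100L, effect = 1.0, pattern,
                             genes = NULL) {
  if (effect < 0) stop("module effect sizes must be >= 0")
  bad <- setdiff(pattern, c("up", "down", "none"))
  if (length(bad))
    stop("module directions must be up/down/none, not: ",
         paste(bad, collapse = ", "))
  list(n_genes = as.integer(n_genes), effect = effect, pattern = pattern,
       genes = genes)
}

#' One layer of a synthetic study layout
#'
#' @param layer_id Layer identifier.
#' @param role Layer role, see [expression_layer()].
#' @param n_target,n_reference Group sizes.
#' @param target_subgroup,reference_subgroup Optional subgroup labels
#'   (e.g. `"responder"`, `"baseline"`).
#' @return A list describing the layer.
#' @export
synthetic_layer <- function(layer_id, role = "target_disease",
                            n_target = 10L, n_reference = 10L,
                            target_subgroup = NULL,
                            reference_subgroup = NULL) {
  list(layer_id = layer_id, role = role, n_target = as.integer(n_target),
       n_reference = as.integer(n_reference),
       target_subgroup = target_subgroup,
       reference_subgroup = reference_subgroup)
}

#' Simulate a multi-layer case/control study
#'
#' Generates per-layer log2 expression matrices with per-gene baselines
#' drawn once from Normal(baseline_mean, baseline_sd), planted module
#' effects (added to the target group of each layer named in a module's
#' pattern, with sign by direction), a shared latent factor per module and
#' sample (standardized loading `factor_loading`; the total per-gene noise
#' SD stays at `noise_sd`), and independent Gaussian noise.  The module
#' factor is centered within each sample group, so module genes are
#' correlated across samples (they co-cluster on the SOM) while the
#' realized group-mean differential effect equals the declared effect size.
#' Deterministic given `seed`.
#'
#' @param layout List of [synthetic_layer()]s (>= 2 layers, each with target
#'   and reference samples).
#' @param n_genes Total gene count.
#' @param modules List of [synthetic_module()]s; gene lists must be
#'   disjoint.
#' @param noise_sd Per-gene noise SD on the log2 scale.
#' @param factor_loading Standardized loading of the shared module factor
#'   in [0, 1).
#' @param baseline_mean,baseline_sd Per-gene baseline distribution
#'   (log2 scale), mimicking RMA-normalized intensities.
#' @param seed Integer seed.
#' @return List with `dataset` (a `MultiLayerDataset`), `sheet` (the sample
#'   sheet data frame) and `truth` (class `SyntheticTruth`: module gene
#'   lists, effects, patterns, and the generator parameters).
#' @export
simulate_study <- function(layout, n_genes = 2000L, modules = list(),
                           noise_sd = 0.5, factor_loading = 0.8,
                           baseline_mean = 7, baseline_sd = 1.5, seed = 1L) {
  if (length(layout) < 2L)
    stop("a multi-layer study needs at least two layers")
  for (l in layout)
    if (l$n_target < 1L || l$n_reference < 1L)
      stop("layer '", l$layer_id,
           "' needs at least one target and one reference sample")
  if (factor_loading < 0 || factor_loading >= 1)
    stop("factor_loading must lie in [0, 1)")
  set.seed(as.integer(seed))
  genes <- sprintf("G%05d", seq_len(n_genes))

  # assign module genes: explicit lists verbatim, otherwise drawn without
  # replacement from the unused pool
  pool <- genes
  for (i in seq_along(modules)) {
    m <- modules[[i]]
    if (is.null(m$genes)) {
      if (m$n_genes > length(pool)) stop("not enough genes for the modules")
      modules[[i]]$genes <- sort(sample(pool, m$n_genes))
    }
    pool <- setdiff(pool, modules[[i]]$genes)
  }
  all_members <- unlist(lapply(modules, `[[`, "genes"))
  if (anyDuplicated(all_members))
    stop("module gene lists must be disjoint")

  baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  names(baseline) <- genes
  lambda <- factor_loading * noise_sd
  resid_sd <- noise_sd * sqrt(1 - factor_loading^2)

  mats <- list(); roles <- character(0L); sheet <- NULL
  for (l in layout) {
    ns <- l$n_target + l$n_reference
    ids <- c(sprintf("%s_T%02d", l$layer_id, seq_len(l$n_target)),
             sprintf("%s_R%02d", l$layer_id, seq_len(l$n_reference)))
    grp <- rep(c("target", "reference"), c(l$n_target, l$n_reference))
    sub <- rep(NA_character_, ns)
    if (!is.null(l$target_subgroup)) sub[grp == "target"] <- l$target_subgroup
    if (!is.null(l$reference_subgroup))
      sub[grp == "reference"] <- l$reference_subgroup
    m <- matrix(baseline, nrow = n_genes, ncol = ns,
                dimnames = list(genes, ids))
    for (mod in modules) {
      dir <- mod$pattern[[l$layer_id]]
      if (!is.null(dir) && !is.na(dir) && dir != "none")
        m[mod$genes, grp == "target"] <- m[mod$genes, grp == "target"] +
          if (dir == "up") mod$effect else -mod$effect
    }
    # shared latent factor per module and sample, then residual noise; the
    # factor is centered within each sample group so that it drives
    # within-group co-expression (the SOM sees correlated profiles) without
    # perturbing the planted group-mean effects
    if (noise_sd > 0) {
      for (mod in modules) {
        f <- stats::rnorm(ns)
        for (g in unique(grp)) f[grp == g] <- f[grp == g] - mean(f[grp == g])
        m[mod$genes, ] <- m[mod$genes, ] +
          lambda * matrix(f, nrow = length(mod$genes), ncol = ns,
                          byrow = TRUE)
      }
      eps_sd <- rep(noise_sd, n_genes)
      eps_sd[genes %in% all_members] <- resid_sd
      m <- m + matrix(stats::rnorm(n_genes * ns), n_genes, ns) * eps_sd
    }
    mats[[l$layer_id]] <- m
    roles[[l$layer_id]] <- l$role
    sheet <- rbind(sheet, data.frame(sample = ids, layer = l$layer_id,
                                     group = grp, subgroup = sub,
                                     row.names = NULL))
  }
  dataset <- multilayer_dataset(mats, sheet, roles, quiet = TRUE)
  truth <- structure(list(
    modules = lapply(modules, function(m)
      m[c("genes", "effect", "pattern")]),
    noise_sd = noise_sd, factor_loading = factor_loading,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    seed = as.integer(seed)), class = "SyntheticTruth")
  list(dataset = dataset, sheet = sheet, truth = truth)
}

#' Write a simulated study as standard pipeline inputs
#'
#' Expression TSVs (one per layer), the sample sheet, and the ground truth
#' as JSON, so a synthetic study is consumed identically to a real one.
#'
#' @param sim Result of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (id in names(sim$dataset$layers)) {
    p <- file.path(dir, paste0(id, ".tsv"))
    write_expression_matrix(sim$dataset$layers[[id]], p)
    paths[[id]] <- p
  }
  sheet_path <- file.path(dir, "samples.tsv")
  sheet <- sim$sheet
  sheet$subgroup[is.na(sheet$subgroup)] <- ""
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(unclass(sim$truth), truth_path, auto_unbox = TRUE,
                       digits = NA)
  paths$sample_sheet <- sheet_path
  paths$truth <- truth_path
  invisible(paths)
}

#' Reference repositioning scenario
#'
#' The generator's showcase study design: a drug layer reversing a module
#' that is upregulated in two disease layers and untouched in a third, on a
#' background of co-regulated but non-differential modules emulating the
#' co-expression programs of real transcriptomes.  Layers `disease1` and
#' `disease2` should yield `candidate` verdicts against the drug layer,
#' `disease3` should yield `not_supported`.
#'
#' @param seed Integer seed.
#' @param n_genes Total genes (default 2000).
#' @param effect Planted log2 effect (default 1.0).
#' @param n_per_group Samples per group in every layer (default 10).
#' @param n_null_modules Co-regulated non-differential background modules
#'   (default 7, of `module_size` genes each).
#' @param module_size Genes per module (default 100).
#' @param noise_sd,factor_loading Passed to [simulate_study()].
#' @return See [simulate_study()].
#' @export
simulate_repositioning_study <- function(seed = 1L, n_genes = 2000L,
                                         effect = 1.0, n_per_group = 10L,
                                         n_null_modules = 7L,
                                         module_size = 100L, noise_sd = 0.5,
                                         factor_loading = 0.8) {
  none <- c(disease1 = "none", disease2 = "none", disease3 = "none",
            drug = "none")
  mods <- c(list(synthetic_module(module_size, effect, c(
    disease1 = "up", disease2 = "up", disease3 = "none", drug = "down"))),
    lapply(seq_len(n_null_modules),
           function(i) synthetic_module(module_size, 0, none)))
  simulate_study(
    layout = list(
      synthetic_layer("disease1", "target_disease", n_per_group, n_per_group),
      synthetic_layer("disease2", "repositioning_disease", n_per_group,
                      n_per_group),
      synthetic_layer("disease3", "repositioning_disease", n_per_group,
                      n_per_group),
      synthetic_layer("drug", "treatment", n_per_group, n_per_group,
                      target_subgroup = "treated",
                      reference_subgroup = "baseline")),
    n_genes = n_genes, modules = mods, noise_sd = noise_sd,
    factor_loading = factor_loading, seed = seed)
}
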