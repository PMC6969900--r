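# Orchestration of the full workflow: read layers and sample sheet,
# preprocess, train the joint SOM, segment spots, call differential spots
# per contrast, annotate, optionally score gene sets and propagate pathway
# signals, and read off repositioning verdicts.  A run manifest (config
# snapshot, input checksums, seed, per-stage timings, outputs) is written on
# both success and handled failure.

.read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a YAML path or a list")
  config
}

.config_from_run <- function(cfg, seed = NULL) {
  get <- function(nm, default) if (is.null(cfg[[nm]])) default else cfg[[nm]]
  ml_config(
    grid_size = get("grid_size", 45L),
    overexpression_quantile = get("overexpression_quantile", 0.95),
    sd_multiplier = get("sd_multiplier", 1.0),
    ttest_alpha = get("ttest_alpha", 0.05),
    fc_threshold = get("fc_threshold", 1.5),
    random_seed = if (!is.null(seed)) seed else get("seed", 1L),
    connectivity = get("connectivity", 8L),
    vote = get("vote", "both"),
    sigma_scope = get("sigma_scope", "layer"))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full portrayal and repositioning pipeline
#'
#' Executes io -> preprocess -> SOM -> spots -> calls -> enrichment ->
#' (optional) GSZ/PSF -> verdicts, writing every result table plus a run
#' manifest into the output directory.  Identical config, inputs and seed
#' reproduce byte-identical TSV outputs.
#'
#' The config (YAML file or list) names the layers
#' (`layers: [{id, role, matrix}]`), the `sample_sheet`, the analysis
#' parameters of [ml_config()], explicit `contrasts`
#' (`{name, layer, target: {group/subgroup}, reference: {...}}`; per-layer
#' target-vs-reference contrasts are enumerated when absent), optional
#' `gene_sets` (GMT path), optional `pathways` (`{edges, node_fc}` paths),
#' and optional `repositioning` (`{drug: contrast, diseases: [contrasts]}`).
#'
#' @param config YAML path or list.
#' @param outdir Output directory; overrides `output_dir` in the config.
#' @param seed Optional seed overriding the config's.
#' @param write_portraits Also write per-group portrait PNGs.
#' @param quiet Suppress log messages.
#' @return Invisibly, a list with the main in-memory results (`joint`,
#'   `model`, `spots`, `perturbation`, `verdicts`, `manifest`).
#' @export
run_pipeline <- function(config, outdir = NULL, seed = NULL,
                         write_portraits = FALSE, quiet = FALSE) {
  cfg <- .read_run_config(config)
  if (is.null(outdir)) outdir <- cfg$output_dir
  if (is.null(outdir)) stop("no output directory given")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  mlc <- .config_from_run(cfg, seed)
  set.seed(mlc$random_seed)

  # run state lives in an environment so that stage expressions (promises
  # evaluated in this frame) can update it with plain assignments
  st <- new.env(parent = emptyenv())
  st$manifest <- list(config = cfg, seed = mlc$random_seed,
                      parameters = unclass(mlc), inputs = list(),
                      timings = list(), outputs = list(),
                      status = "running")
  st$stage_name <- "setup"
  on.exit({
    if (identical(st$manifest$status, "running")) {
      st$manifest$status <- "failed"
      st$manifest$failed_stage <- st$stage_name
    }
    jsonlite::write_json(st$manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE, null = "null")
  })
  stage <- function(name, expr) {
    st$stage_name <- name
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    st$manifest$timings[[name]] <- round(proc.time()[["elapsed"]] - t0, 3L)
    .mlsom_log("stage ", name, " done (",
               st$manifest$timings[[name]], "s)", quiet = quiet)
    out
  }

  mld <- stage("io", {
    if (is.null(cfg$layers) || is.null(cfg$sample_sheet))
      stop("config must name 'layers' and 'sample_sheet'")
    mats <- list(); roles <- character(0L)
    for (l in cfg$layers) {
      mats[[l$id]] <- read_expression_matrix(l$matrix, l$id,
                                             role = l$role)$values
      roles[[l$id]] <- l$role
      st$manifest$inputs[[l$id]] <- unname(tools::md5sum(l$matrix))
    }
    st$manifest$inputs$sample_sheet <- unname(tools::md5sum(cfg$sample_sheet))
    multilayer_dataset(mats, read_sample_sheet(cfg$sample_sheet), roles,
                       quiet = quiet)
  })

  joint <- stage("preprocess", preprocess_dataset(mld, quiet = quiet))
  if (isTRUE(cfg$keep_intermediates))
    st$manifest$outputs$joint_matrix <-
      write_expression_matrix(joint$values, file.path(outdir, "joint.tsv"))

  model <- stage("som", train_som(joint, mlc))
  st$manifest$outputs$assignment <- .write_tsv(
    data.frame(gene = model$genes,
               row = model$coords[model$assignment, "r"],
               col = model$coords[model$assignment, "c"]),
    file.path(outdir, "assignment.tsv"))
  st$manifest$outputs$training_log <- .write_tsv(
    model$training_log, file.path(outdir, "training_log.tsv"))

  spots <- stage("spots", {
    gp <- group_portraits(model)
    if (write_portraits) {
      pdir <- file.path(outdir, "portraits")
      dir.create(pdir, showWarnings = FALSE)
      for (nm in names(gp))
        plot_portrait(gp[[nm]], file.path(pdir, paste0(nm, ".png")))
    }
    segment_spots(gp, model, connectivity = mlc$connectivity,
                  quantile = mlc$overexpression_quantile)
  })
  st$manifest$outputs$spots <- .write_tsv(spot_table(spots),
                                       file.path(outdir, "spots.tsv"))
  if (length(spots$spots))
    st$manifest$outputs$spot_genes <- .write_tsv(
      do.call(rbind, lapply(spots$spots, function(s)
        data.frame(spot = s$label, gene = s$genes, row.names = NULL))),
      file.path(outdir, "spot_genes.tsv"))

  contrasts <- stage("contrasts", {
    if (is.null(cfg$contrasts)) enumerate_contrasts(model)
    else {
      out <- lapply(cfg$contrasts, function(ct)
        contrast_from_selector(model, ct$name, ct$layer,
                               ct$target, ct$reference))
      names(out) <- vapply(out, `[[`, character(1L), "name")
      out
    }
  })

  pm <- stage("call", perturbation_matrix(spots, model, contrasts, mlc))
  st$manifest$outputs$perturbation <- .write_tsv(
    as.data.frame(pm), file.path(outdir, "perturbation.tsv"))

  if (!is.null(cfg$gene_sets)) {
    st$manifest$inputs$gene_sets <- unname(tools::md5sum(cfg$gene_sets))
    gmt <- read_gmt(cfg$gene_sets)
    enr <- stage("enrich",
                 annotate_spots(spots, gmt, mld$shared_genes, quiet = quiet))
    st$manifest$outputs$enrichment <- .write_tsv(
      enr, file.path(outdir, "enrichment.tsv"))
    gsz <- stage("gsz", gsz_matrix(joint, gmt))
    st$manifest$outputs$gsz <- .write_tsv(
      data.frame(set = rownames(gsz), gsz, check.names = FALSE),
      file.path(outdir, "gsz.tsv"))
  }

  if (!is.null(cfg$pathways)) {
    psf <- stage("psf", {
      graph <- read_pathway_graph(cfg$pathways$edges, cfg$pathways$node_fc)
      psf_propagate(graph)
    })
    st$manifest$outputs$psf <- .write_tsv(
      data.frame(node = names(psf$signal), signal = unname(psf$signal),
                 is_sink = names(psf$signal) %in% names(psf$sink_values)),
      file.path(outdir, "psf.tsv"))
  }

  verdicts <- stage("verdict", {
    if (is.null(cfg$repositioning)) list()
    else {
      drug <- cfg$repositioning$drug
      lapply(cfg$repositioning$diseases, function(d)
        repositioning_call(pm, drug, d))
    }
  })
  if (length(verdicts)) {
    vj <- lapply(verdicts, function(v) list(
      drug_contrast = v$drug_contrast, disease_contrast = v$disease_contrast,
      verdict = v$verdict, antagonistic_spots = v$antagonistic_spots,
      unopposed_disease_spots = as.list(v$unopposed_disease_spots)))
    jsonlite::write_json(vj, file.path(outdir, "verdict.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    st$manifest$outputs$verdict <- file.path(outdir, "verdict.json")
    txt <- unlist(lapply(verdicts, function(v) c(
      utils::capture.output(print(v)), "")))
    writeLines(txt, file.path(outdir, "verdict.txt"))
  }

  st$manifest$status <- "ok"
  st$stage_name <- "done"
  invisible(list(joint = joint, model = model, spots = spots,
                 perturbation = pm, contrasts = contrasts,
                 verdicts = verdicts, manifest = st$manifest))
}
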