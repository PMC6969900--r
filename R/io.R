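# Domain containers and readers/writers for the external formats the pipeline
# touches: tab-separated expression matrices, sample sheets, GMT gene sets and
# signed pathway edge lists.  All matrices are genes x samples on a log2
# scale; no re-logging or probe collapsing is performed here.

VALID_ROLES  <- c("treatment", "target_disease", "repositioning_disease")
VALID_GROUPS <- c("target", "reference")
VALID_SIGNS  <- c("activation", "inhibition")

#' Construct an expression layer
#'
#' One case-control dataset ("layer") of the multi-layer assembly: a genes x
#' samples matrix of log2 expression plus the assignment of each sample to the
#' `target` or `reference` group and an optional free-text subgroup
#' (e.g. responder, placebo, baseline).
#'
#' @param values Numeric matrix, genes x samples, with row and column names.
#' @param layer_id Character scalar identifying the layer.
#' @param role One of `"treatment"`, `"target_disease"`,
#'   `"repositioning_disease"`.
#' @param sample_group Named character vector mapping every sample to
#'   `"target"` or `"reference"`.  May be `NULL` while a layer is being
#'   assembled; downstream analysis requires it.
#' @param sample_subgroup Optional named character vector mapping samples to a
#'   free subgroup label.
#' @return An object of class `ExpressionLayer`.
#' @export
expression_layer <- function(values, layer_id, role = "target_disease",
                             sample_group = NULL, sample_subgroup = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression values need gene row names and sample column names")
  if (!all(is.finite(values)))
    stop("expression layer '", layer_id, "' contains non-finite values")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    stop("duplicated gene identifier(s) in layer '", layer_id, "': ",
         paste(head(dup, 5L), collapse = ", "))
  if (length(role) != 1L || !role %in% VALID_ROLES)
    stop("role must be one of: ", paste(VALID_ROLES, collapse = ", "))
  if (!is.null(sample_group)) {
    absent <- setdiff(colnames(values), names(sample_group))
    if (length(absent))
      stop("samples without a group in layer '", layer_id, "': ",
           paste(head(absent, 5L), collapse = ", "))
    bad <- setdiff(unique(sample_group), VALID_GROUPS)
    if (length(bad))
      stop("invalid group value(s) '", paste(bad, collapse = "', '"),
           "'; allowed values: ", paste(VALID_GROUPS, collapse = ", "))
    sample_group <- sample_group[colnames(values)]
    if (!any(sample_group == "target") || !any(sample_group == "reference"))
      stop("layer '", layer_id,
           "' needs at least one target and one reference sample")
    if (!is.null(sample_subgroup))
      sample_subgroup <- sample_subgroup[colnames(values)]
  }
  structure(list(layer_id = layer_id, role = role,
                 genes = rownames(values), samples = colnames(values),
                 values = values, sample_group = sample_group,
                 sample_subgroup = sample_subgroup),
            class = "ExpressionLayer")
}

#' @export
print.ExpressionLayer <- function(x, ...) {
  cat("ExpressionLayer '", x$layer_id, "' (", x$role, "): ",
      length(x$genes), " genes x ", length(x$samples), " samples\n", sep = "")
  invisible(x)
}

#' Read a tab-separated expression matrix
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; the body must be numeric.  The returned layer has no group
#' assignment yet; use [multilayer_dataset()] to join it with a sample sheet.
#'
#' @param path Path to a TSV file.
#' @param layer_id Layer identifier to attach.
#' @param role Layer role, see [expression_layer()].
#' @return An `ExpressionLayer` without sample groups.
#' @export
read_expression_matrix <- function(path, layer_id, role = "target_disease") {
  raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", na.strings = NULL)
  if (ncol(raw) < 2L)
    stop("expression matrix '", path, "' needs a gene column and >=1 sample")
  genes <- raw[[1L]]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicated gene row(s) in '", path, "': ",
         paste(head(dup, 5L), collapse = ", "))
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop("non-numeric value '", body[i, j], "' for gene ", genes[i],
         ", sample ", colnames(body)[j], " in '", path, "'")
  }
  dimnames(num) <- list(genes, colnames(body))
  expression_layer(num, layer_id = layer_id, role = role)
}

#' Write an expression layer (or matrix) as TSV
#'
#' Values are printed with 17 significant digits so that a written matrix
#' re-reads bit-identically.
#'
#' @param x An `ExpressionLayer` or a numeric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  m <- if (inherits(x, "ExpressionLayer")) x$values else x
  header <- paste(c("gene", colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a sample sheet
#'
#' TSV with columns `sample`, `layer`, `group` and optionally `subgroup`.
#' Groups must be `target` or `reference`.
#'
#' @param path Path to the sheet.
#' @return A data frame with columns sample, layer, group, subgroup.
#' @export
read_sample_sheet <- function(path) {
  sheet <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                      colClasses = "character", na.strings = NULL)
  need <- c("sample", "layer", "group")
  absent <- setdiff(need, colnames(sheet))
  if (length(absent))
    stop("sample sheet '", path, "' lacks column(s): ",
         paste(absent, collapse = ", "))
  if (!"subgroup" %in% colnames(sheet)) sheet$subgroup <- NA_character_
  sheet$subgroup[!nzchar(sheet$subgroup)] <- NA_character_
  bad <- setdiff(unique(sheet$group), VALID_GROUPS)
  if (length(bad))
    stop("invalid group value(s) '", paste(bad, collapse = "', '"),
         "' in sample sheet; allowed values: ",
         paste(VALID_GROUPS, collapse = ", "))
  dup <- unique(sheet$sample[duplicated(sheet$sample)])
  if (length(dup))
    stop("duplicated sample(s) in sheet: ", paste(head(dup, 5L), collapse = ", "))
  sheet[, c("sample", "layer", "group", "subgroup")]
}

#' Assemble a multi-layer dataset
#'
#' Joins per-layer expression matrices with a sample sheet, restricts every
#' layer to the samples present in both and to the gene set shared by all
#' layers (in a fixed order), and validates that each layer keeps at least one
#' target and one reference sample.  Dropped samples and genes are logged.
#'
#' @param matrices Named list of numeric matrices or `ExpressionLayer`s,
#'   one per layer; names are layer ids.
#' @param sheet Sample sheet data frame, see [read_sample_sheet()].
#' @param roles Named character vector layer id -> role.
#' @param quiet Suppress log messages.
#' @return An object of class `MultiLayerDataset` with elements `layers`
#'   (named list of `ExpressionLayer`) and `shared_genes`.
#' @export
multilayer_dataset <- function(matrices, sheet, roles, quiet = FALSE) {
  if (is.null(names(matrices)) || any(!nzchar(names(matrices))))
    stop("'matrices' must be a named list keyed by layer id")
  unknown <- setdiff(unique(sheet$layer), names(matrices))
  if (length(unknown))
    stop("sample sheet references unknown layer(s): ",
         paste(unknown, collapse = ", "))
  layers <- lapply(names(matrices), function(id) {
    m <- matrices[[id]]
    if (inherits(m, "ExpressionLayer")) m <- m$values
    rows <- sheet[sheet$layer == id, , drop = FALSE]
    keep <- intersect(colnames(m), rows$sample)
    drop_m <- setdiff(colnames(m), keep)
    drop_s <- setdiff(rows$sample, keep)
    if (length(drop_m))
      .mlsom_log("layer ", id, ": dropping ", length(drop_m),
                 " matrix column(s) absent from sheet", quiet = quiet)
    if (length(drop_s))
      .mlsom_log("layer ", id, ": ", length(drop_s),
                 " sheet sample(s) absent from matrix", quiet = quiet)
    if (!length(keep))
      stop("layer '", id, "' has no samples shared between matrix and sheet")
    grp <- structure(rows$group, names = rows$sample)[keep]
    sub <- structure(rows$subgroup, names = rows$sample)[keep]
    if (all(is.na(sub))) sub <- NULL
    expression_layer(m[, keep, drop = FALSE], layer_id = id,
                     role = roles[[id]], sample_group = grp,
                     sample_subgroup = sub)
  })
  names(layers) <- names(matrices)
  shared <- Reduce(intersect, lapply(layers, `[[`, "genes"))
  if (!length(shared)) stop("no genes shared by all layers")
  for (id in names(layers)) {
    lost <- length(layers[[id]]$genes) - length(shared)
    if (lost > 0L)
      .mlsom_log("layer ", id, ": dropping ", lost,
                 " gene(s) outside the shared set", quiet = quiet)
    layers[[id]]$values <- layers[[id]]$values[shared, , drop = FALSE]
    layers[[id]]$genes <- shared
  }
  structure(list(layers = layers, shared_genes = shared),
            class = "MultiLayerDataset")
}

#' @export
print.MultiLayerDataset <- function(x, ...) {
  cat("MultiLayerDataset:", length(x$layers), "layers,",
      length(x$shared_genes), "shared genes\n")
  for (l in x$layers) print(l)
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' name, description, gene1, gene2, ...  The description is kept as the
#' set's `source_tag`.
#'
#' @param path Path to a GMT file.
#' @return An object of class `GeneSetCollection`: a named list `sets` of
#'   gene identifier vectors plus a named `source_tag` vector.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); tags <- character(0L)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    f <- f[nzchar(f)]
    if (length(f) < 3L)
      stop("GMT parse error at line ", i, ": need name, description and >=1 gene")
    nm <- f[[1L]]
    if (nm %in% names(sets)) stop("duplicated gene set name '", nm, "'")
    sets[[nm]] <- unique(f[-(1:2)])
    tags[[nm]] <- f[[2L]]
  }
  if (!length(sets)) stop("no gene sets in '", path, "'")
  structure(list(sets = sets, source_tag = tags), class = "GeneSetCollection")
}

#' Construct a signed pathway graph
#'
#' Directed topology with edges labelled `activation` or `inhibition` and a
#' positive linear-scale fold change per node.  Input nodes (no incoming
#' edge) and sink nodes (no outgoing edge) are computed from the topology;
#' an isolated node is both.  Nodes without a supplied fold change default to
#' 1.0 with a warning.
#'
#' @param edges Data frame with columns `source`, `sign`, `sink`.
#' @param node_fc Named numeric vector of linear fold changes (> 0).
#' @return An object of class `PathwayGraph`.
#' @export
pathway_graph <- function(edges, node_fc = NULL) {
  need <- c("source", "sign", "sink")
  if (!all(need %in% colnames(edges)))
    stop("edge table needs columns: ", paste(need, collapse = ", "))
  edges <- as.data.frame(edges)[, need]
  edges[] <- lapply(edges, as.character)
  bad <- setdiff(unique(edges$sign), VALID_SIGNS)
  if (length(bad))
    stop("unknown interaction sign token(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(VALID_SIGNS, collapse = ", "))
  nodes <- union(union(edges$source, edges$sink), names(node_fc))
  if (!length(nodes)) stop("pathway graph has no nodes")
  fc <- structure(rep(1.0, length(nodes)), names = nodes)
  if (!is.null(node_fc)) {
    if (any(!is.finite(node_fc)) || any(node_fc <= 0))
      stop("node fold changes must be finite and > 0")
    fc[names(node_fc)] <- node_fc
  }
  missing_fc <- setdiff(nodes, names(node_fc))
  if (length(missing_fc) && !is.null(node_fc))
    warning(length(missing_fc),
            " node(s) without a fold change default to 1.0: ",
            paste(head(missing_fc, 5L), collapse = ", "))
  inputs <- setdiff(nodes, unique(edges$sink))
  sinks <- setdiff(nodes, unique(edges$source))
  structure(list(nodes = nodes, edges = edges, node_fc = fc,
                 input_nodes = inputs, sink_nodes = sinks),
            class = "PathwayGraph")
}

#' Read a pathway graph from TSV files
#'
#' @param edges_path TSV with header `source`, `sign`, `sink`
#'   (sign is `activation` or `inhibition`).
#' @param node_fc_path Optional TSV with header `node`, `fc`
#'   (linear fold change, > 0).
#' @return A `PathwayGraph`.
#' @export
read_pathway_graph <- function(edges_path, node_fc_path = NULL) {
  edges <- read.delim(edges_path, sep = "\t", header = TRUE,
                      check.names = FALSE, colClasses = "character",
                      na.strings = NULL)
  fc <- NULL
  if (!is.null(node_fc_path)) {
    tab <- read.delim(node_fc_path, sep = "\t", header = TRUE,
                      check.names = FALSE, na.strings = NULL)
    if (!all(c("node", "fc") %in% colnames(tab)))
      stop("node fold-change table needs columns 'node' and 'fc'")
    fc <- structure(as.numeric(tab$fc), names = as.character(tab$node))
    if (any(!is.finite(fc)) || any(fc <= 0))
      stop("node fold changes must be finite and > 0")
  }
  pathway_graph(edges, fc)
}
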