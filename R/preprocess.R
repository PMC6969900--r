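# Preprocessing chain producing the joint training matrix: per-layer quantile
# normalization, global per-gene centering, layer harmonization, re-centering.
# The output (delta-e scale) feeds SOM training, portraits, spot profiles and
# GSZ scoring.

#' Quantile-normalize the columns of a matrix
#'
#' Classic rank/row-mean quantile normalization: the reference distribution is
#' the per-rank mean of the sorted columns, and each column's values are
#' replaced by the reference value at their rank.  Ties within a column
#' receive the mean of the reference values over the ranks they occupy, so
#' the result does not depend on the input order.
#'
#' @param values Numeric matrix with at least two columns.
#' @return Matrix of the same shape; all columns share one value multiset
#'   (up to ties).
#' @export
quantile_normalize <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (ncol(values) < 2L)
    stop("quantile normalization is undefined for a single sample")
  ref <- rowMeans(apply(values, 2L, sort))
  out <- values
  for (j in seq_len(ncol(values))) {
    v <- numeric(nrow(values))
    v[order(values[, j])] <- ref
    out[, j] <- ave(v, factor(values[, j]), FUN = mean)
  }
  out
}

#' Quantile-normalize one expression layer
#'
#' @param layer An `ExpressionLayer` with >= 2 samples.
#' @return The layer with normalized values; gene order is preserved.
#' @export
quantile_normalize_layer <- function(layer) {
  stopifnot(inherits(layer, "ExpressionLayer"))
  if (length(layer$samples) < 2L)
    stop("layer '", layer$layer_id,
         "' has a single sample; quantile normalization is undefined")
  layer$values <- quantile_normalize(layer$values)
  layer
}

#' Center every gene to zero mean
#'
#' Global centralization over all samples of all layers: each gene row has
#' its mean subtracted, turning expression into the difference scale used by
#' portraits and spot profiles.
#'
#' @param values Numeric genes x samples matrix.
#' @return The centered matrix.
#' @export
center_genes <- function(values) {
  sweep(values, 1L, rowMeans(values))
}

#' Harmonize layers to equal mean per-gene variability
#'
#' Rescales every layer block by one scalar so that its mean per-gene
#' standard deviation equals the across-layer median of those means,
#' preventing any layer from dominating the Euclidean distances during joint
#' SOM training; rows are re-centered afterwards.  Idempotent.
#'
#' @param values Centered genes x samples matrix.
#' @param layer_of Character vector (length = ncol) naming each sample's layer.
#' @return List with the harmonized `values` and the per-layer
#'   `scale_factors` applied.
#' @export
harmonize_layers <- function(values, layer_of) {
  stopifnot(ncol(values) == length(layer_of))
  layers <- unique(layer_of)
  mean_sd <- vapply(layers, function(l) {
    block <- values[, layer_of == l, drop = FALSE]
    if (ncol(block) < 2L)
      stop("layer '", l, "' has a single sample; cannot harmonize")
    mean(apply(block, 1L, sd))
  }, numeric(1L))
  if (any(mean_sd == 0))
    stop("layer(s) with zero total variance: ",
         paste(layers[mean_sd == 0], collapse = ", "))
  target <- median(mean_sd)
  fac <- target / mean_sd
  out <- values
  for (l in layers) out[, layer_of == l] <- out[, layer_of == l] * fac[[l]]
  list(values = center_genes(out), scale_factors = fac)
}

#' Build the joint training matrix from a multi-layer dataset
#'
#' Runs the fixed preprocessing chain: per-layer quantile normalization,
#' global per-gene centering, layer harmonization, re-centering.  The result
#' carries the sample metadata (layer, group, subgroup, role) needed by all
#' downstream stages.
#'
#' @param mld A `MultiLayerDataset`.
#' @param quiet Suppress log messages.
#' @return An object of class `JointMatrix`: `values` (genes x all samples,
#'   per-gene mean zero), `genes`, `samples`, and named per-sample vectors
#'   `layer`, `sample_group`, `sample_subgroup`, plus per-layer `roles` and
#'   the harmonization `scale_factors`.
#' @export
preprocess_dataset <- function(mld, quiet = FALSE) {
  stopifnot(inherits(mld, "MultiLayerDataset"))
  norm <- lapply(mld$layers, quantile_normalize_layer)
  values <- do.call(cbind, lapply(norm, `[[`, "values"))
  samples <- unlist(lapply(norm, `[[`, "samples"), use.names = FALSE)
  if (anyDuplicated(samples))
    stop("sample identifiers must be unique across layers")
  colnames(values) <- samples
  layer_of <- unlist(lapply(norm, function(l)
    structure(rep(l$layer_id, length(l$samples)), names = l$samples)),
    use.names = FALSE)
  names(layer_of) <- samples
  grp <- unlist(lapply(norm, `[[`, "sample_group"), use.names = FALSE)
  names(grp) <- samples
  sub <- unlist(lapply(norm, function(l) {
    s <- l$sample_subgroup
    if (is.null(s)) structure(rep(NA_character_, length(l$samples)),
                              names = l$samples) else s
  }), use.names = FALSE)
  names(sub) <- samples
  roles <- vapply(norm, `[[`, character(1L), "role")
  harm <- harmonize_layers(center_genes(values), layer_of)
  .mlsom_log("joint matrix: ", nrow(values), " genes x ", ncol(values),
             " samples; layer scale factors ",
             paste(sprintf("%s=%.3f", names(harm$scale_factors),
                           harm$scale_factors), collapse = ", "),
             quiet = quiet)
  structure(list(values = harm$values, genes = rownames(values),
                 samples = samples, layer = layer_of, sample_group = grp,
                 sample_subgroup = sub, roles = roles,
                 scale_factors = harm$scale_factors),
            class = "JointMatrix")
}
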