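# Joint SOM training: genes are the objects, their expression profiles across
# all samples of all layers are the features.  Training is batch Kohonen with
# PCA-plane initialization and a two-phase shrinking neighbourhood, so runs
# are deterministic given the input; the compiled core lives in src/som.cpp.

# PCA-plane initialization: units are laid out on the plane spanned by the
# first two principal components of the gene cloud, the longer grid axis
# along PC1.  Component signs are fixed deterministically.
.som_init <- function(X, kr, kc) {
  mu <- colMeans(X)
  m <- kr * kc
  if (m == 1L) return(matrix(mu, nrow = 1L))
  Xc <- sweep(X, 2L, mu)
  nv <- min(2L, ncol(X), nrow(X))
  sv <- svd(Xc, nu = 0L, nv = nv)
  dirs <- matrix(0, nrow = ncol(X), ncol = 2L)
  sds <- c(0, 0)
  for (k in seq_len(nv)) {
    v <- sv$v[, k]
    if (v[which.max(abs(v))] < 0) v <- -v
    dirs[, k] <- v
    sds[k] <- sv$d[k] / sqrt(max(1L, nrow(X) - 1L))
  }
  ax <- function(k) if (k > 1L) seq(-1, 1, length.out = k) else 0
  ar <- ax(kr); ac <- ax(kc)
  # longer axis carries PC1
  if (kr >= kc) { d1 <- 1L; d2 <- 2L } else { d1 <- 2L; d2 <- 1L }
  P <- matrix(0, nrow = m, ncol = ncol(X))
  u <- 1L
  for (r in seq_len(kr)) {
    for (c in seq_len(kc)) {
      P[u, ] <- mu +
        (if (d1 == 1L) ar[r] else ac[c]) * 2 * sds[1L] * dirs[, 1L] +
        (if (d2 == 1L) ar[r] else ac[c]) * 2 * sds[2L] * dirs[, 2L]
      u <- u + 1L
    }
  }
  P
}

#' Train the joint self-organizing map
#'
#' Batch Kohonen training of all genes of the joint matrix onto a metagene
#' grid.  Units are initialized on the plane of the first two principal
#' components of the gene cloud; training runs a rough phase (neighbourhood
#' radius max(K)/2 shrinking to 3) followed by a fine phase (3 shrinking to
#' 0.5) with a smooth Gaussian neighbourhood of width radius/2, so the final
#' epochs reduce to k-means updates.  Each epoch reassigns every gene to its
#' best-matching unit by Euclidean distance and replaces prototypes by
#' neighbourhood-weighted means; the quantization error (mean Euclidean
#' distance to the best-matching unit) is logged per epoch.  Training is
#' deterministic given the input.
#'
#' @param joint A `JointMatrix` from [preprocess_dataset()].
#' @param config An [ml_config()]; `grid_size`, `rough_epochs` and
#'   `fine_epochs` are used here.
#' @return An object of class `SOMModel`: `dim` (grid rows, columns),
#'   `coords` (units x 2, 0-based, row-major), `prototypes`
#'   (units x samples), `assignment` (named unit index per gene),
#'   `training_log` (epoch, phase, radius, qe), `final_qe`, and the sample
#'   metadata carried over from the joint matrix.
#' @export
train_som <- function(joint, config = ml_config()) {
  stopifnot(inherits(joint, "JointMatrix"), inherits(config, "ml_config"))
  X <- joint$values
  if (nrow(X) == 0L || ncol(X) == 0L) stop("joint matrix is empty")
  if (!all(is.finite(X))) stop("joint matrix contains non-finite values")
  gd <- config$grid_size
  kr <- gd[1L]; kc <- if (length(gd) == 2L) gd[2L] else gd[1L]
  m <- kr * kc
  if (nrow(X) < m / 10)
    warning("only ", nrow(X), " genes for ", m,
            " metagenes; grid may be underpopulated")
  coords <- cbind(r = rep(0:(kr - 1L), each = kc),
                  c = rep(0:(kc - 1L), times = kr))
  G2 <- as.matrix(dist(coords))^2
  rmax <- max(max(kr, kc) / 2, 0.5)
  rmid <- min(3, rmax)
  radii <- c(seq(rmax, rmid, length.out = config$rough_epochs),
             seq(rmid, 0.5, length.out = config$fine_epochs))
  fit <- .som_batch_cpp(X, .som_init(X, kr, kc), G2, radii)
  prototypes <- fit$prototypes
  dimnames(prototypes) <- list(NULL, colnames(X))
  assignment <- structure(as.integer(fit$bmu), names = rownames(X))
  log_df <- data.frame(
    epoch = seq_along(radii),
    phase = rep(c("rough", "fine"),
                c(config$rough_epochs, config$fine_epochs)),
    radius = radii,
    qe = fit$qe)
  structure(list(dim = c(kr, kc), coords = coords, prototypes = prototypes,
                 assignment = assignment, training_log = log_df,
                 final_qe = fit$final_qe, genes = rownames(X),
                 samples = colnames(X), layer = joint$layer,
                 sample_group = joint$sample_group,
                 sample_subgroup = joint$sample_subgroup,
                 roles = joint$roles, config = config),
            class = "SOMModel")
}

#' @export
print.SOMModel <- function(x, ...) {
  cat("SOMModel: ", x$dim[1L], " x ", x$dim[2L], " metagenes, ",
      length(x$genes), " genes, ", length(x$samples),
      " samples over ", length(unique(x$layer)), " layer(s); final QE ",
      format(x$final_qe, digits = 4L), "\n", sep = "")
  invisible(x)
}

#' Metagene portrait of a sample or group
#'
#' The grid-shaped image of metagene expression for one sample (each unit's
#' prototype entry for that sample) or for a group of samples (the
#' element-wise mean of the member portraits).
#'
#' @param model A trained `SOMModel`.
#' @param samples Character vector of sample identifiers.
#' @param owner Label for the portrait; defaults to the sample name(s).
#' @return An object of class `Portrait` with fields `owner` and `values`
#'   (a grid-rows x grid-columns matrix).
#' @export
portrait <- function(model, samples, owner = NULL) {
  stopifnot(inherits(model, "SOMModel"))
  unknown <- setdiff(samples, model$samples)
  if (length(unknown))
    stop("unknown sample(s): ", paste(head(unknown, 5L), collapse = ", "))
  v <- rowMeans(model$prototypes[, samples, drop = FALSE])
  if (is.null(owner))
    owner <- if (length(samples) == 1L) samples else
      paste0("group(", length(samples), ")")
  structure(list(owner = owner,
                 values = matrix(v, nrow = model$dim[1L],
                                 ncol = model$dim[2L], byrow = TRUE)),
            class = "Portrait")
}

#' @export
print.Portrait <- function(x, ...) {
  cat("Portrait '", x$owner, "': ", nrow(x$values), " x ", ncol(x$values),
      " metagenes, range [", sprintf("%.3f", min(x$values)), ", ",
      sprintf("%.3f", max(x$values)), "]\n", sep = "")
  invisible(x)
}

# Enumerate the group portraits of a model: one portrait per
# layer x group x subgroup combination present in the sample metadata.
#' Group portraits for every layer/group/subgroup combination
#'
#' @param model A trained `SOMModel`.
#' @return Named list of `Portrait`s; names are
#'   `layer.group` or `layer.group.subgroup`.
#' @export
group_portraits <- function(model) {
  sub <- model$sample_subgroup
  sub[is.na(sub)] <- ""
  key <- paste(model$layer, model$sample_group,
               ifelse(nzchar(sub), sub, ""), sep = ".")
  key <- sub("\\.$", "", key)
  groups <- split(model$samples, key)
  out <- lapply(names(groups), function(k)
    portrait(model, groups[[k]], owner = k))
  names(out) <- names(groups)
  out
}

#' Supporting maps of a trained model
#'
#' Population (genes per metagene), prototype variance across samples, and
#' the overexpression frequency (in how many of the supplied spot masks each
#' unit is flagged).
#'
#' @param model A trained `SOMModel`.
#' @param spot_masks Optional list of logical grid matrices (e.g. from
#'   [overexpression_mask()]).
#' @return An object of class `SupportMaps` with matrices `population`,
#'   `variance` and `overexpression_frequency`.
#' @export
support_maps <- function(model, spot_masks = NULL) {
  stopifnot(inherits(model, "SOMModel"))
  m <- prod(model$dim)
  pop <- tabulate(model$assignment, nbins = m)
  va <- apply(model$prototypes, 1L, var)
  shape <- function(v) matrix(v, nrow = model$dim[1L], ncol = model$dim[2L],
                              byrow = TRUE)
  freq <- if (is.null(spot_masks) || !length(spot_masks))
    shape(rep(0L, m)) else Reduce(`+`, lapply(spot_masks, function(x) x * 1L))
  structure(list(population = shape(pop), variance = shape(va),
                 overexpression_frequency = freq),
            class = "SupportMaps")
}

#' Plot a portrait in the blue-white-red convention
#'
#' Symmetric colour scale centred at zero: blue underexpression, red
#' overexpression.
#'
#' @param p A `Portrait` (or any numeric matrix).
#' @param file Optional PNG path; plotted to the active device otherwise.
#' @param main Title; defaults to the portrait owner.
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_portrait <- function(p, file = NULL, main = NULL) {
  v <- if (inherits(p, "Portrait")) p$values else p
  if (is.null(main)) main <- if (inherits(p, "Portrait")) p$owner else ""
  lim <- max(abs(v), 1e-12)
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(255L)
  if (!is.null(file)) grDevices::png(file, width = 480L, height = 480L)
  graphics::image(t(v[nrow(v):1, , drop = FALSE]), col = pal,
                  zlim = c(-lim, lim), axes = FALSE, main = main)
  if (!is.null(file)) grDevices::dev.off()
  invisible(file)
}
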