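# Overexpression spot segmentation: metagenes exceeding a portrait quantile
# are flagged, flags from all group portraits are unioned into a summary map,
# and connected components of the union become labelled spots.

#' Overexpression mask of a portrait
#'
#' Flags every metagene whose value strictly exceeds the given quantile of
#' the portrait's own value distribution (type-7 linear interpolation
#' between order statistics).  With `underexpression = TRUE` the mirrored
#' criterion (strictly below the 1 - quantile level) is used instead.
#'
#' @param p A `Portrait` or numeric grid matrix.
#' @param quantile Flagging quantile in (0, 1); default 0.95.
#' @param underexpression Flag underexpressed metagenes instead.
#' @return Logical matrix of the grid shape.
#' @export
overexpression_mask <- function(p, quantile = 0.95, underexpression = FALSE) {
  v <- if (inherits(p, "Portrait")) p$values else p
  if (!all(is.finite(v))) stop("portrait contains non-finite values")
  if (quantile < 0 || quantile >= 1)
    stop("quantile must lie in [0, 1)")
  if (underexpression) {
    thr <- stats::quantile(as.vector(v), probs = 1 - quantile, type = 7L,
                           names = FALSE)
    v < thr
  } else {
    thr <- stats::quantile(as.vector(v), probs = quantile, type = 7L,
                           names = FALSE)
    v > thr
  }
}

# Spot labels: A..Z, then A1..Z1, A2.. (the production maps use A..Y and
# A1, C1, D1 style labels beyond Z).
.spot_label <- function(i) {
  if (i <= 26L) LETTERS[i]
  else paste0(LETTERS[((i - 27L) %% 26L) + 1L], (i - 27L) %/% 26L + 1L)
}

# Connected components of a logical grid under 4- or 8-connectivity, via an
# igraph over the flagged cells.  Returns an integer matrix: 0 background,
# k = component id (arbitrary order).
.label_components <- function(mask, connectivity = 8L) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cells <- which(mask, arr.ind = TRUE)
  if (!nrow(cells)) return(lab)
  id <- paste(cells[, 1L], cells[, 2L], sep = ",")
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  edges <- NULL
  for (o in offs) {
    nr <- cells[, 1L] + o[1L]; nc <- cells[, 2L] + o[2L]
    ok <- nr >= 1L & nr <= nrow(mask) & nc >= 1L & nc <= ncol(mask)
    ok[ok] <- mask[cbind(nr[ok], nc[ok])]
    if (any(ok))
      edges <- rbind(edges, cbind(id[ok], paste(nr[ok], nc[ok], sep = ",")))
  }
  g <- igraph::graph_from_data_frame(
    if (is.null(edges)) data.frame(from = character(0L), to = character(0L))
    else data.frame(from = edges[, 1L], to = edges[, 2L]),
    directed = FALSE, vertices = data.frame(name = id))
  memb <- igraph::components(g)$membership[id]
  lab[cells] <- as.integer(memb)
  lab
}

#' Overexpression summary map of a set of group portraits
#'
#' The pixelwise maximum over the group portraits: each metagene's strongest
#' overexpression across all groups.  Spots detected in the individual
#' portraits are re-detected on this map, which keeps the segmentation
#' support at the configured quantile of the whole landscape rather than
#' accumulating every portrait's own flags.
#'
#' @param portraits A list of `Portrait`s (or numeric grid matrices).
#' @return A numeric grid matrix.
#' @export
summary_map <- function(portraits) {
  if (inherits(portraits, "Portrait") || is.matrix(portraits))
    portraits <- list(portraits)
  Reduce(pmax, lapply(portraits, function(p)
    if (inherits(p, "Portrait")) p$values else p))
}

#' Segment the overexpression landscape into labelled spots
#'
#' When given portraits (the usual case), the overexpression summary map
#' (pixelwise maximum over the group portraits, [summary_map()]) is
#' thresholded at the configured quantile ([overexpression_mask()]) to form
#' the segmentation support.  When given logical masks directly, their
#' union is the support.  Connected components of the support under the
#' configured connectivity become spots; labels A, B, ... are assigned in
#' row-major order of the component centroids.  Each spot carries the genes
#' assigned to its member units and its per-sample expression profile (mean
#' prototype entry over the spot's units).
#'
#' @param masks A list of `Portrait`s, a numeric summary matrix, or a
#'   logical grid matrix / list of logical matrices.
#' @param model The trained `SOMModel` the masks were derived from.
#' @param connectivity 4 or 8 (default 8).
#' @param quantile Overexpression quantile used when portraits (or a
#'   numeric summary map) are supplied.
#' @return An object of class `SpotSet`: named list `spots` (fields `label`,
#'   `units` (r, c matrix, 1-based), `unit_index`, `genes`, `profile`), the
#'   integer `summary` map (0 = background, i = spot rank), `dim` and
#'   `connectivity`.  Zero spots is a valid result.
#' @export
segment_spots <- function(masks, model, connectivity = 8L, quantile = 0.95) {
  stopifnot(inherits(model, "SOMModel"))
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  if (inherits(masks, "Portrait") ||
      (is.matrix(masks) && is.numeric(masks)) ||
      (is.list(masks) && length(masks) &&
       (inherits(masks[[1L]], "Portrait") || is.numeric(masks[[1L]]))))
    masks <- overexpression_mask(summary_map(masks), quantile)
  if (is.matrix(masks)) masks <- list(masks)
  u <- Reduce(`|`, masks)
  if (!all(dim(u) == model$dim)) stop("mask shape does not match the grid")
  lab <- .label_components(u, connectivity)
  n <- max(lab)
  if (n == 0L) {
    .mlsom_log("no metagene exceeds the overexpression criterion; 0 spots")
    return(structure(list(spots = list(), summary = lab, dim = model$dim,
                          connectivity = connectivity), class = "SpotSet"))
  }
  cent <- t(vapply(seq_len(n), function(k) {
    cells <- which(lab == k, arr.ind = TRUE)
    c(mean(cells[, 1L]), mean(cells[, 2L]))
  }, numeric(2L)))
  ord <- order(cent[, 1L], cent[, 2L])
  kc <- model$dim[2L]
  spots <- vector("list", n)
  summary <- matrix(0L, model$dim[1L], model$dim[2L])
  for (i in seq_len(n)) {
    k <- ord[i]
    cells <- which(lab == k, arr.ind = TRUE)
    colnames(cells) <- c("r", "c")
    unit_index <- (cells[, 1L] - 1L) * kc + cells[, 2L]  # row-major
    genes <- names(model$assignment)[model$assignment %in% unit_index]
    prof <- colMeans(model$prototypes[unit_index, , drop = FALSE])
    label <- .spot_label(i)
    spots[[i]] <- structure(list(label = label, units = cells,
                                 unit_index = unit_index, genes = genes,
                                 profile = prof),
                            class = "Spot")
    summary[cells] <- i
  }
  names(spots) <- vapply(spots, `[[`, character(1L), "label")
  structure(list(spots = spots, summary = summary, dim = model$dim,
                 connectivity = connectivity), class = "SpotSet")
}

#' @export
print.SpotSet <- function(x, ...) {
  cat("SpotSet:", length(x$spots), "spot(s) on a", x$dim[1L], "x", x$dim[2L],
      "grid (connectivity", paste0(x$connectivity, ")\n"))
  for (s in x$spots)
    cat("  ", s$label, ": ", nrow(s$units), " units, ", length(s$genes),
        " genes\n", sep = "")
  invisible(x)
}

#' Spot table as a data frame
#'
#' @param spotset A `SpotSet`.
#' @return Data frame with label, unit and gene counts and centroid.
#' @export
spot_table <- function(spotset) {
  if (!length(spotset$spots))
    return(data.frame(label = character(0L), n_units = integer(0L),
                      n_genes = integer(0L), centroid_r = numeric(0L),
                      centroid_c = numeric(0L)))
  do.call(rbind, lapply(spotset$spots, function(s) data.frame(
    label = s$label, n_units = nrow(s$units), n_genes = length(s$genes),
    centroid_r = mean(s$units[, "r"]), centroid_c = mean(s$units[, "c"]),
    row.names = NULL)))
}
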