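# Spot annotation by Fisher's exact overrepresentation test and sample-wise
# gene-set Z (GSZ) scoring on the centered joint matrix.

#' Fisher exact overrepresentation p-value for a spot
#'
#' Right-tailed Fisher exact test on the 2 x 2 table (in-spot/out-spot x
#' in-set/out-set): the hypergeometric tail probability of observing at
#' least the given overlap.
#'
#' @param spot_genes,gene_set Character vectors, both subsets of `universe`.
#' @param universe Character vector of all genes under consideration.
#' @return The right-tailed p-value.
#' @export
fisher_spot_annotation <- function(spot_genes, gene_set, universe) {
  if (!length(universe)) stop("empty gene universe")
  spot_genes <- unique(spot_genes)
  gene_set <- unique(gene_set)
  out <- c(setdiff(spot_genes, universe), setdiff(gene_set, universe))
  if (length(out))
    stop("gene(s) outside the universe: ",
         paste(head(out, 5L), collapse = ", "))
  ov <- length(intersect(spot_genes, gene_set))
  phyper(ov - 1L, length(gene_set), length(universe) - length(gene_set),
         length(spot_genes), lower.tail = FALSE)
}

#' Annotate every spot against a gene-set collection
#'
#' Fisher exact overrepresentation of each set in each spot, with
#' Benjamini-Hochberg FDR computed across sets within each spot.  Set genes
#' absent from the universe are dropped (counts logged).
#'
#' @param spotset A `SpotSet`.
#' @param collection A `GeneSetCollection`.
#' @param universe Gene universe, typically the shared gene list of the
#'   dataset.
#' @param quiet Suppress log messages.
#' @return Data frame with spot, set, set size (in universe), overlap,
#'   p_value, fdr and source_tag, ordered by spot then p-value.
#' @export
annotate_spots <- function(spotset, collection, universe, quiet = FALSE) {
  stopifnot(inherits(spotset, "SpotSet"),
            inherits(collection, "GeneSetCollection"))
  sets <- lapply(collection$sets, intersect, universe)
  lost <- sum(lengths(collection$sets) - lengths(sets))
  if (lost > 0L)
    .mlsom_log("dropping ", lost,
               " gene-set member(s) absent from the universe", quiet = quiet)
  keep <- lengths(sets) > 0L
  sets <- sets[keep]
  rows <- list()
  for (s in spotset$spots) {
    sg <- intersect(s$genes, universe)
    for (nm in names(sets)) {
      rows[[length(rows) + 1L]] <- data.frame(
        spot = s$label, set = nm, set_size = length(sets[[nm]]),
        overlap = length(intersect(sg, sets[[nm]])),
        p_value = fisher_spot_annotation(sg, sets[[nm]], universe),
        fdr = NA_real_, source_tag = unname(collection$source_tag[nm]),
        row.names = NULL)
    }
  }
  if (!length(rows))
    return(data.frame(spot = character(0L), set = character(0L),
                      set_size = integer(0L), overlap = integer(0L),
                      p_value = numeric(0L), fdr = numeric(0L),
                      source_tag = character(0L)))
  res <- do.call(rbind, rows)
  for (sp in unique(res$spot)) {
    i <- res$spot == sp
    res$fdr[i] <- p.adjust(res$p_value[i], method = "BH")
  }
  res[order(res$spot, res$p_value), ]
}

#' Sample-wise gene-set Z (GSZ) score
#'
#' Standardized-mean form of the GSZ statistic on the centered joint matrix:
#' for a sample with per-gene values delta-e,
#' `z = sqrt(n_S) * (mean over set genes - mean over all genes) / SD over
#' all genes`, where `n_S` counts the set genes present in the matrix.
#' This is the simplified standardized-mean variant (no hypergeometric
#' variance correction); set members absent from the matrix are dropped.
#'
#' @param joint A `JointMatrix` (or a numeric genes x samples matrix).
#' @param gene_set Character vector of gene identifiers.
#' @param samples Samples to score; all by default.
#' @return Named numeric vector of z-scores, one per sample.
#' @export
gsz_profile <- function(joint, gene_set, samples = NULL) {
  values <- if (inherits(joint, "JointMatrix")) joint$values else joint
  if (is.null(samples)) samples <- colnames(values)
  unknown <- setdiff(samples, colnames(values))
  if (length(unknown))
    stop("unknown sample(s): ", paste(head(unknown, 5L), collapse = ", "))
  genes <- intersect(unique(gene_set), rownames(values))
  if (!length(genes)) stop("no gene of the set is present in the matrix")
  vapply(samples, function(s) {
    v <- values[, s]
    sd_all <- sd(v)
    if (sd_all == 0) stop("sample '", s, "' has zero expression SD")
    sqrt(length(genes)) * (mean(v[genes]) - mean(v)) / sd_all
  }, numeric(1L))
}

#' GSZ score matrix for a gene-set collection
#'
#' @param joint A `JointMatrix`.
#' @param collection A `GeneSetCollection`.
#' @return Numeric matrix, sets x samples.
#' @export
gsz_matrix <- function(joint, collection) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  t(vapply(collection$sets, function(g) gsz_profile(joint, g),
           numeric(length(joint$samples))))
}
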