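#' Pipeline configuration
#'
#' Bundles every tunable parameter of the portrayal pipeline with its
#' default.  Defaults mirror the production analysis: a 45 x 45 metagene
#' grid, overexpression above the 95th percentile, presence/absence calling
#' at one standard deviation, t-test calling at p < 0.05 with linear fold
#' change > 1.5, and 8-connected spot segmentation.
#'
#' @param grid_size Metagene grid size: one integer K for a K x K grid, or a
#'   length-2 integer vector (rows, columns).
#' @param overexpression_quantile Portrait quantile above which a metagene is
#'   flagged as overexpressed (strict inequality), in (0, 1).
#' @param sd_multiplier Multiplier on the layer metagene SD used by
#'   presence/absence calling.
#' @param ttest_alpha Significance level of the t-test call.
#' @param fc_threshold Linear fold-change gate of the t-test call (> 1);
#'   applied two-sidedly (> threshold or < 1/threshold).
#' @param fdr_method Multiple-testing method for reported adjusted p-values
#'   (passed to [stats::p.adjust()]).
#' @param random_seed Integer seed recorded with every run.
#' @param connectivity Spot segmentation connectivity, 4 or 8.
#' @param vote Joint-vote mode: `"both"` requires agreement of the
#'   presence/absence and t-test votes (conservative AND), `"any"` fires when
#'   either fires and they do not contradict.
#' @param sigma_scope Scope of the SD used by presence/absence calling:
#'   `"layer"` (default; SD of all metagene entries over the layer's samples)
#'   or `"spot"` (SD of the spot's own metagene entries only).
#' @param welch Use Welch's unequal-variance t-test (default) rather than the
#'   pooled-variance Student form.
#' @param rough_epochs,fine_epochs Epochs of the rough (radius max(K)/2 -> 3)
#'   and fine (radius 3 -> 0.5) SOM training phases.
#' @return An object of class `ml_config` (a validated list).
#' @export
ml_config <- function(grid_size = 45L,
                      overexpression_quantile = 0.95,
                      sd_multiplier = 1.0,
                      ttest_alpha = 0.05,
                      fc_threshold = 1.5,
                      fdr_method = "BH",
                      random_seed = 1L,
                      connectivity = 8L,
                      vote = c("both", "any"),
                      sigma_scope = c("layer", "spot"),
                      welch = TRUE,
                      rough_epochs = 20L,
                      fine_epochs = 30L) {
  vote <- match.arg(vote)
  sigma_scope <- match.arg(sigma_scope)
  grid_size <- as.integer(grid_size)
  if (!length(grid_size) %in% c(1L, 2L) || any(grid_size < 1L))
    stop("grid_size must be one or two positive integers")
  if (!is.numeric(overexpression_quantile) ||
      overexpression_quantile <= 0 || overexpression_quantile >= 1)
    stop("overexpression_quantile must lie strictly between 0 and 1")
  if (!is.numeric(sd_multiplier) || sd_multiplier <= 0)
    stop("sd_multiplier must be > 0")
  if (!is.numeric(ttest_alpha) || ttest_alpha <= 0 || ttest_alpha >= 1)
    stop("ttest_alpha must lie strictly between 0 and 1")
  if (!is.numeric(fc_threshold) || fc_threshold <= 1)
    stop("fc_threshold must be > 1")
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8")
  if (rough_epochs < 1L || fine_epochs < 1L)
    stop("training needs at least one epoch per phase")
  structure(list(grid_size = grid_size,
                 overexpression_quantile = overexpression_quantile,
                 sd_multiplier = sd_multiplier,
                 ttest_alpha = ttest_alpha,
                 fc_threshold = fc_threshold,
                 fdr_method = fdr_method,
                 random_seed = as.integer(random_seed),
                 connectivity = as.integer(connectivity),
                 vote = vote,
                 sigma_scope = sigma_scope,
                 welch = isTRUE(welch),
                 rough_epochs = as.integer(rough_epochs),
                 fine_epochs = as.integer(fine_epochs)),
            class = "ml_config")
}

#' @export
print.ml_config <- function(x, ...) {
  cat("mlsom configuration\n")
  for (nm in names(x)) cat("  ", nm, ": ", paste(x[[nm]], collapse = " x "),
                           "\n", sep = "")
  invisible(x)
}
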