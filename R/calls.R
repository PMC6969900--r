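# Differential spot calling per layer and contrast: a presence/absence vote
# (group-mean difference against +/- sd_multiplier * sigma of the layer's
# metagene expression) and a t-test vote (Welch t on per-sample spot means
# gated by p < alpha and linear fold change > threshold), combined into a
# joint vote.  The spots x contrasts table of calls is the perturbation
# matrix from which repositioning verdicts are read.

#' Presence/absence vote from summary statistics
#'
#' Votes `up` when the target-minus-reference mean spot expression exceeds
#' `+sd_multiplier * sigma`, `down` below the negative threshold, `none`
#' otherwise.  Symmetric: swapping target and reference flips up and down.
#'
#' @param target_mean,reference_mean Group-mean spot expression.
#' @param sigma SD of metagene expression in the corresponding layer.
#' @param sd_multiplier Threshold multiplier (default 1).
#' @return `"up"`, `"down"` or `"none"`.
#' @export
pa_vote <- function(target_mean, reference_mean, sigma, sd_multiplier = 1) {
  if (!is.finite(sigma) || sigma <= 0) {
    warning("non-positive metagene SD; presence/absence vote is 'none'")
    return("none")
  }
  d <- target_mean - reference_mean
  if (d > sd_multiplier * sigma) "up"
  else if (d < -sd_multiplier * sigma) "down"
  else "none"
}

# SD of metagene expression over the given samples: all units (scope
# "layer") or the spot's own units (scope "spot").
.metagene_sd <- function(model, samples, unit_index = NULL,
                         sigma_scope = "layer") {
  block <- if (identical(sigma_scope, "spot"))
    model$prototypes[unit_index, samples, drop = FALSE]
  else model$prototypes[, samples, drop = FALSE]
  sd(as.vector(block))
}

#' Presence/absence call for one spot and contrast
#'
#' @param spot A `Spot`.
#' @param model The trained `SOMModel`.
#' @param target,reference Disjoint, non-empty sample id vectors from one
#'   layer.
#' @param sd_multiplier Threshold multiplier.
#' @param sigma_scope `"layer"` (default) or `"spot"`, see [ml_config()].
#' @param sigma Optional explicit SD, overriding the computed one.
#' @return List with `vote`, `target_mean`, `reference_mean`, `sigma`.
#' @export
presence_absence_call <- function(spot, model, target, reference,
                                  sd_multiplier = 1,
                                  sigma_scope = c("layer", "spot"),
                                  sigma = NULL) {
  sigma_scope <- match.arg(sigma_scope)
  if (!length(target) || !length(reference))
    stop("target and reference sample sets must be non-empty")
  if (length(intersect(target, reference)))
    stop("target and reference sample sets must be disjoint")
  if (is.null(sigma)) {
    layer <- unique(model$layer[c(target, reference)])
    layer_samples <- model$samples[model$layer %in% layer]
    sigma <- .metagene_sd(model, layer_samples, spot$unit_index, sigma_scope)
  }
  tm <- mean(model$prototypes[spot$unit_index, target, drop = FALSE])
  rm_ <- mean(model$prototypes[spot$unit_index, reference, drop = FALSE])
  list(vote = pa_vote(tm, rm_, sigma, sd_multiplier),
       target_mean = tm, reference_mean = rm_, sigma = sigma)
}

#' t-test call for one spot and contrast
#'
#' Two-sample t test (Welch by default) on the per-sample spot means, with a
#' two-sided linear fold-change gate: `up` needs p < alpha and
#' fc > fc_threshold, `down` needs p < alpha and fc < 1/fc_threshold.
#' The fold change is computed on the linear scale from the log2 group-mean
#' difference.  Fewer than two samples on either side yields `none` with a
#' warning.
#'
#' @param spot A `Spot`.
#' @param target,reference Sample id vectors.
#' @param alpha Significance level.
#' @param fc_threshold Linear fold-change gate (>= 1; 1 disables the gate).
#' @param welch Use Welch's unequal-variance form (default) or pooled.
#' @return List with `vote`, `p_value`, `linear_fc`.
#' @export
ttest_call <- function(spot, target, reference, alpha = 0.05,
                       fc_threshold = 1.5, welch = TRUE) {
  x <- spot$profile[target]
  y <- spot$profile[reference]
  fc <- 2^(mean(x) - mean(y))
  if (length(x) < 2L || length(y) < 2L) {
    warning("fewer than two samples per side; t-test vote is 'none'")
    return(list(vote = "none", p_value = NA_real_, linear_fc = fc))
  }
  p <- tryCatch(t.test(x, y, var.equal = !welch)$p.value,
                error = function(e) NA_real_)
  vote <- if (is.na(p) || p >= alpha) "none"
  else if (fc > fc_threshold) "up"
  else if (fc < 1 / fc_threshold) "down"
  else "none"
  list(vote = vote, p_value = p, linear_fc = fc)
}

#' Combine the presence/absence and t-test votes
#'
#' Mode `"both"` (default) is the conservative AND: the joint direction is
#' the common value when the votes agree, `none` when they disagree or
#' either abstains.  Mode `"any"` fires when either vote fires, falling back
#' to `none` only on direct contradiction.
#'
#' @param pa,t Votes in `c("up", "down", "none")`.
#' @param mode `"both"` or `"any"`.
#' @return `"up"`, `"down"` or `"none"`.
#' @export
joint_vote <- function(pa, t, mode = c("both", "any")) {
  mode <- match.arg(mode)
  if (pa == t) return(pa)
  if (mode == "any") {
    if (pa == "none") return(t)
    if (t == "none") return(pa)
  }
  "none"
}

#' Define a contrast
#'
#' A named comparison of two disjoint sample sets within one layer.
#'
#' @param name Contrast name.
#' @param layer Layer id.
#' @param target,reference Sample id vectors.
#' @return An object of class `SpotContrast`.
#' @export
spot_contrast <- function(name, layer, target, reference) {
  if (!length(target) || !length(reference))
    stop("contrast '", name, "': target and reference must be non-empty")
  if (length(intersect(target, reference)))
    stop("contrast '", name, "': target and reference overlap")
  structure(list(name = name, layer = layer, target = target,
                 reference = reference), class = "SpotContrast")
}

#' Default contrasts: target vs reference per layer
#'
#' @param model A `SOMModel` (or `JointMatrix`) carrying sample metadata.
#' @return Named list of `SpotContrast`s, one per layer.
#' @export
enumerate_contrasts <- function(model) {
  out <- lapply(unique(model$layer), function(l) {
    s <- model$samples[model$layer == l]
    spot_contrast(paste0(l, ":target_vs_reference"), l,
                  s[model$sample_group[s] == "target"],
                  s[model$sample_group[s] == "reference"])
  })
  names(out) <- vapply(out, `[[`, character(1L), "name")
  out
}

#' Build a contrast from group/subgroup selectors
#'
#' @param model A `SOMModel` or `JointMatrix`.
#' @param name Contrast name.
#' @param layer Layer id.
#' @param target,reference Lists with optional elements `group` and
#'   `subgroup`; samples of the layer matching all given fields are selected.
#' @return A `SpotContrast`.
#' @export
contrast_from_selector <- function(model, name, layer, target, reference) {
  pick <- function(sel) {
    s <- model$samples[model$layer == layer]
    if (!length(s)) stop("contrast '", name, "': unknown layer '", layer, "'")
    if (!is.null(sel$group)) s <- s[model$sample_group[s] %in% sel$group]
    if (!is.null(sel$subgroup))
      s <- s[model$sample_subgroup[s] %in% sel$subgroup]
    s
  }
  spot_contrast(name, layer, pick(target), pick(reference))
}

#' Perturbation matrix: directional calls for every spot and contrast
#'
#' Runs the presence/absence and t-test calls for each spot under each
#' contrast and combines them into the joint direction.  Benjamini-Hochberg
#' adjusted t-test p-values are reported across spots within each contrast
#' (the raw p drives the vote).
#'
#' @param spotset A `SpotSet`.
#' @param model The trained `SOMModel`.
#' @param contrasts List of `SpotContrast`s.
#' @param config An [ml_config()].
#' @return A data frame of class `PerturbationMatrix` with one row per
#'   spot x contrast: `spot`, `contrast`, `layer`, `pa_vote`, `t_vote`,
#'   `direction`, `p_value`, `p_adjusted`, `linear_fc`.
#' @export
perturbation_matrix <- function(spotset, model, contrasts,
                                config = ml_config()) {
  stopifnot(inherits(spotset, "SpotSet"), inherits(model, "SOMModel"))
  if (inherits(contrasts, "SpotContrast")) contrasts <- list(contrasts)
  rows <- list()
  for (ct in contrasts) {
    layer_samples <- model$samples[model$layer == ct$layer]
    for (s in spotset$spots) {
      sigma <- .metagene_sd(model, layer_samples, s$unit_index,
                            config$sigma_scope)
      pa <- presence_absence_call(s, model, ct$target, ct$reference,
                                  sd_multiplier = config$sd_multiplier,
                                  sigma_scope = config$sigma_scope,
                                  sigma = sigma)
      tt <- suppressWarnings(
        ttest_call(s, ct$target, ct$reference, alpha = config$ttest_alpha,
                   fc_threshold = config$fc_threshold, welch = config$welch))
      rows[[length(rows) + 1L]] <- data.frame(
        spot = s$label, contrast = ct$name, layer = ct$layer,
        pa_vote = pa$vote, t_vote = tt$vote,
        direction = joint_vote(pa$vote, tt$vote, config$vote),
        p_value = tt$p_value, p_adjusted = NA_real_,
        linear_fc = tt$linear_fc, row.names = NULL)
    }
  }
  pm <- if (length(rows)) do.call(rbind, rows) else
    data.frame(spot = character(0L), contrast = character(0L),
               layer = character(0L), pa_vote = character(0L),
               t_vote = character(0L), direction = character(0L),
               p_value = numeric(0L), p_adjusted = numeric(0L),
               linear_fc = numeric(0L))
  for (ct_name in unique(pm$contrast)) {
    i <- pm$contrast == ct_name
    pm$p_adjusted[i] <- p.adjust(pm$p_value[i], method = config$fdr_method)
  }
  class(pm) <- c("PerturbationMatrix", "data.frame")
  pm
}

#' Repositioning verdict from a perturbation matrix
#'
#' A drug is a repositioning candidate for a disease when at least one spot
#' is antagonistically regulated between the two contrasts: up in disease
#' and down under the drug, or vice versa.  Disease-dysregulated spots the
#' drug leaves untouched are reported as `unopposed_disease_spots`.
#'
#' @param pm A `PerturbationMatrix`.
#' @param drug_contrast,disease_contrast Contrast names present in `pm`.
#' @return An object of class `RepositioningVerdict` with fields
#'   `drug_contrast`, `disease_contrast`, `antagonistic_spots` (data frame
#'   spot/disease_direction/drug_direction), `verdict`
#'   (`candidate`/`not_supported`) and `unopposed_disease_spots`.
#' @export
repositioning_call <- function(pm, drug_contrast, disease_contrast) {
  if (!nrow(pm))
    return(structure(list(
      drug_contrast = drug_contrast, disease_contrast = disease_contrast,
      antagonistic_spots = data.frame(spot = character(0L),
                                      disease_direction = character(0L),
                                      drug_direction = character(0L)),
      verdict = "not_supported",
      unopposed_disease_spots = character(0L)),
      class = "RepositioningVerdict"))
  for (ct in c(drug_contrast, disease_contrast))
    if (!ct %in% pm$contrast)
      stop("unknown contrast '", ct, "' in perturbation matrix")
  dis <- pm[pm$contrast == disease_contrast, ]
  drg <- pm[pm$contrast == drug_contrast, ]
  drug_dir <- structure(drg$direction, names = drg$spot)[dis$spot]
  drug_dir[is.na(drug_dir)] <- "none"
  antag <- (dis$direction == "up" & drug_dir == "down") |
    (dis$direction == "down" & drug_dir == "up")
  unopposed <- dis$direction != "none" & drug_dir == "none"
  structure(list(
    drug_contrast = drug_contrast, disease_contrast = disease_contrast,
    antagonistic_spots = data.frame(spot = dis$spot[antag],
                                    disease_direction = dis$direction[antag],
                                    drug_direction = drug_dir[antag],
                                    row.names = NULL),
    verdict = if (any(antag)) "candidate" else "not_supported",
    unopposed_disease_spots = dis$spot[unopposed]),
    class = "RepositioningVerdict")
}

#' @export
print.RepositioningVerdict <- function(x, ...) {
  cat("Repositioning verdict: ", x$verdict, "\n  drug:    ", x$drug_contrast,
      "\n  disease: ", x$disease_contrast, "\n", sep = "")
  if (nrow(x$antagonistic_spots)) {
    cat("  antagonistic spot(s):\n")
    for (i in seq_len(nrow(x$antagonistic_spots)))
      cat("    ", x$antagonistic_spots$spot[i], ": disease ",
          x$antagonistic_spots$disease_direction[i], ", drug ",
          x$antagonistic_spots$drug_direction[i], "\n", sep = "")
  }
  if (length(x$unopposed_disease_spots))
    cat("  unopposed disease spot(s): ",
        paste(x$unopposed_disease_spots, collapse = ", "), "\n", sep = "")
  invisible(x)
}
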