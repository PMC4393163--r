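#' Run the full sway-index classification pipeline
#'
#' End-to-end driver: compute (or accept) the trials x indices table,
#' eliminate failure-prone indices, log-transform and standardize, screen
#' normality per subject, select individual-specific candidates by
#' AIC-stepwise LDA with apparent/LOOCV error curves, select universal
#' candidates on the VM-VV plane, expand both groups by pairwise
#' correlation, validate universal candidates with the mixed-model variance
#' ratio, and (when profiles are given) correlate every index with the
#' moment of inertia.
#'
#' @param trials List of \code{\link{cop_trial}} objects, or a precomputed
#'   \code{index_table}.
#' @param profiles Optional list of \code{\link{subject_profile}} for the
#'   body-parameter correlation step.
#' @param config A \code{\link{sway_config}}.
#' @return Object of class \code{"sway_classification"} with components
#'   \code{index_table}, \code{eliminated}, \code{standardized},
#'   \code{normality}, \code{stepwise}, \code{error_curves},
#'   \code{lda_candidates}, \code{candidate_error}, \code{vmvv},
#'   \code{vmvv_candidates}, \code{corr_indiv}, \code{corr_univ},
#'   \code{decomposition}, \code{groups}, \code{dendrogram}, \code{body},
#'   \code{config}.
#' @export
sway_pipeline <- function(trials, profiles = NULL, config = sway_config()) {
  tab <- if (inherits(trials, "index_table")) trials else
    compute_index_table(trials, config)
  elim <- eliminate_failing_indices(tab, config)
  tab2 <- apply_log_transforms(elim$table)
  st <- standardize_indices(tab2)
  normality <- normality_screen(st, config)

  # discriminant step on the normally distributed indices; sporadic NAs are
  # imputed at the pooled mean (z = 0)
  zmat <- as.matrix(st$z[, normality$retained, drop = FALSE])
  n_imputed <- sum(is.na(zmat))
  if (n_imputed) {
    message(sprintf("sway_pipeline: imputing %d missing z-values at 0",
                    n_imputed))
    zmat[is.na(zmat)] <- 0
  }
  labels <- st$labels$subject_id
  stepwise <- stepwise_aic(zmat, labels, config$stepwise_direction)
  curves <- error_rate_curves(zmat, labels, stepwise$selected)
  lda_candidates <- candidate_individual_indices(curves,
                                                 config$error_rate_threshold)
  candidate_error <- error_rates(zmat, labels, lda_candidates)

  points <- vmvv(st)
  ce_indiv <- correlation_expand(st$z, lda_candidates,
                                 config$correlation_threshold)
  indiv_set <- ce_indiv$expanded
  vm_cand <- universal_candidates(points, config$vmvv_radius,
                                  exclude = indiv_set)
  ce_univ <- correlation_expand(
    st$z[, setdiff(names(st$z), indiv_set), drop = FALSE],
    vm_cand, config$correlation_threshold)

  decomp_set <- if (config$mixed_all_indices) names(st$z) else
    unique(c(vm_cand, ce_univ$added))
  decomposition <- mixed_model_decomposition(st, decomp_set)

  groups <- assemble_classification(
    lda_candidates = lda_candidates,
    corr_added_indiv = ce_indiv$added,
    vmvv_candidates = vm_cand,
    corr_added_univ = ce_univ$added,
    decomposition = decomposition,
    all_indices = names(st$z),
    ratio_threshold = config$mixed_ratio_threshold)

  dend <- cluster_dendrogram(st$z)
  body <- if (!is.null(profiles)) {
    body_correlation(st, profiles, groups,
                     level = config$body_correlation_level)
  } else NULL

  structure(list(
    index_table = tab, eliminated = elim$eliminated, standardized = st,
    normality = normality, stepwise = stepwise, error_curves = curves,
    lda_candidates = lda_candidates, candidate_error = candidate_error,
    vmvv = points, vmvv_candidates = vm_cand,
    corr_indiv = ce_indiv, corr_univ = ce_univ,
    decomposition = decomposition, groups = groups, dendrogram = dend,
    body = body, config = config
  ), class = "sway_classification")
}

#' Reclassify with different thresholds
#'
#' Re-runs only the classification geometry (VM-VV radius, correlation
#' threshold, mixed-ratio threshold) on a finished pipeline result, reusing
#' the standardized table, the discriminant candidates and any variance
#' ratios already computed; missing ratios for newly selected candidates
#' are fitted on demand.  Used for threshold-sensitivity analyses.
#'
#' @param result A \code{sway_classification}.
#' @param vmvv_radius,correlation_threshold,mixed_ratio_threshold Overrides
#'   (default: the values used in the original run).
#' @return A new \code{sway_groups} data frame.
#' @export
sway_reclassify <- function(result,
                            vmvv_radius = result$config$vmvv_radius,
                            correlation_threshold =
                              result$config$correlation_threshold,
                            mixed_ratio_threshold =
                              result$config$mixed_ratio_threshold) {
  st <- result$standardized
  ce_indiv <- correlation_expand(st$z, result$lda_candidates,
                                 correlation_threshold)
  indiv_set <- ce_indiv$expanded
  vm_cand <- universal_candidates(result$vmvv, vmvv_radius,
                                  exclude = indiv_set)
  ce_univ <- correlation_expand(
    st$z[, setdiff(names(st$z), indiv_set), drop = FALSE],
    vm_cand, correlation_threshold)
  need <- unique(c(vm_cand, ce_univ$added))
  have <- result$decomposition$index
  missing <- setdiff(need, have)
  decomposition <- result$decomposition
  if (length(missing)) {
    decomposition <- rbind(decomposition,
                           mixed_model_decomposition(st, missing))
  }
  assemble_classification(
    lda_candidates = result$lda_candidates,
    corr_added_indiv = ce_indiv$added,
    vmvv_candidates = vm_cand,
    corr_added_univ = ce_univ$added,
    decomposition = decomposition,
    all_indices = names(st$z),
    ratio_threshold = mixed_ratio_threshold)
}

#' @export
print.sway_classification <- function(x, ...) {
  g <- x$groups
  cat("<sway_classification>\n")
  cat(sprintf("  trials: %d, subjects: %d, surviving indices: %d\n",
              nrow(x$standardized$labels),
              length(unique(x$standardized$labels$subject_id)),
              nrow(g)))
  cat(sprintf("  individual-specific: %d (%s)\n",
              sum(g$group == "individual_specific"),
              paste(g$index[g$group == "individual_specific"],
                    collapse = ", ")))
  cat(sprintf("  universal: %d (%s)\n", sum(g$group == "universal"),
              paste(g$index[g$group == "universal"], collapse = ", ")))
  cat(sprintf("  candidate-set error rates: apparent %.1f%%, LOOCV %.1f%%\n",
              100 * x$candidate_error$apparent,
              100 * x$candidate_error$loocv))
  invisible(x)
}

#' @export
summary.sway_classification <- function(object, ...) {
  x <- object
  print(x)
  cat("\nStepwise AIC ordering:\n  ",
      paste(x$stepwise$selected, collapse = " > "), "\n", sep = "")
  cat("\nEliminated indices:\n")
  if (nrow(x$eliminated)) print(x$eliminated) else cat("  none\n")
  cat("\nVariance ratios (universal candidates):\n")
  print(x$decomposition[, c("index", "ratio", "method")])
  if (!is.null(x$body) && !is.null(x$body$wilcoxon)) {
    cat(sprintf("\nWilcoxon |r| universal vs individual-specific: p = %.4g\n",
                x$body$wilcoxon$p.value))
  }
  invisible(x)
}

#' Plot a sway classification
#'
#' @param x A \code{sway_classification}.
#' @param type \code{"vmvv"} (VM-VV plane with the selection radius),
#'   \code{"error_curves"} (apparent and LOOCV error versus model size) or
#'   \code{"dendrogram"}.
#' @param ... Passed to the underlying plot call.
#' @export
plot.sway_classification <- function(x, type = c("vmvv", "error_curves",
                                                 "dendrogram"), ...) {
  type <- match.arg(type)
  if (type == "vmvv") {
    pts <- x$vmvv
    g <- x$groups$group[match(pts$index, x$groups$index)]
    col <- ifelse(g == "universal", "blue",
                  ifelse(g == "individual_specific", "red", "grey40"))
    graphics::plot(pts$vm, pts$vv, type = "n", xlab = "VM", ylab = "VV", ...)
    th <- seq(0, pi / 2, length.out = 100)
    graphics::lines(x$config$vmvv_radius * cos(th),
                    x$config$vmvv_radius * sin(th), lty = 2)
    graphics::text(pts$vm, pts$vv, sub("^I", "", pts$index), col = col,
                   cex = 0.7)
  } else if (type == "error_curves") {
    cv <- x$error_curves
    graphics::plot(cv$q, 100 * cv$apparent, type = "b", pch = 16,
                   xlab = "number of indices",
                   ylab = "error rate (%)", ...)
    graphics::lines(cv$q, 100 * cv$loocv, type = "b", pch = 1, lty = 2)
    graphics::abline(h = 100 * x$config$error_rate_threshold, lty = 3)
    graphics::legend("topright", c("apparent", "LOOCV"), pch = c(16, 1),
                     lty = c(1, 2), bty = "n")
  } else {
    graphics::plot(x$dendrogram, xlab = "", sub = "",
                   ylab = "1 - r (group average)", ...)
  }
  invisible(x)
}
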