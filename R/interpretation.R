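# Correlation of index values with body parameters and the final report.

#' Correlation of indices with the moment of inertia
#'
#' Pearson correlations between each index and the standardized (zero mean,
#' unit variance across subjects) moment-of-inertia proxy mh^2.  By default
#' every trial is paired with its subject's inertia (many points per
#' subject, as in scatter-style displays); a subject-mean-level pairing is
#' available.  A two-sided Wilcoxon rank-sum test (exact for small groups)
#' compares the absolute correlations of the universal and the
#' individual-specific group.
#'
#' @param st A \code{standardized_table}.
#' @param profiles List of \code{\link{subject_profile}}.
#' @param groups A \code{sway_groups} classification (or \code{NULL} to skip
#'   the group comparison).
#' @param level \code{"trial"} or \code{"subject"}.
#' @return List of class \code{"body_correlation_report"}: \code{r} (named
#'   vector per index), \code{wilcoxon} (htest or \code{NULL}),
#'   \code{groups}.
#' @export
body_correlation <- function(st, profiles, groups = NULL,
                             level = c("trial", "subject")) {
  level <- match.arg(level)
  stopifnot(length(profiles) >= 3)
  iner <- vapply(profiles, inertia, numeric(1))
  names(iner) <- vapply(profiles, function(p) p$subject_id, character(1))
  iner_z <- (iner - mean(iner)) / stats::sd(iner)
  if (level == "trial") {
    x <- iner_z[st$labels$subject_id]
    r <- vapply(st$z, function(v) {
      suppressWarnings(stats::cor(x, v, use = "complete.obs"))
    }, numeric(1))
  } else {
    subs <- names(iner_z)
    r <- vapply(st$z, function(v) {
      m <- vapply(subs, function(s) {
        mean(v[st$labels$subject_id == s], na.rm = TRUE)
      }, numeric(1))
      suppressWarnings(stats::cor(iner_z, m, use = "complete.obs"))
    }, numeric(1))
  }
  wt <- NULL
  if (!is.null(groups)) {
    ru <- abs(r[groups$index[groups$group == "universal"]])
    ri <- abs(r[groups$index[groups$group == "individual_specific"]])
    ru <- ru[is.finite(ru)]; ri <- ri[is.finite(ri)]
    if (length(ru) >= 2 && length(ri) >= 2) {
      if (length(unique(c(ru, ri))) == 1L) {
        # all |r| identical: no evidence of a group difference
        wt <- structure(list(statistic = c(W = length(ru) * length(ri) / 2),
                             p.value = 1,
                             method = "Wilcoxon rank sum test (all tied)",
                             alternative = "two.sided",
                             data.name = "|r| universal vs individual"),
                        class = "htest")
      } else {
      exact <- length(ru) <= 25 && length(ri) <= 25 &&
        !anyDuplicated(c(ru, ri))
      wt <- suppressWarnings(stats::wilcox.test(ru, ri, exact = exact))
      }
    } else {
      warning("body_correlation: a group has fewer than 2 indices; ",
              "Wilcoxon comparison skipped")
    }
  }
  structure(list(r = r, inertia_z = iner_z, wilcoxon = wt, groups = groups,
                 level = level),
            class = "body_correlation_report")
}

#' Render the pipeline report
#'
#' Writes a machine-readable JSON and a human-readable Markdown summary of
#' a finished pipeline run: eliminated indices, normality fractions, AIC
#' ordering with error curves, the VM-VV table, variance ratios, final
#' groups with provenance, and body-parameter correlations.
#'
#' @param result A \code{sway_classification} from
#'   \code{\link{sway_pipeline}}.
#' @param dir Output directory.
#' @return Invisibly, the JSON path.
#' @export
render_report <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  groups <- result$groups
  payload <- list(
    n_trials = nrow(result$standardized$labels),
    n_subjects = length(unique(result$standardized$labels$subject_id)),
    eliminated = result$eliminated,
    normality = list(
      pass_fraction = as.list(result$normality$pass_fraction),
      retained = result$normality$retained
    ),
    stepwise = list(
      ordering = result$stepwise$selected,
      aic_trajectory = result$stepwise$aic_trajectory,
      error_curves = result$error_curves
    ),
    vmvv = result$vmvv,
    variance_ratios = result$decomposition[, c("index", "ratio", "method")],
    groups = groups,
    body_correlation = list(
      r = as.list(result$body$r),
      wilcoxon_p = if (!is.null(result$body$wilcoxon))
        result$body$wilcoxon$p.value else NULL
    )
  )
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, dataframe = "rows")
  md <- c(
    "# Sway index classification report", "",
    sprintf("Trials: %d; subjects: %d.", payload$n_trials,
            payload$n_subjects),
    "",
    "## Eliminated indices",
    if (nrow(result$eliminated)) {
      sprintf("- index %d (failure rate %.2f)", result$eliminated$index,
              result$eliminated$failure_rate)
    } else "- none",
    "",
    "## Individual-specific indices",
    sprintf("- %s (%s)", groups$index[groups$group == "individual_specific"],
            groups$provenance[groups$group == "individual_specific"]),
    "",
    "## Universal indices",
    sprintf("- %s (%s)", groups$index[groups$group == "universal"],
            groups$provenance[groups$group == "universal"]),
    "",
    "## Error rates",
    sprintf("Candidate set: apparent %.1f%%, leave-one-out %.1f%%.",
            100 * result$candidate_error$apparent,
            100 * result$candidate_error$loocv),
    "",
    "## Wilcoxon |r| comparison (universal vs individual-specific)",
    if (!is.null(result$body$wilcoxon)) {
      sprintf("p = %.4g", result$body$wilcoxon$p.value)
    } else "not performed"
  )
  writeLines(md, file.path(dir, "report.md"))
  invisible(json_path)
}
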