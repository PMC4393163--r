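# Universality screening: VM-VV geometry, correlation expansion,
# correlation-distance clustering and mixed-model variance decomposition.

#' VM-VV points for every index
#'
#' For each index, the per-subject means and variances of the z-scores are
#' computed; VM is the (n-1 divisor) variance across subjects of the
#' subject means, VV the variance across subjects of the subject variances.
#' Universal indices sit near the origin of the VM-VV plane;
#' individual-specific indices sit far out along the VM axis.
#'
#' @param st A \code{standardized_table} (or a list with \code{z} and
#'   \code{labels}).
#' @return Data frame with \code{index} (column name), \code{vm}, \code{vv}
#'   and \code{distance} = sqrt(vm^2 + vv^2).
#' @export
vmvv <- function(st) {
  subjects <- unique(st$labels$subject_id)
  stopifnot(length(subjects) >= 2)
  out <- data.frame(index = names(st$z), vm = NA_real_, vv = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_along(st$z)) {
    v <- st$z[[j]]
    means <- vars <- rep(NA_real_, length(subjects))
    for (i in seq_along(subjects)) {
      vi <- v[st$labels$subject_id == subjects[i]]
      vi <- vi[!is.na(vi)]
      if (length(vi) >= 2) {
        means[i] <- mean(vi)
        vars[i] <- stats::var(vi)
      }
    }
    ok <- !is.na(means)
    if (sum(ok) >= 2) {
      out$vm[j] <- stats::var(means[ok])
      out$vv[j] <- stats::var(vars[ok])
    }
  }
  out$distance <- sqrt(out$vm^2 + out$vv^2)
  out
}

#' Universal index candidates from the VM-VV plane
#'
#' @param points Data frame from \code{\link{vmvv}}.
#' @param radius Selection radius (default 0.35); an index is a candidate
#'   when its distance from the origin is less than or equal to the radius.
#' @param exclude Index column names already classified individual-specific.
#' @return Character vector of candidate column names.
#' @export
universal_candidates <- function(points, radius = 0.35,
                                 exclude = character(0)) {
  sel <- points$index[!is.na(points$distance) & points$distance <= radius]
  setdiff(sel, exclude)
}

#' Single-pass correlation expansion of a seed set
#'
#' Any index whose absolute Pearson correlation with any member of the seed
#' set exceeds the threshold joins the set.  The pass is not chained: newly
#' added members do not recruit further indices.
#'
#' @param z Data frame or matrix of z-scores.
#' @param seed_set Column names of the seed group.
#' @param threshold Absolute correlation threshold (default 0.8, strict
#'   inequality).
#' @return List with \code{expanded} (seed plus additions) and \code{added}.
#' @export
correlation_expand <- function(z, seed_set, threshold = 0.8) {
  z <- as.matrix(z)
  seed_set <- intersect(seed_set, colnames(z))
  others <- setdiff(colnames(z), seed_set)
  if (!length(seed_set) || !length(others)) {
    return(list(expanded = seed_set, added = character(0)))
  }
  r <- suppressWarnings(
    stats::cor(z[, others, drop = FALSE], z[, seed_set, drop = FALSE],
               use = "pairwise.complete.obs"))
  maxr <- apply(abs(r), 1, max, na.rm = TRUE)
  added <- others[is.finite(maxr) & maxr > threshold]
  list(expanded = c(seed_set, added), added = added)
}

#' Correlation-distance dendrogram of the indices
#'
#' Agglomerative clustering with group-average (UPGMA) linkage on the
#' distance 1 - r, where r is the pairwise Pearson correlation.
#'
#' @param z Data frame or matrix of z-scores.
#' @param distance \code{"one_minus_r"} (default, sign-sensitive) or
#'   \code{"one_minus_abs_r"}.
#' @return An \code{hclust} object.
#' @export
cluster_dendrogram <- function(z, distance = c("one_minus_r",
                                               "one_minus_abs_r")) {
  distance <- match.arg(distance)
  r <- suppressWarnings(stats::cor(as.matrix(z),
                                   use = "pairwise.complete.obs"))
  d <- if (distance == "one_minus_r") 1 - r else 1 - abs(r)
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Variance decomposition of indices over subject, day and time
#'
#' For each index, a linear mixed-effects model with crossed random
#' intercepts for subject, day, time-of-day and their three two-way
#' interactions is fitted by REML (non-negative variance components;
#' boundary estimates reported as 0).  If the REML fit fails, balanced-ANOVA
#' method-of-moments estimates (expected-mean-square equations, truncated at
#' zero) are used and flagged.  The key statistic is the
#' subject-to-residual variance ratio: at or below the threshold the
#' index's variability is generic rather than subject-driven.
#'
#' @param st A \code{standardized_table}.
#' @param indices Column names to decompose (default: all).
#' @param method \code{"reml"} (default) or \code{"anova"} (method of
#'   moments, exact for the balanced design).
#' @return Data frame with one row per index: the seven variance components
#'   (\code{sigma2_sub}, \code{sigma2_day}, \code{sigma2_time},
#'   \code{sigma2_sub_day}, \code{sigma2_sub_time}, \code{sigma2_day_time},
#'   \code{sigma2_e}), \code{ratio} = sigma2_sub / sigma2_e, and
#'   \code{method} actually used.
#' @export
mixed_model_decomposition <- function(st, indices = names(st$z),
                                      method = c("reml", "anova")) {
  method <- match.arg(method)
  lab <- st$labels
  sub <- factor(lab$subject_id)
  day <- factor(lab$day)
  tim <- factor(lab$time_slot)
  stopifnot(nlevels(sub) >= 2, nlevels(day) >= 2, nlevels(tim) >= 2)
  comp_names <- c("sigma2_sub", "sigma2_day", "sigma2_time",
                  "sigma2_sub_day", "sigma2_sub_time", "sigma2_day_time",
                  "sigma2_e")
  out <- data.frame(index = indices, matrix(NA_real_, length(indices),
                                            length(comp_names) + 1))
  names(out) <- c("index", comp_names, "ratio")
  out$method <- NA_character_
  df <- data.frame(sub = sub, day = day, tim = tim)
  for (i in seq_along(indices)) {
    y <- st$z[[indices[i]]]
    ok <- !is.na(y)
    comp <- NULL
    used <- method
    if (method == "reml") {
      comp <- tryCatch(
        reml_components(y[ok], df[ok, , drop = FALSE]),
        error = function(e) NULL)
      if (is.null(comp)) used <- "anova"
    }
    if (is.null(comp)) {
      comp <- anova_components(y[ok], df[ok, , drop = FALSE])
    }
    out[i, comp_names] <- comp
    out$ratio[i] <- if (comp[["sigma2_e"]] > 0) {
      comp[["sigma2_sub"]] / comp[["sigma2_e"]]
    } else Inf
    out$method[i] <- used
  }
  out
}

reml_components <- function(y, df) {
  dat <- cbind(df, y = y)
  fit <- suppressMessages(suppressWarnings(lme4::lmer(
    y ~ 1 + (1 | sub) + (1 | day) + (1 | tim) +
      (1 | sub:day) + (1 | sub:tim) + (1 | day:tim),
    data = dat, REML = TRUE,
    control = lme4::lmerControl(calc.derivs = FALSE,
                                check.conv.singular = "ignore"))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  get <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v[1] else 0
  }
  c(sigma2_sub = get("sub"), sigma2_day = get("day"),
    sigma2_time = get("tim"), sigma2_sub_day = get("sub:day"),
    sigma2_sub_time = get("sub:tim"), sigma2_day_time = get("day:tim"),
    sigma2_e = get("Residual"))
}

# Expected-mean-square estimates for the balanced crossed design
# subject x day x time with equal replication; the three-way interaction is
# pooled into the residual.  Negative solutions are truncated at zero.
anova_components <- function(y, df) {
  a <- nlevels(droplevels(df$sub))
  b <- nlevels(droplevels(df$day))
  c_ <- nlevels(droplevels(df$tim))
  n_rep <- length(y) / (a * b * c_)
  fit <- stats::aov(y ~ sub + day + tim + sub:day + sub:tim + day:tim,
                    data = cbind(df, y = y))
  ms <- summary(fit)[[1]][, "Mean Sq"]
  terms_ <- rownames(summary(fit)[[1]])
  terms_ <- trimws(terms_)
  g <- function(t) ms[match(t, terms_)]
  mse <- g("Residuals")
  s_ab <- max(0, (g("sub:day") - mse) / (c_ * n_rep))
  s_ac <- max(0, (g("sub:tim") - mse) / (b * n_rep))
  s_bc <- max(0, (g("day:tim") - mse) / (a * n_rep))
  s_a <- max(0, (g("sub") - c_ * n_rep * s_ab - b * n_rep * s_ac - mse) /
               (b * c_ * n_rep))
  s_b <- max(0, (g("day") - c_ * n_rep * s_ab - a * n_rep * s_bc - mse) /
               (a * c_ * n_rep))
  s_c <- max(0, (g("tim") - b * n_rep * s_ac - a * n_rep * s_bc - mse) /
               (a * b * n_rep))
  c(sigma2_sub = s_a, sigma2_day = s_b, sigma2_time = s_c,
    sigma2_sub_day = s_ab, sigma2_sub_time = s_ac, sigma2_day_time = s_bc,
    sigma2_e = unname(mse))
}

#' Assemble the final three-group classification
#'
#' Individual-specific indices (the discriminant candidates plus their
#' correlation additions) are fixed first; universal candidates (VM-VV
#' selection minus individual-specific, plus correlation additions to the
#' universal side) are then confirmed by the subject-to-residual variance
#' ratio; everything else is \code{other}.  Provenance of every decision is
#' recorded.
#'
#' @param lda_candidates Individual-specific candidate column names from the
#'   discriminant step.
#' @param corr_added_indiv Columns added to the individual-specific group by
#'   correlation.
#' @param vmvv_candidates Universal candidate column names from the VM-VV
#'   rule.
#' @param corr_added_univ Columns added to the universal group by
#'   correlation.
#' @param decomposition Data frame from
#'   \code{\link{mixed_model_decomposition}} covering at least the universal
#'   candidates.
#' @param all_indices All surviving index column names.
#' @param ratio_threshold Subject/residual variance ratio at or below which
#'   a universal candidate is confirmed (default 1.0).
#' @return Data frame of class \code{"sway_groups"} with \code{index},
#'   \code{group} (universal / individual_specific / other) and
#'   \code{provenance}.
#' @export
assemble_classification <- function(lda_candidates, corr_added_indiv,
                                    vmvv_candidates, corr_added_univ,
                                    decomposition, all_indices,
                                    ratio_threshold = 1.0) {
  group <- stats::setNames(rep("other", length(all_indices)), all_indices)
  prov <- stats::setNames(rep("unclassified", length(all_indices)),
                          all_indices)
  indiv <- unique(c(lda_candidates, corr_added_indiv))
  group[indiv] <- "individual_specific"
  prov[lda_candidates] <- "lda_candidate"
  prov[setdiff(corr_added_indiv, lda_candidates)] <- "correlation_added"
  univ_cand <- unique(c(vmvv_candidates, corr_added_univ))
  clash <- intersect(univ_cand, indiv)
  if (length(clash)) {
    message("assemble_classification: ",
            paste(clash, collapse = ", "),
            " in both seed sets; individual-specific wins")
    univ_cand <- setdiff(univ_cand, indiv)
  }
  for (cn in univ_cand) {
    ratio <- decomposition$ratio[decomposition$index == cn]
    if (!length(ratio) || !is.finite(ratio)) {
      prov[cn] <- "mixed_model_rejected"
      next
    }
    if (ratio <= ratio_threshold) {
      group[cn] <- "universal"
      prov[cn] <- "mixed_model_confirmed"
    } else {
      prov[cn] <- "mixed_model_rejected"
    }
  }
  out <- data.frame(index = all_indices, group = unname(group[all_indices]),
                    provenance = unname(prov[all_indices]),
                    stringsAsFactors = FALSE)
  class(out) <- c("sway_groups", class(out))
  out
}
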