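# AIC-stepwise multi-class linear discriminant analysis for selecting
# individual-specific index candidates, with apparent and leave-one-out
# error rates.

within_scatter <- function(X, cls) {
  # pooled within-class scatter and class means
  p <- nlevels(cls)
  M <- matrix(0, p, ncol(X), dimnames = list(levels(cls), colnames(X)))
  S <- matrix(0, ncol(X), ncol(X), dimnames = list(colnames(X), colnames(X)))
  for (g in levels(cls)) {
    Xg <- X[cls == g, , drop = FALSE]
    M[g, ] <- colMeans(Xg)
    S <- S + crossprod(sweep(Xg, 2, M[g, ]))
  }
  list(S = S, M = M, n = nrow(X), p = p)
}

logdet_chol <- function(A) {
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  d <- diag(ch)
  # numerically singular submatrix (e.g. a duplicated column): no valid model
  if (min(d) < 1e-7 * max(d)) return(NA_real_)
  2 * sum(log(d))
}

# Additional-information AIC for the variable subset `sel`: all candidate
# models describe the same full data, differing only in which variables
# carry class-mean information, so -2 log L reduces (up to a constant shared
# by every subset) to N log Lambda with Wilks' Lambda = |W_sel| / |T_sel|
# (within / total scatter), and each selected variable adds p - 1 free
# discriminant-mean parameters.  The empty model has AIC 0.
lda_aic_from_scatter <- function(W, T_, sel, n, p) {
  if (!length(sel)) return(0)
  q <- length(sel)
  ldW <- logdet_chol(W[sel, sel, drop = FALSE])
  ldT <- logdet_chol(T_[sel, sel, drop = FALSE])
  if (!is.finite(ldW) || !is.finite(ldT)) return(Inf)
  n * (ldW - ldT) + 2 * q * (p - 1)
}

#' Fit a pooled-covariance multi-class LDA model
#'
#' Gaussian classes share one pooled within-class covariance; points are
#' classified by the maximum linear discriminant score under equal priors,
#' so every pairwise decision boundary is a hyperplane.
#'
#' @param z Numeric matrix (trials x indices) of z-scores.
#' @param labels Subject labels (coerced to factor), one per row.
#' @param selected Column names (or indices) to use.
#' @return Object of class \code{"sway_lda"}: class means, pooled
#'   covariance, selected columns.
#' @export
fit_lda <- function(z, labels, selected = colnames(z)) {
  cls <- factor(labels)
  X <- as.matrix(z)[, selected, drop = FALSE]
  stopifnot(nlevels(cls) >= 2, all(table(cls) > ncol(X)))
  ws <- within_scatter(X, cls)
  Sigma <- ws$S / (ws$n - ws$p)
  ev_min <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 1e-10 * mean(diag(Sigma))) {
    warning("fit_lda: near-singular pooled covariance; adding ridge jitter")
    diag(Sigma) <- diag(Sigma) + 1e-8 * sum(diag(Sigma)) / ncol(Sigma)
  }
  structure(list(means = ws$M, sigma = Sigma, selected = colnames(X),
                 levels = levels(cls), n = ws$n),
            class = "sway_lda")
}

#' @export
print.sway_lda <- function(x, ...) {
  cat(sprintf("<sway_lda> %d classes, %d indices: %s\n",
              length(x$levels), length(x$selected),
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Predict subjects from a fitted LDA model
#'
#' @param object A \code{sway_lda} model.
#' @param newdata Matrix or data frame with the model's selected columns.
#' @param ... Unused.
#' @return Factor of predicted class labels.
#' @export
predict.sway_lda <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$selected, drop = FALSE]
  Sinv <- solve(object$sigma)
  W <- Sinv %*% t(object$means)                     # q x p
  b <- -0.5 * colSums(t(object$means) * W)          # p
  scores <- X %*% W + rep(b, each = nrow(X))
  factor(object$levels[max.col(scores, ties.method = "first")],
         levels = object$levels)
}

#' Forward stepwise index selection by AIC
#'
#' At each step the index giving the largest AIC decrease joins the model;
#' selection stops when no addition decreases the AIC.  Candidates that are
#' collinear with the selected set within classes (conditional within-class
#' variance below a 1e-6 fraction of their marginal variance) are skipped,
#' so perfectly redundant duplicates never enter.  Ties are broken by the
#' lower index number.  With \code{direction = "both"} each inclusion is
#' followed by a removal sweep that drops any index whose removal lowers
#' the AIC.
#'
#' @param z Numeric matrix (trials x indices) of z-scores.
#' @param labels Subject labels.
#' @param direction \code{"forward"} or \code{"both"}.
#' @return List of class \code{"sway_stepwise"}: \code{selected} (ordered
#'   column names), \code{aic_trajectory} (AIC after each inclusion),
#'   \code{aic_start} (empty-model reference), \code{aic} (final).
#' @export
stepwise_aic <- function(z, labels, direction = c("forward", "both")) {
  direction <- match.arg(direction)
  cls <- factor(labels)
  X <- as.matrix(z)
  ws <- within_scatter(X, cls)
  W <- ws$S; n <- ws$n; p <- ws$p
  Xc <- sweep(X, 2, colMeans(X))
  T_ <- crossprod(Xc)
  all_cols <- colnames(X)
  selected <- character(0)
  aic_cur <- 0  # empty model: Wilks' Lambda = 1
  trajectory <- numeric(0)
  repeat {
    remaining <- setdiff(all_cols, selected)
    if (!length(remaining)) break
    best_aic <- Inf; best_col <- NULL
    for (cn in remaining) {
      # collinearity guard: conditional total variance given the selected
      # set; a (near-)duplicate of selected columns carries no new
      # information and is skipped
      if (length(selected)) {
        t_cc <- T_[cn, cn]
        t_cs <- T_[cn, selected, drop = FALSE]
        t_ss <- T_[selected, selected, drop = FALSE]
        cond <- t_cc - t_cs %*% solve(t_ss, t(t_cs))
        if (!is.finite(cond) || cond < 1e-6 * t_cc) next
      } else if (T_[cn, cn] <= 0) next
      a <- lda_aic_from_scatter(W, T_, c(selected, cn), n, p)
      if (a < best_aic - 1e-12) { best_aic <- a; best_col <- cn }
    }
    if (is.null(best_col) || best_aic >= aic_cur) break
    selected <- c(selected, best_col)
    aic_cur <- best_aic
    trajectory <- c(trajectory, aic_cur)
    if (direction == "both" && length(selected) > 2) {
      repeat {
        drop_aics <- vapply(selected[-length(selected)], function(cn) {
          lda_aic_from_scatter(W, T_, setdiff(selected, cn), n, p)
        }, numeric(1))
        if (!length(drop_aics) || min(drop_aics) >= aic_cur) break
        rm_col <- names(drop_aics)[which.min(drop_aics)]
        selected <- setdiff(selected, rm_col)
        aic_cur <- min(drop_aics)
      }
    }
  }
  structure(list(selected = selected, aic_trajectory = trajectory,
                 aic = aic_cur),
            class = "sway_stepwise")
}

#' Exhaustive-subset AIC search (small problems)
#'
#' Evaluates every non-empty subset of the candidate columns with the same
#' AIC as \code{\link{stepwise_aic}}; used as an oracle for the greedy
#' search on problems with few indices.
#'
#' @inheritParams stepwise_aic
#' @return List with \code{selected} and \code{aic}.
#' @export
exhaustive_aic <- function(z, labels) {
  cls <- factor(labels)
  X <- as.matrix(z)
  stopifnot(ncol(X) <= 16)
  ws <- within_scatter(X, cls)
  Xc <- sweep(X, 2, colMeans(X))
  T_ <- crossprod(Xc)
  best <- 0; best_set <- character(0)  # empty model reference
  cols <- colnames(X)
  for (mask in seq_len(2^ncol(X) - 1)) {
    sel <- cols[bitwAnd(mask, 2^(seq_along(cols) - 1)) > 0]
    a <- lda_aic_from_scatter(ws$S, T_, sel, ws$n, ws$p)
    if (a < best - 1e-12) { best <- a; best_set <- sel }
  }
  list(selected = best_set, aic = best)
}

#' Apparent and leave-one-out error rates of an LDA index set
#'
#' @param z Numeric matrix of z-scores.
#' @param labels Subject labels.
#' @param selected Columns to use.
#' @return List with \code{apparent}, \code{loocv} (fractions in [0, 1])
#'   and \code{per_subject} (apparent error fraction by subject).
#' @export
error_rates <- function(z, labels, selected) {
  cls <- factor(labels)
  X <- as.matrix(z)[, selected, drop = FALSE]
  ci <- as.integer(cls) - 1L
  pred <- .lda_apparent_errors(X, ci, nlevels(cls))
  wrong <- pred != ci
  apparent <- mean(wrong)
  loocv <- .lda_loocv_errors(X, ci, nlevels(cls)) / nrow(X)
  per_subject <- tapply(wrong, cls, mean)
  list(apparent = apparent, loocv = loocv, per_subject = per_subject)
}

#' Error-rate curves over prefixes of the stepwise ordering
#'
#' @param z Numeric matrix of z-scores.
#' @param labels Subject labels.
#' @param ordering Ordered selected column names.
#' @return Data frame with \code{q}, \code{index}, \code{apparent},
#'   \code{loocv}.
#' @export
error_rate_curves <- function(z, labels, ordering) {
  out <- data.frame(q = seq_along(ordering), index = ordering,
                    apparent = NA_real_, loocv = NA_real_,
                    stringsAsFactors = FALSE)
  for (q in seq_along(ordering)) {
    er <- error_rates(z, labels, ordering[seq_len(q)])
    out$apparent[q] <- er$apparent
    out$loocv[q] <- er$loocv
  }
  out
}

#' Individual-specific candidate set from the error-rate curves
#'
#' The smallest prefix of the AIC ordering whose apparent AND leave-one-out
#' error rates both fall below the threshold; if the curves never reach the
#' threshold the full selected set is returned with a warning.
#'
#' @param curves Data frame from \code{\link{error_rate_curves}}.
#' @param threshold Error-rate threshold (default 0.10).
#' @return Character vector of column names (the candidate set).
#' @export
candidate_individual_indices <- function(curves, threshold = 0.10) {
  hit <- which(curves$apparent < threshold & curves$loocv < threshold)
  if (!length(hit)) {
    warning("candidate_individual_indices: error rates never fell below ",
            threshold, "; returning the full selected set")
    return(curves$index)
  }
  curves$index[seq_len(hit[1])]
}
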