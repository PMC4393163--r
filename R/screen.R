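# Elimination of failing indices, log transforms, pooled z-score
# standardization and per-subject Lilliefors normality screening.

#' Drop indices whose estimation-failure rate exceeds a threshold
#'
#' Reproduces the reduction of the index set before classification: any
#' index whose fraction of non-\code{ok} flags across trials exceeds
#' \code{elimination_rate} (critical-frequency and log-scale diffusion
#' critical-point indices on single-power-law-like data) is removed.
#'
#' @param table An \code{index_table}.
#' @param config A \code{\link{sway_config}}.
#' @return List with \code{table} (columns of eliminated indices removed)
#'   and \code{eliminated} (data frame of index number and failure rate).
#' @export
eliminate_failing_indices <- function(table, config = sway_config()) {
  rates <- colMeans(table$flags != "ok")
  drop <- which(rates > config$elimination_rate)
  eliminated <- data.frame(
    index = as.integer(sub("^I", "", names(rates)[drop])),
    failure_rate = unname(rates[drop])
  )
  if (length(drop)) {
    table$values <- table$values[, -drop, drop = FALSE]
    table$flags <- table$flags[, -drop, drop = FALSE]
    message(sprintf("eliminate_failing_indices: dropped %d of %d indices (%s)",
                    length(drop), length(rates),
                    paste(eliminated$index, collapse = ", ")))
  }
  list(table = table, eliminated = eliminated)
}

#' Apply log10 transforms to the conventional log-indices
#'
#' @param table An \code{index_table} with raw values.
#' @param log_set Integer index numbers to transform (default: all indices
#'   whose conventional name has a \code{log-} prefix).
#' @return The table with listed columns replaced by log10(value);
#'   non-positive values become \code{NA} with a \code{degenerate} flag.
#' @export
apply_log_transforms <- function(table, log_set = log_index_set()) {
  cols <- intersect(paste0("I", log_set), names(table$values))
  for (cn in cols) {
    v <- table$values[[cn]]
    bad <- !is.na(v) & v <= 0
    v[bad] <- NA_real_
    table$flags[[cn]][bad] <- "degenerate"
    table$values[[cn]] <- ifelse(is.na(v), NA_real_, log10(v))
  }
  table
}

#' Pooled z-score standardization
#'
#' Each index is centred and scaled by its pooled mean and standard
#' deviation over all trials of all subjects (NA values excluded pairwise
#' and propagated).
#'
#' @param table An \code{index_table} (after log transforms).
#' @return List of class \code{"standardized_table"}: \code{labels},
#'   \code{z} (data frame of z-scores), \code{center}, \code{scale}
#'   (named vectors) and \code{dropped} (indices with zero pooled SD).
#' @export
standardize_indices <- function(table) {
  z <- table$values
  center <- scale_ <- stats::setNames(rep(NA_real_, ncol(z)), names(z))
  dropped <- character(0)
  for (cn in names(z)) {
    v <- z[[cn]]
    mu <- mean(v, na.rm = TRUE)
    sdv <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(sdv) || sdv <= 0) {
      dropped <- c(dropped, cn)
      next
    }
    center[[cn]] <- mu
    scale_[[cn]] <- sdv
    z[[cn]] <- (v - mu) / sdv
  }
  if (length(dropped)) {
    message("standardize_indices: dropping zero-variance indices: ",
            paste(dropped, collapse = ", "))
    z <- z[, setdiff(names(z), dropped), drop = FALSE]
    center <- center[setdiff(names(center), dropped)]
    scale_ <- scale_[setdiff(names(scale_), dropped)]
  }
  structure(list(labels = table$labels, z = z, center = center,
                 scale = scale_, dropped = dropped),
            class = "standardized_table")
}

#' Per-subject Lilliefors normality screening
#'
#' Lilliefors' test (Kolmogorov-Smirnov with estimated mean and SD) is run
#' on each index within each subject.  An index is retained for the
#' discriminant analysis when it passes (p >= alpha) for strictly more than
#' \code{subject_fraction} of the subjects (11 or more of 15 at the
#' defaults).  Subjects contributing fewer than 4 non-missing values are
#' excluded from that index's denominator.
#'
#' @param st A \code{standardized_table}.
#' @param config A \code{\link{sway_config}}.
#' @return List of class \code{"normality_report"}: \code{p} (subjects x
#'   indices matrix of p-values), \code{h} (1 = rejected at alpha),
#'   \code{pass_fraction} (per index), \code{retained} (character column
#'   names), \code{alpha}, \code{subject_fraction}.
#' @export
normality_screen <- function(st, config = sway_config()) {
  subjects <- unique(st$labels$subject_id)
  idx <- names(st$z)
  p <- matrix(NA_real_, length(subjects), length(idx),
              dimnames = list(subjects, idx))
  for (s in subjects) {
    rows <- st$labels$subject_id == s
    for (cn in idx) {
      v <- st$z[[cn]][rows]
      v <- v[!is.na(v)]
      if (length(v) < 4L || stats::sd(v) == 0) next
      p[s, cn] <- suppressWarnings(nortest::lillie.test(v)$p.value)
    }
  }
  h <- ifelse(is.na(p), NA, as.integer(p < config$normality_alpha))
  pass_fraction <- apply(p, 2, function(col) {
    ok <- !is.na(col)
    if (!any(ok)) return(NA_real_)
    mean(col[ok] >= config$normality_alpha)
  })
  retained <- idx[!is.na(pass_fraction) &
                    pass_fraction > config$normality_subject_fraction]
  structure(list(p = p, h = h, pass_fraction = pass_fraction,
                 retained = retained, alpha = config$normality_alpha,
                 subject_fraction = config$normality_subject_fraction),
            class = "normality_report")
}
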