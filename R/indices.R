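#' Compute all 73 sway indices for one trial
#'
#' Values are raw (mm, mm/s, mm^2, s, Hz, counts, dimensionless); the log10
#' transform of the conventionally log-named indices is applied later by
#' \code{\link{apply_log_transforms}}.  Every index number 1..73 is present,
#' paired with a validity flag (\code{"ok"}, \code{"degenerate"},
#' \code{"failed_single_power_law"} or \code{"failed_critical_fit"});
#' the value is \code{NA} exactly when the flag is not \code{"ok"}.
#'
#' @param trial A \code{\link{cop_trial}} or \code{processed_trial}.
#' @param config A \code{\link{sway_config}}.
#' @return List with \code{values} (named numeric, length 73) and
#'   \code{flags} (named character, length 73).
#' @export
compute_trial_indices <- function(trial, config = sway_config()) {
  pt <- if (inherits(trial, "processed_trial")) trial else
    preprocess_trial(trial, config)
  values <- stats::setNames(rep(NA_real_, 73L), as.character(1:73))
  flags <- stats::setNames(rep("degenerate", 73L), as.character(1:73))
  put <- function(res) {
    values[names(res$values)] <<- res$values
    flags[names(res$flags)] <<- res$flags
  }
  put(positional_indices(pt))
  ell <- ellipse_indices(pt)
  put(ell)
  sp <- spectral_indices(pt, config)
  put(sp)
  put(power_indices(pt, config, sp$welch_ml, sp$welch_ap))
  put(velocity_indices(pt, ellipse_area = ell$values[["3"]]))
  put(misc_indices(pt, config))
  put(gamma_interval_indices(pt, config))
  put(sway_density_indices(pt, config))
  put(stabilogram_diffusion(pt, config)[c("values", "flags")])
  stopifnot(identical(unname(is.na(values)), unname(flags != "ok")))
  list(values = values, flags = flags)
}

#' Compute the trials x indices table
#'
#' @param trials List of \code{\link{cop_trial}} objects.
#' @param config A \code{\link{sway_config}}.
#' @param progress Print a progress message every \code{progress} trials
#'   (0 = silent).
#' @return An object of class \code{"index_table"}: \code{labels} (data frame
#'   subject_id/day/time_slot/trial), \code{values} (data frame, columns
#'   \code{I1}..\code{I73}, raw values) and \code{flags} (character data
#'   frame of the same shape).
#' @export
compute_index_table <- function(trials, config = sway_config(),
                                progress = 0) {
  n <- length(trials)
  vals <- matrix(NA_real_, n, 73L,
                 dimnames = list(NULL, paste0("I", 1:73)))
  flgs <- matrix("degenerate", n, 73L,
                 dimnames = list(NULL, paste0("I", 1:73)))
  labels <- data.frame(
    subject_id = vapply(trials, function(t) t$subject_id, character(1)),
    day = vapply(trials, function(t) t$day, integer(1)),
    time_slot = vapply(trials, function(t) t$time_slot, integer(1)),
    trial = vapply(trials, function(t) t$trial, integer(1)),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    res <- compute_trial_indices(trials[[i]], config)
    vals[i, ] <- res$values
    flgs[i, ] <- res$flags
    if (progress > 0 && i %% progress == 0) {
      message(sprintf("compute_index_table: %d/%d trials", i, n))
    }
  }
  structure(list(labels = labels, values = as.data.frame(vals),
                 flags = as.data.frame(flgs, stringsAsFactors = FALSE)),
            class = "index_table")
}

#' @export
print.index_table <- function(x, ...) {
  cat(sprintf("<index_table> %d trials x %d indices; %d values flagged\n",
              nrow(x$values), ncol(x$values), sum(x$flags != "ok")))
  invisible(x)
}
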