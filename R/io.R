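#' Write a CoP dataset to disk
#'
#' One CSV per trial (columns \code{ml_mm}, \code{ap_mm}) plus a JSON
#' manifest listing subjects (with body parameters) and trial files with
#' their design labels.  The layout is diffable and language-agnostic.
#'
#' @param trials List of \code{\link{cop_trial}} objects.
#' @param profiles List of \code{\link{subject_profile}} objects.
#' @param dir Output directory (created if missing).
#' @param provenance Free-text provenance string stored in the manifest.
#' @param seed Optional integer seed recorded in the manifest.
#' @return Invisibly, the manifest path.
#' @export
write_cop_dataset <- function(trials, profiles, dir, provenance = "",
                              seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  keys <- vapply(trials, trial_key, character(1))
  if (anyDuplicated(keys)) {
    stop("write_cop_dataset: duplicate trial labels: ",
         paste(keys[duplicated(keys)], collapse = ", "))
  }
  refs <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    fn <- sprintf("trial_%s_d%d_t%d_r%d.csv", tr$subject_id, tr$day,
                  tr$time_slot, tr$trial)
    df <- data.frame(ml_mm = tr$ml, ap_mm = tr$ap)
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     file.path(dir, fn), row.names = FALSE, quote = FALSE)
    refs[[i]] <- list(subject_id = tr$subject_id, day = tr$day,
                      time_slot = tr$time_slot, trial = tr$trial,
                      fs = tr$fs, file = fn)
  }
  manifest <- list(
    subjects = lapply(profiles, function(p) {
      list(subject_id = p$subject_id, mass_kg = p$mass_kg,
           height_m = p$height_m)
    }),
    trials = refs,
    provenance = provenance,
    seed = seed
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a CoP dataset from a manifest
#'
#' @param manifest_path Path to a \code{manifest.json} written by
#'   \code{\link{write_cop_dataset}} (or produced by hand in the same shape).
#' @return A list with \code{profiles} (list of \code{subject_profile}),
#'   \code{trials} (list of \code{cop_trial}) and \code{manifest} (the parsed
#'   manifest).
#' @export
read_cop_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("read_cop_dataset: manifest not found: ", manifest_path)
  }
  manifest <- jsonlite::read_json(manifest_path)
  dir <- dirname(manifest_path)
  profiles <- lapply(manifest$subjects, function(s) {
    subject_profile(s$subject_id, s$mass_kg, s$height_m)
  })
  trials <- vector("list", length(manifest$trials))
  keys <- character(length(manifest$trials))
  for (i in seq_along(manifest$trials)) {
    ref <- manifest$trials[[i]]
    fp <- file.path(dir, ref$file)
    if (!file.exists(fp)) stop("read_cop_dataset: trial file missing: ", fp)
    df <- utils::read.csv(fp)
    if (!all(c("ml_mm", "ap_mm") %in% names(df))) {
      stop("read_cop_dataset: ", fp, " lacks ml_mm/ap_mm columns")
    }
    bad <- which(!is.finite(df$ml_mm) | !is.finite(df$ap_mm))
    if (length(bad)) {
      stop("read_cop_dataset: non-numeric sample in ", fp, " at row ", bad[1])
    }
    trials[[i]] <- cop_trial(df$ml_mm, df$ap_mm, ref$subject_id, ref$day,
                             ref$time_slot, ref$trial,
                             fs = if (is.null(ref$fs)) 60 else ref$fs)
    keys[i] <- trial_key(trials[[i]])
  }
  if (anyDuplicated(keys)) {
    stop("read_cop_dataset: duplicate trial tuple: ",
         keys[which(duplicated(keys))[1]])
  }
  message(sprintf("read_cop_dataset: %d trials from %d subjects",
                  length(trials), length(profiles)))
  list(profiles = profiles, trials = trials, manifest = manifest)
}

#' Write an index table as CSV
#'
#' One row per trial: the four design labels followed by one column per
#' index (named \code{I1} ... \code{I73}).  Invalid values are written as
#' literal \code{NA}.
#'
#' @param table An index table from \code{\link{compute_index_table}}.
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_index_table <- function(table, path) {
  df <- table$values
  out <- cbind(table$labels, df)
  utils::write.csv(format(out, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read an index table written by \code{\link{write_index_table}}
#'
#' @param path CSV path.
#' @return An index table (list with \code{labels}, \code{values},
#'   \code{flags}); flags are reconstructed as \code{"ok"} or \code{"failed"}
#'   from the NA pattern.
#' @export
read_index_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  label_cols <- c("subject_id", "day", "time_slot", "trial")
  stopifnot(all(label_cols %in% names(df)))
  vals <- as.matrix(df[, setdiff(names(df), label_cols), drop = FALSE])
  storage.mode(vals) <- "double"
  flags <- ifelse(is.na(vals), "failed", "ok")
  structure(list(labels = df[, label_cols], values = as.data.frame(vals),
                 flags = as.data.frame(flags, stringsAsFactors = FALSE)),
            class = "index_table")
}
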