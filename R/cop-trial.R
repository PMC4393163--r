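#' A single CoP trial
#'
#' One two-channel center-of-pressure recording of quiet standing, with the
#' design labels identifying where it sits in the subjects x days x
#' times-of-day x trials layout.
#'
#' @param ml,ap Numeric vectors, CoP position (mm) along the medio-lateral
#'   and anterior-posterior axes (platform origin at the ankle axis).
#' @param subject_id Subject identifier (character).
#' @param day Day number (1-based integer).
#' @param time_slot Ordinal time of day within a day (1-based integer).
#' @param trial Trial number within the session (1-based integer).
#' @param fs Sampling frequency (Hz), 60 by default.
#' @return An object of class \code{"cop_trial"}.
#' @export
cop_trial <- function(ml, ap, subject_id, day = 1L, time_slot = 1L,
                      trial = 1L, fs = 60) {
  ml <- as.numeric(ml)
  ap <- as.numeric(ap)
  if (length(ml) != length(ap)) {
    stop("cop_trial: ML and AP channels have different lengths (",
         length(ml), " vs ", length(ap), ")")
  }
  if (length(ml) == 0L) stop("cop_trial: empty channels")
  if (!all(is.finite(ml)) || !all(is.finite(ap))) {
    stop("cop_trial: non-finite sample in trial ", subject_id, "/", day, "/",
         time_slot, "/", trial)
  }
  if (!is.numeric(fs) || fs <= 0) stop("cop_trial: fs must be > 0")
  structure(
    list(subject_id = as.character(subject_id), day = as.integer(day),
         time_slot = as.integer(time_slot), trial = as.integer(trial),
         fs = fs, ml = ml, ap = ap),
    class = "cop_trial"
  )
}

#' @export
print.cop_trial <- function(x, ...) {
  cat(sprintf("<cop_trial> subject %s day %d time %d trial %d: %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$day, x$time_slot, x$trial,
              length(x$ml), x$fs, length(x$ml) / x$fs))
  invisible(x)
}

#' Subject body parameters
#'
#' @param subject_id Subject identifier.
#' @param mass_kg Body mass in kg.
#' @param height_m Body height in m.
#' @return An object of class \code{"subject_profile"} with the derived
#'   moment-of-inertia proxy \code{inertia = mass_kg * height_m^2} (kg m^2).
#' @export
subject_profile <- function(subject_id, mass_kg, height_m) {
  stopifnot(is.numeric(mass_kg), mass_kg > 0,
            is.numeric(height_m), height_m > 0)
  structure(
    list(subject_id = as.character(subject_id),
         mass_kg = mass_kg, height_m = height_m,
         inertia = mass_kg * height_m^2),
    class = "subject_profile"
  )
}

#' Moment-of-inertia proxy of a subject
#'
#' The whole-body rotational inertia about the ankle is approximated by
#' mass times height squared.
#'
#' @param profile A \code{subject_profile}.
#' @return \code{mass_kg * height_m^2} in kg m^2.
#' @export
inertia <- function(profile) {
  stopifnot(inherits(profile, "subject_profile"))
  profile$mass_kg * profile$height_m^2
}

trial_key <- function(trial) {
  paste(trial$subject_id, trial$day, trial$time_slot, trial$trial, sep = "/")
}
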