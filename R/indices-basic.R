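# Positional, confidence-ellipse, velocity and geometric sway indices.
# All values are raw (mm, mm/s, mm^2, Hz, counts); log10 transforms of the
# "log-" indices happen later in the screening stage.

sign_changes <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s[-1] != s[-length(s)])
}

#' Positional indices (1, 2, 7, 8, 67-69)
#'
#' Channel means, mean-cross counts (sign changes of the demeaned channel)
#' and root-mean-square distances (planar radial and per channel).
#'
#' @param pt A \code{processed_trial}.
#' @return List with \code{values} and \code{flags} named by index number.
#' @export
positional_indices <- function(pt) {
  ml <- pt$ml_f; ap <- pt$ap_f
  mml <- mean(ml); map <- mean(ap)
  dml <- ml - mml; dap <- ap - map
  rms_pl <- sqrt(mean(dml^2 + dap^2))
  rms_ml <- sqrt(mean(dml^2))
  rms_ap <- sqrt(mean(dap^2))
  vals <- c(`1` = mml, `2` = map,
            `7` = as.numeric(sign_changes(dml)),
            `8` = as.numeric(sign_changes(dap)),
            `67` = rms_pl, `68` = rms_ml, `69` = rms_ap)
  flags <- stats::setNames(rep("ok", length(vals)), names(vals))
  for (k in c("67", "68", "69")) {
    if (vals[[k]] <= 0) { vals[[k]] <- NA_real_; flags[[k]] <- "degenerate" }
  }
  list(values = vals, flags = flags)
}

#' 95\% confidence ellipse indices (3, 4, 5, 6, 73)
#'
#' Eigen-decomposition of the ML/AP covariance; semi-axes
#' \code{a_i = sqrt(chi2(0.95, 2) * lambda_i)} with \code{chi2 = 5.991}.
#' Area is \code{pi * a1 * a2}; Axis1/Axis2 are the full axis lengths;
#' Angle is the absolute angle between the major axis and the ML axis folded
#' to [0, 90] degrees; Flattening is \code{(a1 - a2) / a1}.
#'
#' @param pt A \code{processed_trial}.
#' @return List with \code{values} and \code{flags}.
#' @export
ellipse_indices <- function(pt) {
  chi2 <- 5.991
  vals <- c(`3` = NA_real_, `4` = NA_real_, `5` = NA_real_,
            `6` = NA_real_, `73` = NA_real_)
  flags <- stats::setNames(rep("degenerate", 5L), names(vals))
  S <- stats::cov(cbind(pt$ml_f, pt$ap_f))
  if (!all(is.finite(S))) return(list(values = vals, flags = flags))
  e <- eigen(S, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  a1 <- sqrt(chi2 * lam[1]); a2 <- sqrt(chi2 * lam[2])
  if (a1 <= 0) return(list(values = vals, flags = flags))
  v <- e$vectors[, 1]
  ang <- abs(atan2(v[2], v[1])) * 180 / pi
  if (ang > 90) ang <- 180 - ang
  vals[["4"]] <- 2 * a1
  vals[["6"]] <- ang
  vals[["73"]] <- (a1 - a2) / a1
  flags[c("4", "6", "73")] <- "ok"
  if (a2 > 0) {
    vals[["3"]] <- pi * a1 * a2
    vals[["5"]] <- 2 * a2
    flags[c("3", "5")] <- "ok"
  }
  list(values = vals, flags = flags)
}

#' Velocity and path-length indices (15-18, 70-72)
#'
#' Velocity zero-cross counts use the additionally low-pass filtered
#' velocity; LNG is the total planar path length; MV are mean speeds.
#'
#' @param pt A \code{processed_trial}.
#' @param ellipse_area Raw 95\% ellipse area (mm^2) or \code{NA}.
#' @return List with \code{values} and \code{flags}.
#' @export
velocity_indices <- function(pt, ellipse_area = NA_real_) {
  duration <- length(pt$ml_f) / pt$fs
  steps <- sqrt(diff(pt$ml_f)^2 + diff(pt$ap_f)^2)
  lng <- sum(steps)
  vals <- c(`15` = as.numeric(sign_changes(pt$vml_lp)),
            `16` = as.numeric(sign_changes(pt$vap_lp)),
            `17` = lng,
            `18` = NA_real_,
            `70` = lng / duration,
            `71` = mean(abs(pt$vml)),
            `72` = mean(abs(pt$vap)))
  flags <- stats::setNames(rep("ok", length(vals)), names(vals))
  flags[["18"]] <- "degenerate"
  if (is.finite(ellipse_area) && ellipse_area > 0 && lng > 0) {
    vals[["18"]] <- lng / ellipse_area
    flags[["18"]] <- "ok"
  }
  if (lng <= 0) { vals[["17"]] <- vals[["70"]] <- NA_real_
                  flags[c("17", "70")] <- "degenerate" }
  if (vals[["71"]] <= 0 && flags[["71"]] == "ok") {
    vals[["71"]] <- NA_real_; flags[["71"]] <- "degenerate"
  }
  if (!is.na(vals[["72"]]) && vals[["72"]] <= 0) {
    vals[["72"]] <- NA_real_; flags[["72"]] <- "degenerate"
  }
  list(values = vals, flags = flags)
}

#' Fractal dimension, sway-area rate and mean-frequency indices (29-33)
#'
#' FD follows the classical planar estimate
#' \code{FD = log(N) / (log(N) + log(d / LNG))} with \code{d} the trajectory
#' diameter (by default approximated as twice the maximum distance from the
#' mean point).  Area-SW is the mean triangle area swept per consecutive
#' sample pair about the mean point.  MFREQ is the frequency of the circular
#' motion that would reproduce the observed mean speed at a radius equal to
#' the mean amplitude.
#'
#' @param pt A \code{processed_trial}.
#' @param config A \code{\link{sway_config}}.
#' @return List with \code{values} and \code{flags}.
#' @export
misc_indices <- function(pt, config = sway_config()) {
  ml <- pt$ml_f; ap <- pt$ap_f
  n <- length(ml)
  dml <- ml - mean(ml); dap <- ap - mean(ap)
  lng <- sum(sqrt(diff(ml)^2 + diff(ap)^2))
  r <- sqrt(dml^2 + dap^2)
  if (config$fd_exact_diameter) {
    d <- max(stats::dist(cbind(ml, ap)))
  } else {
    d <- 2 * max(r)
  }
  vals <- c(`29` = NA_real_, `30` = NA_real_, `31` = NA_real_,
            `32` = NA_real_, `33` = NA_real_)
  flags <- stats::setNames(rep("degenerate", 5L), names(vals))
  if (lng > 0 && d > 0) {
    vals[["29"]] <- log(n) / (log(n) + log(d / lng))
    flags[["29"]] <- "ok"
  }
  tri <- abs(dml[-n] * dap[-1] - dml[-1] * dap[-n]) / 2
  asw <- mean(tri)
  if (asw > 0) { vals[["30"]] <- asw; flags[["30"]] <- "ok" }
  mean_r <- mean(r)
  mv <- lng / (n / pt$fs)
  if (mean_r > 0 && mv > 0) {
    vals[["31"]] <- mv / (2 * pi * mean_r); flags[["31"]] <- "ok"
  }
  amp_ml <- mean(abs(dml)); amp_ap <- mean(abs(dap))
  if (amp_ml > 0) {
    vals[["32"]] <- mean(abs(pt$vml)) / (2 * pi * amp_ml); flags[["32"]] <- "ok"
  }
  if (amp_ap > 0) {
    vals[["33"]] <- mean(abs(pt$vap)) / (2 * pi * amp_ap); flags[["33"]] <- "ok"
  }
  list(values = vals, flags = flags)
}
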