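# Spectral sway indices: two-segment log-log PSD regression (Slope-L,
# Slope-H, Critical-freq) and band power / power frequencies (log-Power,
# PF50, PF95).

#' Two-segment power-law fit of a channel PSD (indices 9-14)
#'
#' Straight lines are regressed on log10 PSD versus log10 frequency over the
#' low band (default 0.04-0.5 Hz) and the high band (default 0.5-5 Hz); the
#' critical frequency is the abscissa of their intersection.  The fit is
#' flagged \code{failed_single_power_law} when the two slopes differ by less
#' than \code{psd_slope_margin} or the intersection falls outside the fitted
#' range, mirroring the known failure of the critical-frequency algorithm on
#' spectra with a single power-law regime.
#'
#' @param pt A \code{processed_trial}.
#' @param channel \code{"ml"} or \code{"ap"}.
#' @param config A \code{\link{sway_config}}.
#' @return List with \code{slope_low}, \code{slope_high}, \code{fcrit},
#'   \code{valid} and the underlying Welch PSD.
#' @export
psd_two_segment <- function(pt, channel = c("ml", "ap"),
                            config = sway_config()) {
  channel <- match.arg(channel)
  x <- if (channel == "ml") pt$ml_f else pt$ap_f
  if (length(x) / pt$fs < 60) stop("psd_two_segment: need >= 60 s of data")
  w <- welch_psd(x, pt$fs, config$welch_nperseg, config$welch_overlap)
  lo <- band_mask(w$freq, config$psd_low_band)
  hi <- band_mask(w$freq, config$psd_high_band)
  fit_band <- function(mask) {
    f <- w$freq[mask]; p <- w$psd[mask]
    keep <- p > 0
    if (sum(keep) < 3) return(NULL)
    line_fit(log10(f[keep]), log10(p[keep]))
  }
  clo <- fit_band(lo); chi <- fit_band(hi)
  out <- list(slope_low = NA_real_, slope_high = NA_real_,
              fcrit = NA_real_, valid = FALSE, welch = w)
  if (is.null(clo) || is.null(chi)) return(out)
  out$slope_low <- unname(clo[2]); out$slope_high <- unname(chi[2])
  db <- clo[2] - chi[2]
  if (abs(db) >= config$psd_slope_margin) {
    lf <- unname((chi[1] - clo[1]) / db)
    fc <- 10^lf
    if (is.finite(fc) && fc >= config$psd_low_band[1] &&
        fc <= config$psd_high_band[2]) {
      out$fcrit <- fc
      out$valid <- TRUE
    }
  }
  out
}

spectral_indices <- function(pt, config = sway_config()) {
  fml <- psd_two_segment(pt, "ml", config)
  fap <- psd_two_segment(pt, "ap", config)
  vals <- c(`9` = fml$slope_low, `10` = fml$slope_high,
            `11` = if (fml$valid) fml$fcrit else NA_real_,
            `12` = fap$slope_low, `13` = fap$slope_high,
            `14` = if (fap$valid) fap$fcrit else NA_real_)
  flags <- stats::setNames(rep("ok", 6L), names(vals))
  if (!fml$valid) flags[["11"]] <- "failed_single_power_law"
  if (!fap$valid) flags[["14"]] <- "failed_single_power_law"
  for (k in c("9", "10", "12", "13")) {
    if (!is.finite(vals[[k]])) { vals[[k]] <- NA_real_; flags[[k]] <- "degenerate" }
  }
  list(values = vals, flags = flags,
       welch_ml = fml$welch, welch_ap = fap$welch)
}

#' Band power and power-frequency indices (34-42)
#'
#' Total power is the integral of the PSD over the power band (default
#' 0.15-5 Hz); the planar PSD is the sum of the ML and AP PSDs.  PF50 and
#' PF95 are the smallest frequencies at which the cumulative band power
#' reaches 50\% and 95\% of the band total, with linear interpolation
#' between Welch bins.
#'
#' @param pt A \code{processed_trial}.
#' @param config A \code{\link{sway_config}}.
#' @param welch_ml,welch_ap Optional precomputed Welch PSDs (reused from the
#'   two-segment fit).
#' @return List with \code{values} and \code{flags}.
#' @export
power_indices <- function(pt, config = sway_config(),
                          welch_ml = NULL, welch_ap = NULL) {
  if (is.null(welch_ml)) {
    welch_ml <- welch_psd(pt$ml_f, pt$fs, config$welch_nperseg,
                          config$welch_overlap)
  }
  if (is.null(welch_ap)) {
    welch_ap <- welch_psd(pt$ap_f, pt$fs, config$welch_nperseg,
                          config$welch_overlap)
  }
  if (config$planar_power_sum) {
    psd_pl <- welch_ml$psd + welch_ap$psd
  } else {
    r <- sqrt((pt$ml_f - mean(pt$ml_f))^2 + (pt$ap_f - mean(pt$ap_f))^2)
    psd_pl <- welch_psd(r, pt$fs, config$welch_nperseg, config$welch_overlap)$psd
  }
  freq <- welch_ml$freq
  mask <- band_mask(freq, config$power_band)
  df <- freq[2] - freq[1]
  one <- function(psd) {
    p <- psd[mask]; f <- freq[mask]
    tot <- sum(p) * df
    if (tot <= 0) return(list(power = NA_real_, pf50 = NA_real_,
                              pf95 = NA_real_, ok = FALSE))
    cum <- cumsum(p) * df
    pf <- function(q) {
      target <- q * tot
      i <- which(cum >= target)[1]
      if (i == 1L) return(f[1])
      f[i - 1] + (f[i] - f[i - 1]) * (target - cum[i - 1]) / (cum[i] - cum[i - 1])
    }
    list(power = tot, pf50 = pf(0.5), pf95 = pf(0.95), ok = TRUE)
  }
  pl <- one(psd_pl); ml <- one(welch_ml$psd); ap <- one(welch_ap$psd)
  vals <- c(`34` = pl$power, `35` = pl$pf50, `36` = pl$pf95,
            `37` = ml$power, `38` = ml$pf50, `39` = ml$pf95,
            `40` = ap$power, `41` = ap$pf50, `42` = ap$pf95)
  flags <- stats::setNames(rep("ok", 9L), names(vals))
  if (!pl$ok) flags[c("34", "35", "36")] <- "degenerate"
  if (!ml$ok) flags[c("37", "38", "39")] <- "degenerate"
  if (!ap$ok) flags[c("40", "41", "42")] <- "degenerate"
  list(values = vals, flags = flags)
}
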