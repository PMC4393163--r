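#' Pipeline configuration
#'
#' Collects every tunable threshold and band used by the index computation
#' and classification pipeline.  Defaults follow the published analysis
#' protocol for quiet-standing CoP recordings sampled at 60 Hz for 70 s.
#'
#' @param fs Sampling frequency in Hz.
#' @param lowpass_cutoff_hz Cut-off (Hz) of the fourth-order zero-phase
#'   Butterworth filter applied to raw CoP before any index is computed.
#' @param velocity_cutoff_hz Cut-off (Hz) of the additional zero-phase filter
#'   applied to the CoP velocity before counting velocity zero crossings
#'   (indices 15/16).  Keeps the fast (0.5-1.0 Hz) component fully and the
#'   lower end of the very fast (1.0-2.5 Hz) band partially; typical
#'   reported crossing counts (~146 in 70 s, i.e. above the 2/s ceiling of
#'   a strict 1 Hz band limit) imply the effective filter passes content
#'   above 1 Hz.
#' @param gamma_use_velocity_lowpass If \code{TRUE} the Gamma interval fit
#'   (indices 19-22) uses the additionally low-pass-filtered velocity instead
#'   of the 10 Hz-filtered velocity.
#' @param psd_low_band,psd_high_band Frequency bands (Hz) for the two-segment
#'   log-log PSD regression (Slope-L / Slope-H / Critical-freq).
#' @param power_band Band (Hz) over which total power, PF50 and PF95 are
#'   evaluated.
#' @param welch_nperseg,welch_overlap Welch PSD segment length (samples) and
#'   fractional overlap.
#' @param psd_slope_margin Minimum difference between the low- and high-band
#'   slopes below which the spectrum is treated as a single power law and the
#'   critical-frequency fit is flagged as failed.
#' @param sdc_radii Radii (mm) of the sway-density circles.
#' @param sdc_peak_radius Radius (mm) at which MT3/MP3/MD3 are reported.
#' @param sdc_smooth_s Width (s) of the zero-phase moving average applied to
#'   the sway density curve before peak detection.
#' @param sdc_min_prominence Minimum peak prominence, as a fraction of the
#'   smoothed sway-density range, below which a peak/valley pair is pruned.
#' @param diff_max_lag_s Largest stabilogram-diffusion lag (s).
#' @param diff_short_window,diff_long_window Lag windows (s) for the
#'   short-term and long-term diffusion regressions.
#' @param diff_slope_margin Minimum difference between short and long log-log
#'   diffusion slopes below which the critical-point fit is flagged.
#' @param fd_exact_diameter Use the exact maximum pairwise distance for the
#'   fractal-dimension diameter instead of the O(n) proxy (twice the maximum
#'   distance from the mean point).
#' @param normality_alpha Significance level of Lilliefors' test.
#' @param normality_subject_fraction An index enters the discriminant analysis
#'   only if it passes normality for strictly more than this fraction of
#'   subjects.
#' @param elimination_rate An index whose estimation-failure rate across
#'   trials exceeds this fraction is eliminated before classification.
#' @param error_rate_threshold Apparent and LOOCV error rates must both fall
#'   below this value for the individual-specific candidate set.
#' @param vmvv_radius Distance from the origin of the VM-VV plane at or below
#'   which an index is a universal candidate.
#' @param correlation_threshold Absolute pairwise correlation above which an
#'   index joins an already-selected group.
#' @param mixed_ratio_threshold A universal candidate is confirmed when its
#'   subject-to-residual variance ratio is at or below this value.
#' @param mixed_all_indices Fit the variance decomposition for every surviving
#'   index (as in a full report) rather than only for the universal
#'   candidates needed by the classification.
#' @param planar_power_sum Use the sum of the ML and AP PSDs for planar power
#'   indices (Parseval-consistent); the alternative uses the PSD of the radial
#'   displacement.
#' @param body_correlation_level \code{"trial"} pairs every trial with its
#'   subject's inertia; \code{"subject"} uses subject means.
#' @param stepwise_direction \code{"forward"} (default) or \code{"both"}
#'   (forward with a removal sweep after each inclusion).
#'
#' @return An object of class \code{"sway_config"} (a named list).
#' @export
sway_config <- function(fs = 60,
                        lowpass_cutoff_hz = 10,
                        velocity_cutoff_hz = 1.5,
                        gamma_use_velocity_lowpass = FALSE,
                        psd_low_band = c(0.04, 0.5),
                        psd_high_band = c(0.5, 5.0),
                        power_band = c(0.15, 5.0),
                        welch_nperseg = 2048,
                        welch_overlap = 0.5,
                        psd_slope_margin = 0.4,
                        sdc_radii = c(2, 3, 4, 5),
                        sdc_peak_radius = 3,
                        sdc_smooth_s = 0.5,
                        sdc_min_prominence = 0.05,
                        diff_max_lag_s = 10,
                        diff_short_window = c(0, 1),
                        diff_long_window = c(2, 10),
                        diff_slope_margin = 0.35,
                        fd_exact_diameter = FALSE,
                        normality_alpha = 0.01,
                        normality_subject_fraction = 0.70,
                        elimination_rate = 0.10,
                        error_rate_threshold = 0.10,
                        vmvv_radius = 0.35,
                        correlation_threshold = 0.8,
                        mixed_ratio_threshold = 1.0,
                        mixed_all_indices = FALSE,
                        planar_power_sum = TRUE,
                        body_correlation_level = c("trial", "subject"),
                        stepwise_direction = c("forward", "both")) {
  cfg <- list(
    fs = fs,
    lowpass_cutoff_hz = lowpass_cutoff_hz,
    velocity_cutoff_hz = velocity_cutoff_hz,
    gamma_use_velocity_lowpass = isTRUE(gamma_use_velocity_lowpass),
    psd_low_band = psd_low_band,
    psd_high_band = psd_high_band,
    power_band = power_band,
    welch_nperseg = welch_nperseg,
    welch_overlap = welch_overlap,
    psd_slope_margin = psd_slope_margin,
    sdc_radii = sdc_radii,
    sdc_peak_radius = sdc_peak_radius,
    sdc_smooth_s = sdc_smooth_s,
    sdc_min_prominence = sdc_min_prominence,
    diff_max_lag_s = diff_max_lag_s,
    diff_short_window = diff_short_window,
    diff_long_window = diff_long_window,
    diff_slope_margin = diff_slope_margin,
    fd_exact_diameter = isTRUE(fd_exact_diameter),
    normality_alpha = normality_alpha,
    normality_subject_fraction = normality_subject_fraction,
    elimination_rate = elimination_rate,
    error_rate_threshold = error_rate_threshold,
    vmvv_radius = vmvv_radius,
    correlation_threshold = correlation_threshold,
    mixed_ratio_threshold = mixed_ratio_threshold,
    mixed_all_indices = isTRUE(mixed_all_indices),
    planar_power_sum = isTRUE(planar_power_sum),
    body_correlation_level = match.arg(body_correlation_level),
    stepwise_direction = match.arg(stepwise_direction)
  )
  class(cfg) <- "sway_config"
  validate_sway_config(cfg)
  cfg
}

validate_sway_config <- function(cfg) {
  stopifnot(
    cfg$fs > 0,
    cfg$lowpass_cutoff_hz > 0, cfg$lowpass_cutoff_hz < cfg$fs / 2,
    cfg$velocity_cutoff_hz > 0, cfg$velocity_cutoff_hz < cfg$fs / 2,
    length(cfg$psd_low_band) == 2, diff(cfg$psd_low_band) > 0,
    length(cfg$psd_high_band) == 2, diff(cfg$psd_high_band) > 0,
    length(cfg$power_band) == 2, diff(cfg$power_band) > 0,
    cfg$psd_high_band[2] < cfg$fs / 2,
    cfg$welch_nperseg > 8,
    cfg$welch_overlap >= 0, cfg$welch_overlap < 1,
    all(cfg$sdc_radii > 0),
    cfg$sdc_peak_radius %in% cfg$sdc_radii,
    cfg$sdc_smooth_s >= 0,
    cfg$sdc_min_prominence >= 0, cfg$sdc_min_prominence < 1,
    cfg$diff_max_lag_s > 0,
    cfg$diff_short_window[2] > cfg$diff_short_window[1],
    cfg$diff_long_window[2] > cfg$diff_long_window[1],
    cfg$normality_alpha > 0, cfg$normality_alpha < 1,
    cfg$normality_subject_fraction >= 0, cfg$normality_subject_fraction <= 1,
    cfg$elimination_rate >= 0, cfg$elimination_rate <= 1,
    cfg$error_rate_threshold > 0, cfg$error_rate_threshold <= 1,
    cfg$vmvv_radius > 0,
    cfg$correlation_threshold > 0, cfg$correlation_threshold <= 1,
    cfg$mixed_ratio_threshold > 0
  )
  invisible(cfg)
}

#' @export
print.sway_config <- function(x, ...) {
  cat("<sway_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
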