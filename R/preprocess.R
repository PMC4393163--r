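#' Zero-phase low-pass Butterworth filter
#'
#' Forward-backward application of a Butterworth low-pass filter (order as
#' designed per pass, net zero phase lag).  Edge transients are suppressed by
#' odd-reflection padding of length 3 x order at both ends.
#'
#' @param x Numeric series.
#' @param fs Sampling frequency (Hz).
#' @param cutoff Cut-off frequency (Hz), must be below the Nyquist frequency.
#' @param order Filter order per pass (default 4).
#' @return Filtered series, same length as \code{x}.
#' @export
lowpass_zero_phase <- function(x, fs, cutoff, order = 4) {
  stopifnot(cutoff > 0, cutoff < fs / 2, order >= 1)
  npad <- 3L * as.integer(order)
  if (length(x) <= 2L * npad) {
    stop("lowpass_zero_phase: series too short; need more than ",
         2L * npad, " samples")
  }
  ba <- butter_cached(order, cutoff / (fs / 2))
  # odd reflection about the end points
  head_pad <- 2 * x[1] - x[(npad + 1):2]
  tail_pad <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - npad)]
  xp <- c(head_pad, x, tail_pad)
  y <- .iir_filter(ba$b, ba$a, xp, ba$zi * xp[1])
  y <- rev(.iir_filter(ba$b, ba$a, rev(y), ba$zi * y[length(y)]))
  y <- y[(npad + 1):(npad + length(x))]
  if (!all(is.finite(y))) stop("lowpass_zero_phase: non-finite output")
  y
}

# Butterworth design plus the steady-state filter state of a unit-step
# input; the state initialization removes the start-up transient of each
# filtering pass (classic filtfilt edge treatment).
butter_env <- new.env(parent = emptyenv())
butter_cached <- function(order, w) {
  key <- paste(order, signif(w, 12))
  hit <- butter_env[[key]]
  if (!is.null(hit)) return(hit)
  bf <- signal::butter(order, w, type = "low")
  b <- bf$b; a <- bf$a
  nn <- length(a)
  comp <- rbind(-a[2:nn] / a[1], cbind(diag(nn - 2), 0))
  zi <- solve(diag(nn - 1) - t(comp), b[2:nn] - a[2:nn] * b[1])
  out <- list(b = b, a = a, zi = zi)
  butter_env[[key]] <- out
  out
}

#' CoP velocity by central finite differences
#'
#' Central difference on the interior, one-sided differences at the end
#' points, so the velocity series has the same length as the position series.
#'
#' @param x Position series (mm), normally the 10 Hz-filtered CoP.
#' @param fs Sampling frequency (Hz).
#' @return Velocity series (mm/s) of the same length.
#' @export
cop_velocity <- function(x, fs) {
  n <- length(x)
  stopifnot(n >= 3)
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  v[1] <- (x[2] - x[1]) * fs
  v[n] <- (x[n] - x[n - 1]) * fs
  v
}

#' Additional low-pass filter for the velocity signal
#'
#' Zero-phase Butterworth on the velocity, used before counting velocity
#' zero crossings: the cut-off (default 1 Hz) keeps the fast (0.5-1.0 Hz)
#' oscillatory component and suppresses the very fast (1.0-2.5 Hz) one.
#'
#' @inheritParams lowpass_zero_phase
#' @param v Velocity series (mm/s).
#' @export
velocity_lowpass <- function(v, fs, cutoff, order = 4) {
  lowpass_zero_phase(v, fs, cutoff, order = order)
}

#' Preprocess a CoP trial
#'
#' Applies the 10 Hz zero-phase Butterworth filter to both channels, derives
#' channel velocities by central differences, and the additionally low-pass
#' filtered velocities used for velocity zero-cross counting.
#'
#' @param trial A \code{\link{cop_trial}}.
#' @param config A \code{\link{sway_config}}.
#' @return An object of class \code{"processed_trial"}: the trial fields plus
#'   \code{ml_f}, \code{ap_f} (filtered position, mm), \code{vml}, \code{vap}
#'   (velocity, mm/s) and \code{vml_lp}, \code{vap_lp} (low-pass filtered
#'   velocity, mm/s).
#' @export
preprocess_trial <- function(trial, config = sway_config()) {
  stopifnot(inherits(trial, "cop_trial"))
  fs <- trial$fs
  ml_f <- lowpass_zero_phase(trial$ml, fs, config$lowpass_cutoff_hz)
  ap_f <- lowpass_zero_phase(trial$ap, fs, config$lowpass_cutoff_hz)
  vml <- cop_velocity(ml_f, fs)
  vap <- cop_velocity(ap_f, fs)
  vml_lp <- velocity_lowpass(vml, fs, config$velocity_cutoff_hz)
  vap_lp <- velocity_lowpass(vap, fs, config$velocity_cutoff_hz)
  structure(
    c(unclass(trial),
      list(ml_f = ml_f, ap_f = ap_f, vml = vml, vap = vap,
           vml_lp = vml_lp, vap_lp = vap_lp)),
    class = "processed_trial"
  )
}
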