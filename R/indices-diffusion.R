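# Stabilogram diffusion indices 43-66: mean-square CoP displacement versus
# time lag, with short- and long-term regressions on linear and log scales,
# diffusion coefficients and the critical point separating the two regimes.

#' Mean-square displacement of a series over a range of lags
#'
#' Computed exactly (average over all start times) using the FFT-based
#' autocorrelation identity, O(n log n).
#'
#' @param x Numeric series.
#' @param max_lag Largest lag in samples.
#' @return Numeric vector \code{msd[k]} for lags 1..max_lag.
#' @export
msd_fft <- function(x, max_lag) {
  n <- length(x)
  stopifnot(max_lag < n)
  nfft <- 2^ceiling(log2(2 * n))
  X <- stats::fft(c(x, rep(0, nfft - n)))
  ac <- Re(stats::fft(Mod(X)^2, inverse = TRUE)) / nfft
  x2 <- x^2
  cs <- cumsum(x2)
  total <- cs[n]
  k <- seq_len(max_lag)
  # sum_{i<=n-k} x_i^2  and  sum_{i>k} x_i^2
  head_sum <- cs[n - k]
  tail_sum <- total - cs[k]
  (head_sum + tail_sum - 2 * ac[k + 1]) / (n - k)
}

# least-squares straight line without the lm() overhead
line_fit <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  b <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  c(intercept = my - b * mx, slope = b)
}

fit_two_lines <- function(xx, yy, w_short, w_long) {
  m1 <- w_short[1] < xx & xx <= w_short[2]
  m2 <- w_long[1] <= xx & xx <= w_long[2]
  if (sum(m1) < 3 || sum(m2) < 3) return(NULL)
  c1 <- line_fit(xx[m1], yy[m1])
  c2 <- line_fit(xx[m2], yy[m2])
  list(a1 = unname(c1[1]), b1 = unname(c1[2]),
       a2 = unname(c2[1]), b2 = unname(c2[2]))
}

#' Stabilogram diffusion analysis of one trial
#'
#' MSD for lags up to \code{diff_max_lag_s} for the ML, AP and planar
#' (ML + AP) displacements; linear-scale regressions over the short and long
#' lag windows give diffusion coefficients (slope / 2 per channel,
#' slope / 4 planar, Brownian convention) and a critical point at the line
#' intersection; log-scale regressions give the scaling exponents and the
#' log-scale critical point.  Critical points falling outside the lag range
#' are flagged as failed, as is the log-scale critical point when the two
#' scaling exponents are closer than \code{diff_slope_margin} (a
#' single-power-law diffusion plot has no identifiable crossover).
#'
#' @param pt A \code{processed_trial}.
#' @param config A \code{\link{sway_config}}.
#' @return List with per-series lag grids, MSDs, fits and the index
#'   \code{values}/\code{flags}.
#' @export
stabilogram_diffusion <- function(pt, config = sway_config()) {
  fs <- pt$fs
  n <- length(pt$ml_f)
  if (n / fs < 60) stop("stabilogram_diffusion: need >= 60 s of data")
  max_lag <- as.integer(round(config$diff_max_lag_s * fs))
  lags_s <- seq_len(max_lag) / fs
  msd_ml <- msd_fft(pt$ml_f, max_lag)
  msd_ap <- msd_fft(pt$ap_f, max_lag)
  msd_pl <- msd_ml + msd_ap
  w_s <- config$diff_short_window
  w_l <- config$diff_long_window
  analyze <- function(msd, dscale) {
    out <- list(d_short = NA_real_, d_long = NA_real_,
                dtc_lin = NA_real_, dc_lin = NA_real_,
                slope_short = NA_real_, slope_long = NA_real_,
                dtc_log = NA_real_, dc_log = NA_real_,
                lin_valid = FALSE, log_valid = FALSE, degenerate = FALSE)
    if (any(!is.finite(msd)) || any(msd <= 0)) {
      out$degenerate <- TRUE
      return(out)
    }
    lin <- fit_two_lines(lags_s, msd, w_s, w_l)
    if (!is.null(lin)) {
      out$d_short <- lin$b1 / dscale
      out$d_long <- lin$b2 / dscale
      if (abs(lin$b1 - lin$b2) > 0) {
        t_star <- (lin$a2 - lin$a1) / (lin$b1 - lin$b2)
        if (is.finite(t_star) && t_star > 0 && t_star <= config$diff_max_lag_s) {
          out$dtc_lin <- t_star
          out$dc_lin <- lin$a1 + lin$b1 * t_star
          out$lin_valid <- TRUE
        }
      }
    }
    lg <- fit_two_lines(log10(lags_s), log10(msd), log10(pmax(w_s, 1e-12)),
                        log10(w_l))
    if (!is.null(lg)) {
      out$slope_short <- lg$b1
      out$slope_long <- lg$b2
      db <- lg$b1 - lg$b2
      if (abs(db) >= config$diff_slope_margin) {
        lt_star <- (lg$a2 - lg$a1) / db
        t_star <- 10^lt_star
        if (is.finite(t_star) && t_star > 0 && t_star <= config$diff_max_lag_s) {
          out$dtc_log <- t_star
          out$dc_log <- 10^(lg$a1 + lg$b1 * lt_star)
          out$log_valid <- TRUE
        }
      }
    }
    out
  }
  pl <- analyze(msd_pl, 4)
  ml <- analyze(msd_ml, 2)
  ap <- analyze(msd_ap, 2)
  pack <- function(a, ks) {
    # ks: index numbers in order d_short, d_long, dtc_lin, dc_lin,
    #     slope_short, slope_long, dtc_log, dc_log
    v <- c(a$d_short, a$d_long, a$dtc_lin, a$dc_lin,
           a$slope_short, a$slope_long, a$dtc_log, a$dc_log)
    names(v) <- as.character(ks)
    f <- stats::setNames(rep("ok", 8L), names(v))
    if (a$degenerate) {
      v[] <- NA_real_; f[] <- "degenerate"
    } else {
      if (!a$lin_valid) f[as.character(ks[3:4])] <- "failed_critical_fit"
      if (!a$log_valid) f[as.character(ks[7:8])] <- "failed_single_power_law"
      for (k in names(v)) {
        if (!is.finite(v[[k]]) && f[[k]] == "ok") {
          f[[k]] <- "degenerate"
        }
        if (!is.finite(v[[k]])) v[[k]] <- NA_real_
      }
    }
    list(values = v, flags = f)
  }
  r_pl <- pack(pl, c(43, 44, 45, 46, 55, 56, 57, 58))
  r_ml <- pack(ml, c(47, 48, 49, 50, 59, 60, 61, 62))
  r_ap <- pack(ap, c(51, 52, 53, 54, 63, 64, 65, 66))
  list(values = c(r_pl$values, r_ml$values, r_ap$values),
       flags = c(r_pl$flags, r_ml$flags, r_ap$flags),
       lags_s = lags_s, msd_planar = msd_pl, msd_ml = msd_ml,
       msd_ap = msd_ap)
}
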