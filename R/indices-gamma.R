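# Gamma fit of inter-zero-cross intervals of the CoP velocity profile
# (indices 19-22).  The interval distribution carries the signature of the
# fast and very fast oscillatory sway components: a dominant very fast
# oscillation produces many short intervals, hence a small scale (beta) and
# a large shape (alpha).

#' Maximum-likelihood Gamma fit
#'
#' Shape/scale parameterization (mean \code{alpha * beta}, variance
#' \code{alpha * beta^2}).  The shape is found by Newton iteration on the
#' profile likelihood score \code{log(alpha) - digamma(alpha) = s} with
#' \code{s = log(mean(x)) - mean(log(x))}, started from the classical
#' closed-form approximation; the scale is \code{mean(x) / alpha}.  If the
#' iteration fails to converge within \code{max_iter} steps the
#' moment-matching estimates are returned, flagged accordingly.
#'
#' @param x Positive observations (here: intervals in seconds).
#' @param max_iter Maximum Newton iterations.
#' @return List with \code{alpha}, \code{beta}, \code{converged},
#'   \code{n}.
#' @export
gamma_mle <- function(x, max_iter = 100) {
  stopifnot(all(x > 0))
  m <- mean(x)
  s <- log(m) - mean(log(x))
  if (!is.finite(s) || s <= 0) {
    # numerically degenerate (all values equal): no MLE
    return(list(alpha = NA_real_, beta = NA_real_, converged = FALSE,
                n = length(x)))
  }
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    g <- log(a) - digamma(a) - s
    gp <- 1 / a - trigamma(a)
    step <- g / gp
    a_new <- a - step
    if (!is.finite(a_new) || a_new <= 0) a_new <- a / 2
    if (abs(a_new - a) < 1e-10 * a) { a <- a_new; converged <- TRUE; break }
    a <- a_new
  }
  if (!converged) {
    # moment fallback
    v <- stats::var(x)
    if (!is.finite(v) || v <= 0) {
      return(list(alpha = NA_real_, beta = NA_real_, converged = FALSE,
                  n = length(x)))
    }
    a <- m^2 / v
  }
  list(alpha = a, beta = m / a, converged = converged, n = length(x))
}

velocity_zero_cross_intervals <- function(v, fs) {
  s <- sign(v)
  idx <- which(s != 0)
  s <- s[idx]
  ch <- which(s[-1] != s[-length(s)])
  if (length(ch) < 2L) return(numeric(0))
  cross_at <- idx[ch]
  diff(cross_at) / fs
}

#' Gamma interval indices (19-22)
#'
#' Intervals between consecutive zero crossings of the channel velocity
#' (10 Hz-filtered by default; the additionally low-pass filtered velocity
#' when \code{gamma_use_velocity_lowpass} is set) are fitted by maximum
#' likelihood with a Gamma distribution.  The shape parameter feeds
#' log-Alpha (indices 19/21 after the log transform) and the scale parameter
#' is Beta (indices 20/22, seconds).  Fewer than 20 intervals or
#' zero-variance intervals give a degenerate flag.
#'
#' @param pt A \code{processed_trial}.
#' @param config A \code{\link{sway_config}}.
#' @return List with \code{values} and \code{flags}.
#' @export
gamma_interval_indices <- function(pt, config = sway_config()) {
  vals <- c(`19` = NA_real_, `20` = NA_real_, `21` = NA_real_,
            `22` = NA_real_)
  flags <- stats::setNames(rep("degenerate", 4L), names(vals))
  one <- function(v, k_alpha, k_beta) {
    iv <- velocity_zero_cross_intervals(v, pt$fs)
    if (length(iv) < 20L) return(NULL)
    if (stats::var(iv) <= 0) return(NULL)
    fit <- gamma_mle(iv)
    if (!is.finite(fit$alpha) || !is.finite(fit$beta)) return(NULL)
    vals[[k_alpha]] <<- fit$alpha
    vals[[k_beta]] <<- fit$beta
    flags[c(k_alpha, k_beta)] <<- "ok"
    fit
  }
  vml <- if (config$gamma_use_velocity_lowpass) pt$vml_lp else pt$vml
  vap <- if (config$gamma_use_velocity_lowpass) pt$vap_lp else pt$vap
  one(vml, "19", "20")
  one(vap, "21", "22")
  list(values = vals, flags = flags)
}
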