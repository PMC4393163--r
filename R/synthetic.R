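# Synthetic CoP generator.  Phenomenological (spectral), not biomechanical:
# each channel is a mean offset plus three random-phase spectral components
# -- a slow power-law band, a fast (0.5-1.0 Hz) and a very fast (1.0-2.5 Hz)
# narrowband Gaussian oscillation -- plus white measurement noise.  Every
# generative parameter follows the crossed hierarchy
#   value = population mean + subject + day + time effects + trial noise,
# so the variance decomposition estimated downstream is testable against
# the configured levels, and the fast/very fast amplitudes are coupled to
# the subject's moment of inertia mh^2.

#' Hierarchical parameter specification
#'
#' @param mean Population mean.
#' @param sub,day,time,trial Standard deviations of the subject, day,
#'   time-of-day and trial-level Gaussian effects.
#' @param couple Coefficient linking the subject effect to the standardized
#'   moment of inertia (added as \code{couple * z(mh^2)}).
#' @return A named numeric vector used by \code{\link{synth_config}}.
#' @export
synth_param <- function(mean, sub = 0, day = 0, time = 0, trial = 0,
                        couple = 0) {
  c(mean = mean, sub = sub, day = day, time = time, trial = trial,
    couple = couple)
}

#' Synthetic CoP study configuration
#'
#' Defaults emulate the quiet-standing study design: 15 subjects x 3 days x
#' 5 times of day x 4 trials of 70 s at 60 Hz, male-cohort body parameters
#' (height 1.710 +/- 0.054 m, mass 66.3 +/- 9.5 kg), a population-shared
#' slow power-law component, and subject-specific, inertia-coupled fast and
#' very fast oscillatory components.  Amplitudes are in mm (log10 scale for
#' the hierarchical draws so they stay positive), frequencies in Hz.
#'
#' @param n_subjects,n_days,n_times,n_trials Design dimensions.
#' @param fs Sampling frequency (Hz).
#' @param duration_s Trial duration (s).
#' @param height_mean,height_sd,mass_mean,mass_sd Body-parameter
#'   distributions (truncated at zero by resampling).
#' @param offset_ml,offset_ap Mean CoP offsets (mm), hierarchical.
#' @param beta_slow Spectral exponent of the slow component, hierarchical.
#' @param log_amp_slow_ml,log_amp_slow_ap log10 RMS amplitude (mm) of the
#'   slow component.
#' @param f_fast Fast oscillation centre frequency (Hz, clamped to
#'   [0.5, 1.0]).
#' @param log_amp_fast_ml,log_amp_fast_ap log10 RMS amplitude of the fast
#'   component.
#' @param f_vfast Very fast oscillation centre frequency (Hz, clamped to
#'   [1.0, 2.5]).
#' @param log_amp_vfast_ml,log_amp_vfast_ap log10 RMS amplitude of the very
#'   fast component.
#' @param offset_habit_rho Correlation of the ML and AP stance-offset
#'   subject effects through a shared postural-habit (lean) factor.
#' @param beta_high Spectral exponent of the slow component's tail above
#'   the knee (the upper edge of \code{slow_band}); the two-segment shape
#'   reproduces the double power law of quiet-standing CoP spectra.
#' @param slow_band Frequency band (Hz) of the slow power-law component's
#'   low segment; its upper edge is the spectral knee.
#' @param slow_tail_max Upper frequency (Hz) of the slow component's tail.
#' @param bw_fast,bw_vfast Spectral bandwidth (Hz, Gaussian) of the fast and
#'   very fast components.
#' @param noise_sd White measurement-noise SD (mm).
#' @param seed Integer seed.
#' @return Object of class \code{"synth_config"}.
#' @export
synth_config <- function(n_subjects = 15, n_days = 3, n_times = 5,
                         n_trials = 4, fs = 60, duration_s = 70,
                         height_mean = 1.710, height_sd = 0.054,
                         mass_mean = 66.3, mass_sd = 9.5,
                         offset_ml = synth_param(0.742, sub = 6.0, day = 0.8,
                                                 time = 0.6, trial = 2.2),
                         offset_ap = synth_param(51.47, sub = 17.0, day = 2.0,
                                                 time = 1.5, trial = 5.0),
                         log_amp_common = synth_param(0, sub = 0.12,
                                                      day = 0.015,
                                                      time = 0.015,
                                                      trial = 0.04,
                                                      couple = 0.12),
                         beta_slow = synth_param(1.2, sub = 0.015, day = 0.02,
                                                 time = 0.02, trial = 0.09),
                         beta_high = synth_param(3.5, trial = 0.10),
                         log_amp_slow_ml = synth_param(log10(2.5),
                                                       day = 0.02, time = 0.01,
                                                       trial = 0.05),
                         log_amp_slow_ap = synth_param(log10(4.5),
                                                       day = 0.02, time = 0.01,
                                                       trial = 0.05),
                         f_fast = synth_param(0.85, sub = 0.10, day = 0.01,
                                              time = 0.01, trial = 0.01),
                         log_amp_fast_ml = synth_param(log10(0.8), trial = 0.03),
                         log_amp_fast_ap = synth_param(log10(1.25), trial = 0.03),
                         f_vfast = synth_param(1.8, sub = 0.45, trial = 0.02),
                         log_amp_vfast_ml = synth_param(log10(0.30),
                                                        sub = 0.14,
                                                        trial = 0.05),
                         log_amp_vfast_ap = synth_param(log10(0.40),
                                                        sub = 0.14,
                                                        trial = 0.05),
                         offset_habit_rho = 0.97,
                         slow_band = c(0.01, 0.5),
                         slow_tail_max = 5.0,
                         bw_fast = 0.07, bw_vfast = 0.15,
                         noise_sd = 0.02,
                         seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_subjects >= 1, cfg$n_days >= 1, cfg$n_times >= 1,
            cfg$n_trials >= 1, cfg$fs > 0, cfg$duration_s > 0,
            cfg$f_fast[["mean"]] >= 0.5, cfg$f_fast[["mean"]] <= 1.0,
            cfg$f_vfast[["mean"]] >= 1.0, cfg$f_vfast[["mean"]] <= 2.5,
            cfg$slow_band[1] > 0, cfg$slow_band[2] < cfg$fs / 2,
            cfg$noise_sd >= 0)
  class(cfg) <- "synth_config"
  cfg
}

# Random-phase spectral synthesis: a zero-mean series whose one-sided
# amplitude profile over the FFT grid is `amp` (arbitrary scale), rescaled
# so the EXPECTED variance is target_sd^2; realized variance fluctuates.
spectral_noise <- function(n, amp, target_sd) {
  nf <- length(amp)
  if (target_sd <= 0 || all(amp == 0)) return(numeric(n))
  g <- amp * complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf))
  X <- complex(length.out = n)
  X[2:(nf + 1)] <- g
  X[n:(n - nf + 1)] <- Conj(g)
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  expected_var <- 4 / n^2 * sum(amp^2)
  x * target_sd / sqrt(expected_var)
}

#' Draw per-subject generative parameters
#'
#' Body mass and height come from truncated normal distributions; each
#' hierarchical parameter's subject effect is drawn once per subject, with
#' the coupling term \code{couple * z(mh^2)} added for the inertia-linked
#' fast-dynamics amplitudes.
#'
#' @param cfg A \code{\link{synth_config}}.
#' @return List with \code{profiles} (subject profiles) and \code{subject}
#'   (data frame of per-subject effects, one column per parameter).
#' @export
sample_subject_parameters <- function(cfg) {
  ns <- cfg$n_subjects
  rtrunc <- function(n, mean, sd) {
    x <- stats::rnorm(n, mean, sd)
    while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
    x
  }
  height <- rtrunc(ns, cfg$height_mean, cfg$height_sd)
  mass <- rtrunc(ns, cfg$mass_mean, cfg$mass_sd)
  ids <- sprintf("S%02d", seq_len(ns))
  profiles <- mapply(subject_profile, ids, mass, height, SIMPLIFY = FALSE)
  iner <- mass * height^2
  iner_z <- if (ns > 1 && stats::sd(iner) > 0) {
    (iner - mean(iner)) / stats::sd(iner)
  } else rep(0, ns)
  pars <- synth_param_names()
  eff <- matrix(0, ns, length(pars), dimnames = list(ids, pars))
  # the stance offsets share a postural-habit factor (lean direction),
  # mirroring the clustering of the two mean-position indices
  habit <- stats::rnorm(ns)
  rho <- cfg$offset_habit_rho
  for (pn in pars) {
    p <- cfg[[pn]]
    if (pn %in% c("offset_ml", "offset_ap")) {
      eff[, pn] <- p[["sub"]] * (rho * habit +
                                   sqrt(1 - rho^2) * stats::rnorm(ns)) +
        p[["couple"]] * iner_z
    } else {
      eff[, pn] <- stats::rnorm(ns, 0, p[["sub"]]) + p[["couple"]] * iner_z
    }
  }
  list(profiles = profiles,
       subject = as.data.frame(eff),
       inertia_z = stats::setNames(iner_z, ids))
}

synth_param_names <- function() {
  c("offset_ml", "offset_ap", "log_amp_common", "beta_slow", "beta_high",
    "log_amp_slow_ml", "log_amp_slow_ap", "f_fast", "log_amp_fast_ml",
    "log_amp_fast_ap", "f_vfast", "log_amp_vfast_ml", "log_amp_vfast_ap")
}

#' Generate a synthetic CoP dataset
#'
#' Draws the crossed hierarchy of generative parameters (subject, day and
#' time effects shared appropriately across the design, trial noise per
#' recording), synthesizes every trial spectrally, and returns the trials
#' with subject profiles and the ground truth needed by parameter-recovery
#' tests: the realized per-trial parameters and the expected group of each
#' index family (universal for slow-component-driven indices,
#' individual-specific for fast/very-fast-driven and offset indices).
#'
#' @param cfg A \code{\link{synth_config}}.
#' @return List with \code{profiles}, \code{trials} (list of
#'   \code{\link{cop_trial}}), and \code{ground_truth} (list with
#'   \code{subject} effects, \code{trial_params} data frame and
#'   \code{expected_groups}).
#' @export
generate_cop_dataset <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- as.integer(round(cfg$duration_s * cfg$fs))
  nf <- (n - 1L) %/% 2L
  freq <- seq_len(nf) * cfg$fs / n
  sp <- sample_subject_parameters(cfg)
  ids <- rownames(sp$subject)
  pars <- synth_param_names()
  # shared day and time effects (crossed with subjects)
  day_eff <- sapply(pars, function(pn) {
    stats::rnorm(cfg$n_days, 0, cfg[[pn]][["day"]])
  })
  time_eff <- sapply(pars, function(pn) {
    stats::rnorm(cfg$n_times, 0, cfg[[pn]][["time"]])
  })
  day_eff <- matrix(day_eff, cfg$n_days, length(pars),
                    dimnames = list(NULL, pars))
  time_eff <- matrix(time_eff, cfg$n_times, length(pars),
                     dimnames = list(NULL, pars))
  knee <- cfg$slow_band[2]
  slow_lo <- freq >= cfg$slow_band[1] & freq <= knee
  slow_hi <- freq > knee & freq <= cfg$slow_tail_max
  trials <- list()
  rows <- list()
  k <- 0L
  for (s in seq_along(ids)) {
    for (d in seq_len(cfg$n_days)) {
      for (t in seq_len(cfg$n_times)) {
        for (r in seq_len(cfg$n_trials)) {
          k <- k + 1L
          th <- vapply(pars, function(pn) {
            cfg[[pn]][["mean"]] + sp$subject[s, pn] + day_eff[d, pn] +
              time_eff[t, pn] + stats::rnorm(1, 0, cfg[[pn]][["trial"]])
          }, numeric(1))
          th[["f_fast"]] <- min(max(th[["f_fast"]], 0.5), 1.0)
          th[["f_vfast"]] <- min(max(th[["f_vfast"]], 1.0), 2.5)
          gen_chan <- function(offset, la_slow, la_fast, la_vfast) {
            la_slow <- la_slow + th[["log_amp_common"]]
            la_fast <- la_fast + th[["log_amp_common"]]
            la_vfast <- la_vfast + th[["log_amp_common"]]
            b_lo <- th[["beta_slow"]]; b_hi <- max(th[["beta_high"]], b_lo)
            amp_slow <- numeric(length(freq))
            amp_slow[slow_lo] <- freq[slow_lo]^(-b_lo / 2)
            amp_slow[slow_hi] <- knee^(-b_lo / 2) *
              (freq[slow_hi] / knee)^(-b_hi / 2)
            amp_fast <- exp(-(freq - th[["f_fast"]])^2 /
                              (4 * cfg$bw_fast^2))
            amp_vfast <- exp(-(freq - th[["f_vfast"]])^2 /
                               (4 * cfg$bw_vfast^2))
            offset +
              spectral_noise(n, amp_slow, 10^la_slow) +
              spectral_noise(n, amp_fast, 10^la_fast) +
              spectral_noise(n, amp_vfast, 10^la_vfast) +
              stats::rnorm(n, 0, cfg$noise_sd)
          }
          ml <- gen_chan(th[["offset_ml"]], th[["log_amp_slow_ml"]],
                         th[["log_amp_fast_ml"]], th[["log_amp_vfast_ml"]])
          ap <- gen_chan(th[["offset_ap"]], th[["log_amp_slow_ap"]],
                         th[["log_amp_fast_ap"]], th[["log_amp_vfast_ap"]])
          trials[[k]] <- cop_trial(ml, ap, ids[s], d, t, r, fs = cfg$fs)
          rows[[k]] <- c(list(subject_id = ids[s], day = d, time_slot = t,
                              trial = r), as.list(th))
        }
      }
    }
  }
  trial_params <- do.call(rbind, lapply(rows, function(x) {
    as.data.frame(x, stringsAsFactors = FALSE)
  }))
  ground_truth <- list(
    subject = sp$subject,
    inertia_z = sp$inertia_z,
    day = day_eff, time = time_eff,
    trial_params = trial_params,
    expected_groups = synth_expected_groups()
  )
  list(profiles = sp$profiles, trials = trials, ground_truth = ground_truth)
}

#' Expected classification of the driven index families
#'
#' Under the generator's default structure the slow component is
#' population-shared, so spectral-slope and PF50 indices should come out
#' universal; the fast and very fast components and the stance offsets are
#' subject-specific, so mean-velocity, sway-density-peak, Gamma-interval,
#' velocity-zero-cross and mean-position indices should come out
#' individual-specific.
#'
#' @return List with \code{universal} and \code{individual_specific}
#'   character vectors of index column names.
#' @export
synth_expected_groups <- function() {
  list(
    universal = paste0("I", c(9, 12, 35, 38, 41)),
    individual_specific = paste0("I", c(1, 2, 15, 16, 19, 20, 21, 22, 24,
                                        70, 71, 72))
  )
}
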