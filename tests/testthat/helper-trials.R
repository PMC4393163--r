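# Deterministic and stochastic test trajectories used across test files.

FS <- 60
DUR <- 70
N <- FS * DUR

tgrid <- function(n = N, fs = FS) (seq_len(n) - 1) / fs

sinusoid_trial <- function(f, amp_ml = 0, amp_ap = 10, n = N, fs = FS,
                           phase = 0) {
  tt <- tgrid(n, fs)
  cop_trial(amp_ml * sin(2 * pi * f * tt + phase),
            amp_ap * sin(2 * pi * f * tt + phase),
            "T01", fs = fs)
}

circle_trial <- function(r = 5, f = 0.4, n = N, fs = FS) {
  tt <- tgrid(n, fs)
  cop_trial(r * cos(2 * pi * f * tt), r * sin(2 * pi * f * tt),
            "T01", fs = fs)
}

random_walk <- function(n, step_sd) cumsum(stats::rnorm(n, 0, step_sd))

ou_series <- function(n, fs, tau, sigma) {
  a <- exp(-1 / (fs * tau))
  innov_sd <- sigma * sqrt(1 - a^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sigma)
  for (i in 2:n) x[i] <- a * x[i - 1] + stats::rnorm(1, 0, innov_sd)
  x
}

# a processed_trial shell for feeding exact series to index operations,
# bypassing the Butterworth filter
fake_processed <- function(ml, ap, fs = FS) {
  vml <- cop_velocity(ml, fs)
  vap <- cop_velocity(ap, fs)
  structure(list(subject_id = "T01", day = 1L, time_slot = 1L, trial = 1L,
                 fs = fs, ml = ml, ap = ap, ml_f = ml, ap_f = ap,
                 vml = vml, vap = vap,
                 vml_lp = velocity_lowpass(vml, fs, 1.0),
                 vap_lp = velocity_lowpass(vap, fs, 1.0)),
            class = "processed_trial")
}

# squared magnitude response of a forward-backward 4th-order Butterworth
butter2pass_gain <- function(f, cutoff) {
  (1 / (1 + (f / cutoff)^8))
}
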