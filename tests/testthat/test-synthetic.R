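test_that("generator produces the configured design dimensions", {
  cfg <- synth_config(n_subjects = 3, n_days = 2, n_times = 2, n_trials = 2,
                      duration_s = 10, seed = 44)
  ds <- generate_cop_dataset(cfg)
  expect_length(ds$trials, 3 * 2 * 2 * 2)
  expect_length(ds$profiles, 3)
  expect_length(ds$trials[[1]]$ml, 600)
  keys <- vapply(ds$trials, function(t) {
    paste(t$subject_id, t$day, t$time_slot, t$trial)
  }, character(1))
  expect_false(anyDuplicated(keys) > 0)
  expect_equal(nrow(ds$ground_truth$trial_params), 24)
})

test_that("the same seed reproduces the dataset bit-identically", {
  cfg <- synth_config(n_subjects = 2, n_days = 1, n_times = 2, n_trials = 1,
                      duration_s = 5, seed = 45)
  d1 <- generate_cop_dataset(cfg)
  d2 <- generate_cop_dataset(cfg)
  expect_identical(d1$trials[[3]]$ml, d2$trials[[3]]$ml)
  expect_identical(d1$ground_truth$subject, d2$ground_truth$subject)
})

test_that("zero amplitudes leave constant trials at the configured offset", {
  cfg <- synth_config(
    n_subjects = 1, n_days = 1, n_times = 1, n_trials = 1, duration_s = 5,
    offset_ml = synth_param(0), offset_ap = synth_param(51.47),
    log_amp_common = synth_param(-99),
    noise_sd = 0, seed = 46)
  ds <- generate_cop_dataset(cfg)
  expect_equal(ds$trials[[1]]$ml, rep(0, 300), tolerance = 1e-8)
  expect_equal(ds$trials[[1]]$ap, rep(51.47, 300), tolerance = 1e-8)
})

test_that("slow component has the configured power-law exponent", {
  # beta = 1: periodogram log-log slope over 0.04-0.5 Hz near -1
  cfg <- synth_config(
    n_subjects = 1, n_days = 1, n_times = 1, n_trials = 50,
    beta_slow = synth_param(1.0),
    log_amp_slow_ml = synth_param(log10(3)),
    log_amp_slow_ap = synth_param(log10(3)),
    log_amp_common = synth_param(0),
    log_amp_fast_ml = synth_param(-99), log_amp_fast_ap = synth_param(-99),
    log_amp_vfast_ml = synth_param(-99), log_amp_vfast_ap = synth_param(-99),
    offset_ml = synth_param(0), offset_ap = synth_param(0),
    noise_sd = 0, seed = 47)
  ds <- generate_cop_dataset(cfg)
  slopes <- vapply(ds$trials, function(tr) {
    w <- welch_psd(tr$ml, tr$fs, nperseg = 2048)
    m <- w$freq >= 0.04 & w$freq <= 0.5
    unname(coef(lm(log10(w$psd[m]) ~ log10(w$freq[m])))[2])
  }, numeric(1))
  expect_equal(mean(slopes), -1.0, tolerance = 0.15)
})

test_that("PSD peaks sit at the configured oscillation frequencies", {
  cfg <- synth_config(
    n_subjects = 1, n_days = 1, n_times = 1, n_trials = 10,
    log_amp_slow_ml = synth_param(-99), log_amp_slow_ap = synth_param(-99),
    log_amp_common = synth_param(0),
    log_amp_fast_ap = synth_param(log10(2)),
    log_amp_vfast_ap = synth_param(-99),
    log_amp_fast_ml = synth_param(-99),
    log_amp_vfast_ml = synth_param(log10(2)),
    f_fast = synth_param(0.7), f_vfast = synth_param(2.2),
    offset_ml = synth_param(0), offset_ap = synth_param(0),
    noise_sd = 0.01, seed = 48)
  ds <- generate_cop_dataset(cfg)
  pk <- sapply(ds$trials, function(tr) {
    wap <- welch_psd(tr$ap, tr$fs, nperseg = 2048)
    wml <- welch_psd(tr$ml, tr$fs, nperseg = 2048)
    c(wap$freq[which.max(wap$psd)], wml$freq[which.max(wml$psd)])
  })
  df <- 60 / 2048
  expect_lt(abs(mean(pk[1, ]) - 0.7), df + 0.02)
  expect_lt(abs(mean(pk[2, ]) - 2.2), df + 0.05)
})

test_that("inertia coupling induces the configured rank correlation", {
  cfg0 <- synth_config(n_subjects = 200, seed = 49)
  set.seed(49)
  sp0 <- sample_subject_parameters(cfg0)
  # coupling present for the common amplitude factor
  rho <- cor(sp0$subject$log_amp_common, sp0$inertia_z, method = "spearman")
  expect_gt(rho, 0.3)
  # with coupling removed the correlation vanishes
  cfg1 <- synth_config(n_subjects = 200,
                       log_amp_common = synth_param(0, sub = 0.12),
                       seed = 49)
  set.seed(49)
  sp1 <- sample_subject_parameters(cfg1)
  rho1 <- cor(sp1$subject$log_amp_common, sp1$inertia_z,
              method = "spearman")
  expect_lt(abs(rho1), 0.2)
})

test_that("subject body parameters follow the cohort distribution", {
  set.seed(50)
  sp <- sample_subject_parameters(synth_config(n_subjects = 400))
  h <- vapply(sp$profiles, function(p) p$height_m, numeric(1))
  m <- vapply(sp$profiles, function(p) p$mass_kg, numeric(1))
  expect_equal(mean(h), 1.710, tolerance = 0.01)
  expect_equal(sd(h), 0.054, tolerance = 0.1)
  expect_equal(mean(m), 66.3, tolerance = 0.03)
  expect_equal(sd(m), 9.5, tolerance = 0.15)
  expect_true(all(m > 0) && all(h > 0))
})
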