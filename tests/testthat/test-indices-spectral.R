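make_spectral_trial <- function(amp_fun, n = N, fs = FS, target_sd = 3) {
  nf <- (n - 1) %/% 2
  freq <- seq_len(nf) * fs / n
  amp <- amp_fun(freq)
  x <- swaylab:::spectral_noise(n, amp, target_sd)
  cop_trial(x, x + rnorm(n, 0, 1e-8), "T01", fs = fs)
}

test_that("white noise gives flat PSD slopes in both bands", {
  set.seed(11)
  slopes <- replicate(30, {
    tr <- cop_trial(rnorm(N), rnorm(N), "T01")
    f <- psd_two_segment(preprocess_trial(tr), "ml")
    c(f$slope_low, f$slope_high)
  })
  expect_lt(abs(mean(slopes[1, ])), 0.15)
  # the 10 Hz pre-filter bends the top of the 0.5-5 Hz band very slightly
  expect_lt(abs(mean(slopes[2, ])), 0.15)
})

test_that("two-segment fit recovers a spliced double power law", {
  set.seed(12)
  # PSD ~ f^-1 below 0.5 Hz and f^-3 above, continuous at 0.5 Hz
  amp_fun <- function(f) {
    a <- ifelse(f <= 0.5, f^(-0.5), sqrt(0.5^2) * f^(-1.5))
    ifelse(f < 0.02 | f > 8, 0, a)
  }
  est <- replicate(12, {
    tr <- make_spectral_trial(amp_fun)
    f <- psd_two_segment(preprocess_trial(tr), "ml")
    c(f$slope_low, f$slope_high, f$fcrit)
  })
  expect_equal(mean(est[1, ]), -1, tolerance = 0.2)
  expect_equal(mean(est[2, ]), -3, tolerance = 0.2)
  expect_equal(mean(est[3, ], na.rm = TRUE), 0.5, tolerance = 0.1)
})

test_that("single power law raises the critical-frequency failure flag", {
  set.seed(13)
  amp_fun <- function(f) ifelse(f < 0.02 | f > 8, 0, f^(-0.75))
  n_failed <- 0
  for (i in 1:10) {
    tr <- make_spectral_trial(amp_fun)
    res <- swaylab:::spectral_indices(preprocess_trial(tr), sway_config())
    if (res$flags[["11"]] == "failed_single_power_law") {
      n_failed <- n_failed + 1
      expect_true(is.na(res$values[["11"]]))
    }
  }
  expect_gte(n_failed, 8)
})

test_that("power frequencies localize tones and respect scaling", {
  # pure 0.3 Hz sinusoid: PF50 = PF95 = 0.3 within one Welch bin
  tr <- sinusoid_trial(0.3, amp_ml = 10, amp_ap = 10)
  pt <- preprocess_trial(tr)
  res <- power_indices(pt)
  df <- FS / 2048
  expect_lt(abs(res$values[["38"]] - 0.3), df + 1e-9)
  expect_lt(abs(res$values[["39"]] - 0.3), df + 1e-9)

  # two equal-power tones at 0.2 and 1.2 Hz
  tt <- tgrid()
  x2 <- sin(2 * pi * 0.2 * tt) + sin(2 * pi * 1.2 * tt)
  pt2 <- preprocess_trial(cop_trial(x2, x2, "T01"))
  res2 <- power_indices(pt2)
  expect_gt(res2$values[["38"]], 0.2 - df)
  expect_lt(res2$values[["38"]], 1.2)
  expect_gte(res2$values[["39"]], 1.2 - df)

  # doubling the amplitude: raw power x4, PF50/PF95 unchanged
  pt3 <- preprocess_trial(cop_trial(2 * x2, 2 * x2, "T01"))
  res3 <- power_indices(pt3)
  expect_equal(unname(res3$values[["37"]] / res2$values[["37"]]), 4,
               tolerance = 1e-6)
  expect_equal(unname(res3$values[["38"]]), unname(res2$values[["38"]]),
               tolerance = 1e-9)
  expect_equal(unname(res3$values[["39"]]), unname(res2$values[["39"]]),
               tolerance = 1e-9)
})
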