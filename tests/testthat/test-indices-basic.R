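test_that("positional indices: means, mean crossings, RMS closed forms", {
  # constant trial: means recovered, crossings zero, RMS degenerate
  pt <- fake_processed(rep(3, 1000), rep(50, 1000))
  res <- positional_indices(pt)
  expect_equal(unname(res$values[c("1", "2")]), c(3, 50))
  expect_equal(unname(res$values[c("7", "8")]), c(0, 0))
  expect_identical(unname(res$flags[c("67", "68", "69")]),
                   rep("degenerate", 3))

  # 0.3 Hz sinusoid crosses its mean 2 f T times
  tr <- sinusoid_trial(0.3, amp_ml = 5, amp_ap = 5)
  res2 <- positional_indices(preprocess_trial(tr))
  expect_equal(unname(res2$values[["8"]]), 2 * 0.3 * DUR, tolerance = 0.03)

  # isotropic bivariate Gaussian: planar RMS -> sigma * sqrt(2)
  set.seed(5)
  sigma <- 2
  pt3 <- fake_processed(rnorm(50000, 0, sigma), rnorm(50000, 0, sigma))
  res3 <- positional_indices(pt3)
  expect_equal(unname(res3$values[["67"]]), sigma * sqrt(2),
               tolerance = 0.02)
})

test_that("confidence ellipse matches closed forms and symmetries", {
  # axis-aligned ellipse with ML range twice AP range
  th <- seq(0, 2 * pi, length.out = 721)[-1]
  pt <- fake_processed(4 * cos(th), 2 * sin(th))
  res <- ellipse_indices(pt)
  expect_equal(unname(res$values[["6"]]), 0, tolerance = 1e-6)
  expect_equal(unname(res$values[["73"]]), 0.5, tolerance = 1e-6)

  # isotropic Gaussian: raw area -> pi * 5.991 * sigma^2
  set.seed(6)
  pt2 <- fake_processed(rnorm(50000), rnorm(50000))
  res2 <- ellipse_indices(pt2)
  expect_equal(unname(res2$values[["3"]]), pi * 5.991, tolerance = 0.05)

  # channel swap: angle -> 90 - angle; area and flattening unchanged
  set.seed(7)
  ml <- rnorm(4200); ap <- 0.6 * ml + 0.5 * rnorm(4200)
  a <- ellipse_indices(fake_processed(ml, ap))
  b <- ellipse_indices(fake_processed(ap, ml))
  expect_equal(unname(a$values[["6"]] + b$values[["6"]]), 90,
               tolerance = 1e-6)
  expect_equal(unname(a$values[["3"]]), unname(b$values[["3"]]))
  expect_equal(unname(a$values[["73"]]), unname(b$values[["73"]]))

  # collinear points: area degenerate, angle still defined
  pt4 <- fake_processed(seq(0, 1, length.out = 100),
                        2 * seq(0, 1, length.out = 100))
  res4 <- ellipse_indices(pt4)
  expect_identical(unname(res4$flags[["3"]]), "degenerate")
  expect_identical(unname(res4$flags[["6"]]), "ok")
})

test_that("velocity and path-length indices match analytic values", {
  # AP sinusoid: MV-AP = 4 A f; zero crossings of velocity = 2 f T
  tr <- sinusoid_trial(0.3, amp_ml = 0, amp_ap = 10)
  pt <- preprocess_trial(tr)
  res <- velocity_indices(pt, ellipse_area = 10)
  expect_equal(unname(res$values[["72"]]), 4 * 10 * 0.3, tolerance = 0.03)
  expect_equal(unname(res$values[["16"]]), 2 * 0.3 * DUR, tolerance = 0.03)

  # straight-line drift at 1 mm/s for 70 s: LNG = 70 mm
  tt <- tgrid()
  pt2 <- fake_processed(tt, rep(0, N))
  res2 <- velocity_indices(pt2, ellipse_area = NA)
  expect_equal(unname(res2$values[["17"]]), DUR - 1 / FS, tolerance = 0.01)

  # circular motion: MV = 2 pi r f
  tr3 <- circle_trial(r = 5, f = 0.4)
  res3 <- velocity_indices(preprocess_trial(tr3), ellipse_area = 10)
  expect_equal(unname(res3$values[["70"]]), 2 * pi * 5 * 0.4,
               tolerance = 0.03)
})

test_that("MFREQ, fractal dimension and sway-area rate behave as designed", {
  # circle: MFREQ equals the rotation frequency (planar and per channel)
  tr <- circle_trial(r = 5, f = 0.4)
  pt <- preprocess_trial(tr)
  res <- misc_indices(pt)
  expect_equal(unname(res$values[["31"]]), 0.4, tolerance = 0.4 * 0.03)
  expect_equal(unname(res$values[["32"]]), 0.4, tolerance = 0.4 * 0.03)
  expect_equal(unname(res$values[["33"]]), 0.4, tolerance = 0.4 * 0.03)

  # back-and-forth segment: FD -> 1
  path <- c(seq(0, 10, length.out = 2101)[-2101],
            seq(10, 0, length.out = 2101)[-2101])
  pt2 <- fake_processed(path, rep(0, length(path)))
  res2 <- misc_indices(pt2)
  expect_equal(unname(res2$values[["29"]]), 1, tolerance = 0.1)

  # scaling by 2: FD and MFREQ unchanged, raw Area-SW x4
  set.seed(8)
  ml <- cumsum(rnorm(2000)); ap <- cumsum(rnorm(2000))
  a <- misc_indices(fake_processed(ml, ap))
  b <- misc_indices(fake_processed(2 * ml, 2 * ap))
  expect_equal(unname(a$values[["29"]]), unname(b$values[["29"]]),
               tolerance = 1e-9)
  expect_equal(unname(b$values[["30"]] / a$values[["30"]]), 4,
               tolerance = 1e-9)
  expect_equal(unname(a$values[["31"]]), unname(b$values[["31"]]),
               tolerance = 1e-9)
})

test_that("rigid translation moves only the mean-position indices", {
  set.seed(9)
  tr <- generate_cop_dataset(synth_config(n_subjects = 1, n_days = 1,
                                          n_times = 1, n_trials = 1,
                                          seed = 9))$trials[[1]]
  cfg <- sway_config()
  v0 <- compute_trial_indices(tr, cfg)$values
  tr2 <- cop_trial(tr$ml + 12.5, tr$ap - 30, tr$subject_id, tr$day,
                   tr$time_slot, tr$trial, tr$fs)
  v1 <- compute_trial_indices(tr2, cfg)$values
  expect_equal(unname(v1[["1"]] - v0[["1"]]), 12.5, tolerance = 1e-6)
  expect_equal(unname(v1[["2"]] - v0[["2"]]), -30, tolerance = 1e-6)
  other <- setdiff(names(v0), c("1", "2"))
  expect_equal(v1[other], v0[other], tolerance = 1e-6)
})

test_that("uniform scaling transforms every index by its declared class", {
  set.seed(10)
  tr <- generate_cop_dataset(synth_config(n_subjects = 1, n_days = 1,
                                          n_times = 1, n_trials = 1,
                                          seed = 10))$trials[[1]]
  cfg <- sway_config()
  cc <- 2.5
  v0 <- compute_trial_indices(tr, cfg)$values
  tr2 <- cop_trial(cc * tr$ml, cc * tr$ap, tr$subject_id, tr$day,
                   tr$time_slot, tr$trial, tr$fs)
  v1 <- compute_trial_indices(tr2, cfg)$values
  cat_ <- index_catalog()
  for (k in seq_len(73)) {
    kk <- as.character(k)
    if (is.na(v0[[kk]]) || is.na(v1[[kk]])) next
    fac <- switch(cat_$scaling[k],
                  invariant = 1, length = cc, area = cc^2,
                  inv_length = 1 / cc, none = NA_real_)
    if (is.na(fac)) next
    expect_equal(unname(v1[[kk]]), unname(fac * v0[[kk]]), tolerance = 0.02,
                 label = sprintf("index %d (%s)", k, cat_$name[k]))
  }
})
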