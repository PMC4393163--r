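make_table <- function(values, subjects) {
  n <- nrow(values)
  structure(list(
    labels = data.frame(subject_id = subjects,
                        day = rep(1:2, length.out = n),
                        time_slot = rep(1:2, each = 2, length.out = n),
                        trial = seq_len(n)),
    values = as.data.frame(values),
    flags = as.data.frame(ifelse(is.na(as.matrix(values)), "degenerate",
                                 "ok"), stringsAsFactors = FALSE)
  ), class = "index_table")
}

test_that("standardization gives pooled mean 0, SD 1 and exact z-scores", {
  vals <- data.frame(I1 = as.numeric(1:900), I2 = rnorm(900))
  tab <- make_table(vals, rep(sprintf("S%02d", 1:15), each = 60))
  st <- standardize_indices(tab)
  expect_equal(mean(st$z$I1), 0, tolerance = 1e-12)
  expect_equal(stats::sd(st$z$I1), 1, tolerance = 1e-12)
  # direct arithmetic oracle for the integer sequence
  expect_equal(st$z$I1, (1:900 - 450.5) / stats::sd(1:900),
               tolerance = 1e-12)
  # idempotence: z of z equals z
  tab2 <- make_table(st$z, tab$labels$subject_id)
  st2 <- standardize_indices(tab2)
  expect_equal(st2$z$I1, st$z$I1, tolerance = 1e-12)
})

test_that("shifting one subject keeps the pooled mean at zero", {
  set.seed(24)
  vals <- data.frame(I1 = rnorm(900))
  subjects <- rep(sprintf("S%02d", 1:15), each = 60)
  vals$I1[subjects == "S03"] <- vals$I1[subjects == "S03"] + 5
  st <- standardize_indices(make_table(vals, subjects))
  expect_equal(mean(st$z$I1), 0, tolerance = 1e-12)
  expect_gt(mean(st$z$I1[subjects == "S03"]), 0)
})

test_that("log transform maps positives, flags non-positives", {
  vals <- data.frame(I3 = c(100, 0, 10), I23 = c(1, 2, 3))
  tab <- make_table(vals, c("S01", "S01", "S02"))
  out <- apply_log_transforms(tab, log_set = 3L)
  expect_equal(out$values$I3, c(2, NA, 1))
  expect_identical(out$flags$I3[2], "degenerate")
  expect_equal(out$values$I23, c(1, 2, 3))  # not in the log set
})

test_that("the conventional log set matches the log-prefixed names", {
  expect_setequal(log_index_set(),
                  c(3, 4, 5, 17, 18, 19, 21, 27, 30, 34, 37, 40,
                    67, 68, 69, 70, 71, 72))
})

test_that("normality screen retains Gaussian and rejects heavy tails", {
  set.seed(25)
  subjects <- rep(sprintf("S%02d", 1:15), each = 60)
  vals <- data.frame(gauss = rnorm(900), heavy = exp(rnorm(900, sd = 1.5)))
  tab <- make_table(vals, subjects)
  st <- standardize_indices(tab)
  rep_ <- normality_screen(st, sway_config())
  expect_true("gauss" %in% rep_$retained)
  expect_false("heavy" %in% rep_$retained)
  # a log-normal index passes after the log transform
  tab2 <- tab
  tab2$values$heavy <- log10(tab2$values$heavy)
  rep2 <- normality_screen(standardize_indices(tab2), sway_config())
  expect_true("heavy" %in% rep2$retained)
})

test_that("retention needs strictly more than 70% of subjects", {
  set.seed(26)
  subjects <- rep(sprintf("S%02d", 1:15), each = 60)
  # 10 Gaussian subjects, 5 strongly bimodal ones -> 10/15 pass at most
  v <- rnorm(900)
  for (s in sprintf("S%02d", 11:15)) {
    idx <- subjects == s
    v[idx] <- sample(c(-3, 3), sum(idx), replace = TRUE) + rnorm(sum(idx), 0, 0.1)
  }
  st <- standardize_indices(make_table(data.frame(I1 = v), subjects))
  rep_ <- normality_screen(st, sway_config())
  expect_lte(sum(rep_$p[, "I1"] >= 0.01), 10.5)
  expect_false("I1" %in% rep_$retained)  # 10/15 = 66.7% is not > 70%
})

test_that("screening is invariant to affine rescaling of an index", {
  set.seed(27)
  subjects <- rep(sprintf("S%02d", 1:5), each = 60)
  v <- rnorm(300)
  p1 <- normality_screen(standardize_indices(
    make_table(data.frame(I1 = v), subjects)), sway_config())
  p2 <- normality_screen(standardize_indices(
    make_table(data.frame(I1 = 7 - 3 * v), subjects)), sway_config())
  expect_equal(p1$p[, "I1"], p2$p[, "I1"], tolerance = 1e-10)
})

test_that("failure-prone indices are eliminated before classification", {
  vals <- data.frame(I1 = rnorm(100), I2 = c(rep(NA, 30), rnorm(70)))
  tab <- make_table(vals, rep(c("S01", "S02"), each = 50))
  tab$flags$I2[1:30] <- "failed_single_power_law"
  out <- suppressMessages(eliminate_failing_indices(tab, sway_config()))
  expect_identical(out$eliminated$index, 2L)
  expect_identical(names(out$table$values), "I1")
  expect_equal(out$eliminated$failure_rate, 0.3)
})
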