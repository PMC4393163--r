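two_class_1d <- function(n, mu, sd = 1) {
  z <- matrix(c(rnorm(n, -mu, sd), rnorm(n, mu, sd)), ncol = 1,
              dimnames = list(NULL, "I1"))
  list(z = z, labels = rep(c("A", "B"), each = n))
}

test_that("1-D two-class LDA: separated means give near-zero error", {
  set.seed(28)
  d <- two_class_1d(200, mu = 5)
  er <- error_rates(d$z, d$labels, "I1")
  expect_lt(er$apparent, 0.01)
  expect_lt(er$loocv, 0.01)
  # boundary at 0: symmetric classes, model predicts by sign
  model <- fit_lda(d$z, d$labels)
  pred <- predict(model, matrix(c(-0.2, 0.2), ncol = 1,
                                dimnames = list(NULL, "I1")))
  expect_identical(as.character(pred), c("A", "B"))
})

test_that("identical class means give chance-level error", {
  set.seed(29)
  d <- two_class_1d(300, mu = 0)
  er <- error_rates(d$z, d$labels, "I1")
  expect_gt(er$apparent, 0.4)
  expect_gt(er$loocv, 0.4)
})

test_that("LOOCV error approaches the Gaussian Bayes error", {
  set.seed(30)
  # two classes, 2-D, shared identity covariance, Mahalanobis distance Delta
  delta <- 2
  n <- 500
  X <- rbind(cbind(rnorm(n, 0), rnorm(n, 0)),
             cbind(rnorm(n, delta), rnorm(n, 0)))
  colnames(X) <- c("I1", "I2")
  labels <- rep(c("A", "B"), each = n)
  er <- error_rates(X, labels, c("I1", "I2"))
  bayes <- pnorm(-delta / 2)
  expect_lt(abs(er$loocv - bayes), 0.03)
})

test_that("LOOCV matches an explicit refit-per-held-out-trial oracle", {
  set.seed(31)
  n <- 40
  X <- rbind(cbind(rnorm(n, 0), rnorm(n, 1)),
             cbind(rnorm(n, 1.2), rnorm(n, 0)),
             cbind(rnorm(n, -1, 1), rnorm(n, -1)))
  colnames(X) <- c("I1", "I2")
  labels <- rep(c("A", "B", "C"), each = n)
  er <- error_rates(X, labels, c("I1", "I2"))
  wrong <- 0
  for (i in seq_len(nrow(X))) {
    m <- fit_lda(X[-i, ], labels[-i])
    if (as.character(predict(m, X[i, , drop = FALSE])) != labels[i]) {
      wrong <- wrong + 1
    }
  }
  expect_equal(er$loocv, wrong / nrow(X), tolerance = 1e-12)
})

test_that("stepwise AIC finds planted informative indices among noise", {
  set.seed(32)
  hits <- replicate(20, {
    n <- 40; p <- 5
    labels <- rep(sprintf("S%d", 1:p), each = n)
    subj_eff <- rep(rnorm(p, 0, 2), each = n)
    z <- cbind(info = subj_eff + rnorm(n * p),
               matrix(rnorm(n * p * 9), ncol = 9,
                      dimnames = list(NULL, paste0("noise", 1:9))))
    sw <- stepwise_aic(z, labels)
    c(first = sw$selected[1] == "info",
      few_noise = sum(grepl("noise", sw$selected)) <= 2)
  })
  expect_gte(mean(hits["first", ]), 0.9)
  expect_gte(mean(hits["few_noise", ]), 0.9)
})

test_that("perfectly correlated duplicates never both enter", {
  set.seed(33)
  n <- 60; p <- 4
  labels <- rep(sprintf("S%d", 1:p), each = n)
  subj_eff <- rep(rnorm(p, 0, 3), each = n)
  base <- subj_eff + rnorm(n * p)
  z <- cbind(a = base, b = base, c = rnorm(n * p))
  sw <- stepwise_aic(z, labels)
  expect_lte(sum(c("a", "b") %in% sw$selected), 1)
  # and the AIC minimum is unchanged by the duplicated column
  sw2 <- stepwise_aic(z[, c("a", "c")], labels)
  expect_equal(sw$aic, sw2$aic, tolerance = 1e-8)
})

test_that("under the global null the selection stays minimal", {
  set.seed(34)
  sizes <- replicate(20, {
    labels <- rep(sprintf("S%d", 1:5), each = 30)
    z <- matrix(rnorm(150 * 8), ncol = 8,
                dimnames = list(NULL, paste0("I", 1:8)))
    length(stepwise_aic(z, labels)$selected)
  })
  expect_gte(mean(sizes <= 2), 0.9)
  expect_lte(stats::median(sizes), 1)
})

test_that("candidate set is the smallest prefix under both thresholds", {
  curves <- data.frame(q = 1:5, index = paste0("I", 1:5),
                       apparent = c(0.5, 0.3, 0.12, 0.09, 0.08),
                       loocv = c(0.5, 0.3, 0.12, 0.09, 0.08))
  expect_identical(candidate_individual_indices(curves, 0.10),
                   paste0("I", 1:4))
  curves$loocv <- rep(0.2, 5)
  expect_warning(out <- candidate_individual_indices(curves, 0.10),
                 "never fell below")
  expect_identical(out, paste0("I", 1:5))
})

test_that("apparent error is invariant to affine index transforms", {
  set.seed(35)
  n <- 50
  X <- cbind(I1 = c(rnorm(n), rnorm(n, 1.5)), I2 = rnorm(2 * n))
  labels <- rep(c("A", "B"), each = n)
  e1 <- error_rates(X, labels, c("I1", "I2"))$apparent
  X2 <- X; X2[, "I1"] <- 100 - 7 * X2[, "I1"]
  e2 <- error_rates(X2, labels, c("I1", "I2"))$apparent
  expect_equal(e1, e2, tolerance = 1e-12)
})
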