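test_that("VM-VV has the sampling-theory scale under exchangeability", {
  set.seed(36)
  # identical standard normal for all subjects: E[VM] = 1/60, E[VV] = 2/59
  vms <- vvs <- numeric(40)
  for (i in 1:40) {
    z <- data.frame(I1 = rnorm(900))
    st <- std_tab(z, rep(sprintf("S%02d", 1:15), each = 60))
    p <- vmvv(st)
    vms[i] <- p$vm; vvs[i] <- p$vv
  }
  expect_equal(mean(vms), 1 / 60, tolerance = 0.25)
  expect_equal(mean(vvs), 2 / 59, tolerance = 0.25)
  expect_lt(max(sqrt(vms^2 + vvs^2)), 0.35)
})

test_that("strong subject effects land far out along the VM axis", {
  set.seed(37)
  subj <- rep(sprintf("S%02d", 1:15), each = 60)
  eff <- rep(rnorm(15, 0, sqrt(0.9)), each = 60)
  v <- eff + rnorm(900, 0, sqrt(0.1))
  z <- scale(v)
  p <- vmvv(std_tab(data.frame(I1 = as.numeric(z)), subj))
  expect_gt(p$distance, 0.35)
  expect_gt(p$vm, 5 * p$vv)
  # constant within subject: VV exactly zero
  v2 <- eff
  p2 <- vmvv(std_tab(data.frame(I1 = as.numeric(scale(v2))), subj))
  expect_equal(p2$vv, 0, tolerance = 1e-12)
  expect_gt(p2$vm, 0)
})

test_that("universal candidate rule is inclusive at the radius and nests", {
  pts <- data.frame(index = c("I1", "I2", "I3"),
                    vm = c(0.35, 0.351, 0.2), vv = c(0, 0, 0))
  pts$distance <- sqrt(pts$vm^2 + pts$vv^2)
  expect_setequal(universal_candidates(pts, 0.35), c("I1", "I3"))
  expect_false("I2" %in% universal_candidates(pts, 0.35))
  s30 <- universal_candidates(pts, 0.30)
  s35 <- universal_candidates(pts, 0.35)
  s40 <- universal_candidates(pts, 0.40)
  expect_true(all(s30 %in% s35) && all(s35 %in% s40))
  expect_setequal(universal_candidates(pts, 0.35, exclude = "I1"), "I3")
})

test_that("correlation expansion adds only strongly correlated indices", {
  set.seed(38)
  n <- 900
  seedv <- rnorm(n)
  z <- data.frame(seed = seedv,
                  corr = 0.85 * seedv + sqrt(1 - 0.85^2) * rnorm(n),
                  indep = rnorm(n))
  out <- correlation_expand(z, "seed", 0.8)
  expect_setequal(out$expanded, c("seed", "corr"))
  expect_identical(out$added, "corr")
  # single pass: an index correlated > 0.8 with the ADDED member but < 0.8
  # with the seed is not recruited
  z$chain <- 0.85 * z$corr + sqrt(1 - 0.85^2) * rnorm(n)
  stopifnot(abs(cor(z$chain, z$seed)) < 0.8,
            abs(cor(z$chain, z$corr)) > 0.8)  # construction check
  out2 <- correlation_expand(z, "seed", 0.8)
  expect_false("chain" %in% out2$expanded)
})

test_that("UPGMA on 1-r distances matches hand computation", {
  # three indices with known pairwise correlations
  r12 <- 0.9; r13 <- 0.4; r23 <- 0.1
  R <- matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  n <- 4000
  set.seed(39)
  L <- chol(R)
  z <- as.data.frame(matrix(rnorm(3 * n), ncol = 3) %*% L)
  names(z) <- c("a", "b", "c")
  hc <- cluster_dendrogram(z)
  r_emp <- cor(z)
  # first merge joins the most correlated pair at height 1 - r
  expect_setequal(hc$merge[1, ], c(-1, -2))
  expect_equal(hc$height[1], 1 - max(r_emp[upper.tri(r_emp)]),
               tolerance = 1e-10)
  # second merge height is the average of the two remaining distances
  d <- 1 - r_emp
  expect_equal(hc$height[2], mean(c(d["a", "c"], d["b", "c"])),
               tolerance = 1e-10)
  expect_true(all(diff(hc$height) >= -1e-12))
})

test_that("block-structured correlations cluster into their blocks", {
  set.seed(40)
  n <- 1500
  f1 <- rnorm(n); f2 <- rnorm(n)
  z <- data.frame(a1 = f1 + 0.3 * rnorm(n), a2 = f1 + 0.3 * rnorm(n),
                  a3 = f1 + 0.3 * rnorm(n), b1 = f2 + 0.3 * rnorm(n),
                  b2 = f2 + 0.3 * rnorm(n))
  hc <- cluster_dendrogram(z)
  cut <- stats::cutree(hc, h = 0.5)
  expect_equal(length(unique(cut[c("a1", "a2", "a3")])), 1)
  expect_equal(length(unique(cut[c("b1", "b2")])), 1)
  expect_false(cut[["a1"]] == cut[["b1"]])
})

test_that("REML and ANOVA variance decompositions agree on balanced data", {
  st <- sim_crossed(0.8, 1.0, seed = 41, s2_day = 0.2)
  reml <- mixed_model_decomposition(st, method = "reml")
  mom <- mixed_model_decomposition(st, method = "anova")
  expect_equal(reml$sigma2_sub, mom$sigma2_sub, tolerance = 0.05)
  expect_equal(reml$sigma2_e, mom$sigma2_e, tolerance = 0.02)
  expect_equal(reml$ratio, mom$ratio, tolerance = 0.1)
})

test_that("variance ratio recovers planted subject-to-residual ratios", {
  ratios_low <- sapply(1:8, function(s) {
    mixed_model_decomposition(sim_crossed(0.5, 1.0, seed = 100 + s))$ratio
  })
  expect_gte(mean(ratios_low >= 0.25 & ratios_low <= 0.9), 0.85)
  ratios_high <- sapply(1:8, function(s) {
    mixed_model_decomposition(sim_crossed(4.0, 1.0, seed = 200 + s))$ratio
  })
  expect_true(all(ratios_high > 1.0))
  # pure residual: ratio near zero
  st0 <- sim_crossed(0, 1.0, seed = 300)
  expect_lt(mixed_model_decomposition(st0)$ratio, 0.2)
})

test_that("classification assembly respects precedence and provenance", {
  decomp <- data.frame(index = c("I5", "I6", "I7"),
                       ratio = c(0.5, 2.0, 0.9), method = "reml")
  g <- suppressMessages(assemble_classification(
    lda_candidates = c("I1", "I2"),
    corr_added_indiv = "I3",
    vmvv_candidates = c("I5", "I6", "I2"),
    corr_added_univ = "I7",
    decomposition = decomp,
    all_indices = paste0("I", 1:8)))
  expect_setequal(g$index[g$group == "individual_specific"],
                  c("I1", "I2", "I3"))
  expect_setequal(g$index[g$group == "universal"], c("I5", "I7"))
  expect_setequal(g$index[g$group == "other"], c("I4", "I6", "I8"))
  expect_identical(g$provenance[g$index == "I2"], "lda_candidate")
  expect_identical(g$provenance[g$index == "I3"], "correlation_added")
  expect_identical(g$provenance[g$index == "I6"], "mixed_model_rejected")
  # groups are disjoint and exhaustive
  expect_identical(sort(g$index), sort(paste0("I", 1:8)))
})
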