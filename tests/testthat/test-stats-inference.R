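# Inference layer: discriminant analysis, rank tests, effect sizes,
# AUC, dispersion. Oracles: brute-force enumeration, analytic identities,
# and independent reference implementations (stats::manova, stats::wilcox.test,
# car::leveneTest, pROC::auc).

random_table <- function(n, p = 3, sep = 0) {
  x <- matrix(rnorm(n * p), n, p)
  g <- rep(c("CF", "FM"), length.out = n)
  x[g == "CF", 1] <- x[g == "CF", 1] + sep
  list(x = x, g = g)
}

test_that("Wilks' lambda matches the determinant-ratio and MANOVA oracles", {
  set.seed(10)
  for (i in 1:25) {
    tb <- random_table(30 + i)
    da <- fisher_da(tb$x, tb$g)
    # independent oracle 1: stats::manova Wilks statistic
    fit <- summary(stats::manova(tb$x ~ tb$g), test = "Wilks")
    expect_equal(da$wilks_lambda, fit$stats[1, "Wilks"], tolerance = 1e-10)
    expect_equal(da$p_value, fit$stats[1, "Pr(>F)"], tolerance = 1e-8)
    # independent oracle 2: Hotelling's T^2 identity for two groups
    x1 <- tb$x[tb$g == "CF", ]; x2 <- tb$x[tb$g == "FM", ]
    n1 <- nrow(x1); n2 <- nrow(x2); p <- ncol(tb$x)
    S <- ((n1 - 1) * stats::cov(x1) + (n2 - 1) * stats::cov(x2)) / (n1 + n2 - 2)
    d <- colMeans(x1) - colMeans(x2)
    T2 <- (n1 * n2) / (n1 + n2) * drop(t(d) %*% solve(S, d))
    Fh <- (n1 + n2 - p - 1) / (p * (n1 + n2 - 2)) * T2
    ph <- stats::pf(Fh, p, n1 + n2 - p - 1, lower.tail = FALSE)
    expect_equal(da$p_value, ph, tolerance = 1e-8)
  }
})

test_that("degenerate and separable discriminant cases behave", {
  # identical groups -> equal means -> lambda = 1, F = 0
  set.seed(20)
  xg <- matrix(rnorm(30), 10, 3)
  x <- rbind(xg, xg)
  g <- rep(c("CF", "FM"), each = 10)
  da0 <- fisher_da(x, g)
  expect_equal(da0$wilks_lambda, 1, tolerance = 1e-12)
  expect_equal(da0$F_stat, 0, tolerance = 1e-12)
  # perfect separation along one feature
  set.seed(11)
  xs <- cbind(c(rnorm(20, 10), rnorm(20, -10)), matrix(rnorm(80), 40, 2))
  gs <- rep(c("CF", "FM"), each = 20)
  das <- fisher_da(xs, gs)
  expect_equal(das$auc, 1.0)
  expect_equal(das$misclassification_rate, 0)
  # constant feature rejected
  xc <- cbind(rep(1, 40), matrix(rnorm(80), 40, 2))
  expect_error(fisher_da(xc, gs), "constant")
})

test_that("signed-rank test matches full enumeration and reference", {
  set.seed(12)
  # n = 8 fixture, plus assorted small samples with ties
  fixtures <- list(c(1.2, -0.4, 2.5, 3.1, -1.7, 0.6, 0.9, -2.2),
                   c(1, 1, -1, 2, 3, -2, 4),
                   c(0.5, 0.5, 0.5, -0.5, 1.5, 2.5),
                   rnorm(10), rnorm(6) + 0.8)
  for (d in fixtures) {
    res <- wilcoxon_signed_rank(d)
    oracle <- enumerate_signed_rank(d)
    expect_equal(res$statistic, oracle$W)
    expect_equal(res$p_value, oracle$p_two, tolerance = 1e-12)
    g <- wilcoxon_signed_rank(d, alternative = "greater")
    expect_equal(g$p_value, oracle$p_greater, tolerance = 1e-12)
  }
  # agreement with the reference implementation when tie/zero-free
  d <- c(1.3, -0.2, 2.4, -3.3, 0.7, 1.9, -0.5, 2.2, 0.1, -1.1)
  expect_equal(wilcoxon_signed_rank(d)$p_value,
               stats::wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("signed-rank effect sizes hit their bounds and zero point", {
  sym <- c(1.5, -1.5, 2.5, -2.5, 3.5, -3.5)
  expect_equal(wilcoxon_signed_rank(sym)$effect_size_rrb, 0)
  pos <- c(0.3, 1.1, 2.2, 0.8, 1.9, 0.4)
  expect_equal(wilcoxon_signed_rank(pos)$effect_size_rrb, 1)
  expect_error(wilcoxon_signed_rank(rep(0, 6)), "zero")
  # zeros are dropped before ranking
  expect_equal(wilcoxon_signed_rank(c(pos, 0, 0))$statistic,
               wilcoxon_signed_rank(pos)$statistic)
})

test_that("rank-sum test matches enumeration, identity and reference", {
  set.seed(13)
  a <- c(3.2, 1.1, 4.8, 2.0, 5.5)
  b <- c(0.4, 2.9, 1.8, 3.6, 0.9, 2.2)
  res <- wilcoxon_rank_sum(a, b)
  oracle <- enumerate_rank_sum(a, b)
  expect_equal(res$statistic, oracle$Ra)
  expect_equal(res$p_value, oracle$p_two, tolerance = 1e-12)
  # AUC / U identity
  expect_equal(res$auc, res$U / (length(a) * length(b)))
  expect_equal(res$auc,
               roc_auc(c(a, b), rep(c("a", "b"), c(length(a), length(b))),
                       positive = "a"))
  # identical samples: no evidence
  same <- wilcoxon_rank_sum(1:6, 1:6)
  expect_gt(same$p_value, 0.9)
  expect_equal(same$effect_size_rrb, 0)
  # disjoint supports: minimal attainable p for these sizes
  disj <- wilcoxon_rank_sum(11:15, 1:5)
  expect_equal(disj$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(disj$auc, 1)
  # asymptotic branch against the reference implementation
  set.seed(14)
  aa <- rnorm(20); bb <- rnorm(25, 0.5)
  expect_equal(wilcoxon_rank_sum(aa, bb)$p_value,
               stats::wilcox.test(aa, bb, exact = FALSE,
                                  correct = TRUE)$p.value,
               tolerance = 1e-9)
})

test_that("levene test detects gross violations and matches car reference", {
  expect_equal(levene_test(c(1, 2, 3, 4), c(1, 2, 3, 4))$statistic, 0)
  set.seed(15)
  a <- rnorm(100); b <- rnorm(100) * 10
  expect_lt(levene_test(a, b)$p_value, 0.001)
  skip_if_not_installed("car")
  g <- factor(rep(c("a", "b"), each = 100))
  ref <- car::leveneTest(c(a, b), g, center = stats::median)
  res <- levene_test(a, b)
  expect_equal(res$statistic, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(res$p_value, ref[1, "Pr(>F)"], tolerance = 1e-10)
})

test_that("levene test rejects at roughly the nominal rate under the null", {
  set.seed(16)
  rej <- mean(replicate(200, {
    levene_test(rnorm(200), rnorm(200))$p_value < 0.05
  }))
  expect_gt(rej, 0.01)
  expect_lt(rej, 0.11)
})

test_that("Cohen's d matches hand computations", {
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5)), -2)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(17)
  expect_equal(cohens_d(rnorm(20000, 1), rnorm(20000, 0)), 1, tolerance = 0.05)
  expect_error(cohens_d(rep(1, 5), rep(1, 5)), "undefined")
})

test_that("rank AUC equals pair counting and the pROC reference", {
  scores <- c(0.9, 0.8, 0.8, 0.3, 0.2, 0.1)
  labels <- c("p", "p", "n", "p", "n", "n")
  expect_equal(roc_auc(scores, labels, positive = "p"),
               pair_count_auc(scores, labels, "p"))
  expect_equal(roc_auc(c(5, 6, 7, 1, 2, 3), rep(c("p", "n"), each = 3),
                       positive = "p"), 1)
  set.seed(18)
  s <- rnorm(4000); l <- sample(c("p", "n"), 4000, TRUE)
  expect_equal(roc_auc(s, l, positive = "p"), 0.5, tolerance = 0.05)
  skip_if_not_installed("pROC")
  expect_equal(roc_auc(scores, labels, positive = "p"),
               as.numeric(pROC::auc(pROC::roc(
                 response = factor(labels, levels = c("n", "p")),
                 predictor = scores, quiet = TRUE, direction = "<"))))
})

test_that("per-fish second-level test handles identity and exclusions", {
  feats <- data.frame(fish_id = rep(sprintf("f%d", 1:6), each = 6),
                      cue = rep(c("NCF", "DFM"), 18),
                      distance_from_screen = rep(c(100, 100), 18))
  res <- per_fish_second_level(feats)
  expect_equal(res$p_value, 1)
  expect_equal(res$effect_size_rrb, 0)
  # a fish with only one cue is excluded with a message
  feats2 <- rbind(feats,
                  data.frame(fish_id = "f7", cue = "NCF",
                             distance_from_screen = 50))
  expect_message(res2 <- per_fish_second_level(feats2), "f7")
  expect_equal(res2$n_fish, 6L)
  expect_error(per_fish_second_level(feats[feats$fish_id == "f1", ]), "5")
})

test_that("state-space dispersion equals the analytic variance sum", {
  frozen <- data.frame(distance = rep(100, 20), yaw = rep(0, 20))
  expect_equal(state_space_dispersion(frozen)$trace, 0)
  set.seed(19)
  s <- data.frame(distance = rnorm(1000, 125, 5), yaw = rnorm(1000, 0, 0.2))
  disp <- state_space_dispersion(s, +1)
  expect_equal(disp$trace, 25.04, tolerance = 0.1)
  expect_equal(disp$trace, disp$var_proximity + disp$var_yaw)
  # goal alignment: proximity variance is invariant to the goal side here
  disp2 <- state_space_dispersion(s, -1)
  expect_equal(disp2$var_proximity, disp$var_proximity)
  expect_equal(state_space_dispersion(s, +1, standardize = TRUE)$trace, 2)
  expect_error(state_space_dispersion(s[1:5, ]), "10")
})

test_that("consolidation comparison reports rank-biserial per enumeration", {
  expect_equal(consolidation_compare(c(3, 4, 5, 6), c(3, 4, 5, 6))$effect_size_rrb, 0)
  all_red <- consolidation_compare(c(10, 12, 9, 14), c(5, 6, 4, 7))
  expect_equal(all_red$effect_size_rrb, 1)
  # 3 reductions and 1 smaller-rank increase: diffs (3, 2, 4, -1)
  day1 <- c(10, 10, 10, 10); day2 <- c(7, 8, 6, 11)
  cc <- consolidation_compare(day1, day2)
  oracle <- enumerate_signed_rank(day1 - day2)
  expect_equal(cc$statistic, oracle$W)
  expect_equal(cc$p_value, oracle$p_two)
  expect_equal(cc$effect_size_rrb, 0.8)
  # unpaired fish are excluded by name
  expect_message(
    cc2 <- consolidation_compare(c(a = 10, b = 12, c = 9, d = 14, e = 20),
                                 c(a = 5, b = 6, c = 4, d = 7)), "e")
  expect_equal(cc2$n_pairs, 4L)
})
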