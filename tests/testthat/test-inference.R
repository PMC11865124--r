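test_that("one-sample Hotelling reduces correctly", {
  # exact mean at mu0: T2 = 0, p = 1
  X <- rbind(c(0, 0), c(2, 1), c(1, 3), c(3, 4), c(4, 2))
  res <- hotelling_one_sample(X, mu0 = colMeans(X))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
  # p = 1 variable: F equals the squared one-sample t
  set.seed(111)
  x <- rnorm(20, 0.5)
  res1 <- hotelling_one_sample(matrix(x), mu0 = 0)
  tt <- t.test(x, mu = 0)
  expect_equal(res1$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res1$p, tt$p.value, tolerance = 1e-9)
  # df conventions for the printed test shapes
  dfs <- function(n, p) {
    X <- matrix(rnorm(n * p), n, p)
    r <- hotelling_one_sample(X)
    c(r$df1, r$df2)
  }
  expect_equal(dfs(193, 2), c(2, 191))
  expect_equal(dfs(193, 5), c(5, 188))
  expect_equal(dfs(77, 2), c(2, 75))
  expect_equal(dfs(76, 2), c(2, 74))
  expect_error(hotelling_one_sample(matrix(rnorm(6), 3, 2) %*% matrix(1, 2, 2)),
               "singular")
  expect_error(hotelling_one_sample(matrix(rnorm(8), 2, 4)), "n > p")
})

test_that("two-sample Hotelling reduces to the pooled t-test", {
  X <- matrix(rnorm(30), 15, 2)
  res <- hotelling_two_sample(X, X)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  set.seed(121)
  x1 <- rnorm(18, 0); x2 <- rnorm(14, 1)
  res1 <- hotelling_two_sample(matrix(x1), matrix(x2))
  tt <- t.test(x1, x2, var.equal = TRUE)
  expect_equal(res1$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res1$p, tt$p.value, tolerance = 1e-9)
  # df check: p = 2 with 184 total subjects gives (2, 181)
  r <- hotelling_two_sample(matrix(rnorm(184), 92, 2),
                            matrix(rnorm(184), 92, 2))
  expect_equal(c(r$df1, r$df2), c(2, 181))
})

test_that("paired Hotelling is the one-sample test on differences", {
  set.seed(131)
  X1 <- matrix(rnorm(77 * 3), 77, 3)
  X2 <- X1 + matrix(rnorm(77 * 3, 0.2), 77, 3)
  res <- hotelling_paired(X1, X2)
  ref <- hotelling_one_sample(X1 - X2, 0)
  expect_equal(res$statistic, ref$statistic)
  expect_equal(res$p, ref$p)
  # standard df at n = 77, p = 3 is (3, 74)
  expect_equal(c(res$df1, res$df2), c(3, 74))
  expect_equal(hotelling_paired(X1, X1)$statistic, 0, tolerance = 1e-12)
})

test_that("repeated-measures MANOVA behaves at its reduction points", {
  # factor-invariant data: Lambda = 1, F = 0
  Y <- array(rep(rnorm(10), 3 * 2), c(10, 3, 2))
  res <- rm_manova(Y)
  expect_equal(res$statistic, 1)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  # k = 2, m = 1: p-value equals the paired t-test
  set.seed(141)
  a <- rnorm(25); b <- a + rnorm(25, 0.3)
  res2 <- rm_manova(cbind(a, b))
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(res2$p, tt$p.value, tolerance = 1e-9)
  expect_error(rm_manova(array(rnorm(5 * 5 * 2), c(5, 5, 2))), "n >")
})

test_that("repeated-measures ANOVA matches its oracles", {
  # identical levels: F = 0
  v <- matrix(rep(rnorm(8), 4), 8, 4)
  res <- rm_anova(v)
  expect_equal(res$F, 0)
  # k = 2: epsilons 1 and F equals the squared paired t
  set.seed(151)
  a <- rnorm(20); b <- a + rnorm(20, 0.5)
  res2 <- rm_anova(cbind(a, b))
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(res2$eps_gg, 1)
  expect_equal(res2$eps_hf, 1)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res2$p, tt$p.value, tolerance = 1e-9)
  # epsilon estimates against the direct double-centering formulas
  set.seed(152)
  v3 <- matrix(rnorm(30), 10, 3) %*% matrix(c(1, .3, 0, 0, 1, 0, 0, .2, 2), 3)
  res3 <- rm_anova(v3)
  S <- cov(v3)
  k <- 3; n <- 10
  Sc <- S - outer(rowMeans(S), rep(1, k)) -
    outer(rep(1, k), colMeans(S)) + mean(S)
  eps_gg <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
  expect_equal(res3$eps_gg, eps_gg, tolerance = 1e-9)
  eps_hf <- min(1, (n * (k - 1) * eps_gg - 2) /
                    ((k - 1) * (n - 1 - (k - 1) * eps_gg)))
  expect_equal(res3$eps_hf, eps_hf, tolerance = 1e-9)
  # uncorrected F and dfs against aov's within-subject stratum
  long <- data.frame(y = as.vector(v3),
                     subj = factor(rep(1:10, 3)),
                     lvl = factor(rep(1:3, each = 10)))
  av <- summary(aov(y ~ lvl + Error(subj/lvl), data = long))
  tab <- av[["Error: subj:lvl"]][[1]]
  expect_equal(res3$F, tab["lvl", "F value"], tolerance = 1e-9)
  expect_equal(res3$p, tab["lvl", "Pr(>F)"], tolerance = 1e-9)
})

test_that("Holm adjustment is the step-down with monotonicity", {
  expect_equal(holm_bonferroni(0.03), 0.03)
  expect_equal(holm_bonferroni(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_bonferroni(rep(1, 4)), rep(1, 4))
  set.seed(161)
  for (r in 1:25) {
    p <- runif(sample(2:10, 1))
    adj <- holm_bonferroni(p)
    expect_equal(adj, p.adjust(p, "holm"))
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    # order invariance
    o <- sample(length(p))
    expect_equal(holm_bonferroni(p[o]), adj[o])
  }
  expect_error(holm_bonferroni(c(0.5, 1.2)), "0, 1")
})

test_that("effect-size conventions reproduce the standard formulas", {
  expect_equal(cohens_d_one_sample(0, 50), 0)
  # |t|/sqrt(n) = 0.4945: the published 0.494 reflects an unrounded t, so
  # agreement is to one unit in the last printed place
  expect_lt(abs(cohens_d_one_sample(-6.87, 193) - 0.494), 0.001)
  expect_equal(round(partial_eta_sq(10.51, 5, 188), 3), 0.218)
  # eta_p^2 from F is t^2/(t^2 + df) at df1 = 1
  t <- 2.5; df <- 30
  expect_equal(partial_eta_sq(t^2, 1, df), t^2 / (t^2 + df))
})

test_that("posthoc table matches t.test and keeps Holm monotone", {
  set.seed(171)
  X <- matrix(rnorm(40 * 3, mean = c(0, 0.5, 1)), 40, 3, byrow = TRUE)
  colnames(X) <- c("a", "b", "c")
  tab <- posthoc_t_tests(X, 0)
  for (j in 1:3) {
    tt <- t.test(X[, j], mu = 0)
    expect_equal(tab$t[j], unname(tt$statistic), tolerance = 1e-9)
    expect_equal(tab$p[j], tt$p.value, tolerance = 1e-9)
    expect_equal(c(tab$ci_lower[j], tab$ci_upper[j]),
                 as.numeric(tt$conf.int), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  expect_true(all(tab$p_holm >= tab$p))
})

test_that("Box's M is zero for identical groups and tracks variance ratios", {
  set.seed(181)
  X <- matrix(rnorm(60), 20, 3)
  res <- box_m(list(X, X))
  expect_equal(res$M, 0, tolerance = 1e-9)
  expect_equal(res$df, 6)
  # univariate reduction: more discrepant variances give larger M, smaller p
  x1 <- matrix(rnorm(40, sd = 1))
  near <- box_m(list(x1, matrix(rnorm(40, sd = 1.1))))
  far <- box_m(list(x1, matrix(rnorm(40, sd = 4))))
  expect_gt(far$M, near$M)
  expect_lt(far$p, near$p)
  expect_error(box_m(list(x1)), "2 groups")
})
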