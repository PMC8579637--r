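test_that("paired comparison gates on normality of the differences", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  same <- compare_paired(x, x)
  expect_equal(same$test, "paired t")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # a clear additive shift on normal data (the post-treatment ADC situation)
  set.seed(56)
  pre <- rnorm(56, 1238, 212)
  post <- pre + 300 + rnorm(56, 0, 80)
  sh <- compare_paired(pre, post)
  expect_equal(sh$test, "paired t")
  expect_lt(sh$p_value, 0.001)

  # heavily skewed differences take the signed-rank branch
  set.seed(57)
  pre2 <- rnorm(40, 100, 5)
  post2 <- pre2 + rlnorm(40, 2, 1.2)
  sk <- compare_paired(pre2, post2)
  expect_equal(sk$test, "Wilcoxon signed-rank")
})

test_that("unpaired comparison gates on normality and variance homogeneity", {
  g <- c(2, 4, 4, 5, 7, 9)
  same <- compare_unpaired(g, g)
  expect_equal(same$p_value, 1)

  set.seed(58)
  n1 <- rnorm(30, 0, 1); n2 <- rnorm(30, 0.2, 1)
  expect_equal(compare_unpaired(n1, n2)$test, "Student t")
  s1 <- rlnorm(30, 0, 1); s2 <- rlnorm(30, 0.5, 1)
  expect_equal(compare_unpaired(s1, s2)$test, "Mann-Whitney U")
})

test_that("the group separation in pre-treatment ADC is reliably detected", {
  # power simulation at the published group moments and sizes
  set.seed(59)
  hits <- 0
  for (i in 1:200) {
    rg <- rnorm(36, 1119.58, 144.06)
    nrg <- rnorm(20, 1386.25, 198.23)
    if (compare_unpaired(rg, nrg)$p_value < 0.01) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.95)
})

test_that("pooled t from summaries matches published statistics and raw-data t", {
  expect_equal(t_from_summary(5, 1, 10, 5, 2, 12), 0)
  expect_equal(t_from_summary(-64.98, 17.77, 36, -30.35, 14.94, 20),
               7.377, tolerance = 1e-3)
  expect_equal(t_from_summary(1119.58, 144.06, 36, 1386.25, 198.23, 20),
               5.790, tolerance = 1e-3)
  # data constructed to match the summary moments exactly
  set.seed(60)
  mk_group <- function(n, m, s) {
    x <- rnorm(n); x <- (x - mean(x)) / sd(x); m + s * x
  }
  g1 <- mk_group(36, 1119.58, 144.06); g2 <- mk_group(20, 1386.25, 198.23)
  cmp <- compare_unpaired(g1, g2)
  expect_equal(cmp$test, "Student t")
  expect_equal(abs(cmp$statistic),
               t_from_summary(1119.58, 144.06, 36, 1386.25, 198.23, 20),
               tolerance = 1e-10)
})

test_that("categorical tests follow the expected-count rules", {
  prop <- matrix(c(10, 20, 5, 10), 2)   # perfectly proportional
  p <- compare_categorical(prop)
  expect_equal(p$test, "chi-square")
  expect_equal(p$statistic, 0)
  expect_equal(p$p_value, 1)

  # sex distribution across response groups: small expected counts trigger
  # the continuity correction; the difference is non-significant
  sex <- matrix(c(29, 17, 7, 3), 2, dimnames = list(c("RG", "NRG"), c("M", "F")))
  cs <- compare_categorical(sex)
  expect_match(cs$test, "continuity")
  expect_gt(cs$p_value, 0.05)

  # Fisher p for a perfectly split 2x2, against the hypergeometric oracle
  tab <- matrix(c(10, 0, 0, 10), 2)
  fi <- compare_categorical(tab)
  expect_equal(fi$test, "Fisher exact")
  probs <- dhyper(0:10, 10, 10, 10)
  oracle <- sum(probs[probs <= dhyper(10, 10, 10, 10) * (1 + 1e-7)])
  expect_equal(fi$p_value, oracle)        # = 2 / choose(20, 10)
  expect_equal(oracle, 2 / choose(20, 10))
})

test_that("logistic combination produces a usable responder score", {
  # perfectly separable toy problem: flagged, score still separates
  y <- c(rep(TRUE, 5), rep(FALSE, 5))
  x <- data.frame(m = c(6:10, 1:5))
  fit <- logistic_combine(x, y)
  expect_true(fit$separation)
  expect_equal(auc_mann_whitney(fit$score, y), 1)

  # informative feature: coefficient sign matches the orientation
  set.seed(61)
  y2 <- rep(c(TRUE, FALSE), c(30, 30))
  x2 <- data.frame(a = as.numeric(y2) + rnorm(60, 0, 0.4))
  fit2 <- logistic_combine(x2, y2)
  expect_gt(fit2$coefficients[["a"]], 0)

  # constant feature: aliased, zero coefficient, score = prevalence
  x3 <- data.frame(c = rep(2, 60))
  fit3 <- logistic_combine(x3, y2)
  expect_equal(unname(fit3$coefficients[["c"]]), 0)
  expect_equal(fit3$score, rep(0.5, 60), tolerance = 1e-8)
})
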