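# Brute-force oracles: AUC by exhaustive pair counting, Youden by scanning
# every empirical operating point.

auc_brute <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (x in pos) for (y in neg)
    total <- total + if (x > y) 1 else if (x == y) 0.5 else 0
  total / (length(pos) * length(neg))
}

youden_brute <- function(scores, labels, orientation) {
  s <- if (orientation == "higher") scores else -scores
  pos <- s[labels]; neg <- s[!labels]
  best <- -Inf
  for (ct in sort(unique(c(s, min(s) - 1, max(s) + 1)))) {
    j <- mean(pos >= ct) + mean(neg < ct) - 1
    if (j > best) best <- j
  }
  best
}

test_that("AUC equals the concordant-pair fraction on small examples", {
  scores <- c(2, 4, 1, 3)
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(auc_mann_whitney(scores, labels), 0.75)
  expect_equal(auc_brute(scores, labels), 0.75)
  r <- roc_analysis(scores, labels)
  expect_equal(r$auc, 0.75)

  # perfect separation
  rp <- roc_analysis(c(5, 6, 7, 1, 2), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(rp$auc, 1)
  expect_equal(rp$youden, 1)
})

test_that("trapezoid AUC and Youden cutoff match brute force on random instances", {
  set.seed(70)
  for (i in 1:100) {
    n1 <- sample(3:15, 1); n0 <- sample(3:15, 1)
    scores <- round(c(rnorm(n1, 1), rnorm(n0)), sample(0:2, 1))  # induce ties
    labels <- rep(c(TRUE, FALSE), c(n1, n0))
    expect_equal(auc_mann_whitney(scores, labels), auc_brute(scores, labels))
    r <- roc_analysis(scores, labels)
    expect_equal(r$youden, youden_brute(scores, labels, r$orientation),
                 tolerance = 1e-12)
    # the reported operating point attains the reported Youden index
    expect_equal(r$youden, r$sensitivity + r$specificity - 1)
  }
})

test_that("orientation is auto-selected and recorded so AUC >= 0.5", {
  set.seed(71)
  y <- rep(c(TRUE, FALSE), c(20, 20))
  low_marker <- ifelse(y, rnorm(40, 0), rnorm(40, 2))   # lower value = case
  r <- roc_analysis(low_marker, y)
  expect_equal(r$orientation, "lower")
  expect_gte(r$auc, 0.5)
  # a case is called when the score is at or below the cutoff
  sens <- mean(low_marker[y] <= r$cutoff)
  expect_equal(sens, r$sensitivity)
})

test_that("AUC and DeLong CI agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(72)
  y <- rep(c(TRUE, FALSE), c(36, 20))
  s <- as.numeric(y) * 1.2 + rnorm(56)
  r <- roc_analysis(s, y)
  pr <- pROC::roc(response = y, predictor = s, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)))
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(r$ci, ci[c(1, 3)], tolerance = 1e-8)
})

test_that("diagnostic metrics identities hold at boundary operating points", {
  m <- diagnostic_metrics(1, 1, 10, 10)
  expect_equal(m$youden, 1)
  expect_equal(m$nlr, 0)
  expect_equal(m$plr, Inf)
  expect_equal(m$ppv, 100)
  expect_equal(m$npv, 100)
  m2 <- diagnostic_metrics(0.75, 0.9, 36, 20)
  expect_equal(m2$youden, m2$tp / 36 + m2$tn / 20 - 1, tolerance = 0.02)
  expect_equal(m2$ppv, 100 * m2$tp / (m2$tp + m2$fp))
})

test_that("paired DeLong comparison is rank-invariant and correctly null", {
  set.seed(73)
  y <- rep(c(TRUE, FALSE), c(15, 15))
  s <- rnorm(30) + y
  same <- delong_compare(s, s, y)
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)
  mono <- delong_compare(s, exp(2 * s) + 5, y)
  expect_equal(mono$difference, 0)
  expect_equal(mono$p_value, 1)
})

test_that("DeLong z and p agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(74)
  y <- rep(c(TRUE, FALSE), c(36, 20))
  s1 <- as.numeric(y) + rnorm(56)
  s2 <- 0.8 * as.numeric(y) + rnorm(56)
  ours <- delong_compare(s1, s2, y)
  r1 <- pROC::roc(y, s1, quiet = TRUE, direction = "<")
  r2 <- pROC::roc(y, s2, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  expect_equal(abs(ours$z), abs(as.numeric(ref$statistic)), tolerance = 1e-8)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
})
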