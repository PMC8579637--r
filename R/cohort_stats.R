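# Group comparisons with the normality gate, categorical tests, and the
# logistic combination of markers into a single predictive score.

group_summary <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(mean = mean(x), sd = stats::sd(x), median = q[2], iqr = q[3] - q[1])
}

is_normal <- function(x, alpha) {
  if (length(unique(x)) < 3) return(FALSE)
  stats::shapiro.test(x)$p.value >= alpha
}

comparison_result <- function(variable, test, statistic, p_value, summaries) {
  structure(list(variable = variable, test = test,
                 statistic = unname(statistic), p_value = unname(p_value),
                 summaries = summaries),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s, statistic=%.4g, p=%.4g\n",
              x$variable, x$test, x$statistic, x$p_value))
  invisible(x)
}

#' Paired pre/post comparison with a normality gate
#'
#' Shapiro-Wilk on the paired differences selects a paired t test (normal
#' differences, summaries as mean +/- SD) or the Wilcoxon signed-rank test
#' (otherwise, summaries as median (IQR)). Identical pre/post vectors are
#' a degenerate case reported on the t branch with statistic 0 and p = 1.
#'
#' @param pre,post Numeric vectors of equal length (>= 3).
#' @param alpha_normality Significance level of the normality gate
#'   (default 0.05).
#' @param variable Label carried into the result.
#' @return A `group_comparison` with fields `test`, `statistic`, `p_value`
#'   and per-timepoint `summaries`.
#' @export
compare_paired <- function(pre, post, alpha_normality = 0.05,
                           variable = "value") {
  if (length(pre) != length(post)) stop("pre and post must pair up")
  if (length(pre) < 3) stop("need at least 3 pairs")
  d <- post - pre
  summaries <- list(pre = group_summary(pre), post = group_summary(post))
  if (all(d == d[1])) {
    if (d[1] == 0)
      return(comparison_result(variable, "paired t", 0, 1, summaries))
    # constant non-zero shift: exact fit, infinitely strong evidence
    return(comparison_result(variable, "paired t", Inf, 0, summaries))
  }
  if (is_normal(d, alpha_normality)) {
    tt <- stats::t.test(post, pre, paired = TRUE)
    comparison_result(variable, "paired t", tt$statistic, tt$p.value, summaries)
  } else {
    wt <- stats::wilcox.test(post, pre, paired = TRUE, exact = FALSE,
                             correct = FALSE)
    comparison_result(variable, "Wilcoxon signed-rank", wt$statistic,
                      wt$p.value, summaries)
  }
}

#' Two-group comparison with normality and variance gates
#'
#' A pooled-variance Student t test is used when both groups pass
#' Shapiro-Wilk normality and Levene's test (mean-centered) finds the
#' variances homogeneous; otherwise the Mann-Whitney U test (normal
#' approximation, no continuity correction).
#'
#' @param g1,g2 Numeric vectors (each n >= 3).
#' @param alpha_normality Significance level of both gates (default 0.05).
#' @param variable Label carried into the result.
#' @return A `group_comparison`.
#' @export
compare_unpaired <- function(g1, g2, alpha_normality = 0.05,
                             variable = "value") {
  if (length(g1) < 3 || length(g2) < 3) stop("each group needs n >= 3")
  summaries <- list(g1 = group_summary(g1), g2 = group_summary(g2))
  normal <- is_normal(g1, alpha_normality) && is_normal(g2, alpha_normality)
  homo <- FALSE
  if (normal) {
    lev <- car::leveneTest(c(g1, g2),
                           factor(rep(c("a", "b"), c(length(g1), length(g2)))),
                           center = mean)
    homo <- lev[["Pr(>F)"]][1] >= alpha_normality
  }
  if (normal && homo) {
    tt <- stats::t.test(g1, g2, var.equal = TRUE)
    comparison_result(variable, "Student t", tt$statistic, tt$p.value, summaries)
  } else {
    if (stats::sd(c(g1, g2)) == 0)
      return(comparison_result(variable, "Mann-Whitney U",
                               length(g1) * length(g2) / 2, 1, summaries))
    wt <- stats::wilcox.test(g1, g2, exact = FALSE, correct = FALSE)
    comparison_result(variable, "Mann-Whitney U", wt$statistic, wt$p.value,
                      summaries)
  }
}

#' Pooled-variance t statistic from group summaries
#'
#' Recomputes the Student t statistic from printed group means, SDs and
#' sizes, as used to verify published group comparisons.
#'
#' @param mean1,sd1,n1 First group summary (n >= 2, sd > 0).
#' @param mean2,sd2,n2 Second group summary.
#' @return The absolute pooled-variance t statistic.
#' @examples
#' t_from_summary(-64.98, 17.77, 36, -30.35, 14.94, 20)  # 7.377
#' @export
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  if (sd1 <= 0 || sd2 <= 0) stop("SDs must be positive")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  abs(mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Categorical comparison (chi-square / continuity-corrected / Fisher)
#'
#' Test choice follows the usual expected-count rules. For 2x2 tables:
#' Fisher's exact test when the total count is below 40 or any expected
#' count is below 1; Yates continuity correction when any expected count is
#' below 5; plain chi-square otherwise. For larger tables: plain chi-square
#' when every expected count is >= 5, Fisher's exact test otherwise.
#'
#' @param table A matrix of non-negative integer counts (groups x levels).
#' @param variable Label carried into the result.
#' @return A `group_comparison`; the statistic is the chi-square value (NA
#'   for Fisher's test).
#' @export
compare_categorical <- function(table, variable = "category") {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  summaries <- list(counts = tab, expected = expected)
  is2x2 <- all(dim(tab) == 2)
  use_fisher <- if (is2x2) sum(tab) < 40 || any(expected < 1) else any(expected < 5)
  if (use_fisher) {
    ft <- stats::fisher.test(tab)
    comparison_result(variable, "Fisher exact", NA_real_, ft$p.value, summaries)
  } else if (is2x2 && any(expected < 5)) {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    comparison_result(variable, "chi-square (continuity corrected)",
                      ct$statistic, ct$p.value, summaries)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    comparison_result(variable, "chi-square", ct$statistic, ct$p.value, summaries)
  }
}

# Ridge-penalized logistic fit by iteratively reweighted least squares.
# The (tiny) penalty is excluded from the intercept.
ridge_logistic <- function(X, y, lambda = 1e-6, max_iter = 200, tol = 1e-10) {
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  beta <- numeric(p)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  for (i in seq_len(max_iter)) {
    eta <- as.numeric(Xd %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-12)
    grad <- crossprod(Xd, y - mu) - pen %*% beta
    H <- crossprod(Xd * w, Xd) + pen
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  names(beta) <- colnames(Xd)
  beta
}

#' Combine markers into a logistic predictive score
#'
#' Maximum-likelihood logistic regression with all features entered
#' simultaneously; the score for each patient is the fitted probability of
#' being a responder. Complete or quasi-complete separation is flagged and
#' handled with a tiny ridge penalty (1e-6) so a usable score is always
#' returned; aliased (e.g. constant) features get coefficient 0.
#'
#' @param features data.frame or matrix of marker values (no missing
#'   values), one row per patient.
#' @param labels Responder indicator (logical, 0/1, or a factor whose
#'   second level is the responder class... see Details). Both classes must
#'   have at least 2 patients.
#' @return A list of class `logistic_score`: `score` (fitted responder
#'   probability per patient), `coefficients`, `separation` flag and the
#'   `glm` fit (NULL when the ridge fallback was used).
#' @export
logistic_combine <- function(features, labels) {
  X <- as.matrix(as.data.frame(features))
  if (anyNA(X)) stop("features must not contain missing values")
  y <- as.integer(as.logical(labels))
  if (anyNA(y)) stop("labels must be coercible to logical")
  if (min(table(y)) < 2) stop("need at least 2 patients per class")
  fit <- suppressWarnings(stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                                         family = stats::binomial()))
  mu <- fit$fitted.values
  # separation heuristic: non-convergence or fitted probabilities pinned at 0/1
  separation <- !fit$converged || any(mu > 1 - 1e-8 | mu < 1e-8)
  coefs <- stats::coef(fit)
  used_ridge <- FALSE
  if (separation || anyNA(mu)) {
    Xs <- scale(X)
    keep <- is.finite(colSums(Xs))            # drop constant columns
    beta_s <- ridge_logistic(Xs[, keep, drop = FALSE], y)
    eta <- as.numeric(cbind(1, Xs[, keep, drop = FALSE]) %*% beta_s)
    mu <- 1 / (1 + exp(-eta))
    # back-transform coefficients to the original scale
    coefs <- stats::setNames(numeric(ncol(X) + 1), c("(Intercept)", colnames(X)))
    sds <- attr(Xs, "scaled:scale")[keep]
    ctr <- attr(Xs, "scaled:center")[keep]
    coefs[names(beta_s)[-1]] <- beta_s[-1] / sds
    coefs[1] <- beta_s[1] - sum(beta_s[-1] * ctr / sds)
    used_ridge <- TRUE
  }
  coefs[is.na(coefs)] <- 0
  structure(list(score = as.numeric(mu), coefficients = coefs,
                 separation = separation, ridge = used_ridge),
            class = "logistic_score")
}
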