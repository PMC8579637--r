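# Empirical ROC analysis with Youden-optimal operating point, diagnostic
# metrics at cohort prevalence, and the DeLong machinery for AUC variance
# and pairwise comparison of correlated ROC curves.

# Mid-rank placements: V10[i] = P-hat(X_i beats a random control),
# V01[j] = P-hat(a random case beats Y_j); ties count one half.
delong_placements <- function(pos, neg) {
  cmp <- outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y))
  list(v10 = rowMeans(cmp), v01 = 1 - colMeans(cmp), auc = mean(cmp))
}

#' Empirical AUC by concordant-pair counting
#'
#' The Mann-Whitney statistic `U/(n1*n0)`: the fraction of case-control
#' pairs ranked concordantly, ties counted one half. Equals the trapezoidal
#' area under the empirical ROC curve.
#'
#' @param scores Numeric marker values.
#' @param labels Case (responder) indicator, coercible to logical.
#' @return AUC in [0, 1] for the "higher score = case" orientation.
#' @export
auc_mann_whitney <- function(scores, labels) {
  y <- as.logical(labels)
  delong_placements(scores[y], scores[!y])$auc
}

#' Diagnostic metrics at an operating point
#'
#' Youden index, likelihood ratios and predictive values from sensitivity,
#' specificity and the group sizes. Predictive values are computed from the
#' integer confusion counts reconstructed at cohort prevalence
#' (`TP = round(sens * n_pos)` etc.) and reported as percentages.
#'
#' @param sensitivity,specificity Rates in [0, 1].
#' @param n_pos,n_neg Case and control counts (>= 1).
#' @return A list: `youden`, `plr` (positive likelihood ratio, `Inf` when
#'   specificity is 1), `nlr`, `ppv`, `npv` (percent), and the confusion
#'   counts `tp`, `fp`, `tn`, `fn`.
#' @examples
#' diagnostic_metrics(0.75, 0.90, 36, 20)
#' @export
diagnostic_metrics <- function(sensitivity, specificity, n_pos, n_neg) {
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 || specificity > 1)
    stop("rates must lie in [0, 1]")
  if (n_pos < 1 || n_neg < 1) stop("need at least one subject per class")
  tp <- round(sensitivity * n_pos); fn <- n_pos - tp
  fp <- round((1 - specificity) * n_neg); tn <- n_neg - fp
  list(
    youden = sensitivity + specificity - 1,
    plr = if (specificity == 1) Inf else sensitivity / (1 - specificity),
    nlr = if (specificity == 0) Inf else (1 - sensitivity) / specificity,
    ppv = if (tp + fp == 0) NA_real_ else 100 * tp / (tp + fp),
    npv = if (tn + fn == 0) NA_real_ else 100 * tn / (tn + fn),
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

#' ROC analysis with Youden-optimal cutoff
#'
#' Builds the empirical ROC over all cutoffs, computes the AUC as
#' `U/(n1*n0)` with a DeLong-variance 95% CI, and selects the cutoff
#' maximizing the Youden index (sensitivity + specificity - 1). Candidate
#' cutoffs are placed midway between adjacent observed values; ties on the
#' Youden index are broken toward the smallest cutoff. Orientation is
#' auto-selected so AUC >= 0.5 and recorded explicitly: with orientation
#' `"higher"` a score at or above the cutoff predicts a case (responder),
#' with `"lower"` a score at or below it does.
#'
#' @param scores Numeric marker values, one per patient.
#' @param labels Case (responder) indicator; both classes must be present.
#' @param orientation `"auto"` (default), `"higher"` or `"lower"`.
#' @param marker Label carried into the result.
#' @param conf_level Confidence level of the AUC CI.
#' @return An object of class `roc_result` with fields `marker`,
#'   `orientation`, `auc`, `ci` (length-2), `youden`, `cutoff`,
#'   `sensitivity`, `specificity`, `plr`, `nlr`, `ppv`, `npv`, `n_pos`,
#'   `n_neg`.
#' @export
roc_analysis <- function(scores, labels, orientation = c("auto", "higher", "lower"),
                         marker = "marker", conf_level = 0.95) {
  orientation <- match.arg(orientation)
  y <- as.logical(labels)
  if (anyNA(scores) || anyNA(y)) stop("scores and labels must be complete")
  if (!any(y) || all(y)) stop("both classes must be present")
  auc_higher <- auc_mann_whitney(scores, y)
  if (orientation == "auto")
    orientation <- if (auc_higher >= 0.5) "higher" else "lower"
  s <- if (orientation == "higher") scores else -scores
  pos <- s[y]; neg <- s[!y]
  n1 <- length(pos); n0 <- length(neg)
  pl <- delong_placements(pos, neg)
  auc <- pl$auc
  v10 <- pl$v10; v01 <- pl$v01
  var_auc <- stats::var(v10) / n1 + stats::var(v01) / n0
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- clamp(auc + c(-1, 1) * z * sqrt(max(var_auc, 0)), 0, 1)
  # candidate cutoffs midway between adjacent observed values, plus the ends
  su <- sort(unique(s))
  cand <- if (length(su) == 1) su else
    c(su[1] - 1, (su[-1] + su[-length(su)]) / 2, su[length(su)] + 1)
  sens <- vapply(cand, function(ct) mean(pos >= ct), 0)
  spec <- vapply(cand, function(ct) mean(neg < ct), 0)
  yj <- sens + spec - 1
  best <- which(yj >= max(yj) - 1e-12)
  pick <- best[which.min(cand[best])]
  cutoff_internal <- cand[pick]
  cutoff <- if (orientation == "higher") cutoff_internal else -cutoff_internal
  dm <- diagnostic_metrics(sens[pick], spec[pick], n1, n0)
  structure(list(marker = marker, orientation = orientation,
                 auc = auc, ci = ci, youden = dm$youden, cutoff = cutoff,
                 sensitivity = sens[pick], specificity = spec[pick],
                 plr = dm$plr, nlr = dm$nlr, ppv = dm$ppv, npv = dm$npv,
                 n_pos = n1, n_neg = n0, var_auc = var_auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> %s (%s): AUC %.3f (%.3f, %.3f), Youden %.3f at cutoff %.4g\n  sens %.1f%% spec %.1f%% +LR %.2f -LR %.2f +PV %.1f -PV %.1f\n",
    x$marker, x$orientation, x$auc, x$ci[1], x$ci[2], x$youden, x$cutoff,
    100 * x$sensitivity, 100 * x$specificity, x$plr, x$nlr, x$ppv, x$npv))
  invisible(x)
}

#' DeLong test for two correlated ROC curves
#'
#' Paired comparison of the AUCs of two markers measured on the same
#' patients, using the DeLong structural-components estimate of the
#' variance of the AUC difference. Each marker is first oriented so its
#' AUC is >= 0.5 (as when comparing markers that predict in opposite
#' directions); identical or rank-equivalent markers give difference 0 and
#' p = 1.
#'
#' @param scores1,scores2 Marker values on the same patients.
#' @param labels Shared case indicator.
#' @param orient Auto-orient each marker before comparing (default TRUE).
#' @return A list: `auc1`, `auc2`, `difference`, `z`, `p_value`.
#' @export
delong_compare <- function(scores1, scores2, labels, orient = TRUE) {
  y <- as.logical(labels)
  if (length(scores1) != length(scores2) || length(scores1) != length(y))
    stop("markers must be measured on the same patients")
  if (!any(y) || all(y)) stop("both classes must be present")
  if (orient) {
    if (auc_mann_whitney(scores1, y) < 0.5) scores1 <- -scores1
    if (auc_mann_whitney(scores2, y) < 0.5) scores2 <- -scores2
  }
  p1 <- delong_placements(scores1[y], scores1[!y])
  p2 <- delong_placements(scores2[y], scores2[!y])
  n1 <- sum(y); n0 <- sum(!y)
  d10 <- p1$v10 - p2$v10
  d01 <- p1$v01 - p2$v01
  var_diff <- stats::var(d10) / n1 + stats::var(d01) / n0
  diff <- p1$auc - p2$auc
  if (var_diff < 1e-14) {
    z <- 0; p <- 1
  } else {
    z <- diff / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc1 = p1$auc, auc2 = p2$auc, difference = diff, z = z, p_value = p)
}
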