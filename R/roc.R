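#' ROC curve and AUC by the Mann-Whitney concordance estimator
#'
#' AUC is the mean over all (positive, negative) pairs of the indicator
#' `score_pos > score_neg`, with half credit for ties (midrank convention) —
#' identical to the Mann-Whitney U statistic divided by `n_pos * n_neg`, and
#' invariant under strictly increasing score transforms. Curve points are
#' generated at every unique score threshold (predict positive when
#' `score >= threshold`).
#'
#' @param scores Numeric marker values, higher = more indicative of the
#'   event.
#' @param labels Binary 0/1 outcome labels; both classes must be present.
#' @return A list of class `roc_result`: `auc`, `curve` (data.frame with
#'   `threshold`, `fpr`, `tpr`), `n_pos`, `n_neg`.
#' @export
auc_mann_whitney <- function(scores, labels) {
  scores <- as.numeric(scores); labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stop("length mismatch", call. = FALSE)
  if (anyNA(scores)) stop("scores must not contain NA", call. = FALSE)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("both outcome classes must be present", call. = FALSE)

  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[labels == 1] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[labels == 0] >= t), numeric(1))
  structure(list(auc = auc,
                 curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC AUC = %.4f (%d events / %d non-events)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

# placement values (structural components): for each positive, the fraction
# of negatives it beats (ties at half credit), and vice versa
placements <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong paired test for two correlated AUCs
#'
#' Nonparametric comparison of the AUCs of two markers measured on the same
#' subjects, using the placement-value (structural-components) covariance
#' estimator with midrank tie handling:
#' `var(AUC1 - AUC2) = (s10_11 + s10_22 - 2 s10_12)/n_pos +
#' (s01_11 + s01_22 - 2 s01_12)/n_neg`, `z = diff / sqrt(var)`, two-sided
#' normal p-value.
#'
#' @param scores1,scores2 Marker values for the same subjects.
#' @param labels Common binary 0/1 labels; both classes present.
#' @return A list of class `delong_test`: `auc1`, `auc2`, `difference`
#'   (`auc1 - auc2`), `variance`, `z`, `p`, `degenerate` (TRUE when the
#'   variance estimate is zero but the AUCs differ).
#' @export
delong_paired_test <- function(scores1, scores2, labels) {
  labels <- as.numeric(labels)
  if (length(scores1) != length(labels) || length(scores2) != length(labels))
    stop("scores and labels must have equal length (same subjects)",
         call. = FALSE)
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2)
    stop("labels must be 0/1 with both classes present", call. = FALSE)

  p1 <- placements(as.numeric(scores1), labels)
  p2 <- placements(as.numeric(scores2), labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)

  s10 <- stats::cov(cbind(p1$v10, p2$v10))
  s01 <- stats::cov(cbind(p1$v01, p2$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n_pos +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n_neg
  diff <- p1$auc - p2$auc

  if (v <= 0 || !is.finite(v)) {
    if (abs(diff) < 1e-12)
      return(structure(list(auc1 = p1$auc, auc2 = p2$auc, difference = 0,
                            variance = 0, z = 0, p = 1, degenerate = FALSE),
                       class = "delong_test"))
    return(structure(list(auc1 = p1$auc, auc2 = p2$auc, difference = diff,
                          variance = 0, z = NA_real_, p = NA_real_,
                          degenerate = TRUE),
                     class = "delong_test"))
  }
  z <- diff / sqrt(v)
  structure(list(auc1 = p1$auc, auc2 = p2$auc, difference = diff,
                 variance = v, z = z, p = 2 * stats::pnorm(-abs(z)),
                 degenerate = FALSE),
            class = "delong_test")
}

#' @export
print.delong_test <- function(x, ...) {
  cat(sprintf("DeLong: AUC %.4f vs %.4f, diff %.4f, z = %.3f, p = %.4g%s\n",
              x$auc1, x$auc2, x$difference, x$z, x$p,
              if (isTRUE(x$degenerate)) " [degenerate variance]" else ""))
  invisible(x)
}

#' DeLong variance and confidence interval for a single AUC
#'
#' The placement-value variance `var(V10)/n_pos + var(V01)/n_neg` with a
#' normal-approximation CI. Provided as a convenience for reporting.
#'
#' @inheritParams auc_mann_whitney
#' @param conf_level Confidence level, default 0.95.
#' @return List with `auc`, `variance`, `ci_low`, `ci_high`.
#' @export
auc_delong_ci <- function(scores, labels, conf_level = 0.95) {
  labels <- as.numeric(labels)
  pl <- placements(as.numeric(scores), labels)
  v <- stats::var(pl$v10) / sum(labels == 1) +
    stats::var(pl$v01) / sum(labels == 0)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(auc = pl$auc, variance = v,
       ci_low = max(0, pl$auc - z * sqrt(v)),
       ci_high = min(1, pl$auc + z * sqrt(v)))
}
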