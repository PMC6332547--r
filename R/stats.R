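#' Odds ratio for a 2x2 table with Wald inference
#'
#' Closed-form odds ratio `(a/b) / (c/d)` for a 2x2 contingency table laid
#' out as events/non-events (columns) by exposed/reference group (rows),
#' with a 95% Wald confidence interval `exp(log OR +/- 1.96 * SE)`,
#' `SE = sqrt(1/a + 1/b + 1/c + 1/d)`, and a two-sided Wald p-value. This is
#' the convention that reproduces published univariate tables to their
#' printed precision.
#'
#' With a zero cell the OR degenerates to 0 or Inf; the degenerate point
#' estimate is returned with `estimable = FALSE` and no CI/p (mirroring
#' reports that print "0.00" for an event-free stratum).
#'
#' @param a,b Events and non-events in the exposed group.
#' @param c,d Events and non-events in the reference group.
#' @param conf_level Confidence level, default 0.95.
#' @return A list of class `or_result`: `or`, `ci_low`, `ci_high`, `p`,
#'   `se_log_or`, `estimable`.
#' @examples
#' # female 6 events / 15 non-events vs male 20 / 142
#' odds_ratio(6, 15, 20, 142)  # OR 2.84, CI 0.99-8.17, p 0.053
#' @export
odds_ratio <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  if (any(cells == 0)) {
    or_pt <- (a / b) / (c / d)  # 0, Inf or NaN depending on the zero pattern
    return(structure(list(or = or_pt, ci_low = NA_real_, ci_high = NA_real_,
                          p = NA_real_, se_log_or = NA_real_,
                          estimable = FALSE),
                     class = "or_result"))
  }
  or_pt <- (a / b) / (c / d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(or_pt) + c(-1, 1) * z * se)
  p <- 2 * stats::pnorm(-abs(log(or_pt) / se))
  structure(list(or = or_pt, ci_low = ci[1], ci_high = ci[2], p = p,
                 se_log_or = se, estimable = TRUE),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  if (x$estimable)
    cat(sprintf("OR %.2f (95%% CI %.2f-%.2f), p = %.3f\n",
                x$or, x$ci_low, x$ci_high, x$p))
  else
    cat(sprintf("OR %.2f (non-estimable: zero cell)\n", x$or))
  invisible(x)
}

#' Univariate logistic regression with Wald inference
#'
#' Maximum-likelihood fit of `logit P(y=1) = intercept + beta * x` via
#' [stats::glm()] (IRLS). For a binary 0/1 covariate the fitted OR equals
#' the closed-form [odds_ratio()] of the corresponding 2x2 table to machine
#' precision. Complete separation and non-identifiable (constant-x) designs
#' are flagged, never silently estimated.
#'
#' @param x Numeric covariate (continuous or 0/1), finite.
#' @param y Binary 0/1 outcome; both classes must be present.
#' @return A list of class `logistic_fit`: `beta`, `se`, `or_per_unit`,
#'   `ci_low`, `ci_high`, `p`, `converged`, `identifiable`, `n`.
#' @export
logistic_fit_univariate <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (any(!is.finite(x))) stop("x must be finite", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("both outcome classes must be present", call. = FALSE)
  if (stats::sd(x) == 0)
    return(structure(list(beta = NA_real_, se = NA_real_,
                          or_per_unit = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, p = NA_real_,
                          converged = FALSE, identifiable = FALSE,
                          n = length(y)),
                     class = "logistic_fit"))
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  beta <- sm["x", "Estimate"]; se <- sm["x", "Std. Error"]
  converged <- fit$converged && !separated && is.finite(se) && se < 1e3
  structure(list(beta = beta, se = se, or_per_unit = exp(beta),
                 ci_low = exp(beta - 1.959963984540054 * se),
                 ci_high = exp(beta + 1.959963984540054 * se),
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 converged = converged, identifiable = TRUE, n = length(y)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (!x$identifiable) {
    cat("logistic fit: slope non-identifiable (constant covariate)\n")
  } else {
    cat(sprintf("OR per unit %.3f (95%% CI %.3f-%.3f), p = %.4g%s\n",
                x$or_per_unit, x$ci_low, x$ci_high, x$p,
                if (x$converged) "" else " [NOT CONVERGED / SEPARATED]"))
  }
  invisible(x)
}

#' Mann-Whitney U test
#'
#' U statistic from midranks (so ties are handled), with a two-sided
#' p-value by exact enumeration when the combined sample size is at most 10
#' and no ties are present, otherwise by the normal approximation with tie
#' correction and continuity correction. Inference is delegated to
#' [stats::wilcox.test()]; the U statistic reported is for `sample_a`
#' (number of (a, b) pairs with a > b, half credit for ties).
#'
#' @param sample_a,sample_b Non-empty numeric samples.
#' @return A list of class `mwu_result`: `u`, `p`, `method`, `n_a`, `n_b`.
#' @export
mann_whitney_u <- function(sample_a, sample_b) {
  sample_a <- as.numeric(sample_a); sample_b <- as.numeric(sample_b)
  if (!length(sample_a) || !length(sample_b))
    stop("both samples must be non-empty", call. = FALSE)
  if (anyNA(sample_a) || anyNA(sample_b))
    stop("samples must not contain NA", call. = FALSE)
  n_a <- length(sample_a); n_b <- length(sample_b)
  r <- rank(c(sample_a, sample_b))
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- any(duplicated(c(sample_a, sample_b)))
  exact <- (n_a + n_b) <= 10 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, exact = exact,
                       correct = TRUE, alternative = "two.sided"))
  structure(list(u = u, p = wt$p.value,
                 method = if (exact) "exact" else "normal_approx",
                 n_a = n_a, n_b = n_b),
            class = "mwu_result")
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d, %d), p = %.4g (%s)\n",
              x$u, x$n_a, x$n_b, x$p, x$method))
  invisible(x)
}

#' Paired mean difference with t-based confidence interval
#'
#' Mean of `x - y` over matched pairs with a 95% t interval and paired
#' t-test p-value. The sign convention follows the arguments: pass the
#' larger-valued series first to report the positive magnitude. A
#' zero-variance difference (e.g. a constant offset) is returned with a
#' degenerate zero-width CI and `degenerate = TRUE`.
#'
#' @param x,y Matched numeric vectors of equal length >= 2.
#' @return A list of class `paired_diff`: `mean_difference`, `ci_low`,
#'   `ci_high`, `p`, `n`, `degenerate`.
#' @export
paired_mean_difference <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  # numerically constant differences (e.g. an exact offset) are degenerate
  if (stats::sd(d) < 1e-10 * max(abs(d), 1)) {
    m <- mean(d)
    return(structure(list(mean_difference = m, ci_low = m, ci_high = m,
                          p = if (m == 0) 1 else 0, n = length(d),
                          degenerate = TRUE),
                     class = "paired_diff"))
  }
  tt <- stats::t.test(d)
  structure(list(mean_difference = unname(tt$estimate),
                 ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
                 p = tt$p.value, n = length(d), degenerate = FALSE),
            class = "paired_diff")
}

#' @export
print.paired_diff <- function(x, ...) {
  cat(sprintf("paired mean difference %.3f (95%% CI %.3f-%.3f), p = %.4g%s\n",
              x$mean_difference, x$ci_low, x$ci_high, x$p,
              if (x$degenerate) " [zero-variance]" else ""))
  invisible(x)
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject ANOVA for one factor measured under k conditions on every
#' subject (here: a dose metric under the three lung definitions).
#' `F = MS_condition / MS_error` on `(k - 1, (k - 1)(n - 1))` degrees of
#' freedom. The balanced complete design admits the closed-form sum-of-squares
#' decomposition (total = subjects + conditions + error), which is computed
#' directly — identical to [stats::aov()] with an `Error(subject)` stratum but
#' without materializing an n-level factor design matrix, so it stays fast for
#' cohorts of thousands. Degenerate inputs are flagged explicitly: identical columns give
#' `degenerate = "identical_columns"`; zero error variance with a real
#' condition effect gives p = 0 and `degenerate = "zero_error_variance"`.
#'
#' @param values Numeric matrix or data.frame, subjects in rows, conditions
#'   in columns (>= 3 subjects, >= 2 conditions, no missing cells).
#' @return A list of class `rm_anova`: `f`, `p`, `df1`, `df2`, `degenerate`
#'   (NULL when regular).
#' @export
repeated_measures_anova <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing cells are not supported", call. = FALSE)
  n <- nrow(values); k <- ncol(values)
  if (n < 3 || k < 2)
    stop("need >= 3 subjects and >= 2 conditions", call. = FALSE)
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)

  grand <- mean(values)
  ss_cond <- n * sum((colMeans(values) - grand)^2)
  ss_subj <- k * sum((rowMeans(values) - grand)^2)
  ss_err <- sum((values - grand)^2) - ss_cond - ss_subj
  ms_cond <- ss_cond / df1
  ms_err <- max(ss_err, 0) / df2  # guard tiny negative rounding residue

  scale_ref <- max(abs(values), 1)
  if (ms_err < 1e-12 * scale_ref^2) {
    if (ms_cond < 1e-12 * scale_ref^2)
      return(structure(list(f = NA_real_, p = NA_real_, df1 = df1, df2 = df2,
                            degenerate = "identical_columns"),
                       class = "rm_anova"))
    return(structure(list(f = Inf, p = 0, df1 = df1, df2 = df2,
                          degenerate = "zero_error_variance"),
                     class = "rm_anova"))
  }
  f <- ms_cond / ms_err
  structure(list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
                 df1 = df1, df2 = df2, degenerate = NULL),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  if (!is.null(x$degenerate))
    cat(sprintf("repeated-measures ANOVA: degenerate (%s)\n", x$degenerate))
  else
    cat(sprintf("repeated-measures ANOVA F(%d, %d) = %.3f, p = %.4g\n",
                x$df1, x$df2, x$f, x$p))
  invisible(x)
}
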