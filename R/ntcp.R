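#' Lyman NTCP model parameters
#'
#' The Lyman model maps an effective dose through a probit curve,
#' `NTCP = Phi(t)` with `t = (d_eff - TD50) / (m * TD50)`: `TD50` is the dose
#' producing 50% complication probability, `m` the (dimensionless) relative
#' slope. The volume-effect exponent `n` is fixed at 1 here, which reduces
#' the effective dose to the mean lung dose — the covariate used throughout
#' this package.
#'
#' @param td50 Dose at 50% complication probability (Gy), > 0.
#' @param m Relative slope, > 0.
#' @return An object of class `lyman_params`.
#' @export
lyman_params <- function(td50, m) {
  if (!is.numeric(td50) || length(td50) != 1L || !is.finite(td50) || td50 <= 0)
    stop("`td50` must be a single positive dose (Gy)", call. = FALSE)
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m <= 0)
    stop("`m` must be a single positive slope", call. = FALSE)
  structure(list(td50 = td50, m = m, n = 1), class = "lyman_params")
}

#' @export
print.lyman_params <- function(x, ...) {
  cat(sprintf("<lyman_params> TD50 = %.3f Gy, m = %.4f, n = %d\n",
              x$td50, x$m, x$n))
  invisible(x)
}

#' Lyman NTCP dose-response
#'
#' Complication probability at effective dose `d_eff` (here: MLD), computed
#' through the standard-normal CDF. Strictly increasing in dose.
#'
#' @param d_eff Effective dose(s) in Gy, >= 0 (vectorized).
#' @param params A [lyman_params()].
#' @return Probabilities in (0, 1).
#' @examples
#' p <- lyman_params(17.5, 0.34)
#' ntcp_lyman(17.5, p)  # 0.5 by probit symmetry
#' @export
ntcp_lyman <- function(d_eff, params) {
  stopifnot(inherits(params, "lyman_params"))
  if (any(!is.finite(d_eff)) || any(d_eff < 0))
    stop("`d_eff` must be finite non-negative dose (Gy)", call. = FALSE)
  stats::pnorm((d_eff - params$td50) / (params$m * params$td50))
}

#' Iso-risk cutoff dose
#'
#' Exact inverse of [ntcp_lyman()]: the dose at which the fitted curve
#' crosses a target complication probability,
#' `D = TD50 * (1 + m * qnorm(p_target))`. With `p_target = 0.20` this is
#' the MLD constraint that limits predicted pneumonitis incidence to 20%.
#'
#' @param params A [lyman_params()].
#' @param p_target Target probability in (0, 1).
#' @return Cutoff dose in Gy.
#' @export
cutoff_dose <- function(params, p_target) {
  stopifnot(inherits(params, "lyman_params"))
  if (!is.numeric(p_target) || any(p_target <= 0) || any(p_target >= 1))
    stop("`p_target` must lie strictly inside (0, 1)", call. = FALSE)
  params$td50 * (1 + params$m * stats::qnorm(p_target))
}

#' Solve Lyman parameters through two (dose, probability) anchors
#'
#' Closed-form two-point probit solve: given NTCP(d1) = p1 and
#' NTCP(d2) = p2, `m * TD50 = (d2 - d1) / (z2 - z1)` and
#' `TD50 = d1 - z1 * m * TD50` with `z = qnorm(p)`. Used both as a
#' convenience for reconstructing a published curve from two printed points
#' and as the oracle for the MLE fitter.
#'
#' @param d1,d2 Anchor doses (Gy), distinct.
#' @param p1,p2 Anchor probabilities in (0, 1), distinct.
#' @return A [lyman_params()].
#' @export
lyman_from_anchors <- function(d1, p1, d2, p2) {
  stopifnot(d1 != d2, p1 > 0, p1 < 1, p2 > 0, p2 < 1, p1 != p2)
  z1 <- stats::qnorm(p1); z2 <- stats::qnorm(p2)
  mt <- (d2 - d1) / (z2 - z1)
  td50 <- d1 - z1 * mt
  lyman_params(td50, mt / td50)
}

# Bernoulli negative log-likelihood with probability clipping so extreme
# parameter proposals during the grid/simplex search never produce -Inf.
lyman_nll <- function(par, doses, outcomes) {
  td50 <- par[1]; m <- par[2]
  if (!is.finite(td50) || !is.finite(m) || td50 <= 0 || m <= 0) return(Inf)
  p <- stats::pnorm((doses - td50) / (m * td50))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(outcomes * log(p) + (1 - outcomes) * log(1 - p))
}

#' Maximum-likelihood fit of the Lyman NTCP model
#'
#' Fits `(TD50, m)` (with `n` fixed at 1, dose covariate = MLD) by maximizing
#' the Bernoulli log-likelihood. The optimizer is deterministic: a coarse
#' grid search over TD50 in `[5, 60]` Gy by m in `[0.05, 2]`, followed by
#' Nelder-Mead refinement from the best grid point — no stochastic restarts,
#' so fits are bit-reproducible given the data.
#'
#' @param doses Numeric vector of per-patient effective doses (MLD, Gy).
#' @param outcomes Binary vector (0/1) of the same length; both classes must
#'   be present, else the parameters are non-identifiable.
#' @return An object of class `lyman_fit`: `params` ([lyman_params()]),
#'   `log_likelihood`, `converged`, `at_boundary`, `n_patients`, `n_events`.
#' @export
fit_lyman_mle <- function(doses, outcomes) {
  doses <- as.numeric(doses); outcomes <- as.numeric(outcomes)
  if (length(doses) != length(outcomes))
    stop("`doses` and `outcomes` must have equal length", call. = FALSE)
  if (any(!is.finite(doses)) || any(doses < 0))
    stop("doses must be finite non-negative (Gy)", call. = FALSE)
  if (!all(outcomes %in% c(0, 1)))
    stop("outcomes must be binary 0/1", call. = FALSE)
  if (sum(outcomes) == 0 || sum(outcomes) == length(outcomes))
    stop("all-event or no-event outcomes: (td50, m) non-identifiable",
         call. = FALSE)

  grid_td50 <- seq(5, 60, by = 1)
  grid_m <- seq(0.05, 2, by = 0.05)
  gr <- expand.grid(td50 = grid_td50, m = grid_m)
  nll <- mapply(function(t, mm) lyman_nll(c(t, mm), doses, outcomes),
                gr$td50, gr$m)
  best <- gr[which.min(nll), ]

  opt <- stats::optim(c(best$td50, best$m), lyman_nll, doses = doses,
                      outcomes = outcomes, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  td50 <- opt$par[1]; m <- opt$par[2]
  at_boundary <- td50 <= min(grid_td50) || td50 >= max(grid_td50) ||
    m <= min(grid_m) || m >= max(grid_m)
  structure(list(params = lyman_params(td50, m),
                 log_likelihood = -opt$value,
                 converged = opt$convergence == 0 && !at_boundary,
                 at_boundary = at_boundary,
                 n_patients = length(doses),
                 n_events = sum(outcomes)),
            class = "lyman_fit")
}

#' @export
print.lyman_fit <- function(x, ...) {
  cat(sprintf(paste0("<lyman_fit> TD50 = %.2f Gy, m = %.3f (n = 1), ",
                     "logLik = %.2f, %d/%d events%s\n"),
              x$params$td50, x$params$m, x$log_likelihood,
              x$n_events, x$n_patients,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Compare fitted NTCP curves across lung definitions
#'
#' Evaluates each fit at the requested dose points and reports all pairwise
#' relative probability differences, `100 * (p_high - p_low) / p_low`
#' (percent relative to the smaller probability), rounded to integer
#' percent — the convention under which probability pairs 0.13 vs 0.20 and
#' 0.20 vs 0.29 differ by 54% and 45%.
#'
#' @param fits Named list (>= 2) of [lyman_params()] or `lyman_fit` objects,
#'   one per lung definition.
#' @param dose_grid_points Numeric vector of doses (Gy) at which to compare.
#' @return A data.frame with one row per dose point per ordered pair:
#'   `dose_gy`, `def_low`, `def_high`, `p_low`, `p_high`, `rel_diff_pct`.
#' @export
compare_definitions_ntcp <- function(fits, dose_grid_points) {
  if (length(fits) < 2) stop("need at least two fits", call. = FALSE)
  pars <- lapply(fits, function(f)
    if (inherits(f, "lyman_fit")) f$params else f)
  stopifnot(all(vapply(pars, inherits, logical(1), "lyman_params")))
  nms <- names(pars)
  if (is.null(nms)) nms <- paste0("def", seq_along(pars))
  out <- list()
  for (d in dose_grid_points) {
    p <- vapply(pars, function(q) ntcp_lyman(d, q), numeric(1))
    cmb <- utils::combn(seq_along(p), 2)
    for (c_i in seq_len(ncol(cmb))) {
      i <- cmb[1, c_i]; j <- cmb[2, c_i]
      lo <- if (p[i] <= p[j]) i else j
      hi <- if (p[i] <= p[j]) j else i
      out[[length(out) + 1L]] <- data.frame(
        dose_gy = d, def_low = nms[lo], def_high = nms[hi],
        p_low = p[lo], p_high = p[hi],
        rel_diff_pct = relative_risk_difference_pct(p[lo], p[hi]))
    }
  }
  do.call(rbind, out)
}

#' Relative probability difference in percent
#'
#' `100 * (p_high - p_low) / p_low`, rounded to integer percent. This is the
#' "probability variance" quoted when two dose-response curves are compared
#' at a common dose.
#'
#' @param p_low,p_high Probabilities with `p_low <= p_high`. A zero `p_low`
#'   makes the relative difference undefined; `NA` is returned.
#' @return Integer percent, or `NA` when `p_low` is 0.
#' @export
relative_risk_difference_pct <- function(p_low, p_high) {
  stopifnot(p_low >= 0, p_high >= p_low)
  if (p_low == 0) return(NA_real_)
  round(100 * (p_high - p_low) / p_low)
}
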