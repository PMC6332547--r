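DEF_SUFFIX <- c("Lung-PTV" = "lungptv", "Lung-PGTV" = "lungpgtv",
                "Total Lung" = "total")
METRICS <- c("v5", "v20", "mld")

#' Analysis configuration
#'
#' @param p_target Iso-risk probability for cutoff-dose inversion, in
#'   (0, 1); default 0.20.
#' @param definitions Display names of the lung definitions to analyze
#'   (subset of `"Lung-PTV"`, `"Lung-PGTV"`, `"Total Lung"`).
#' @param bin_width DVH bin width in Gy (kept in the config echo; DVHs are
#'   produced by the phantom demo, the cohort analysis consumes metrics).
#' @param seed Integer seed echoed into outputs (the analysis itself is
#'   deterministic).
#' @param output_dir Directory for report files, or `NULL` for no files.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(p_target = 0.20,
                            definitions = names(DEF_SUFFIX),
                            bin_width = 0.1, seed = 1L, output_dir = NULL) {
  if (!is.numeric(p_target) || p_target <= 0 || p_target >= 1)
    stop("`p_target` must lie in (0, 1)", call. = FALSE)
  definitions <- match.arg(definitions, names(DEF_SUFFIX), several.ok = TRUE)
  if (!length(definitions)) stop("need at least one definition", call. = FALSE)
  structure(list(p_target = p_target, definitions = definitions,
                 bin_width = bin_width, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "analysis_config")
}

or_row <- function(factor_name, level, a, b, c, d) {
  orr <- odds_ratio(a, b, c, d)
  data.frame(factor = factor_name, level = level,
             n = a + b, n_events = a,
             or = orr$or, ci_low = orr$ci_low, ci_high = orr$ci_high,
             p = orr$p, estimable = orr$estimable)
}

# Table-1-style covariate screen: every non-reference level of each
# categorical covariate against its reference, continuous covariates
# dichotomized at <= median vs > median (reference = lower half).
covariate_or_table <- function(cohort) {
  y <- cohort$rp2
  rows <- list()
  add_cat <- function(name, values, ref) {
    for (lev in setdiff(unique(values), ref)) {
      a <- sum(values == lev & y == 1); b <- sum(values == lev & y == 0)
      c <- sum(values == ref & y == 1); d <- sum(values == ref & y == 0)
      rows[[length(rows) + 1L]] <<- or_row(name, paste(lev, "vs", ref),
                                           a, b, c, d)
    }
  }
  add_median_split <- function(name, values) {
    med <- stats::median(values)
    hi <- values > med
    rows[[length(rows) + 1L]] <<- or_row(
      name, sprintf("> %.1f (median) vs <=", med),
      sum(hi & y == 1), sum(hi & y == 0),
      sum(!hi & y == 1), sum(!hi & y == 0))
  }
  add_median_split("age", cohort$age)
  add_cat("gender", cohort$gender, "male")
  add_cat("smoking", cohort$smoking, "never")
  add_cat("pathology", cohort$pathology, "squamous")
  add_cat("stage", cohort$stage, "III")
  add_cat("chemo", ifelse(cohort$chemo == 1, "yes", "no"), "no")
  add_cat("surgery", ifelse(cohort$surgery == 1, "yes", "no"), "no")
  add_median_split("pgtv_volume_cm3", cohort$pgtv_volume_cm3)
  add_median_split("ptv_volume_cm3", cohort$ptv_volume_cm3)
  add_median_split("pgtv_rx_gy", cohort$pgtv_rx_gy)
  add_median_split("ptv_rx_gy", cohort$ptv_rx_gy)
  do.call(rbind, rows)
}

# Table-2-style paired differences between definitions, reported as the
# larger-metric definition minus the smaller (Lung-PTV has the smallest
# metrics, Total Lung the largest), plus the repeated-measures ANOVA across
# all analyzed definitions.
paired_difference_table <- function(cohort, defs) {
  sufs <- DEF_SUFFIX[defs]
  rows <- list()
  for (metric in METRICS) {
    cols <- paste0(metric, "_", sufs)
    if (length(cols) >= 2) {
      cmb <- utils::combn(seq_along(cols), 2)
      for (ci in seq_len(ncol(cmb))) {
        i <- cmb[1, ci]; j <- cmb[2, ci]  # j is the larger-volume definition
        pd <- paired_mean_difference(cohort[[cols[j]]], cohort[[cols[i]]])
        rows[[length(rows) + 1L]] <- data.frame(
          metric = toupper(metric),
          comparison = paste(defs[i], "vs.", defs[j]),
          mean_difference = pd$mean_difference,
          ci_low = pd$ci_low, ci_high = pd$ci_high, p_paired_t = pd$p,
          degenerate = pd$degenerate)
      }
    }
  }
  do.call(rbind, rows)
}

rm_anova_table <- function(cohort, defs) {
  sufs <- DEF_SUFFIX[defs]
  if (length(sufs) < 3) return(NULL)
  do.call(rbind, lapply(METRICS, function(metric) {
    an <- repeated_measures_anova(as.matrix(cohort[, paste0(metric, "_", sufs)]))
    data.frame(metric = toupper(metric), f = an$f, df1 = an$df1,
               df2 = an$df2, p = an$p,
               degenerate = if (is.null(an$degenerate)) "" else an$degenerate)
  }))
}

# Table-3-style descriptives: median and range of each metric in RP2 vs
# non-RP2 patients with the Mann-Whitney p-value.
group_comparison_table <- function(cohort, defs) {
  y <- cohort$rp2
  rows <- list()
  for (def in defs) {
    for (metric in METRICS) {
      col <- paste0(metric, "_", DEF_SUFFIX[def])
      v0 <- cohort[[col]][y == 0]; v1 <- cohort[[col]][y == 1]
      mw <- mann_whitney_u(v1, v0)
      rows[[length(rows) + 1L]] <- data.frame(
        definition = def, metric = toupper(metric),
        median_non_rp2 = stats::median(v0),
        min_non_rp2 = min(v0), max_non_rp2 = max(v0),
        median_rp2 = stats::median(v1),
        min_rp2 = min(v1), max_rp2 = max(v1),
        u = mw$u, p_mann_whitney = mw$p)
    }
  }
  do.call(rbind, rows)
}

# Table-4-style univariate logistic regressions of RP2 on each metric.
univariate_or_table <- function(cohort, defs) {
  rows <- list()
  for (def in defs) {
    for (metric in METRICS) {
      col <- paste0(metric, "_", DEF_SUFFIX[def])
      fit <- logistic_fit_univariate(cohort[[col]], cohort$rp2)
      rows[[length(rows) + 1L]] <- data.frame(
        definition = def, metric = toupper(metric),
        or_per_unit = fit$or_per_unit, ci_low = fit$ci_low,
        ci_high = fit$ci_high, p = fit$p, converged = fit$converged)
    }
  }
  do.call(rbind, rows)
}

roc_comparison_table <- function(cohort, defs) {
  y <- cohort$rp2
  aucs <- list()
  for (def in defs)
    for (metric in METRICS) {
      col <- paste0(metric, "_", DEF_SUFFIX[def])
      aucs[[length(aucs) + 1L]] <- data.frame(
        definition = def, metric = toupper(metric),
        auc = auc_mann_whitney(cohort[[col]], y)$auc)
    }
  auc_tab <- do.call(rbind, aucs)

  pairs <- list()
  if (length(defs) >= 2) {
    cmb <- utils::combn(seq_along(defs), 2)
    for (metric in METRICS)
      for (ci in seq_len(ncol(cmb))) {
        i <- cmb[1, ci]; j <- cmb[2, ci]
        c1 <- paste0(metric, "_", DEF_SUFFIX[defs[i]])
        c2 <- paste0(metric, "_", DEF_SUFFIX[defs[j]])
        dl <- delong_paired_test(cohort[[c1]], cohort[[c2]], y)
        pairs[[length(pairs) + 1L]] <- data.frame(
          metric = toupper(metric), def1 = defs[i], def2 = defs[j],
          auc1 = dl$auc1, auc2 = dl$auc2, difference = dl$difference,
          z = dl$z, p_delong = dl$p)
      }
  }
  list(auc = auc_tab,
       delong = if (length(pairs)) do.call(rbind, pairs) else NULL)
}

ntcp_fit_table <- function(cohort, defs, p_target) {
  fits <- list(); rows <- list()
  for (def in defs) {
    col <- paste0("mld_", DEF_SUFFIX[def])
    fit <- fit_lyman_mle(cohort[[col]], cohort$rp2)
    fits[[def]] <- fit
    rows[[length(rows) + 1L]] <- data.frame(
      definition = def, td50_gy = fit$params$td50, m = fit$params$m, n = 1,
      log_likelihood = fit$log_likelihood, converged = fit$converged,
      n_patients = fit$n_patients, n_events = fit$n_events,
      cutoff_mld_gy = cutoff_dose(fit$params, p_target),
      p_target = p_target)
  }
  list(fits = fits, table = do.call(rbind, rows))
}

#' End-to-end cohort analysis
#'
#' Runs the full univariate analysis of a cohort table: covariate odds
#' ratios, paired between-definition metric differences with
#' repeated-measures ANOVA, RP2 vs non-RP2 descriptives with Mann-Whitney
#' tests, univariate logistic regressions, ROC/AUC with DeLong paired
#' comparisons, Lyman NTCP fits per definition with iso-risk MLD cutoffs,
#' and the between-definition NTCP probability comparison at those cutoffs.
#' Deterministic given the input table and config; when `output_dir` is set,
#' all report CSVs, `ntcp_fits.json`, `ntcp_curves.csv`, `run_log.txt` and
#' `config_echo.json` are written (byte-stable across identical runs).
#'
#' With a single-class outcome the inferential tables are downgraded: only
#' descriptives are produced and `report$downgraded` explains why.
#'
#' @param cohort A cohort data.frame (schema of [cohort_schema()]) or a path
#'   to such a CSV.
#' @param config An [analysis_config()].
#' @return A list of class `analysis_report` with elements
#'   `covariate_or` (table1), `paired_differences` + `rm_anova` (table2),
#'   `group_comparison` (table3), `univariate_or` (table4), `roc`
#'   (`$auc`, `$delong`), `ntcp` (`$table`, `$fits`, `$comparison`),
#'   `incidence`, `n`, `downgraded`, `log`.
#' @export
run_analysis <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.character(cohort)) cohort <- read_cohort_csv(cohort)
  validate_cohort(cohort)
  defs <- config$definitions
  n <- nrow(cohort); n_events <- sum(cohort$rp2)
  log_lines <- c(sprintf("run_analysis: n=%d, events=%d (%.1f%%), definitions=%s, p_target=%.2f, seed=%d",
                         n, n_events, 100 * n_events / n,
                         paste(defs, collapse = "/"), config$p_target,
                         config$seed))

  report <- list(n = n, n_events = n_events,
                 incidence = n_events / n, downgraded = NULL)

  single_class <- n_events == 0 || n_events == n
  report$group_descriptives_overall <- do.call(rbind, lapply(defs, function(def)
    do.call(rbind, lapply(METRICS, function(metric) {
      col <- paste0(metric, "_", DEF_SUFFIX[def])
      data.frame(definition = def, metric = toupper(metric),
                 median = stats::median(cohort[[col]]),
                 min = min(cohort[[col]]), max = max(cohort[[col]]))
    }))))

  if (single_class) {
    report$downgraded <- paste("outcome has a single class:",
                               "inferential tables omitted, descriptives only")
    log_lines <- c(log_lines, report$downgraded)
  } else {
    unstable <- n_events < 5 || (n - n_events) < 5
    if (unstable) {
      report$downgraded <- paste("fewer than 5 events or non-events:",
                                 "inferential estimates are unstable")
      log_lines <- c(log_lines, report$downgraded)
    }
    # a section that cannot be computed on this cohort (e.g. too few
    # subjects) is dropped with an explicit log line, never a hard failure
    try_section <- function(label, expr) {
      tryCatch({
        log_lines <<- c(log_lines, label)
        expr
      }, error = function(e) {
        log_lines <<- c(log_lines, paste0(label, " SKIPPED: ",
                                          conditionMessage(e)))
        NULL
      })
    }
    report$covariate_or <- try_section(
      "covariate_or_table: odds_ratio per Table-1-style row",
      covariate_or_table(cohort))
    report$paired_differences <- try_section(
      "paired_difference_table: paired_mean_difference per metric pair",
      paired_difference_table(cohort, defs))
    report$rm_anova <- try_section(
      "rm_anova_table: repeated_measures_anova per metric",
      rm_anova_table(cohort, defs))
    report$group_comparison <- try_section(
      "group_comparison_table: mann_whitney_u per metric/definition",
      group_comparison_table(cohort, defs))
    report$univariate_or <- try_section(
      "univariate_or_table: logistic_fit_univariate per metric/definition",
      univariate_or_table(cohort, defs))
    report$roc <- try_section(
      "roc_comparison_table: auc_mann_whitney + delong_paired_test",
      roc_comparison_table(cohort, defs))
    ntcp <- try_section(
      sprintf("ntcp_fit_table: fit_lyman_mle per definition + cutoff_dose(p=%.2f)",
              config$p_target),
      ntcp_fit_table(cohort, defs, config$p_target))
    if (!is.null(ntcp)) {
      report$ntcp <- list(table = ntcp$table, fits = ntcp$fits)
      if (length(ntcp$fits) >= 2) {
        report$ntcp$comparison <- compare_definitions_ntcp(
          ntcp$fits, sort(unique(round(ntcp$table$cutoff_mld_gy, 1))))
        log_lines <- c(log_lines, "compare_definitions_ntcp at fitted cutoffs")
      }
    }
  }
  report$log <- log_lines
  class(report) <- "analysis_report"

  if (!is.null(config$output_dir)) write_report(report, cohort, config)
  report
}

write_report <- function(report, cohort, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  wr <- function(tab, f) if (!is.null(tab))
    utils::write.csv(tab, out(f), row.names = FALSE)
  wr(report$covariate_or, "report_table1.csv")
  wr(report$paired_differences, "report_table2.csv")
  wr(report$rm_anova, "report_table2_anova.csv")
  wr(report$group_comparison, "report_table3.csv")
  wr(report$univariate_or, "report_table4.csv")
  wr(report$roc$auc, "roc_auc.csv")
  wr(report$roc$delong, "roc_comparison.csv")
  wr(report$ntcp$comparison, "ntcp_comparison.csv")
  if (!is.null(report$ntcp)) {
    jsonlite::write_json(
      lapply(report$ntcp$fits, function(f)
        list(td50_gy = f$params$td50, m = f$params$m, n = 1,
             loglik = f$log_likelihood, converged = f$converged,
             n_patients = f$n_patients, events = f$n_events)),
      out("ntcp_fits.json"), auto_unbox = TRUE, digits = NA)
    dose_gy <- seq(0, 40, by = 0.5)
    curves <- data.frame(dose_gy = dose_gy)
    for (def in names(report$ntcp$fits))
      curves[[paste0("ntcp_", DEF_SUFFIX[def])]] <-
        ntcp_lyman(dose_gy, report$ntcp$fits[[def]]$params)
    utils::write.csv(curves, out("ntcp_curves.csv"), row.names = FALSE)
  }
  writeLines(report$log, out("run_log.txt"))
  jsonlite::write_json(
    list(p_target = config$p_target, definitions = config$definitions,
         bin_width = config$bin_width, seed = config$seed,
         n = report$n, n_events = report$n_events),
    out("config_echo.json"), auto_unbox = TRUE, digits = NA)
  invisible(config$output_dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> n = %d, RP2 events = %d (%.1f%%)\n",
              x$n, x$n_events, 100 * x$incidence))
  if (!is.null(x$downgraded)) cat("  NOTE:", x$downgraded, "\n")
  if (!is.null(x$ntcp)) {
    cat("  NTCP fits:\n")
    for (i in seq_len(nrow(x$ntcp$table)))
      cat(sprintf("    %-10s TD50 = %5.1f Gy, m = %.3f, MLD cutoff(%.0f%%) = %.1f Gy\n",
                  x$ntcp$table$definition[i], x$ntcp$table$td50_gy[i],
                  x$ntcp$table$m[i], 100 * x$ntcp$table$p_target[i],
                  x$ntcp$table$cutoff_mld_gy[i]))
  }
  invisible(x)
}

#' Phantom demonstration: metrics under the three lung definitions
#'
#' Generates the synthetic thorax, derives the three normal-lung masks, and
#' reports V5/V20/MLD per definition together with their DVHs — a
#' self-contained demonstration that the definition-ordering invariant
#' (Lung-PTV <= Lung-PGTV <= Total Lung for every metric) holds by
#' construction. When `output_dir` is set, writes `phantom_metrics.csv` and
#' one `dvh_<definition>.csv` per definition.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed passed to [generate_phantom()].
#' @param bin_width DVH bin width in Gy.
#' @param output_dir Optional output directory.
#' @return List with `metrics` (data.frame, one row per definition),
#'   `dvhs` (named list), `phantom` (dose + masks).
#' @export
run_phantom_demo <- function(config = phantom_config(), seed = 1L,
                             bin_width = 0.1, output_dir = NULL) {
  ph <- generate_phantom(config, seed)
  defs <- lung_definitions(ph$masks$LUNGS, ph$masks$PTV, ph$masks$PGTV)
  display <- c(TOTAL_LUNG = "Total Lung", LUNG_MINUS_PGTV = "Lung-PGTV",
               LUNG_MINUS_PTV = "Lung-PTV")
  metrics <- do.call(rbind, lapply(names(defs), function(nm)
    dose_metrics(ph$dose, defs[[nm]], display[[nm]])))
  dvhs <- lapply(defs, function(m) compute_dvh(ph$dose, m, bin_width))
  names(dvhs) <- display[names(defs)]
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(metrics, file.path(output_dir, "phantom_metrics.csv"),
                     row.names = FALSE)
    for (nm in names(dvhs))
      write_dvh_csv(dvhs[[nm]],
                    file.path(output_dir,
                              paste0("dvh_", gsub("[^A-Za-z0-9]", "_", nm),
                                     ".csv")))
  }
  list(metrics = metrics, dvhs = dvhs, phantom = ph)
}
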