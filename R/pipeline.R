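# End-to-end analysis: full-sample log-t test, club clustering when
# convergence is rejected, and a report mirroring the published table layout
# (coefficient, t-statistic, number of countries, number of years per row).
# Also the small elasticity arithmetic used in the worked examples.

#' Run the full convergence analysis on a cadre panel
#'
#' Computes the full-sample log-t test under the given configuration; when
#' global convergence is rejected, runs the endogenous club clustering.
#' The report echoes the complete configuration so any discrepancy with other
#' implementations is attributable to transform/smoothing/bandwidth choices.
#'
#' @param p A `conv_panel` of densities for one cadre.
#' @param config A [club_config()].
#' @param cadre Label for the cadre analysed (e.g. `"physicians"`,
#'   `"nurses_midwives"`).
#' @return An object of class `analysis_report`: `cadre`, `full_sample`
#'   (`logt_result`), `partition` (`club_partition`), `config`, `n_units`,
#'   `years`.
#' @export
run_analysis <- function(p, config = club_config(), cadre = "physicians") {
  .check_inference_dims(p)
  tp <- relative_transition(p, config$transform, config$hp_lambda)
  full <- logt_regression(tp, trim_fraction = config$trim,
                          bandwidth = config$bandwidth, crit = config$crit)
  partition <- form_clubs(p, config)
  structure(list(cadre = cadre, full_sample = full, partition = partition,
                 config = config, n_units = length(p$unit_ids),
                 years = p$years),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("Convergence analysis: %s, %d locations, %d-%d\n", x$cadre,
              x$n_units, min(x$years), max(x$years)))
  cat(sprintf("  %-10s %8s %9s %6s %6s\n", "", "Coeff", "t-stat",
              "N.loc", "N.yrs"))
  fmt_row <- function(label, r, n) {
    if (is.finite(r$t_stat))
      cat(sprintf("  %-10s %8.3f %9.3f %6d %6d\n", label, r$beta_hat,
                  r$t_stat, n, r$n_years))
    else
      cat(sprintf("  %-10s %8s %9s %6d %6d\n", label, "--", "+Inf", n,
                  r$n_years))
  }
  fmt_row("Log(t)", x$full_sample, x$n_units)
  for (nm in names(x$partition$clubs))
    fmt_row(nm, x$partition$club_results[[nm]], length(x$partition$clubs[[nm]]))
  if (length(x$partition$divergent))
    cat(sprintf("  Divergent: %d location(s)\n", length(x$partition$divergent)))
  cat(sprintf("  config: transform=%s, HP lambda=%s, trim r=%.2f, crit=%.2f, NW lag=%s\n",
              x$config$transform,
              if (is.null(x$config$hp_lambda)) "none" else x$config$hp_lambda,
              x$config$trim, x$config$crit,
              if (is.null(x$config$bandwidth)) "auto" else x$config$bandwidth))
  invisible(x)
}

.config_as_list <- function(cfg) {
  list(transform = cfg$transform,
       hp_lambda = if (is.null(cfg$hp_lambda)) "none" else cfg$hp_lambda,
       trim = cfg$trim, crit = cfg$crit,
       bandwidth = if (is.null(cfg$bandwidth)) "auto" else cfg$bandwidth,
       order_fraction = cfg$order_fraction, cstar = cfg$cstar,
       cstar_step = cfg$cstar_step)
}

#' Serialize an analysis report to JSON
#'
#' @param report An `analysis_report`.
#' @return A JSON string (class `json`). Parsing and re-serializing this
#'   string reproduces it byte-identically.
#' @export
report_json <- function(report) {
  obj <- list(
    cadre = report$cadre,
    n_units = report$n_units,
    years = list(first = min(report$years), last = max(report$years)),
    config = .config_as_list(report$config),
    full_sample = .logt_as_list(report$full_sample),
    partition = .partition_as_list(report$partition)
  )
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Write an analysis report to a JSON file
#'
#' @param report An `analysis_report`.
#' @param file Destination path.
#' @return The file path, invisibly.
#' @export
write_report <- function(report, file) {
  writeLines(report_json(report), file)
  invisible(file)
}

#' Growth elasticity from two percentage changes
#'
#' Ratio of the percent change of an outcome (e.g. physician-density growth
#' over a period) to the percent change of a driver (e.g. real GDP per capita
#' growth), rounded to two decimals for reporting. An elasticity well below
#' one means the outcome responded much less than proportionally.
#'
#' @param pct_change_outcome,pct_change_driver Percent changes (e.g. 129 for
#'   +129%). The driver change must be non-zero.
#' @return The elasticity, rounded to 2 decimals.
#' @examples
#' growth_elasticity(129, 163)  # 0.79
#' growth_elasticity(78, 160)   # 0.49
#' @export
growth_elasticity <- function(pct_change_outcome, pct_change_driver) {
  if (!is.numeric(pct_change_outcome) || !is.numeric(pct_change_driver))
    .err("percent changes must be numeric", "logtclub_domain_error")
  if (any(pct_change_driver == 0))
    .err("driver percent change must be non-zero", "logtclub_domain_error")
  round(pct_change_outcome / pct_change_driver, 2)
}

#' Project an index level through an elasticity
#'
#' Applies the linear elasticity approximation
#' `baseline * (1 + elasticity * rel_change_driver)` — the back-of-envelope
#' arithmetic used to translate "doubling physician density" into index
#' points. The exact log-linear form
#' `baseline * (1 + rel_change_driver)^elasticity` is also available; it gives
#' a smaller projection because the approximation overstates large changes.
#'
#' @param baseline_index Positive baseline level of the index.
#' @param elasticity Dimensionless elasticity.
#' @param rel_change_driver Proportional change of the driver (1.0 = +100%).
#' @param form `"linear"` (default) or `"loglinear"`.
#' @return Projected level, rounded to 1 decimal.
#' @examples
#' project_index(55.6, 0.23, 1.0)                      # 68.4
#' project_index(55.6, 0.23, 1.0, form = "loglinear")  # 65.2
#' @export
project_index <- function(baseline_index, elasticity, rel_change_driver,
                          form = c("linear", "loglinear")) {
  form <- match.arg(form)
  if (!is.numeric(baseline_index) || any(baseline_index <= 0))
    .err("baseline index must be positive", "logtclub_domain_error")
  out <- switch(form,
    linear = baseline_index * (1 + elasticity * rel_change_driver),
    loglinear = baseline_index * (1 + rel_change_driver)^elasticity
  )
  round(out, 1)
}

#' Cross-sectional log-linear fit of an index on workforce densities
#'
#' Ordinary least squares of `ln(haq)` on an intercept, `ln(phy)` and
#' (optionally) `ln(nm)` with classical standard errors — the elasticity
#' regression of a health-system performance index on physician and
#' nurse/midwife densities. Omitting `nm` gives the bivariate fit.
#'
#' @param haq Positive index levels (e.g. Healthcare Access and Quality
#'   index), one per location.
#' @param phy Positive physician densities per 10,000, same length.
#' @param nm Optional positive nurse/midwife densities per 10,000.
#' @return An object of class `haq_fit`: `coefficients`, `se`, `t_stats`
#'   (classical), `adj_r_squared`, `n`, and the underlying `lm` fit.
#' @export
fit_loglinear_haq <- function(haq, phy, nm = NULL) {
  n <- length(haq)
  if (n < 10) .err("need at least 10 observations", "logtclub_insufficient_sample")
  if (length(phy) != n || (!is.null(nm) && length(nm) != n))
    .err("inputs must have equal length", "logtclub_domain_error")
  if (any(haq <= 0) || any(phy <= 0) || (!is.null(nm) && any(nm <= 0)))
    .err("all inputs must be strictly positive for the log transform",
         "logtclub_domain_error")
  dat <- data.frame(lhaq = log(haq), lphy = log(phy))
  fml <- lhaq ~ lphy
  if (!is.null(nm)) {
    dat$lnm <- log(nm)
    fml <- lhaq ~ lphy + lnm
  }
  fit <- stats::lm(fml, data = dat)
  s <- summary(fit)
  structure(list(coefficients = stats::coef(fit),
                 se = s$coefficients[, "Std. Error"],
                 t_stats = s$coefficients[, "t value"],
                 adj_r_squared = s$adj.r.squared,
                 n = n, fit = fit),
            class = "haq_fit")
}

#' @export
print.haq_fit <- function(x, ...) {
  cat("Log-linear index elasticity fit (classical OLS)\n")
  for (nm in names(x$coefficients))
    cat(sprintf("  %-12s %8.3f (se %.3f, t = %.2f)\n", nm,
                x$coefficients[nm], x$se[nm], x$t_stats[nm]))
  cat(sprintf("  N = %d, adj. R-squared = %.2f\n", x$n, x$adj_r_squared))
  invisible(x)
}
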