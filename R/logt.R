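# The trimmed log-t regression. With time indexed t = 1..T, the dependent
# variable y_t = log(H_1/H_t) - 2 log(log t) is regressed on {1, log t} over
# t = floor(rT)+1, ..., T. Under convergence at rate alpha the slope estimates
# beta = 2*alpha >= 0; divergence drives the slope negative. Inference uses a
# Bartlett-kernel (Newey-West) long-run variance with lag truncation
# floor(4 (T_reg/100)^(2/9)). The null of convergence is rejected, one-sided
# at 5%, when t = beta_hat/se < -1.65.

.nw_bandwidth <- function(n) as.integer(floor(4 * (n / 100)^(2 / 9)))

# Closed-form OLS of y on {1, lx} with Bartlett HAC vcov of the scores.
# Returns list(alpha, beta, se_beta, rss, bandwidth).
.ols_hac <- function(lx, y, bandwidth = NULL) {
  n <- length(y)
  sx <- sum(lx); sxx <- sum(lx * lx)
  sy <- sum(y); sxy <- sum(lx * y)
  det <- n * sxx - sx * sx
  beta <- (n * sxy - sx * sy) / det
  alpha <- (sy - beta * sx) / n
  u <- y - alpha - beta * lx
  L <- if (is.null(bandwidth)) .nw_bandwidth(n) else as.integer(bandwidth)
  sc <- cbind(u, u * lx)                       # scores u_t * (1, log t)
  meat <- crossprod(sc)
  if (L >= 1) {
    for (j in seq_len(min(L, n - 1))) {
      w <- 1 - j / (L + 1)
      G <- crossprod(sc[(1 + j):n, , drop = FALSE], sc[1:(n - j), , drop = FALSE])
      meat <- meat + w * (G + t(G))
    }
  }
  xtx_inv <- matrix(c(sxx, -sx, -sx, n), 2, 2) / det
  V <- xtx_inv %*% meat %*% xtx_inv
  list(alpha = alpha, beta = beta, se_beta = sqrt(V[2, 2]),
       rss = sum(u * u), bandwidth = L)
}

.logt_result <- function(alpha, beta, se, t_stat, r, n_units, T, n_reg,
                         bandwidth, crit, rss = NA_real_) {
  structure(list(alpha_hat = alpha, beta_hat = beta, se_beta = se,
                 t_stat = t_stat, trim_fraction = r,
                 n_units = n_units, n_years = T, n_regression_obs = n_reg,
                 hac_bandwidth = bandwidth, crit = crit,
                 converged = convergence_decision(t_stat, crit), rss = rss),
            class = "logt_result")
}

#' The log-t convergence regression
#'
#' Fits \eqn{\log(H_1/H_t) - 2\log(\log t) = \alpha + \beta \log t + \nu_t}
#' over the post-trim window \eqn{t = \lfloor rT \rfloor + 1, \ldots, T} by
#' OLS with a Bartlett-kernel (Newey-West) robust standard error, and applies
#' the one-sided 5% decision rule: convergence is rejected when the
#' t-statistic falls below `crit` (default -1.65).
#'
#' If any retained \eqn{H_t} is exactly zero the cross-section has already
#' collapsed, which is perfect convergence: the result carries a `+Inf`
#' t-statistic sentinel and `converged = TRUE` rather than an error.
#'
#' @param H A `transition_paths` object or a positive numeric series of
#'   cross-sectional transition variances, indexed t = 1..T (T >= 10).
#' @param trim_fraction Fraction r in (0, 0.5) of early periods discarded;
#'   0.3 is the convention for annual data.
#' @param bandwidth Newey-West lag truncation; `NULL` (default) uses
#'   `floor(4 * (T_reg/100)^(2/9))` on the retained sample.
#' @param crit One-sided critical value (default -1.65).
#' @param n_units Cross-section size, recorded in the result (taken from `H`
#'   when it is a `transition_paths`).
#' @return An object of class `logt_result` with fields `alpha_hat`,
#'   `beta_hat`, `se_beta`, `t_stat`, `trim_fraction`, `n_units`, `n_years`,
#'   `n_regression_obs`, `hac_bandwidth`, `converged` and `rss`.
#' @export
logt_regression <- function(H, trim_fraction = 0.3, bandwidth = NULL,
                            crit = -1.65, n_units = NA_integer_) {
  if (inherits(H, "transition_paths")) {
    n_units <- nrow(H$h)
    H <- H$H
  }
  H <- as.numeric(H)
  T <- length(H)
  if (T < 10)
    .err(sprintf("log-t regression needs T >= 10 periods, got %d", T),
         "logtclub_insufficient_sample")
  if (!is.numeric(trim_fraction) || trim_fraction <= 0 || trim_fraction >= 0.5)
    .err("trim fraction must lie in (0, 0.5)", "logtclub_domain_error")
  if (any(H < 0)) .err("H must be non-negative", "logtclub_domain_error")
  trim <- floor(trim_fraction * T)
  stopifnot(trim >= 1)                # guarantees log(log t) is defined (t >= 2)
  tt <- (trim + 1):T
  n_reg <- T - trim
  if (n_reg < 5)
    .err(sprintf("only %d observations remain after trimming; need >= 5", n_reg),
         "logtclub_insufficient_sample")
  L <- if (is.null(bandwidth)) .nw_bandwidth(n_reg) else as.integer(bandwidth)
  if (any(H[tt] == 0)) {
    # retained cross-section fully collapsed: exact convergence
    return(.logt_result(NA_real_, NA_real_, NA_real_, Inf, trim_fraction,
                        n_units, T, n_reg, L, crit, rss = 0))
  }
  if (H[1] == 0)
    .err("H is zero at t = 1 but positive later: dependent variable undefined",
         "logtclub_degenerate_cross_section")
  y <- log(H[1] / H[tt]) - 2 * log(log(tt))
  fit <- .ols_hac(log(tt), y, bandwidth = L)
  .logt_result(fit$alpha, fit$beta, fit$se_beta, fit$beta / fit$se_beta,
               trim_fraction, n_units, T, n_reg, fit$bandwidth, crit,
               rss = fit$rss)
}

#' One-sided convergence decision
#'
#' The null of convergence is rejected at the 5% level iff the robust
#' t-statistic is strictly lower than the critical value; `-1.65` exactly is
#' therefore not a rejection.
#'
#' @param t_stat Robust t-statistic (may be `+Inf`, the perfect-convergence
#'   sentinel).
#' @param crit Critical value, default -1.65.
#' @return `TRUE` (convergence not rejected) or `FALSE` (rejected).
#' @export
convergence_decision <- function(t_stat, crit = -1.65) {
  if (is.na(t_stat)) .err("t-statistic is NA", "logtclub_domain_error")
  !(t_stat < crit)
}

#' @export
print.logt_result <- function(x, ...) {
  cat("log-t convergence regression\n")
  if (is.finite(x$t_stat)) {
    cat(sprintf("  beta_hat = %.3f (se %.3f), t = %.3f\n",
                x$beta_hat, x$se_beta, x$t_stat))
  } else {
    cat("  perfect convergence (H_t = 0 on the retained window)\n")
  }
  cat(sprintf("  N = %s units, T = %d years, %d obs after trim r = %.2f, NW lag %d\n",
              ifelse(is.na(x$n_units), "?", x$n_units), x$n_years,
              x$n_regression_obs, x$trim_fraction, x$hac_bandwidth))
  cat(sprintf("  convergence %s (one-sided crit %.2f)\n",
              if (x$converged) "not rejected" else "REJECTED", x$crit))
  invisible(x)
}

# list view used by the JSON report
.logt_as_list <- function(x) {
  list(alpha_hat = x$alpha_hat, beta_hat = x$beta_hat, se_beta = x$se_beta,
       t_stat = if (is.finite(x$t_stat)) x$t_stat else "Inf",
       trim_fraction = x$trim_fraction, n_units = x$n_units,
       n_years = x$n_years, n_regression_obs = x$n_regression_obs,
       hac_bandwidth = x$hac_bandwidth, converged = x$converged)
}
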