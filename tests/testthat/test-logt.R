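# For H_t decaying exactly as C t^(-2a) (log t)^(-2), the dependent variable
# is affine in log t with slope 2a: the closed-form limit of the method under
# convergence at rate a.
analytic_H <- function(a, T, C = 1) {
  H <- C * (1:T)^(-2 * a) * log(1:T)^(-2)
  H[1] <- C    # t = 1 is undefined in the closed form; any positive H_1 only
               # shifts the intercept and is trimmed out of the window anyway
  H
}

test_that("slope recovers twice the decay rate exactly on analytic H", {
  for (a in c(0.25, 0.5, 1)) {
    res <- logt_regression(analytic_H(a, 30), trim_fraction = 0.3)
    expect_equal(res$beta_hat, 2 * a, tolerance = 1e-8)
    expect_lt(res$rss, 1e-16)
    expect_true(res$converged)
  }
})

test_that("estimates and robust errors match the brute-force oracle", {
  set.seed(314)
  for (i in 1:20) {
    T <- sample(12:40, 1)
    H <- exp(cumsum(rnorm(T, -0.1, 0.3)))
    res <- logt_regression(H, trim_fraction = 0.3)
    o <- oracle_logt(H, r = 0.3)
    expect_equal(res$alpha_hat, o$alpha, tolerance = 1e-10)
    expect_equal(res$beta_hat, o$beta, tolerance = 1e-10)
    expect_equal(res$se_beta, o$se_beta, tolerance = 1e-10)
    expect_equal(res$t_stat, o$t_stat, tolerance = 1e-10)
    expect_identical(res$hac_bandwidth, as.integer(o$bandwidth))
  }
})

test_that("robust variance agrees with an established HAC implementation", {
  set.seed(99)
  for (i in 1:10) {
    T <- sample(15:35, 1)
    H <- exp(cumsum(rnorm(T, -0.05, 0.2)))
    res <- logt_regression(H, trim_fraction = 0.3)
    trim <- floor(0.3 * T)
    tt <- (trim + 1):T
    y <- log(H[1] / H[tt]) - 2 * log(log(tt))
    fit <- lm(y ~ log(tt))
    V <- sandwich::NeweyWest(fit, lag = res$hac_bandwidth, prewhite = FALSE,
                             adjust = FALSE)
    expect_equal(res$se_beta, sqrt(V[2, 2]), tolerance = 1e-8)
  }
})

test_that("result bookkeeping invariants hold", {
  H <- exp(cumsum(rnorm(30, -0.1, 0.2)))
  res <- logt_regression(H, trim_fraction = 0.3)
  expect_equal(res$t_stat, res$beta_hat / res$se_beta, tolerance = 1e-10)
  expect_identical(res$n_regression_obs, 30L - floor(0.3 * 30))
  expect_identical(res$converged, convergence_decision(res$t_stat))
  expect_identical(res$n_years, 30L)
})

test_that("collapsed cross-sections signal perfect convergence, not an error", {
  H <- c(0.5, 0.4, rep(0, 28))
  res <- logt_regression(H)
  expect_true(res$converged)
  expect_identical(res$t_stat, Inf)
  # zero at t = 1 with positive H later has no defined dependent variable
  expect_error(logt_regression(c(0, rep(0.2, 29))),
               class = "logtclub_degenerate_cross_section")
})

test_that("the one-sided decision rule is strict at the critical value", {
  expect_false(convergence_decision(-28.277))
  expect_true(convergence_decision(0.825))
  expect_true(convergence_decision(-1.65))   # 'lower than' is strict
  expect_false(convergence_decision(-1.6500001))
  expect_true(convergence_decision(Inf))
})

test_that("short or over-trimmed samples are refused", {
  expect_error(logt_regression(rep(1, 9)), class = "logtclub_insufficient_sample")
  expect_error(logt_regression(rep(1, 30), trim_fraction = 0.6),
               class = "logtclub_domain_error")
})

test_that("a pure common factor leaves the whole test unchanged (levels mode)", {
  set.seed(8)
  p <- random_panel(12, 25, seed = 8)
  ct <- exp(rnorm(25, 0, 0.4))
  p2 <- panel(sweep(p$values, 2, ct, "*"), p$unit_ids, p$years)
  r1 <- logt_regression(relative_transition(p, "levels", NULL))
  r2 <- logt_regression(relative_transition(p2, "levels", NULL))
  expect_equal(r1$t_stat, r2$t_stat, tolerance = 1e-9)
  expect_equal(r1$beta_hat, r2$beta_hat, tolerance = 1e-9)
})

test_that("a diverging two-club panel is rejected in nearly all replicates", {
  rej <- vapply(1:200, function(s) {
    sim <- simulate_panel(sim_config(n_units_per_club = c(25, 25),
                                     club_deltas = c(2, 1), seed = 5000 + s))
    !logt_regression(relative_transition(sim$panel))$converged
  }, logical(1))
  expect_gte(mean(rej), 0.99)
})
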