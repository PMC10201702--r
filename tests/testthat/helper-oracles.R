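# Independent oracles: literal transcriptions of the defining formulas,
# deliberately naive (dense solves, explicit double sums) so they share no
# code path with the package internals.

# penalized least squares trend: solve (I + lambda D'D) tau = y densely
oracle_hp <- function(y, lambda) {
  n <- length(y)
  D <- diff(diag(n), differences = 2)
  as.vector(solve(diag(n) + lambda * crossprod(D), y))
}

# log-t regression by lm-style normal equations plus an explicit Bartlett
# double-sum long-run variance
oracle_logt <- function(H, r = 0.3, bandwidth = NULL) {
  T <- length(H)
  trim <- floor(r * T)
  tt <- (trim + 1):T
  y <- log(H[1] / H[tt]) - 2 * log(log(tt))
  X <- cbind(1, log(tt))
  n <- length(y)
  b <- solve(crossprod(X), crossprod(X, y))
  u <- as.vector(y - X %*% b)
  L <- if (is.null(bandwidth)) floor(4 * (n / 100)^(2 / 9)) else bandwidth
  M <- matrix(0, 2, 2)
  for (t in 1:n) {
    for (s in 1:n) {
      j <- abs(t - s)
      if (j <= L) {
        M <- M + (1 - j / (L + 1)) * u[t] * u[s] * (X[t, ] %o% X[s, ])
      }
    }
  }
  XtXinv <- solve(crossprod(X))
  V <- XtXinv %*% M %*% XtXinv
  se <- sqrt(V[2, 2])
  list(alpha = b[1], beta = b[2], se_beta = se, t_stat = b[2] / se,
       bandwidth = L)
}

# classical OLS with textbook standard errors
oracle_ols <- function(X, y) {
  XtXinv <- solve(crossprod(X))
  b <- as.vector(XtXinv %*% crossprod(X, y))
  u <- as.vector(y - X %*% b)
  k <- ncol(X)
  n <- length(y)
  sigma2 <- sum(u^2) / (n - k)
  list(coef = b, se = sqrt(diag(sigma2 * XtXinv)))
}

# element-wise re-evaluation of the transition definitions
oracle_transition <- function(values) {
  N <- nrow(values)
  T <- ncol(values)
  h <- matrix(NA_real_, N, T)
  H <- numeric(T)
  for (t in 1:T) {
    m <- sum(values[, t]) / N
    h[, t] <- values[, t] / m
    H[t] <- sum((h[, t] - 1)^2) / N
  }
  list(h = h, H = H)
}

random_panel <- function(n_units = 10, n_years = 20, seed = 1,
                         start_year = 1990) {
  set.seed(seed)
  v <- matrix(exp(rnorm(n_units * n_years, mean = 1.5, sd = 0.5)),
              n_units, n_years)
  panel(v, sprintf("u%03d", seq_len(n_units)),
        start_year + seq_len(n_years) - 1)
}

# club labels (integer, 0 = divergent) implied by a partition, aligned to ids
partition_labels <- function(partition, ids) {
  lab <- setNames(rep(0L, length(ids)), ids)
  for (i in seq_along(partition$clubs)) lab[partition$clubs[[i]]] <- i
  lab
}

truth_labels <- function(truth) {
  setNames(ifelse(is.na(truth$labels$club), 0L, truth$labels$club),
           truth$labels$unit_id)
}
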