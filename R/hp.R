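# Hodrick-Prescott trend extraction by direct solution of the penalized
# least-squares normal equations (I + lambda D'D) tau = y, with D the
# second-difference operator. T is small (decades), so a dense Cholesky
# factorization is cheap; it is cached per (T, lambda) because the clustering
# and simulation loops smooth many series of identical length.

.hp_cache <- new.env(parent = emptyenv())

.hp_inverse <- function(n, lambda) {
  key <- paste(n, lambda, sep = ":")
  inv <- .hp_cache[[key]]
  if (is.null(inv)) {
    D <- diff(diag(n), differences = 2L)
    A <- diag(n) + lambda * crossprod(D)
    inv <- chol2inv(chol(A))
    .hp_cache[[key]] <- inv
  }
  inv
}

#' Hodrick-Prescott trend of a time series
#'
#' Returns the trend component minimizing
#' \eqn{\sum_t (y_t - \tau_t)^2 + \lambda \sum_t (\Delta^2 \tau_t)^2},
#' the standard pre-smoothing step applied to each (log) series before the
#' transition paths are computed. `lambda = 400` is the conventional weight
#' for annual panels.
#'
#' @param x Numeric series, length at least 4.
#' @param lambda Positive smoothing weight.
#' @return Numeric trend of the same length as `x`. A series that is exactly
#'   linear (or constant) is returned unchanged for any `lambda`.
#' @export
hp_smooth <- function(x, lambda = 400) {
  if (length(x) < 4)
    .err(sprintf("series too short for trend extraction: length %d < 4", length(x)),
         "logtclub_insufficient_sample")
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0)
    .err("smoothing weight lambda must be a positive scalar", "logtclub_domain_error")
  as.vector(.hp_inverse(length(x), lambda) %*% x)
}

# Smooth every row of a matrix at once (shared factorization).
.hp_smooth_rows <- function(m, lambda) {
  if (ncol(m) < 4)
    .err("series too short for trend extraction", "logtclub_insufficient_sample")
  out <- m %*% .hp_inverse(ncol(m), lambda)
  dimnames(out) <- dimnames(m)
  out
}
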