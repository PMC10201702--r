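# Relative transition paths: h_it = x_it / cross-sectional mean, and the
# cross-sectional transition variance H_t = mean_i (h_it - 1)^2. Under full
# convergence every h_it tends to 1 and H_t to 0.

# Shared transform step: optional element-wise log, optional per-unit HP
# smoothing. Returns the working matrix x the test and the clustering operate
# on.
.transform_values <- function(p, transform = c("log", "levels"), smooth = 400) {
  transform <- match.arg(transform)
  x <- p$values
  if (transform == "log") x <- log(x)
  if (!is.null(smooth)) x <- .hp_smooth_rows(x, smooth)
  x
}

# H_t values this small mean the cross-sectional spread of h is at machine
# precision; snap to exact zero so perfect convergence is detected reliably.
.H_ZERO_TOL <- 1e-14

.snap_H <- function(H) {
  H[H < .H_ZERO_TOL] <- 0
  H
}

#' Relative transition paths and cross-sectional transition variance
#'
#' Computes each unit's relative transition parameter
#' \eqn{h_{it} = x_{it} / (N^{-1} \sum_i x_{it})} and the cross-sectional
#' variance \eqn{H_t = N^{-1} \sum_i (h_{it} - 1)^2}, where \eqn{x} is the
#' panel after an optional log transform and optional per-unit
#' Hodrick-Prescott smoothing. The defaults (logs, `smooth = 400`) are the
#' conventional pre-treatment for annual data; `transform = "levels"` applies
#' the definitions to the raw densities.
#'
#' @param p A `conv_panel`.
#' @param transform `"log"` (default) or `"levels"`.
#' @param smooth Positive HP smoothing weight, or `NULL` for no smoothing.
#' @return An object of class `transition_paths`: `h` (unit x year matrix,
#'   column means identically 1), `H` (year-indexed variance series),
#'   `source_transform`, `smooth` and `years`.
#' @examples
#' p <- panel(matrix(c(2, 4, 2, 4), 2, 2), c("a", "b"), 2000:2001)
#' tp <- relative_transition(p, transform = "levels", smooth = NULL)
#' tp$h[, 1]  # 2/3, 4/3
#' tp$H[1]    # 1/9
#' @export
relative_transition <- function(p, transform = c("log", "levels"), smooth = 400) {
  transform <- match.arg(transform)
  .check_inference_dims(p, min_units = 2, min_years = if (is.null(smooth)) 2 else 4)
  x <- .transform_values(p, transform, smooth)
  m <- colMeans(x)
  if (any(m <= 0)) {
    bad <- p$years[which(m <= 0)[1]]
    .err(sprintf(paste0("degenerate cross-section at year %s: mean of transformed",
                        " values is not positive (log transform with densities",
                        " below 1?)"), bad),
         "logtclub_degenerate_cross_section")
  }
  h <- sweep(x, 2, m, "/")
  H <- .snap_H(colMeans((h - 1)^2))
  names(H) <- colnames(x)
  structure(list(h = h, H = H, source_transform = transform, smooth = smooth,
                 years = p$years),
            class = "transition_paths")
}

#' @export
print.transition_paths <- function(x, ...) {
  cat(sprintf("Relative transition paths: %d units x %d years (%s%s)\n",
              nrow(x$h), ncol(x$h), x$source_transform,
              if (is.null(x$smooth)) "" else sprintf(", HP lambda = %g", x$smooth)))
  cat(sprintf("  H_t: first = %.4g, last = %.4g\n",
              x$H[1], x$H[length(x$H)]))
  invisible(x)
}
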