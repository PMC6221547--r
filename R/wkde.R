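#' Weighted kernel density estimate
#'
#' A univariate density built as a weighted sum of standard normal kernels
#' centred at the observed sample points,
#' f(x) = sum_i w_i * phi((x - x_i)/h) / h. In the npEM model every
#' (feature, cluster) pair carries one of these, with weights given by the
#' cluster's normalised posterior column.
#'
#' @param x Numeric vector of sample points (scaled training values of one
#'   feature).
#' @param w Non-negative weights, one per sample point; normalised to sum
#'   to 1.
#' @param h Positive bandwidth.
#' @param support Length-2 numeric: the observed training range of the
#'   feature, used by the classifier's out-of-range clipping rule. Defaults
#'   to `range(x)`.
#' @return An object of class `wkde`.
#' @export
wkde <- function(x, w = NULL, h, support = range(x)) {
  x <- as.numeric(x)
  if (is.null(w)) w <- rep(1, length(x))
  if (length(w) != length(x)) stop("one weight per sample point required")
  if (any(w < 0)) stop("weights must be non-negative")
  total <- sum(w)
  if (total <= 0) stop("degenerate component: total weight is zero")
  if (!is.numeric(h) || length(h) != 1L || h <= 0) stop("bandwidth must be positive")
  structure(list(x = unname(x), w = unname(w / total), h = unname(h),
                 support = as.numeric(support)),
            class = "wkde")
}

#' Evaluate a weighted KDE
#'
#' @param kde A `wkde` object.
#' @param at Numeric vector of evaluation points.
#' @return Numeric vector of density values (non-negative).
#' @export
wkde_eval <- function(kde, at) {
  stopifnot(inherits(kde, "wkde"))
  as.numeric(stats::dnorm(outer(at, kde$x, "-") / kde$h) %*% kde$w) / kde$h
}

#' @export
print.wkde <- function(x, ...) {
  cat(sprintf("<wkde> %d sample points, h = %.4g, support [%.4g, %.4g]\n",
              length(x$x), x$h, x$support[1L], x$support[2L]))
  invisible(x)
}

#' Default constant bandwidth for one scaled feature
#'
#' Silverman-style rule of thumb evaluated once on the pooled scaled
#' complete-case column and held constant across clusters and EM
#' iterations: h = 0.9 * min(sd, IQR/1.34) * n^(-1/5). If the minimum term
#' is zero (e.g. a binary feature whose IQR collapses), the rule falls back
#' to 0.9 * sd * n^(-1/5); the result is floored at 1e-6.
#'
#' @param column Numeric vector with at least two distinct values.
#' @return A positive bandwidth.
#' @export
bandwidth_default <- function(column) {
  column <- column[!is.na(column)]
  n <- length(column)
  s <- stats::sd(column)
  if (!is.finite(s) || s == 0) {
    stop("constant column: bandwidth undefined (feature should be excluded upstream)")
  }
  iqr <- stats::IQR(column)
  spread <- min(s, iqr / 1.34)
  if (spread == 0) spread <- s
  max(0.9 * spread * n^(-1 / 5), 1e-6)
}
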