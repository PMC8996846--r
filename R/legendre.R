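#' Scale a covariate to the reaction-norm range \[-1, 1\]
#'
#' Affine min-max rescaling used to express an environmental gradient on the
#' standard Legendre support: the smallest value maps to -1, the largest to
#' +1, and the midrange to 0.  This is the conventional scaling for
#' random-regression covariates, so intercepts are interpreted at the average
#' environment and slopes as sensitivity per half-range of environmental
#' quality.
#'
#' @param values Numeric vector with at least two distinct finite values.
#' @return Numeric vector of the same length, spanning exactly \[-1, 1\].
#' @examples
#' scale_covariate(c(0, 5, 10))
#' @export
scale_covariate <- function(values) {
  stopifnot(is.numeric(values))
  v <- values[is.finite(values)]
  if (length(v) < 2L || diff(range(v)) == 0) {
    stop("covariate is constant (or has < 2 finite values); cannot scale to [-1, 1]",
         call. = FALSE)
  }
  r <- range(v)
  2 * (values - r[1]) / (r[2] - r[1]) - 1
}

#' Evaluate plain Legendre polynomials on \[-1, 1\]
#'
#' Returns the unnormalized Legendre polynomials P0..P_order evaluated at
#' `x`.  Orders 0 and 1 are the constant and linear terms of the linear
#' reaction norm; orders up to 4 cover the lactation-curve regressions.
#' Plain (unnormalized) polynomials are used throughout so that the order-1
#' basis is literally `x` and variance components keep the covariate's scale.
#'
#' @param x Numeric vector in \[-1, 1\].
#' @param order Highest polynomial order, an integer in 0..4.
#' @return A numeric matrix with `length(x)` rows and `order + 1` columns,
#'   named `P0`..`P<order>`.
#' @examples
#' legendre_basis(0.5, 1)
#' legendre_basis(0, 4)
#' @export
legendre_basis <- function(x, order = 1L) {
  stopifnot(is.numeric(x), length(order) == 1L, order >= 0L, order <= 4L)
  if (any(abs(x) > 1 + 1e-8, na.rm = TRUE)) {
    stop("legendre_basis() requires x in [-1, 1]", call. = FALSE)
  }
  x <- pmin(pmax(x, -1), 1)
  order <- as.integer(order)
  p <- list(
    rep(1, length(x)),
    x,
    (3 * x^2 - 1) / 2,
    (5 * x^3 - 3 * x) / 2,
    (35 * x^4 - 30 * x^2 + 3) / 8
  )
  out <- do.call(cbind, p[seq_len(order + 1L)])
  colnames(out) <- paste0("P", 0:order)
  out
}

#' Assign records to residual-variance classes by covariate quantiles
#'
#' Partitions records into `k` heterogeneous-residual classes using the
#' (1/k, ..., (k-1)/k) quantiles of the supplied covariate (typically each
#' record's herd-environment solution).  Ties at a class boundary go to the
#' lower class, so the assignment is a deterministic sort-and-cut.
#'
#' @param covariate Numeric vector, one value per record.
#' @param k Number of classes (>= 1).
#' @return Integer vector of class indices in 1..k (possibly fewer after
#'   merging when there are fewer distinct values than classes).
#' @export
residual_classes <- function(covariate, k = 5L) {
  stopifnot(is.numeric(covariate), length(covariate) > 0L, k >= 1L)
  k <- as.integer(k)
  if (k == 1L) return(rep(1L, length(covariate)))
  n_distinct <- length(unique(covariate))
  if (n_distinct < k) {
    warning("fewer distinct covariate values (", n_distinct, ") than classes (",
            k, "); classes merged", call. = FALSE)
    k <- n_distinct
    if (k == 1L) return(rep(1L, length(covariate)))
  }
  breaks <- stats::quantile(covariate, probs = seq_len(k - 1L) / k,
                            type = 1, names = FALSE)
  # left-open intervals: a record exactly on a boundary joins the lower class
  cls <- findInterval(covariate, unique(breaks), left.open = TRUE) + 1L
  as.integer(cls)
}

#' @keywords internal
skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  mean((x - m)^3) / s^3
}

#' @keywords internal
kurtosis <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s2 <- mean((x - m)^2)
  mean((x - m)^4) / s2^2 - 3
}
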