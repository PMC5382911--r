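#' B-spline basis with discrete difference penalty (P-spline)
#'
#' Builds the design and penalty matrices of a penalized B-spline smooth:
#' \code{k} B-spline basis functions of the given degree on equally spaced
#' knots spanning \code{range(x)}, with the Eilers-Marx difference penalty
#' \code{t(D) \%*\% D}, \code{D} the order-\code{m} difference operator on
#' adjacent basis coefficients. On the covariate range the basis is a
#' partition of unity, and coefficient vectors that are polynomial of
#' degree < m in the knot index are unpenalized.
#'
#' @param x Numeric covariate values (finite).
#' @param k Basis dimension (number of columns), at least \code{degree + 1}
#'   and at most the number of distinct \code{x} values.
#' @param degree Spline degree, default 3 (cubic).
#' @param penalty_order Order m of the difference penalty, default 2.
#' @param xrange Optional length-2 range on which to anchor the knots
#'   (defaults to \code{range(x)}); evaluation outside it is an error.
#' @return List with \code{design} (length(x) x k), \code{penalty} (k x k),
#'   \code{knots}, \code{degree}, \code{penalty_order}, \code{xrange}.
#' @export
bspline_basis <- function(x, k, degree = 3L, penalty_order = 2L,
                          xrange = NULL) {
  if (any(!is.finite(x))) {
    stop_sporoscale("covariate values must be finite", "sporoscale_domain_error")
  }
  if (k < degree + 1L) {
    stop_sporoscale(sprintf("k must be at least degree + 1 (= %d)", degree + 1L),
                    "sporoscale_config_error")
  }
  xrange <- xrange %||% range(x)
  n_distinct <- length(unique(x))
  if (k > n_distinct) {
    stop_sporoscale(
      sprintf("basis dimension k = %d exceeds the %d distinct covariate values",
              k, n_distinct),
      "sporoscale_rank_error")
  }
  if (any(x < xrange[1] - 1e-8) || any(x > xrange[2] + 1e-8)) {
    stop_sporoscale("x outside the basis range", "sporoscale_extrapolation_error")
  }
  lo <- xrange[1]; hi <- xrange[2]
  if (hi <= lo) hi <- lo + 1
  dx <- (hi - lo) / (k - degree)
  knots <- lo + dx * seq(-degree, k, by = 1)
  B <- splines::splineDesign(knots, pmin(pmax(x, lo), hi), ord = degree + 1L)
  D <- diff(diag(k), differences = penalty_order)
  list(design = B, penalty = crossprod(D), knots = knots,
       degree = degree, penalty_order = penalty_order,
       xrange = c(lo, hi))
}

# Evaluate an existing basis at new points (same knots). The extended knot
# sequence keeps the B-splines well defined a little beyond the data range,
# which centred finite differences at the boundary rely on.
bspline_eval <- function(basis, x, allow_extrapolate = FALSE) {
  lo <- basis$xrange[1]; hi <- basis$xrange[2]
  span <- hi - lo
  if (!allow_extrapolate &&
      (any(x < lo - 1e-8 * span) || any(x > hi + 1e-8 * span))) {
    stop_sporoscale(
      "grid extends beyond the fitted covariate range (set allow_extrapolate)",
      "sporoscale_extrapolation_error")
  }
  splines::splineDesign(basis$knots, x, ord = basis$degree + 1L,
                        outer.ok = TRUE)
}
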