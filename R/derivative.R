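# Finite-difference first derivatives of a fitted trend, with pointwise
# confidence intervals and segmentation into significant fruiting pulses.

#' First derivative of a fitted trend by finite differences
#'
#' Evaluates the fitted temporal trend of a \code{\link{fit_pgamm}} model on
#' a grid of \code{grid_n} equally spaced time points spanning the
#' observation period, re-evaluates it at points shifted by \code{eps}, and
#' takes the difference quotient as the first derivative. Standard errors
#' come from the delta method: for the contrast row
#' c = (X(t + eps) - X(t)) / eps, se = sqrt(c V c'), with V the coefficient
#' covariance; 95\% pointwise intervals use the normal quantile 1.96. A
#' grid point is flagged as a significant increase when the lower limit is
#' above zero, a significant decrease when the upper limit is below zero.
#' The shift is centred on each grid point, which makes the estimate
#' insensitive to the exact eps; the extended knot sequence keeps the
#' basis defined eps/2 beyond the boundary grid points.
#'
#' @param fit A \code{pgamm} fit containing a temporal trend (smooth over
#'   year and/or a linear year term).
#' @param grid_n Number of grid points (default 100).
#' @param eps Shift in time units; default (time range)/1000. Must be
#'   positive and no larger than the grid spacing.
#' @return An object of class \code{"pgamm_deriv"}: data frame
#'   \code{$grid} with columns \code{grid}, \code{deriv}, \code{se},
#'   \code{ci_lo}, \code{ci_hi}, \code{sig} (increase/decrease/none), and
#'   \code{$periods}, the maximal significant runs (start, end, direction).
#' @export
first_derivative <- function(fit, grid_n = 100L, eps = NULL) {
  stopifnot(inherits(fit, "pgamm"))
  tvar <- if (!is.null(fit$design$smooth)) fit$design$smooth$var else "year"
  tobs <- fit$data[[tvar]]
  rng <- range(tobs)
  span <- diff(rng)
  if (span <= 0) {
    stop_sporoscale("degenerate time range", "sporoscale_data_error")
  }
  eps <- eps %||% (span / 1000)
  spacing <- span / (grid_n - 1)
  if (eps <= 0 || eps > spacing) {
    stop_sporoscale(
      sprintf("eps must be in (0, grid spacing = %.4g]", spacing),
      "sporoscale_config_error")
  }
  grid <- seq(rng[1], rng[2], length.out = grid_n)
  # centred difference; the basis stays defined eps/2 beyond the boundary
  t1 <- grid - eps / 2
  t2 <- grid + eps / 2
  X1 <- pgamm_trend_design(fit, t1, allow_extrapolate = TRUE)
  X2 <- pgamm_trend_design(fit, t2, allow_extrapolate = TRUE)
  Cmat <- (X2 - X1) / eps
  deriv <- as.vector(Cmat %*% fit$coefficients)
  se <- sqrt(pmax(0, rowSums((Cmat %*% fit$Vb) * Cmat)))
  ci_lo <- deriv - 1.96 * se
  ci_hi <- deriv + 1.96 * se
  sig <- ifelse(ci_lo > 0, "increase", ifelse(ci_hi < 0, "decrease", "none"))
  segs <- data.frame(grid = grid, deriv = deriv, se = se,
                     ci_lo = ci_lo, ci_hi = ci_hi, sig = sig,
                     stringsAsFactors = FALSE)
  out <- structure(list(grid = segs, periods = NULL, eps = eps,
                        response = fit$response), class = "pgamm_deriv")
  out$periods <- significant_periods(out)
  out
}

#' Significant increase/decrease periods of a derivative grid
#'
#' Collapses the pointwise significance flags of a
#' \code{\link{first_derivative}} result into maximal runs of consecutive
#' grid points sharing the same non-"none" direction, reported in data time
#' units. A single significant grid point yields a zero-length period
#' (start equals end).
#'
#' @param segs A \code{pgamm_deriv} object (or its \code{$grid} data
#'   frame).
#' @return Data frame with columns \code{start}, \code{end},
#'   \code{direction}; zero rows when nothing is significant.
#' @export
significant_periods <- function(segs) {
  g <- if (inherits(segs, "pgamm_deriv")) segs$grid else segs
  r <- rle(g$sig)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  keep <- r$values != "none"
  data.frame(start = g$grid[starts[keep]],
             end = g$grid[ends[keep]],
             direction = r$values[keep],
             stringsAsFactors = FALSE)
}

#' @export
print.pgamm_deriv <- function(x, ...) {
  cat(sprintf("Finite-difference derivative of the %s trend (%d grid points, eps = %.4g)\n",
              x$response, nrow(x$grid), x$eps))
  n_sig <- sum(x$grid$sig != "none")
  cat(sprintf("%d of %d grid points significant at the pointwise 95%% level\n",
              n_sig, nrow(x$grid)))
  if (nrow(x$periods) == 0L) {
    cat("No significant increase or decrease periods\n")
  } else {
    cat("Significant periods:\n")
    print(x$periods, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.pgamm_deriv <- function(x, ...) {
  g <- x$grid
  graphics::plot(g$grid, g$deriv, type = "n",
                 ylim = range(c(g$ci_lo, g$ci_hi)),
                 xlab = "time", ylab = "first derivative", ...)
  graphics::polygon(c(g$grid, rev(g$grid)), c(g$ci_lo, rev(g$ci_hi)),
                    col = "grey85", border = NA)
  graphics::abline(h = 0, lty = 2)
  graphics::lines(g$grid, g$deriv)
  up <- g$sig == "increase"; dn <- g$sig == "decrease"
  graphics::points(g$grid[up], g$deriv[up], col = "blue", pch = 16, cex = 0.5)
  graphics::points(g$grid[dn], g$deriv[dn], col = "red", pch = 16, cex = 0.5)
  invisible(x)
}
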