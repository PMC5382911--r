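# Per-plot between-year variances and their regression on elevation.

#' Between-year variance of each plot's annual series
#'
#' Extracts, for every plot, the variance of its transformed annual values
#' across years (sample variance, divisor n - 1). With one observation per
#' plot-year this is the identifiable estimand of a plot's yearly
#' variability; a REML fit of a year-plus-residual two-component model is
#' available via \code{method = "reml"} for data with within-year
#' replicates (it reduces to the sample variance otherwise, up to the
#' boundary constraint).
#'
#' Years with undefined responses (e.g. evenness of single-species
#' plot-years) are skipped, with \code{n_years} recording how many values
#' remained; plots with fewer than 2 usable years are excluded with a
#' message.
#'
#' @param data Plot-year table.
#' @param response Response column.
#' @param transformation Transformation applied before taking variances
#'   (default per variable family, as in \code{\link{fit_varcomp}}).
#' @param method \code{"sample"} (default) or \code{"reml"}.
#' @return Data frame with \code{plot_id}, \code{elevation_m},
#'   \code{variance}, \code{n_years}.
#' @export
plot_yearly_variance <- function(data, response, transformation = NULL,
                                 method = c("sample", "reml")) {
  method <- match.arg(method)
  assert_cols(data, c(response, "plot_id", "year", "elevation_m"),
              "plot-year table")
  transformation <- transformation %||% default_transformation(response)
  y <- transform_response(data[[response]], transformation)
  sp <- split(data.frame(y = y, year = data$year,
                         elevation_m = data$elevation_m), data$plot_id)
  rows <- lapply(names(sp), function(pid) {
    d <- sp[[pid]]
    ok <- !is.na(d$y)
    n_yr <- length(unique(d$year[ok]))
    if (n_yr < 2L) return(NULL)
    v <- if (method == "sample" || !anyDuplicated(d$year[ok])) {
      stats::var(d$y[ok])
    } else {
      # two components: between-year and residual, via one-way REML
      fy <- factor(d$year[ok])
      a <- stats::anova(stats::lm(d$y[ok] ~ fy))
      msb <- a$`Mean Sq`[1L]; msw <- a$`Mean Sq`[2L]
      n0 <- (sum(table(fy)) - sum(table(fy)^2) / sum(table(fy))) /
        (nlevels(fy) - 1L)
      max(0, (msb - msw) / n0)
    }
    data.frame(plot_id = pid, elevation_m = d$elevation_m[1L],
               variance = v, n_years = n_yr, stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L) {
    message(sprintf("excluding %d plot(s) with fewer than 2 usable years",
                    dropped))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Ordinary least-squares regression with slope inference
#'
#' Simple linear regression y = a + b x: slope and intercept with standard
#' errors, the two-sided t test of the slope (n - 2 degrees of freedom) and
#' the coefficient of determination. Used for regressing per-plot yearly
#' variances on elevation and for richness-biomass relationships.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, x not constant.
#' @return Object of class \code{"slope_fit"}: \code{slope},
#'   \code{slope_se}, \code{intercept}, \code{intercept_se}, \code{p},
#'   \code{r2}, \code{n}.
#' @export
linear_regression <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) != length(y) || length(x) < 3L) {
    stop_sporoscale("need at least 3 complete (x, y) pairs",
                    "sporoscale_data_error")
  }
  if (stats::var(x) == 0) {
    stop_sporoscale("x is constant: slope is not identifiable",
                    "sporoscale_singular_error")
  }
  fit <- stats::lm(y ~ x)
  s <- suppressWarnings(summary(fit))  # exact fits are legitimate inputs
  co <- s$coefficients
  structure(list(slope = co["x", "Estimate"],
                 slope_se = co["x", "Std. Error"],
                 intercept = co["(Intercept)", "Estimate"],
                 intercept_se = co["(Intercept)", "Std. Error"],
                 p = co["x", "Pr(>|t|)"],
                 r2 = s$r.squared,
                 n = length(x), lm = fit), class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("slope[1,%d] = %.3g ± %.2g, P = %.3g, R2 = %.2f\n",
              x$n - 2L, x$slope, x$slope_se, x$p, x$r2))
  cat(sprintf("intercept = %.3g ± %.2g, n = %d\n",
              x$intercept, x$intercept_se, x$n))
  invisible(x)
}

#' @export
as.data.frame.slope_fit <- function(x, ...) {
  data.frame(slope = x$slope, slope_se = x$slope_se,
             intercept = x$intercept, intercept_se = x$intercept_se,
             p = x$p, r2 = x$r2, n = x$n)
}

#' Regress per-plot yearly variances on elevation
#'
#' Convenience wrapper: \code{\link{plot_yearly_variance}} followed by
#' \code{\link{linear_regression}} of variance on elevation.
#'
#' @inheritParams plot_yearly_variance
#' @return List with \code{variances} (the per-plot table) and
#'   \code{regression} (a \code{slope_fit}).
#' @export
elevation_variance_regression <- function(data, response,
                                          transformation = NULL) {
  v <- plot_yearly_variance(data, response, transformation)
  list(variances = v,
       regression = linear_regression(v$elevation_m, v$variance))
}
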