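# Nested/crossed variance-component estimation by REML.
#
# Model: y = mu + u_year + u_locality + u_plot(locality) + error, all random
# effects independent zero-mean Gaussians. Plot effects are persistent
# across years and crossed with a year main effect: with one observation per
# plot-year this is the only specification in which plot and error variances
# are both identifiable.
#
# The restricted likelihood is profiled over mu and the error variance and
# maximised over the three log variance-ratios r_k = sigma2_k / sigma2_e.
# With W = I + sum_k r_k Z_k Z_k', all quadratic forms in W^-1 and log|W|
# are reduced via the Woodbury identity to a q x q system (q = total number
# of random-effect levels), so one deviance evaluation costs O(q^3)
# regardless of n.

# Precompute the cross-products the deviance needs. `groups` is a list of
# 1-based integer level codes (one element per random factor), `ng` the
# matching level counts.
varcomp_prep <- function(y, groups, ng) {
  n <- length(y)
  M <- matrix(0, n, sum(ng))
  off <- c(0, cumsum(ng))
  for (j in seq_along(groups)) {
    M[cbind(seq_len(n), off[j] + groups[[j]])] <- 1
  }
  list(n = n, q = ng,
       ZtZ = crossprod(M),
       Ztx = colSums(M),
       Zty = as.vector(crossprod(M, y)),
       xtx = n, xty = sum(y), yty = sum(y * y))
}

# Minus twice the restricted log-likelihood, profiled over mu and sigma2_e,
# as a function of the log variance ratios (one per random factor).
varcomp_deviance <- function(log_ratio, pre) {
  lr <- pmin(log_ratio, 35)
  r <- exp(lr)
  dh <- sqrt(rep(r, pre$q))
  A <- pre$ZtZ * (dh %o% dh)
  diag(A) <- diag(A) + 1
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) return(1e10)
  logdetW <- 2 * sum(log(diag(R)))
  # u' W^-1 v = u'v - (dh Z'u)' A^-1 (dh Z'v)
  U <- backsolve(R, cbind(dh * pre$Ztx, dh * pre$Zty), transpose = TRUE)
  xWx <- pre$xtx - sum(U[, 1]^2)
  xWy <- pre$xty - sum(U[, 1] * U[, 2])
  yWy <- pre$yty - sum(U[, 2]^2)
  yPy <- yWy - xWy^2 / xWx
  nm1 <- pre$n - 1
  if (yPy <= 0) return(1e10)
  sigma2 <- yPy / nm1
  nm1 * log(sigma2) + logdetW + log(xWx) + nm1 * (1 + log(2 * pi))
}

# Point estimation on integer-coded data. Returns variances, percentages,
# deviance and a convergence flag. `quick = TRUE` (bootstrap resamples) runs
# a single warm-started Nelder-Mead pass instead of multi-start + restart.
varcomp_core <- function(y, groups, ng,
                         scales = c("year", "locality", "plot"),
                         start = NULL, quick = FALSE) {
  n <- length(y)
  nms <- c(scales, "error")
  if (stats::var(y) < 1e-13) {
    # degenerate: no variation at all; by convention everything is "error"
    sig0 <- stats::setNames(rep(0, length(nms)), nms)
    pct0 <- stats::setNames(c(rep(0, length(scales)), 100), nms)
    return(list(sigma2 = sig0, pct = pct0, deviance = NA_real_,
                converged = TRUE, degenerate = TRUE))
  }
  pre <- varcomp_prep(y, groups, ng)
  k <- length(groups)
  optim_nm <- function(s, maxit, reltol) {
    if (k == 1L) {
      stats::optim(s, varcomp_deviance, pre = pre, method = "Brent",
                   lower = -30, upper = 30, control = list(reltol = 1e-12))
    } else {
      stats::optim(s, varcomp_deviance, pre = pre, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = reltol))
    }
  }
  if (quick) {
    best <- optim_nm(start %||% rep(log(0.5), k), 500, 1e-8)
  } else {
    s2 <- stats::var(y)
    gmean <- function(i) {
      m <- rowsum(y, i)
      v <- stats::var(as.vector(m) / as.vector(rowsum(rep(1, n), i)))
      max(v / s2, 0.02, na.rm = TRUE)
    }
    starts <- list(log(vapply(groups, gmean, numeric(1))),
                   rep(log(0.5), k))
    if (!is.null(start)) starts <- c(list(start), starts)
    best <- NULL
    for (s in starts) {
      o <- optim_nm(s, 1000, 1e-10)
      if (is.null(best) || o$value < best$value) best <- o
    }
    # one restart from the incumbent to let Nelder-Mead re-expand
    o <- optim_nm(best$par, 1000, 1e-10)
    if (o$value <= best$value) best <- o
  }

  r <- exp(pmin(best$par, 35))
  dh <- sqrt(rep(r, pre$q))
  A <- pre$ZtZ * (dh %o% dh)
  diag(A) <- diag(A) + 1
  R <- chol(A)
  U <- backsolve(R, cbind(dh * pre$Ztx, dh * pre$Zty), transpose = TRUE)
  xWx <- pre$xtx - sum(U[, 1]^2)
  xWy <- pre$xty - sum(U[, 1] * U[, 2])
  yWy <- pre$yty - sum(U[, 2]^2)
  sigma2_e <- (yWy - xWy^2 / xWx) / (n - 1)
  sig <- c(r * sigma2_e, sigma2_e)
  sig[sig < 1e-10 * sum(sig)] <- 0
  names(sig) <- nms
  list(sigma2 = sig, pct = 100 * sig / sum(sig),
       deviance = best$value, converged = best$convergence == 0,
       degenerate = FALSE)
}

#' Partition variance across plot, locality and year scales by REML
#'
#' Fits the null linear mixed model y = mu + u_year + u_locality +
#' u_plot(locality) + error to a plot-by-year response and reports the four
#' variance components in absolute terms and as percentages of the total.
#' Estimation is restricted maximum likelihood with the error-variance and
#' mean profiled out; the remaining log variance-ratios are maximised by
#' derivative-free (Nelder-Mead) search with restarts, so non-negativity
#' holds by construction.
#'
#' Plot effects are modelled as persistent across years (plot within
#' locality, crossed with the year main effect): with a single observation
#' per plot-year, a year-specific plot effect would be confounded with the
#' residual.
#'
#' @param data Plot-by-year table as produced by
#'   \code{\link{aggregate_plot_year}} or \code{\link{generate_survey}}.
#' @param response Column to analyse, e.g. \code{"biomass_kg_ha"},
#'   \code{"richness_S"}, \code{"evenness_J"}.
#' @param transformation Response transformation applied before fitting;
#'   default chosen by variable family: square root for biomass, log1p for
#'   richness, identity for evenness.
#' @return An object of class \code{"varcomp"}: component table
#'   (\code{$components} with scale, variance, pct), the response and
#'   transformation used, sample size, convergence flag and the data needed
#'   by \code{\link{bootstrap_varcomp}}.
#' @seealso \code{\link{bootstrap_varcomp}} for bootstrap confidence
#'   intervals on the percentage shares.
#' @export
fit_varcomp <- function(data, response,
                        transformation = NULL) {
  assert_cols(data, c(response, "plot_id", "locality_id", "year"),
              "plot-year table")
  transformation <- transformation %||% default_transformation(response)
  y <- transform_response(data[[response]], transformation)
  keep <- !is.na(y)
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    message(sprintf("dropping %d plot-year(s) with undefined %s",
                    n_drop, response))
  }
  d <- data[keep, , drop = FALSE]
  y <- y[keep]
  if (length(y) < 10L) {
    stop_sporoscale("need at least 10 non-missing plot-year responses",
                    "sporoscale_data_error")
  }
  fy <- factor(d$year); fl <- factor(d$locality_id); fp <- factor(d$plot_id)
  if (nlevels(fy) < 2L || nlevels(fl) < 2L || nlevels(fp) < 2L) {
    stop_sporoscale(
      "each of year, locality and plot needs at least 2 levels",
      "sporoscale_data_error")
  }
  plot_loc <- table(fp, fl) > 0
  if (nlevels(fp) == nlevels(fl)) {
    stop_sporoscale(
      paste("one plot per locality everywhere: plot and locality variance",
            "components are confounded (terms: locality_id, plot_id)"),
      "sporoscale_identifiability_error")
  }
  if (any(rowSums(plot_loc) > 1L)) {
    stop_sporoscale("a plot belongs to more than one locality",
                    "sporoscale_data_error")
  }

  core <- varcomp_core(y,
                       list(as.integer(fy), as.integer(fl), as.integer(fp)),
                       c(nlevels(fy), nlevels(fl), nlevels(fp)))
  if (!core$converged) {
    warning("REML optimisation did not report convergence", call. = FALSE)
  }
  structure(list(
    components = data.frame(scale = names(core$sigma2),
                            variance = unname(core$sigma2),
                            pct = unname(core$pct),
                            stringsAsFactors = FALSE),
    ci = NULL, n_boot = 0L,
    response = response, transformation = transformation,
    n = length(y), converged = core$converged,
    deviance = core$deviance,
    data = data.frame(plot_id = as.character(d$plot_id),
                      locality_id = as.character(d$locality_id),
                      year = d$year, y = y, stringsAsFactors = FALSE),
    call = match.call()), class = "varcomp")
}

# One two-stage case resample: years with replacement, then plots (whole
# series) within localities with replacement. Returns integer-coded data.
resample_case <- function(Y, plot_loc) {
  ny <- ncol(Y)
  yr_draw <- sample.int(ny, ny, replace = TRUE)
  plots <- unlist(lapply(split(seq_along(plot_loc), plot_loc), function(ix) {
    ix[sample.int(length(ix), length(ix), replace = TRUE)]
  }), use.names = FALSE)
  Yb <- Y[plots, yr_draw, drop = FALSE]
  list(y = as.vector(Yb),
       iy = rep(seq_len(ny), each = length(plots)),
       il = rep(as.integer(factor(plot_loc[plots])), ny),
       ip = rep(seq_along(plots), ny),
       ny = ny, nl = length(unique(plot_loc)), np = length(plots))
}

#' Bootstrap confidence intervals for variance-component percentages
#'
#' Attaches percentile 95\% confidence intervals to a fitted
#' \code{\link{fit_varcomp}} decomposition, from \code{n_boot} resamples
#' (default 199, with replacement). The default resampling unit is the
#' two-stage case bootstrap: years are resampled with replacement, then
#' plots (whole time series) within localities; \code{type = "parametric"}
#' instead simulates from the fitted model. Resamples whose REML fit fails
#' or does not converge are dropped and counted.
#'
#' @param object A \code{varcomp} fit.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed for the resampling.
#' @param type \code{"case"} (default) or \code{"parametric"}.
#' @param level Confidence level (default 0.95).
#' @param strict If \code{TRUE}, more than 20\% failed resamples is an
#'   error rather than a warning.
#' @return The \code{varcomp} object with \code{$ci} (scale, lo, hi),
#'   \code{$n_boot} and \code{$n_boot_failed} filled in.
#' @export
bootstrap_varcomp <- function(object, n_boot = 199L, seed = 1L,
                              type = c("case", "parametric"),
                              level = 0.95, strict = FALSE) {
  stopifnot(inherits(object, "varcomp"))
  type <- match.arg(type)
  d <- object$data
  fy <- factor(d$year); fl <- factor(d$locality_id); fp <- factor(d$plot_id)
  # plot x year response matrix (NA where a plot-year is missing)
  Y <- matrix(NA_real_, nlevels(fp), nlevels(fy),
              dimnames = list(levels(fp), levels(fy)))
  Y[cbind(as.integer(fp), as.integer(fy))] <- d$y
  plot_loc <- vapply(split(as.character(fl), fp), function(v) v[1L],
                     character(1))

  set.seed(seed)
  pcts <- matrix(NA_real_, n_boot, 4L)
  failed <- 0L
  # warm start at the full-data solution's variance ratios
  sig_hat <- stats::setNames(object$components$variance,
                             object$components$scale)
  warm <- log(pmax(sig_hat[c("year", "locality", "plot")] /
                   max(sig_hat["error"], 1e-8), 1e-4))
  if (type == "parametric") {
    sig <- stats::setNames(object$components$variance,
                           object$components$scale)
    mu <- mean(d$y)
    iy <- as.integer(fy); il <- as.integer(fl); ip <- as.integer(fp)
  }
  for (b in seq_len(n_boot)) {
    res <- tryCatch({
      if (type == "case") {
        rs <- resample_case(Y, plot_loc)
        ok <- !is.na(rs$y)
        varcomp_core(rs$y[ok], list(rs$iy[ok], rs$il[ok], rs$ip[ok]),
                     c(rs$ny, rs$nl, rs$np), start = warm, quick = TRUE)
      } else {
        ysim <- mu + stats::rnorm(nlevels(fy), 0, sqrt(sig["year"]))[iy] +
          stats::rnorm(nlevels(fl), 0, sqrt(sig["locality"]))[il] +
          stats::rnorm(nlevels(fp), 0, sqrt(sig["plot"]))[ip] +
          stats::rnorm(length(iy), 0, sqrt(sig["error"]))
        varcomp_core(ysim, list(iy, il, ip),
                     c(nlevels(fy), nlevels(fl), nlevels(fp)),
                     start = warm, quick = TRUE)
      }
    }, error = function(e) NULL)
    if (is.null(res) || !res$converged) failed <- failed + 1L
    else pcts[b, ] <- res$pct
  }
  if (failed > 0.2 * n_boot) {
    msg <- sprintf("%d of %d bootstrap resamples failed to converge",
                   failed, n_boot)
    if (strict) stop_sporoscale(msg, "sporoscale_bootstrap_error")
    warning(msg, call. = FALSE)
  }
  alpha <- (1 - level) / 2
  qs <- apply(pcts, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE)
  object$ci <- data.frame(scale = object$components$scale,
                          lo = qs[1L, ], hi = qs[2L, ],
                          stringsAsFactors = FALSE)
  object$n_boot <- n_boot
  object$n_boot_failed <- failed
  object$boot_type <- type
  object
}

#' @export
print.varcomp <- function(x, digits = 3, ...) {
  cat(sprintf("Variance decomposition of %s (%s transform), REML, n = %d\n",
              x$response, x$transformation, x$n))
  tab <- x$components
  tab$variance <- signif(tab$variance, digits)
  tab$pct <- round(tab$pct, 1)
  if (!is.null(x$ci)) {
    tab$ci95 <- sprintf("[%.1f-%.1f]", x$ci$lo, x$ci$hi)
  }
  print(tab, row.names = FALSE)
  if (!is.null(x$ci)) {
    cat(sprintf("Percentile CIs from %d bootstrap resamples (%s; %d failed)\n",
                x$n_boot, x$boot_type, x$n_boot_failed))
  }
  if (!x$converged) cat("WARNING: REML optimisation did not converge\n")
  invisible(x)
}

#' @export
summary.varcomp <- function(object, ...) {
  print(object, ...)
}

#' @export
as.data.frame.varcomp <- function(x, ...) {
  out <- x$components
  if (!is.null(x$ci)) {
    out$ci_lo <- x$ci$lo
    out$ci_hi <- x$ci$hi
  } else {
    out$ci_lo <- NA_real_
    out$ci_hi <- NA_real_
  }
  out
}
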