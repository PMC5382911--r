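# Penalized B-spline mixed models with nested random intercepts and AR(1)
# within-plot residual correlation.
#
# All terms are assembled into one penalized regression: the smooth carries
# its difference penalty, random intercepts (locality, plot within locality)
# enter as ridge-penalized indicator blocks (the standard mixed-model
# representation: ridge weight tau_j = sigma2 / sigma2_j), and the AR(1)
# correlation is removed by within-plot whitening. Smoothing parameters,
# ridge weights and the AR(1) coefficient are chosen jointly by maximising
# the restricted likelihood, with the scale profiled out; coefficients then
# solve one penalized (generalized) least squares. Poisson responses are
# fitted by penalized quasi-likelihood around the same Gaussian core.

default_gamm_transformation <- function(response) {
  if (grepl("biomass", response)) "sqrt"
  else if (grepl("evenness", response)) "arcsine_sqrt"
  else "identity"
}

# Design assembly. d must be sorted by plot then year.
pgamm_design <- function(d, smooth, linear, elevation_by_year, random) {
  n <- nrow(d)
  blocks <- list()
  cols <- list()
  col_names <- "(Intercept)"
  X <- matrix(1, n, 1)
  std <- list()  # per standardized covariate: center, scale

  std_col <- function(v, name) {
    c0 <- mean(v); s0 <- stats::sd(v)
    if (!is.finite(s0) || s0 == 0) {
      stop_sporoscale(sprintf("covariate '%s' is constant", name),
                      "sporoscale_rank_error")
    }
    std[[name]] <<- c(center = c0, scale = s0)
    (v - c0) / s0
  }

  for (v in linear) {
    if (!is.null(smooth) && identical(smooth$var, v)) {
      stop_sporoscale(
        sprintf("'%s' cannot have both a smooth and a linear term", v),
        "sporoscale_config_error")
    }
    X <- cbind(X, std_col(d[[v]], v))
    col_names <- c(col_names, v)
  }

  year_levels <- NULL
  if (elevation_by_year) {
    fy <- factor(d$year)
    year_levels <- levels(fy)
    Fy <- stats::model.matrix(~ 0 + fy)
    elev <- std_col(d$elevation_m, "elevation_m")
    X <- cbind(X, Fy[, -1L, drop = FALSE], Fy * elev)
    col_names <- c(col_names,
                   paste0("year", year_levels[-1L]),
                   paste0("elevation_m:year", year_levels))
  }
  p_fixed <- ncol(X)

  penalties <- list()
  smooth_info <- NULL
  if (!is.null(smooth)) {
    bs <- bspline_basis(d[[smooth$var]], k = smooth$k,
                        degree = smooth$degree %||% 3L,
                        penalty_order = smooth$m %||% 2L)
    # sum-to-zero constraint for identifiability with the intercept,
    # then rotate to the penalty eigenbasis: the penalty becomes diagonal
    # with exact zeros on its null space, which keeps the unpenalized
    # (polynomial) directions numerically clean even as lambda -> Inf
    cvec <- colSums(bs$design)
    Q <- qr.Q(qr(cvec), complete = TRUE)[, -1L, drop = FALSE]
    Sc <- t(Q) %*% bs$penalty %*% Q
    eg <- eigen((Sc + t(Sc)) / 2, symmetric = TRUE)
    ev <- eg$values
    rank_s <- sum(ev > max(ev) * 1e-10)
    ev_clean <- c(ev[seq_len(rank_s)], rep(0, length(ev) - rank_s))
    Q <- Q %*% eg$vectors
    Bc <- bs$design %*% Q
    idx <- p_fixed + seq_len(ncol(Bc))
    penalties[[length(penalties) + 1L]] <- list(
      idx = idx, S = diag(ev_clean, nrow = length(ev_clean)), rank = rank_s,
      logdet_const = sum(log(ev_clean[seq_len(rank_s)])),
      name = paste0("s(", smooth$var, ")"))
    smooth_info <- list(var = smooth$var, basis = bs, Q = Q, idx = idx,
                        null_dim = ncol(Bc) - rank_s)
    X <- cbind(X, Bc)
    col_names <- c(col_names, paste0("s(", smooth$var, ").", seq_len(ncol(Bc))))
  }

  ranef_info <- list()
  if ("locality" %in% random) {
    fl <- factor(d$locality_id)
    if (nlevels(fl) > 1L) {
      Zl <- stats::model.matrix(~ 0 + fl)
      idx <- ncol(X) + seq_len(ncol(Zl))
      penalties[[length(penalties) + 1L]] <- list(
        idx = idx, S = diag(ncol(Zl)), rank = ncol(Zl), logdet_const = 0,
        name = "locality")
      ranef_info$locality <- idx
      X <- cbind(X, Zl)
      col_names <- c(col_names, paste0("loc:", levels(fl)))
    }
  }
  if ("plot" %in% random) {
    fp <- factor(d$plot_id)
    if (nlevels(fp) > 1L) {
      Zp <- stats::model.matrix(~ 0 + fp)
      idx <- ncol(X) + seq_len(ncol(Zp))
      penalties[[length(penalties) + 1L]] <- list(
        idx = idx, S = diag(ncol(Zp)), rank = ncol(Zp), logdet_const = 0,
        name = "plot")
      ranef_info$plot <- idx
      X <- cbind(X, Zp)
      col_names <- c(col_names, paste0("plot:", levels(fp)))
    }
  }
  colnames(X) <- col_names
  Mp <- p_fixed + if (is.null(smooth_info)) 0L else smooth_info$null_dim
  list(X = X, penalties = penalties, smooth = smooth_info,
       ranef = ranef_info, std = std, p_fixed = p_fixed, Mp = Mp,
       year_levels = year_levels, col_names = col_names)
}

# AR(1) whitening with unit-lag correlation rho; rows must be grouped by
# plot and sorted by year. Weights w enter as Cov = sigma2 W^-1/2 C W^-1/2.
pgamm_whiten <- function(M, rho, w, first, phi_pow) {
  Mw <- M * sqrt(w)
  if (rho == 0) return(Mw)
  phi <- rho^phi_pow
  idx <- which(!first)
  sc <- sqrt(1 - phi[idx]^2)
  if (is.matrix(Mw)) {
    Mw[idx, ] <- (Mw[idx, , drop = FALSE] -
                  phi[idx] * Mw[idx - 1L, , drop = FALSE]) / sc
  } else {
    Mw[idx] <- (Mw[idx] - phi[idx] * Mw[idx - 1L]) / sc
  }
  Mw
}

# Minus twice the restricted log-likelihood (scale profiled out).
pgamm_deviance_at <- function(theta, env) {
  rho <- if (env$ar1) tanh(theta[env$rho_pos]) else 0
  Ct <- pgamm_whiten(env$X, rho, env$w, env$first, env$phi_pow)
  yt <- pgamm_whiten(env$y, rho, env$w, env$first, env$phi_pow)
  p <- ncol(Ct)
  S <- matrix(0, p, p)
  logdetS <- 0
  for (j in seq_along(env$penalties)) {
    pen <- env$penalties[[j]]
    lam <- if (!is.null(env$fixed_sp[[pen$name]])) env$fixed_sp[[pen$name]]
           else exp(min(theta[env$sp_pos[j]], 35))
    S[pen$idx, pen$idx] <- S[pen$idx, pen$idx] + lam * pen$S
    logdetS <- logdetS + pen$rank * log(lam) + pen$logdet_const
  }
  H <- crossprod(Ct) + S
  R <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(R)) return(list(dev = 1e10))
  Xty <- crossprod(Ct, yt)
  b <- backsolve(R, backsolve(R, Xty, transpose = TRUE))
  resid <- yt - Ct %*% b
  rss_pen <- sum(resid^2) + sum(b * (S %*% b))
  df <- env$n - env$Mp
  if (!is.finite(rss_pen) || rss_pen <= 0) return(list(dev = 1e10))
  sigma2 <- rss_pen / df
  phi <- rho^env$phi_pow
  logC <- sum(log(1 - phi[!env$first]^2))
  dev <- df * (log(2 * pi * sigma2) + 1) + 2 * sum(log(diag(R))) -
    logdetS + logC - sum(log(env$w))
  if (!is.finite(dev)) return(list(dev = 1e10))
  list(dev = dev, R = R, b = as.vector(b), sigma2 = sigma2, S = S,
       XtX = crossprod(Ct), rho = rho)
}

# Gaussian penalized GLS core: optimise theta, return full fit pieces.
pgamm_gaussian_core <- function(X, y, w, design, ar1, fixed_sp, d,
                                theta_init = NULL) {
  first <- !duplicated(d$plot_id)
  dy <- c(1, diff(d$year))
  dy[first] <- 1
  env <- list(X = X, y = y, w = w, first = first, phi_pow = dy,
              penalties = design$penalties, fixed_sp = fixed_sp,
              n = length(y), Mp = design$Mp, ar1 = ar1)
  free_sp <- vapply(design$penalties,
                    function(pen) is.null(fixed_sp[[pen$name]]), logical(1))
  env$sp_pos <- cumsum(free_sp) * ifelse(free_sp, 1L, NA)
  n_sp <- sum(free_sp)
  env$rho_pos <- n_sp + 1L
  n_theta <- n_sp + as.integer(ar1)

  if (n_theta == 0L) {
    fit <- pgamm_deviance_at(numeric(0), env)
    return(c(fit, list(theta = numeric(0), converged = TRUE, env = env)))
  }
  obj <- function(th) pgamm_deviance_at(th, env)$dev
  start <- theta_init %||% rep(0, n_theta)
  if (n_theta == 1L) {
    o <- stats::optim(start, obj, method = "Brent",
                      lower = -30, upper = 30,
                      control = list(reltol = 1e-10))
  } else {
    o <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 1500, reltol = 1e-9))
    o2 <- stats::optim(o$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 1500, reltol = 1e-9))
    if (o2$value <= o$value) o <- o2
  }
  fit <- pgamm_deviance_at(o$par, env)
  c(fit, list(theta = o$par, converged = o$convergence == 0, env = env,
              free_sp = free_sp))
}

#' Fit a penalized-spline mixed model for plot-year survey responses
#'
#' Fits the trend models used throughout the package: a response observed
#' once per plot and year, explained by an optional penalized B-spline
#' smooth (typically over year), optional linear covariates (elevation,
#' LSEA precipitation and mean temperature, or a linear year term),
#' optional per-year elevation slopes, random intercepts for locality and
#' plot within locality, and a first-order autoregressive correlation
#' between successive years of the same plot. Gaussian responses are
#' transformed first (square root for biomass, arcsine-square-root for
#' evenness by default); richness uses a Poisson family with log link,
#' fitted by penalized quasi-likelihood.
#'
#' Smoothing parameters, random-intercept ridge weights and the AR(1)
#' coefficient are selected jointly by restricted maximum likelihood
#' (Nelder-Mead on the log/atanh scale with a restart).
#'
#' @param data Plot-year table (see \code{\link{aggregate_plot_year}});
#'   columns referenced by the terms must be present.
#' @param response Response column name.
#' @param family \code{"gaussian"} or \code{"poisson"}.
#' @param transformation Transformation for Gaussian responses (default by
#'   variable family); ignored for Poisson.
#' @param smooth \code{NULL} or a list \code{list(var, k, degree, m)};
#'   default a cubic P-spline over \code{year} with \code{k = 5} basis
#'   functions and a second-order difference penalty.
#' @param linear Character vector of linear fixed terms (e.g.
#'   \code{c("year", "elevation_m", "lsea_precip_mm", "lsea_tmean_c")}).
#'   Covariates are standardized internally; estimates are reported per
#'   data unit.
#' @param elevation_by_year If \code{TRUE}, adds year main effects (factor)
#'   and one elevation slope per year (the yearly elevational-change model).
#' @param random Random-intercept grouping factors, subset of
#'   \code{c("locality", "plot")}.
#' @param ar1 Include the within-plot AR(1) residual correlation.
#' @param sp Optional named numeric vector of fixed smoothing parameters
#'   (names as in the fit's \code{$sp}, e.g. \code{c("s(year)" = 1e12)});
#'   unnamed single value applies to the smooth.
#' @param pql_maxit,pql_tol Penalized quasi-likelihood iteration controls
#'   (Poisson only).
#' @return An object of class \code{"pgamm"} with coefficients, their
#'   covariance, the fixed-term table (estimate, SE, statistic, p, stars),
#'   smoothing parameters, AR(1) rho, random-intercept variances, scale,
#'   effective degrees of freedom and fitted values.
#' @export
fit_pgamm <- function(data, response,
                      family = c("gaussian", "poisson"),
                      transformation = NULL,
                      smooth = list(var = "year", k = 5, degree = 3, m = 2),
                      linear = character(),
                      elevation_by_year = FALSE,
                      random = c("locality", "plot"),
                      ar1 = TRUE, sp = NULL,
                      pql_maxit = 30L, pql_tol = 1e-7) {
  family <- match.arg(family)
  need <- c(response, "plot_id", "year", linear,
            if (!is.null(smooth)) smooth$var,
            if (elevation_by_year) "elevation_m",
            if ("locality" %in% random) "locality_id")
  assert_cols(data, unique(need), "plot-year table")

  if (family == "gaussian") {
    transformation <- transformation %||% default_gamm_transformation(response)
    yraw <- transform_response(data[[response]], transformation)
  } else {
    transformation <- "identity"
    yraw <- data[[response]]
    if (any(yraw < 0 | yraw != round(yraw), na.rm = TRUE)) {
      stop_sporoscale("poisson family requires non-negative integer counts",
                      "sporoscale_domain_error")
    }
  }
  keep <- !is.na(yraw)
  if (sum(!keep) > 0L) {
    message(sprintf("dropping %d row(s) with undefined response", sum(!keep)))
  }
  d <- data[keep, , drop = FALSE]
  d <- d[order(d$plot_id, d$year), , drop = FALSE]
  yv <- if (family == "gaussian") transform_response(d[[response]],
                                                     transformation)
        else as.numeric(d[[response]])

  if (ar1) {
    per_plot <- table(d$plot_id)
    if (any(per_plot < 2L)) {
      stop_sporoscale(
        "AR(1) correlation needs at least 2 years per plot",
        "sporoscale_data_error")
    }
  }

  design <- pgamm_design(d, smooth, linear, elevation_by_year, random)
  fixed_sp <- list()
  if (!is.null(sp)) {
    if (is.null(names(sp)) && length(sp) == 1L && !is.null(smooth)) {
      names(sp) <- paste0("s(", smooth$var, ")")
    }
    fixed_sp <- as.list(sp)
  }

  if (family == "gaussian") {
    core <- pgamm_gaussian_core(design$X, yv, rep(1, nrow(d)), design,
                                ar1, fixed_sp, d)
    eta <- as.vector(design$X %*% core$b)
    mu <- eta
  } else {
    mu0 <- pmax(yv, 0.25)
    eta <- log(mu0)
    core <- NULL
    theta <- NULL
    for (it in seq_len(pql_maxit)) {
      mu_w <- exp(eta)
      z <- eta + (yv - mu_w) / mu_w
      core <- pgamm_gaussian_core(design$X, z, mu_w, design, ar1, fixed_sp,
                                  d, theta_init = theta)
      theta <- core$theta
      eta_new <- as.vector(design$X %*% core$b)
      delta <- max(abs(eta_new - eta))
      eta <- eta_new
      if (delta < pql_tol) break
    }
    if (delta >= pql_tol) {
      warning("PQL iterations did not fully converge", call. = FALSE)
    }
    mu <- exp(eta)
  }
  if (!core$converged) {
    warning("REML optimisation did not report convergence", call. = FALSE)
  }
  if (ar1 && abs(core$rho) > 0.99) {
    warning("AR(1) coefficient at the boundary (|rho| > 0.99)", call. = FALSE)
  }

  Hinv <- chol2inv(core$R)
  Vb <- core$sigma2 * Hinv
  edf <- rowSums(Hinv * core$XtX)

  # smoothing parameters / random-effect variances on the variance scale
  sp_out <- numeric(0)
  var_random <- c(locality = NA_real_, plot = NA_real_)
  k <- 0L
  for (j in seq_along(design$penalties)) {
    pen <- design$penalties[[j]]
    lam <- if (!is.null(fixed_sp[[pen$name]])) fixed_sp[[pen$name]]
           else { k <- k + 1L; exp(min(core$theta[k], 35)) }
    sp_out[pen$name] <- lam
    if (pen$name %in% c("locality", "plot")) {
      var_random[pen$name] <- core$sigma2 / lam
    }
  }
  rho <- if (ar1) core$rho else 0

  fit <- structure(list(
    coefficients = stats::setNames(core$b, design$col_names),
    Vb = Vb, edf = stats::setNames(edf, design$col_names),
    sigma2 = core$sigma2, sp = sp_out, rho = rho,
    var_random = var_random,
    family = family, transformation = transformation,
    response = response, design = design, data = d,
    y = yv, fitted_link = eta, fitted = mu,
    deviance = core$dev, converged = core$converged,
    theta = core$theta, n = nrow(d), ar1 = ar1,
    call = match.call()), class = "pgamm")
  fit$fixed_table <- pgamm_fixed_table(fit)
  fit
}

# Wald table for the unpenalized terms, reported on the data scale.
pgamm_fixed_table <- function(fit) {
  design <- fit$design
  p_fixed <- design$p_fixed
  b <- fit$coefficients
  Vb <- fit$Vb
  nms <- design$col_names[seq_len(p_fixed)]
  df_resid <- fit$n - sum(fit$edf)

  est <- se <- numeric(p_fixed)
  for (j in seq_len(p_fixed)) {
    nm <- nms[j]
    L <- rep(0, length(b))
    if (nm == "(Intercept)") {
      L[1L] <- 1
      for (v in names(design$std)) {
        jj <- match(v, nms)
        if (!is.na(jj)) {
          L[jj] <- -design$std[[v]]["center"] / design$std[[v]]["scale"]
        }
      }
    } else if (nm %in% names(design$std)) {
      L[j] <- 1 / design$std[[nm]]["scale"]
    } else if (startsWith(nm, "elevation_m:year")) {
      L[j] <- 1 / design$std[["elevation_m"]]["scale"]
    } else {
      L[j] <- 1
    }
    est[j] <- sum(L * b)
    se[j] <- sqrt(max(0, as.vector(t(L) %*% Vb %*% L)))
  }
  stat <- est / se
  p <- if (fit$family == "gaussian") 2 * stats::pt(-abs(stat), df_resid)
       else 2 * stats::pnorm(-abs(stat))
  data.frame(term = nms, estimate = est, se = se,
             statistic = stat, p = p, stars = p_stars(p),
             stringsAsFactors = FALSE)
}

# Full-width design rows carrying only the temporal trend: the smooth's
# columns plus a linear year column when present.
pgamm_trend_design <- function(fit, t, include_intercept = FALSE,
                               allow_extrapolate = FALSE) {
  design <- fit$design
  X <- matrix(0, length(t), length(fit$coefficients))
  if (include_intercept) X[, 1L] <- 1
  used <- FALSE
  if (!is.null(design$smooth) && design$smooth$var == "year") {
    B <- bspline_eval(design$smooth$basis, t, allow_extrapolate)
    X[, design$smooth$idx] <- B %*% design$smooth$Q
    used <- TRUE
  }
  jy <- match("year", design$col_names)
  if (!is.na(jy)) {
    s <- design$std[["year"]]
    X[, jy] <- (t - s["center"]) / s["scale"]
    used <- TRUE
  }
  if (!used) {
    stop_sporoscale("fit contains no temporal trend term",
                    "sporoscale_config_error")
  }
  X
}

#' Evaluate a fitted smooth with pointwise standard errors
#'
#' @param fit A \code{\link{fit_pgamm}} object with a smooth (or linear)
#'   trend over year.
#' @param grid Numeric grid of time points within the fitted range.
#' @param include_intercept Add the model intercept to the curve.
#' @param allow_extrapolate Permit grid points outside the fitted range.
#' @return Data frame with \code{grid}, \code{fit} (linear-predictor
#'   scale), \code{se}, \code{lo}, \code{hi} (95\% pointwise).
#' @export
predict_smooth <- function(fit, grid, include_intercept = FALSE,
                           allow_extrapolate = FALSE) {
  stopifnot(inherits(fit, "pgamm"))
  X <- pgamm_trend_design(fit, grid, include_intercept, allow_extrapolate)
  mu <- as.vector(X %*% fit$coefficients)
  se <- sqrt(pmax(0, rowSums((X %*% fit$Vb) * X)))
  data.frame(grid = grid, fit = mu, se = se,
             lo = mu - 1.96 * se, hi = mu + 1.96 * se)
}

#' @export
print.pgamm <- function(x, digits = 4, ...) {
  cat(sprintf("Penalized-spline mixed model: %s (%s family", x$response,
              x$family))
  if (x$family == "gaussian") cat(sprintf(", %s transform", x$transformation))
  cat(sprintf("), n = %d\n", x$n))
  tab <- x$fixed_table
  cat("Fixed terms:\n")
  out <- data.frame(term = tab$term,
                    estimate = sprintf("%.*g ± %.*g%s", digits,
                                       tab$estimate, 3, tab$se, tab$stars),
                    p = signif(tab$p, 3))
  print(out, row.names = FALSE)
  if (!is.null(x$design$smooth)) {
    edf_s <- sum(x$edf[x$design$smooth$idx])
    cat(sprintf("Smooth s(%s): edf = %.2f, lambda = %.3g\n",
                x$design$smooth$var, edf_s,
                x$sp[paste0("s(", x$design$smooth$var, ")")]))
  }
  if (x$ar1) cat(sprintf("AR(1) rho = %.3f\n", x$rho))
  vr <- x$var_random[!is.na(x$var_random)]
  if (length(vr) > 0) {
    cat("Random-intercept variances:",
        paste(sprintf("%s = %.4g", names(vr), vr), collapse = ", "), "\n")
  }
  cat(sprintf("Scale = %.4g\n", x$sigma2))
  invisible(x)
}

#' @export
summary.pgamm <- function(object, ...) print(object, ...)

#' @export
coef.pgamm <- function(object, ...) object$coefficients

#' @export
predict.pgamm <- function(object, type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (type == "link" || object$family == "gaussian") object$fitted_link
  else object$fitted
}

#' @export
residuals.pgamm <- function(object, ...) {
  object$y - object$fitted
}

#' @export
plot.pgamm <- function(x, n_grid = 100, ...) {
  tvar <- if (!is.null(x$design$smooth)) x$design$smooth$var else "year"
  t <- x$data[[tvar]]
  grid <- seq(min(t), max(t), length.out = n_grid)
  pr <- predict_smooth(x, grid, include_intercept = TRUE)
  ylim <- range(c(x$y, pr$lo, pr$hi), na.rm = TRUE)
  graphics::plot(t, x$y, pch = 16, col = "grey50",
                 xlab = tvar, ylab = paste0(x$response, " (model scale)"),
                 ylim = ylim, ...)
  graphics::polygon(c(grid, rev(grid)), c(pr$lo, rev(pr$hi)),
                    col = grDevices::adjustcolor("steelblue", 0.25),
                    border = NA)
  graphics::lines(grid, pr$fit, col = "steelblue", lwd = 2)
  invisible(x)
}

#' Time-trend model (penalized smooth over years)
#'
#' Convenience wrapper for the first model specification: the response
#' explained by a penalized spline over year with locality/plot random
#' intercepts and AR(1) residuals.
#'
#' @inheritParams fit_pgamm
#' @param k Basis dimension of the year smooth.
#' @param ... Passed to \code{\link{fit_pgamm}}.
#' @return A \code{pgamm} fit.
#' @export
pgamm_time <- function(data, response, family = "gaussian",
                       transformation = NULL, k = 5, ...) {
  fit_pgamm(data, response, family = family, transformation = transformation,
            smooth = list(var = "year", k = k, degree = 3, m = 2), ...)
}

#' Climate/elevation model (linear year, elevation and LSEA terms)
#'
#' The second model specification: linear fixed effects of year, elevation
#' and the LSEA climate covariates (August-October accumulated
#' precipitation and mean temperature), with random intercepts and AR(1)
#' residuals. Its fixed-term table is the "Year / Elevation / Precipitation
#' / Temperature" row layout used to summarise climate effects.
#'
#' @inheritParams fit_pgamm
#' @param ... Passed to \code{\link{fit_pgamm}}.
#' @return A \code{pgamm} fit.
#' @export
pgamm_climate <- function(data, response, family = "gaussian",
                          transformation = NULL, ...) {
  fit_pgamm(data, response, family = family, transformation = transformation,
            smooth = NULL,
            linear = c("year", "elevation_m", "lsea_precip_mm",
                       "lsea_tmean_c"), ...)
}

#' Yearly elevational-change model (one elevation slope per year)
#'
#' The third model specification: year as a factor plus a separate linear
#' elevation slope for each year, so elevational trends can strengthen,
#' vanish or reverse between years.
#'
#' @inheritParams fit_pgamm
#' @param ... Passed to \code{\link{fit_pgamm}}.
#' @return A \code{pgamm} fit; the per-year slopes appear in
#'   \code{$fixed_table} as \code{elevation_m:year<year>} rows.
#' @export
pgamm_year_elevation <- function(data, response, family = "gaussian",
                                 transformation = NULL, ...) {
  fit_pgamm(data, response, family = family, transformation = transformation,
            smooth = NULL, elevation_by_year = TRUE, ...)
}
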