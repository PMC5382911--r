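test_that("the P-spline basis is a partition of unity with the right
           penalty null space and rank", {
  x <- 2007:2014
  bs <- bspline_basis(x, k = 5)
  expect_equal(rowSums(bs$design), rep(1, 8), tolerance = 1e-12)
  expect_equal(dim(bs$design), c(8L, 5L))
  expect_equal(qr(bs$design)$rank, 5L)
  # coefficients linear in knot index are unpenalized for m = 2
  gam <- 0.3 + 1.7 * seq_len(5)
  expect_equal(as.numeric(t(gam) %*% bs$penalty %*% gam), 0,
               tolerance = 1e-10)
  expect_error(bspline_basis(x, k = 9), class = "sporoscale_rank_error")
  expect_error(bspline_basis(x, k = 3, degree = 3),
               class = "sporoscale_config_error")
})

test_that("noise-free linear data are reproduced with minimal freedom", {
  sv <- default_survey()
  d <- sv$plot_year
  d$ylin <- (2 + 3 * (d$year - 2007))^2
  f <- fit_pgamm(d, "ylin", transformation = "sqrt",
                 random = character(0), ar1 = FALSE)
  expect_lt(max(abs(f$y - f$fitted)), 1e-6)
  expect_lt(sum(f$edf), 2.05)  # intercept + line, smooth shrunk to null space
})

test_that("lambda -> infinity with AR(1) off recovers the OLS line", {
  sv <- default_survey()
  f <- fit_pgamm(sv$plot_year, "biomass_kg_ha",
                 smooth = list(var = "year", k = 5, degree = 3, m = 2),
                 random = character(0), ar1 = FALSE,
                 sp = c("s(year)" = 1e12))
  ols <- lm(sqrt(biomass_kg_ha) ~ year, data = f$data)
  expect_lt(max(abs(f$fitted - fitted(ols))), 1e-6)
  # the smooth-implied line is affine in the grid
  pr <- predict_smooth(f, seq(2007, 2014, length.out = 50),
                       include_intercept = TRUE)
  curv <- diff(diff(pr$fit))
  expect_lt(max(abs(curv)), 1e-8)
})

test_that("the REML-selected lambda dominates log-spaced alternatives", {
  sv <- default_survey()
  f <- fit_pgamm(sv$plot_year, "biomass_kg_ha", random = character(0),
                 ar1 = FALSE)
  alt <- 10^seq(-5, 5, length.out = 20)
  devs <- vapply(alt, function(l) {
    fit_pgamm(sv$plot_year, "biomass_kg_ha", random = character(0),
              ar1 = FALSE, sp = c("s(year)" = l))$deviance
  }, numeric(1))
  expect_lte(f$deviance, min(devs) + 1e-8)
})

test_that("AR(1) whitening removes the configured lag-1 correlation", {
  set.seed(5)
  rho <- 0.6
  n_plot <- 60; n_year <- 40
  plot_id <- rep(seq_len(n_plot), each = n_year)
  first <- !duplicated(plot_id)
  e <- numeric(n_plot * n_year)
  for (i in seq_along(e)) {
    e[i] <- if (first[i]) rnorm(1) else rho * e[i - 1] + rnorm(1, 0, sqrt(1 - rho^2))
  }
  w <- sporoscale:::pgamm_whiten(e, rho, rep(1, length(e)), first,
                                 rep(1, length(e)))
  lag1 <- cor(w[-1][!first[-1]], w[-length(w)][!first[-1]])
  expect_lt(abs(lag1), 3 / sqrt(length(w)))
})

test_that("poisson PQL on large counts approaches gaussian log-count fit", {
  sv <- default_survey()
  d <- sv$plot_year
  set.seed(9)
  mu <- exp(5 + 0.8 * sin(pi * (d$year - 2007) / 7))
  d$bigcount <- rpois(nrow(d), mu)
  fp <- fit_pgamm(d, "bigcount", family = "poisson", random = character(0),
                  ar1 = FALSE)
  d$logcount <- log(d$bigcount)
  fg <- fit_pgamm(d, "logcount", transformation = "identity",
                  random = character(0), ar1 = FALSE)
  expect_lt(max(abs(fp$fitted_link - fg$fitted)), 0.05)
})

test_that("smooth predictions are consistent, positive-SE and range-guarded", {
  sv <- default_survey()
  f <- fit_pgamm(sv$plot_year, "biomass_kg_ha", random = character(0),
                 ar1 = FALSE)
  pr <- predict_smooth(f, f$data$year, include_intercept = TRUE)
  expect_equal(pr$fit, unname(f$fitted), tolerance = 1e-9)
  expect_true(all(pr$se > 0))
  expect_error(predict_smooth(f, c(2006, 2010)),
               class = "sporoscale_extrapolation_error")
  pr2 <- predict_smooth(f, c(2006.5, 2010), allow_extrapolate = TRUE)
  expect_equal(nrow(pr2), 2L)
})

test_that("the fixed-term table renders one estimate ± SE row with stars", {
  sv <- default_survey()
  f <- pgamm_climate(sv$plot_year, "biomass_kg_ha")
  tab <- f$fixed_table
  expect_setequal(tab$term, c("(Intercept)", "year", "elevation_m",
                              "lsea_precip_mm", "lsea_tmean_c"))
  expect_true(all(tab$se > 0))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_true(all(tab$stars %in% c("", "*", "**", "***")))
  rendered <- sprintf("%.2f ± %.2f%s", tab$estimate, tab$se, tab$stars)
  expect_match(rendered, "^-?[0-9.]+ ± [0-9.]+\\**$", all = TRUE)
  # stars match the p-value cut-offs used in the table footnote convention
  expect_equal(tab$stars[tab$p < 0.001], rep("***", sum(tab$p < 0.001)))
})

test_that("per-year elevation slopes are reported for every year", {
  sv <- default_survey()
  f <- pgamm_year_elevation(sv$plot_year, "biomass_kg_ha")
  slopes <- f$fixed_table[startsWith(f$fixed_table$term, "elevation_m:year"), ]
  expect_equal(nrow(slopes), 8L)
  expect_true(all(slopes$se > 0))
})

test_that("spec validation refuses contradictory or unusable terms", {
  sv <- default_survey()
  expect_error(fit_pgamm(sv$plot_year, "biomass_kg_ha",
                         smooth = list(var = "year", k = 5),
                         linear = "year"),
               class = "sporoscale_config_error")
  one_year <- sv$plot_year[sv$plot_year$year == 2007, ]
  expect_error(fit_pgamm(one_year, "biomass_kg_ha", ar1 = TRUE),
               class = "sporoscale_data_error")
  expect_error(fit_pgamm(sv$plot_year, "evenness_J", family = "poisson"),
               class = "sporoscale_domain_error")
})

test_that("fitted trends agree with an independent mgcv fit", {
  skip_if_not_installed("mgcv")
  sv <- default_survey()
  f <- fit_pgamm(sv$plot_year, "biomass_kg_ha", random = "plot",
                 ar1 = FALSE)
  d <- f$data  # row order of the fitted values
  d$y <- sqrt(d$biomass_kg_ha)
  d$fplot <- factor(d$plot_id)
  m <- mgcv::gam(y ~ s(year, k = 5, bs = "ps", m = 2) + s(fplot, bs = "re"),
                 data = d, method = "REML")
  expect_gt(cor(f$fitted, fitted(m)), 0.99)
  expect_lt(mean(abs(f$fitted - fitted(m))), 0.15)
})
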