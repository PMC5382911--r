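test_that("per-plot yearly variances match closed forms and exclusion rules", {
  d <- data.frame(plot_id = rep(c("a", "b", "c"), times = c(4, 2, 1)),
                  year = c(2001:2004, 2001:2002, 2001),
                  elevation_m = rep(c(700, 900, 1100), times = c(4, 2, 1)),
                  v = c(5, 5, 5, 5, 0, 2, 3))
  expect_message(
    out <- plot_yearly_variance(d, "v", transformation = "identity"),
    "fewer than 2")
  expect_equal(out$variance[out$plot_id == "a"], 0)
  expect_equal(out$variance[out$plot_id == "b"], 2)  # var(c(0,2)), n-1
  expect_false("c" %in% out$plot_id)
  expect_equal(out$n_years, c(4L, 2L))
})

test_that("yearly variance shifts and scales as a variance should", {
  sv <- default_survey()
  d <- sv$plot_year
  v0 <- plot_yearly_variance(d, "biomass_kg_ha")
  d$shift <- (sqrt(d$biomass_kg_ha) + 11)^2
  v1 <- plot_yearly_variance(d, "shift", transformation = "sqrt")
  expect_equal(v0$variance, v1$variance, tolerance = 1e-9)
  d$scaled <- (3 * sqrt(d$biomass_kg_ha))^2
  v2 <- plot_yearly_variance(d, "scaled", transformation = "sqrt")
  expect_equal(v2$variance, 9 * v0$variance, tolerance = 1e-9)
})

test_that("OLS matches the closed-form normal equations and hand cases", {
  # hand oracle: x = (1,2,3), y = (1,3,2)
  r <- linear_regression(c(1, 2, 3), c(1, 3, 2))
  expect_equal(r$slope, 0.5)
  expect_equal(r$r2, 0.25)

  # perfect fit
  rp <- linear_regression(1:5, 2 * (1:5))
  expect_equal(rp$slope, 2)
  expect_equal(rp$r2, 1)
  expect_lt(rp$p, 1e-6)

  # closed-form agreement on random instances
  set.seed(13)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- 1 + 0.5 * x + rnorm(n)
    r <- linear_regression(x, y)
    sxx <- sum((x - mean(x))^2)
    b <- sum((x - mean(x)) * (y - mean(y))) / sxx
    a <- mean(y) - b * mean(x)
    res <- y - a - b * x
    s2 <- sum(res^2) / (n - 2)
    expect_equal(r$slope, b, tolerance = 1e-10)
    expect_equal(r$intercept, a, tolerance = 1e-10)
    expect_equal(r$slope_se, sqrt(s2 / sxx), tolerance = 1e-10)
    expect_equal(r$r2, 1 - sum(res^2) / sum((y - mean(y))^2),
                 tolerance = 1e-10)
    expect_equal(r$p, 2 * pt(-abs(b / sqrt(s2 / sxx)), n - 2),
                 tolerance = 1e-10)
  }

  expect_error(linear_regression(rep(1, 5), rnorm(5)),
               class = "sporoscale_singular_error")
  expect_error(linear_regression(1:2, 1:2), class = "sporoscale_data_error")
})

test_that("slope p-values are calibrated under the null", {
  set.seed(17)
  p <- replicate(400, {
    x <- rnorm(12); y <- rnorm(12)
    linear_regression(x, y)$p
  })
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.09)
})

test_that("elevation regression of yearly variance recovers the gradient", {
  cfg <- survey_config(trend = "flat", beta_precip = 0, beta_temp = 0,
                       year_sd_elev_gradient = 1, seed = 77)
  sv <- generate_survey(cfg, detail = "plot_year")
  ev <- elevation_variance_regression(sv$plot_year, "biomass_kg_ha")
  expect_equal(nrow(ev$variances), 19L)
  expect_gt(ev$regression$slope, 0)
  expect_equal(ev$regression$n, 19L)
})

test_that("richness relates positively to biomass across plot-years", {
  sv <- default_survey()
  r <- linear_regression(sqrt(sv$plot_year$biomass_kg_ha),
                         log1p(sv$plot_year$richness_S))
  expect_gt(r$slope, 0)
  expect_lt(r$p, 0.001)
})
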