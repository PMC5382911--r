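test_that("REML on a balanced one-way design equals the ANOVA estimator", {
  set.seed(42)
  for (rep in 1:5) {
    k <- sample(4:8, 1); n <- sample(3:6, 1)
    g <- rep(seq_len(k), each = n)
    y <- rnorm(k, sd = runif(1, 0, 2))[g] + rnorm(k * n)
    core <- sporoscale:::varcomp_core(y, list(g), k, scales = "group")
    a <- anova(lm(y ~ factor(g)))
    msb <- a$`Mean Sq`[1]; msw <- a$`Mean Sq`[2]
    expect_equal(unname(core$sigma2["group"]), max(0, (msb - msw) / n),
                 tolerance = 1e-6)
    if (msb > msw) {
      expect_equal(unname(core$sigma2["error"]), msw, tolerance = 1e-6)
    }
  }
})

test_that("optimizer dominates a brute-force restricted-likelihood grid", {
  # 3 years x 3 localities x 2 plots each, one observation per plot-year
  set.seed(11)
  d <- expand.grid(year = 1:3, locality = 1:3, rep = 1:2)
  d$plot <- (d$locality - 1) * 2 + d$rep
  y <- rnorm(3, sd = 1.5)[d$year] + rnorm(3)[d$locality] +
    rnorm(6, sd = 1.2)[d$plot] + rnorm(nrow(d), sd = 0.7)
  groups <- list(d$year, d$locality, d$plot)
  core <- sporoscale:::varcomp_core(y, groups, c(3L, 3L, 6L))
  pre <- sporoscale:::varcomp_prep(y, groups, c(3L, 3L, 6L))
  gr <- seq(-6, 4, length.out = 9)
  grid_devs <- apply(expand.grid(gr, gr, gr), 1, function(p) {
    sporoscale:::varcomp_deviance(as.numeric(p), pre)
  })
  expect_lte(core$deviance, min(grid_devs) + 1e-8)
})

test_that("full-model REML agrees with lme4 on a synthetic survey", {
  skip_if_not_installed("lme4")
  sv <- null_survey(seed = 11, sigma2 = c(4, 1.5, 3, 0.6))
  vc <- fit_varcomp(sv$plot_year, "biomass_kg_ha")
  d <- sv$plot_year
  d$y <- sqrt(d$biomass_kg_ha)
  m <- lme4::lmer(y ~ 1 + (1 | year) + (1 | locality_id) + (1 | plot_id),
                  data = d, REML = TRUE)
  ref <- as.data.frame(lme4::VarCorr(m))
  ref_map <- c(year = "year", locality = "locality_id", plot = "plot_id")
  for (sc in names(ref_map)) {
    expect_equal(vc$components$variance[vc$components$scale == sc],
                 ref$vcov[ref$grp == ref_map[[sc]]], tolerance = 1e-3)
  }
  expect_equal(vc$components$variance[vc$components$scale == "error"],
               ref$vcov[ref$grp == "Residual"], tolerance = 1e-3)
  expect_equal(sum(vc$components$pct), 100, tolerance = 1e-9)
})

test_that("estimates are invariant to relabeling and response shifts", {
  sv <- null_survey(seed = 21)
  d <- sv$plot_year
  vc1 <- fit_varcomp(d, "biomass_kg_ha")

  d2 <- d
  d2$plot_id <- paste0("zzz_", rev(as.integer(factor(d$plot_id))))
  d2$locality_id <- chartr("1234", "dcba", d2$locality_id)
  d2$year <- d2$year + 1000L
  vc2 <- fit_varcomp(d2, "biomass_kg_ha")
  expect_equal(vc1$components$variance, vc2$components$variance,
               tolerance = 1e-6)

  # adding a constant on the analysis scale
  d3 <- d
  d3$y_shift <- (sqrt(d3$biomass_kg_ha) + 7)^2
  vc3 <- fit_varcomp(d3, "y_shift", transformation = "sqrt")
  expect_equal(vc1$components$variance, vc3$components$variance,
               tolerance = 1e-5)
})

test_that("degenerate and pathological inputs are handled explicitly", {
  sv <- null_survey(seed = 31)
  d <- sv$plot_year
  d$const <- 4
  vc <- fit_varcomp(d, "const", transformation = "identity")
  expect_equal(vc$components$pct, c(0, 0, 0, 100))
  expect_true(all(vc$components$variance == 0))

  # one plot per locality everywhere: plot vs locality confounded
  d2 <- d[d$plot_id %in% c("p01", "p05", "p10", "p15"), ]
  err <- tryCatch(fit_varcomp(d2, "biomass_kg_ha"), error = identity)
  expect_s3_class(err, "sporoscale_identifiability_error")
  expect_match(conditionMessage(err), "locality_id, plot_id")

  expect_error(fit_varcomp(d[1:5, ], "biomass_kg_ha"),
               class = "sporoscale_data_error")
})

test_that("bootstrap CIs are ordered, counted and degenerate-safe", {
  sv <- null_survey(seed = 41)
  vc <- fit_varcomp(sv$plot_year, "biomass_kg_ha")
  vb <- bootstrap_varcomp(vc, n_boot = 60L, seed = 1)
  expect_true(all(vb$ci$lo <= vb$ci$hi))
  expect_equal(vb$n_boot, 60L)
  expect_lte(vb$n_boot_failed, 12L)
  tab <- as.data.frame(vb)
  expect_named(tab, c("scale", "variance", "pct", "ci_lo", "ci_hi"))

  # same seed reproduces the same intervals
  vb2 <- bootstrap_varcomp(vc, n_boot = 60L, seed = 1)
  expect_identical(vb$ci, vb2$ci)

  # zero-variance data: intervals collapse onto the convention bounds
  d <- sv$plot_year
  d$const <- 9
  vcc <- bootstrap_varcomp(
    fit_varcomp(d, "const", transformation = "identity"),
    n_boot = 20L, seed = 2)
  expect_true(all(vcc$ci$lo[1:3] == 0))
  expect_equal(vcc$ci$hi[4], 100)

  # parametric flavour runs and stays ordered
  vp <- bootstrap_varcomp(vc, n_boot = 40L, seed = 3, type = "parametric")
  expect_true(all(vp$ci$lo <= vp$ci$hi))
})
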