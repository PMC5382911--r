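test_that("the default design reproduces the emulated study dimensions", {
  sv <- default_survey()
  expect_equal(nrow(sv$meta), 19L)
  expect_equal(length(unique(sv$meta$locality_id)), 4L)
  expect_equal(min(sv$meta$elevation_m), 684)
  expect_equal(max(sv$meta$elevation_m), 1615)
  expect_equal(sort(unique(sv$plot_year$year)), 2007:2014)
  expect_equal(nrow(sv$plot_year), 19L * 8L)
  # weekly September-December sampling
  mo <- as.integer(format(as.Date(sv$records$sample_date), "%m"))
  expect_true(all(mo %in% 9:12))
})

test_that("generation is deterministic and streams are config-isolated", {
  a <- generate_survey(survey_config(seed = 8))
  b <- generate_survey(survey_config(seed = 8))
  expect_identical(a$records, b$records)
  expect_identical(a$climate, b$climate)
  expect_identical(a$truth$u_year, b$truth$u_year)
  # changing a week/species knob must not perturb the latent biomass
  c2 <- generate_survey(survey_config(seed = 8, lognormal_shape = 2))
  expect_identical(a$plot_year$biomass_kg_ha, c2$plot_year$biomass_kg_ha)
  expect_false(identical(a$records$taxon, c2$records$taxon))
})

test_that("degenerate config collapses to identical transformed biomass", {
  cfg <- survey_config(trend = "flat", beta_precip = 0, beta_temp = 0,
                       sigma2_year = 0, sigma2_locality = 0,
                       sigma2_plot = 0, sigma2_error = 0, seed = 2)
  sv <- generate_survey(cfg, detail = "plot_year")
  expect_equal(stats::var(sqrt(sv$plot_year$biomass_kg_ha)), 0)
  expect_error(survey_config(sigma2_year = -1),
               class = "sporoscale_config_error")
  expect_error(survey_config(years = integer(0)),
               class = "sporoscale_config_error")
})

test_that("truth summary gives analytic shares and trend periods", {
  cfg <- survey_config(sigma2_year = 4, sigma2_locality = 1,
                       sigma2_plot = 2, sigma2_error = 0.5, seed = 3)
  ts <- truth_summary(generate_survey(cfg, detail = "plot_year")$truth)
  expect_equal(unname(ts$expected_pct["year"]), 100 * 4 / 7.5)
  expect_equal(sum(ts$expected_pct), 100)
  ts0 <- truth_summary(generate_survey(
    survey_config(sigma2_year = 0, sigma2_locality = 0, sigma2_plot = 0,
                  sigma2_error = 1, seed = 3), detail = "plot_year")$truth)
  expect_equal(unname(ts0$expected_pct["error"]), 100)
  # hump trend: one increase then one decrease interval
  tsh <- truth_summary(generate_survey(
    survey_config(trend = "hump", seed = 3), detail = "plot_year")$truth)
  expect_equal(tsh$trend_periods$direction, c("increase", "decrease"))
})

test_that("realized effects match configured variances at 10x design size", {
  cfg <- survey_config(years = 1951:2030,
                       plots_per_locality = c(40, 50, 50, 50),
                       trend = "flat", beta_precip = 0, beta_temp = 0,
                       sigma2_year = 4, sigma2_locality = 1.5,
                       sigma2_plot = 3, sigma2_error = 0.6, seed = 99)
  sv <- generate_survey(cfg, detail = "plot_year")
  expect_equal(stats::var(sv$truth$u_year), 4, tolerance = 0.35)
  expect_equal(stats::var(sv$truth$u_plot), 3, tolerance = 0.2)
  # residual realized variance from the latent decomposition
  expect_equal(nrow(sv$plot_year), 80L * 190L)
})

test_that("guild shares and heavier mycorrhizal sporocarps are emulated", {
  sv <- default_survey()
  tot <- sum(sv$plot_year$biomass_kg_ha)
  myc <- sum(sv$plot_year$biomass_myco_kg_ha)
  expect_gt(myc / tot, 0.90)
  expect_lt(myc / tot, 0.97)
  rec <- sv$records[sv$records$count > 0, ]
  per <- rec$fresh_mass_g / rec$count
  expect_gt(mean(per[rec$guild == "mycorrhizal"]),
            mean(per[rec$guild == "saprotrophic"]))
})

test_that("LSEA precipitation increases with elevation as configured", {
  sv <- default_survey()
  cum8 <- rowsum(sv$lsea$lsea_precip_mm, sv$lsea$plot_id)
  elev <- sv$meta$elevation_m[match(rownames(cum8), sv$meta$plot_id)]
  fit <- linear_regression(elev, as.vector(cum8))
  expect_gt(fit$slope, 0)
  # 8-year cumulative LSEA contrast between gradient extremes (~1100 vs
  # ~1660 mm): check the fitted endpoints fall in wide bands around these
  lo <- fit$intercept + fit$slope * 684
  hi <- fit$intercept + fit$slope * 1615
  expect_gt(lo, 700); expect_lt(lo, 1500)
  expect_gt(hi, 1300); expect_lt(hi, 2100)
})
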