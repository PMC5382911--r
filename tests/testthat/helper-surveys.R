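# Shared fixtures, built in code.

# Default-design survey with full weekly records (cached across tests).
default_survey <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_survey(survey_config(seed = 42))
    cache
  }
})

# Null-model survey: flat trend, no climate effects, known variance
# components on the sqrt-biomass scale.
null_survey <- function(seed, sigma2 = c(4, 1.5, 3, 0.6), ...) {
  cfg <- survey_config(trend = "flat", beta_precip = 0, beta_temp = 0,
                       sigma2_year = sigma2[1], sigma2_locality = sigma2[2],
                       sigma2_plot = sigma2[3], sigma2_error = sigma2[4],
                       seed = seed, ...)
  generate_survey(cfg, detail = "plot_year")
}

# Tiny hand-written record set: one plot, one year, three collections.
tiny_records <- function() {
  data.frame(
    plot_id = "p1",
    sample_date = c("2010-09-15", "2010-10-01", "2010-10-08"),
    taxon = c("A", "A", "B"),
    guild = c("mycorrhizal", "mycorrhizal", "saprotrophic"),
    count = c(3L, 2L, 1L),
    fresh_mass_g = c(500, 700, 300),
    stringsAsFactors = FALSE)
}

tiny_meta <- function() {
  data.frame(plot_id = "p1", locality_id = "L1", elevation_m = 900,
             area_m2 = 100, stringsAsFactors = FALSE)
}
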