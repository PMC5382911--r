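# sporoscale

Spatio-temporal scales of variation in fungal sporocarp surveys.

Mushroom fruiting is notoriously episodic: on permanent forest plots
surveyed weekly over many years, the biomass of epigeous sporocarps can
swing by two orders of magnitude between years, while species richness and
evenness vary more between plots and localities than over time. `sporoscale`
packages the statistical workflow needed to quantify and model that
structure from raw weekly collection records:

- **Community metrics.** Weekly records (plot, date, taxon, guild, count,
  fresh mass) are aggregated to the plot-by-year analysis table: fresh
  biomass in kg ha⁻¹, species richness S, and Pielou's evenness
  J = H′/ln S computed from annual per-species biomass shares
  (`aggregate_plot_year()`, `pielou_evenness()`). Monthly climate is
  collapsed to the late-summer/early-autumn (LSEA) window: August–October
  accumulated precipitation and mean temperature
  (`compute_lsea_climate()`).
- **Variance components.** The null mixed model
  y = μ + u_year + u_locality + u_plot(locality) + ε is fitted by REML and
  reported as percentages of total variance per ecological scale, with
  percentile 95% confidence intervals from a two-stage case bootstrap
  (years, then plot series within localities; 199 resamples by default)
  (`fit_varcomp()`, `bootstrap_varcomp()`).
- **Trend models.** Penalized B-spline (P-spline) mixed models with
  locality/plot random intercepts and AR(1) within-plot residual
  correlation, for Gaussian responses (√biomass, arcsin√evenness) and
  Poisson richness via penalized quasi-likelihood. Smoothing parameters,
  ridge weights and ρ are selected jointly by restricted maximum
  likelihood (`fit_pgamm()`, with `pgamm_time()`, `pgamm_climate()`,
  `pgamm_year_elevation()` for the three standard specifications).
- **Fruiting pulses.** The first derivative of the fitted trend is
  estimated by finite differences on a 100-point grid with delta-method
  pointwise 95% intervals; maximal runs whose interval excludes zero are
  reported as significant increase/decrease periods
  (`first_derivative()`, `significant_periods()`).
- **Elevational variability.** Each plot's between-year variance is
  regressed on elevation by ordinary least squares
  (`elevation_variance_regression()`, `linear_regression()`).
- **Synthetic surveys.** `generate_survey()` simulates the full nested
  design — 19 plots in 4 localities spanning 684–1615 m, 8 years of weekly
  September–December sampling, a 349/231 mycorrhizal/saprotrophic species
  pool, LSEA precipitation increasing with elevation — with known variance
  components, trend shape and climate effects, so every estimator can be
  validated against ground truth.

## Worked example

```r
library(sporoscale)

sv <- generate_survey(survey_config(seed = 42))
py <- sv$plot_year  # plot-by-year biomass / richness / evenness + LSEA

vc <- bootstrap_varcomp(fit_varcomp(py, "biomass_kg_ha"), seed = 1)
vc
#> Variance decomposition of biomass_kg_ha (sqrt transform), REML, n = 152
#>     scale variance  pct        ci95
#>      year     4.42 38.9 [11.0-63.6]
#>  locality     2.04 17.9  [3.4-49.3]
#>      plot     3.36 29.6  [9.2-48.4]
#>     error     1.53 13.5  [6.5-18.0]
#> Percentile CIs from 199 bootstrap resamples (case; 0 failed)
```

Most variance in √biomass sits at the year and plot scales, as the
generator's defaults dictate (the configured shares are 42/17/34/7); with
only 8 years and 4 localities the bootstrap intervals on single-survey
shares are wide.

```r
ft <- pgamm_time(py, "biomass_kg_ha")
dv <- first_derivative(ft)
dv$periods
#>      start      end direction
#> 1 2007.000 2008.202  decrease
#> 2 2008.485 2011.313  increase
#> 3 2012.232 2014.000  decrease
```

The derivative of the fitted year smooth flags three significant pulses
under this seed — the hump-shaped mean trend interacting with realized
year effects; between them the derivative's 95% interval includes zero.

```r
ev <- elevation_variance_regression(py, "biomass_kg_ha")
ev$regression
#> slope[1,17] = 0.0043 ± 0.0016, P = 0.0164, R2 = 0.29
#> intercept = 0.521 ± 2.1, n = 19
```

Between-year variance of √biomass increases with elevation here even
though the generator's year effects are homoscedastic: LSEA precipitation
anomalies are multiplicative, so wetter high-elevation plots see larger
absolute climate-driven swings.

End-to-end runs are driven by one YAML config:

```r
cfg <- system.file("extdata", "demo-config.yaml", package = "sporoscale")
run_pipeline(cfg, out_dir = "demo-out", seed = 1)
```

which writes the generated inputs, all result CSVs and a JSON manifest.

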