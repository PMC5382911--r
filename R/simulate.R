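#' Configuration for the synthetic sporocarp survey generator
#'
#' Builds the parameter list consumed by \code{\link{generate_survey}}. The
#' defaults emulate the study design the package targets: 19 permanent
#' 10 x 10 m plots grouped in four localities (4/5/5/5 plots), elevations
#' spanning 684-1615 m with locality bands centred near 785, 1180, 1422 and
#' 1604 m, eight consecutive survey years (2007-2014) sampled weekly from
#' September to December, a mycorrhizal/saprotrophic species pool of
#' 349/231 taxa with the mycorrhizal guild contributing about 94% of total
#' biomass, and LSEA (August-October) precipitation increasing with
#' elevation such that the 8-year cumulative LSEA precipitation rises from
#' about 1100 mm at the bottom of the gradient to about 1660 mm at the top.
#'
#' Variance components are specified on the square-root biomass scale, the
#' scale on which biomass is analysed. The defaults (4.2, 1.7, 3.4, 0.7 for
#' year, locality, plot, error) put 42/17/34/7 percent of variance at the
#' four scales.
#'
#' @param n_localities Number of localities.
#' @param plots_per_locality Integer vector, plots in each locality (sums to
#'   the total plot count).
#' @param years Integer vector of consecutive survey years.
#' @param elevation_range_m Length-2 numeric, the exact elevations of the
#'   lowest and highest plot (pinned, not random).
#' @param locality_elev_m Target mean elevation per locality; interpolated
#'   across \code{elevation_range_m} when lengths disagree.
#' @param sigma2_year,sigma2_locality,sigma2_plot,sigma2_error Variance
#'   components of the random year, locality, plot effects and residual, on
#'   the square-root biomass scale (kg^0.5 ha^-0.5).
#' @param intercept Mean square-root biomass (default 8, i.e. 64 kg/ha).
#' @param trend Shape of the fixed temporal trend on the sqrt scale:
#'   \code{"flat"}, \code{"linear"} (amplitude spread over the period) or
#'   \code{"hump"} (half-sine rise and fall).
#' @param trend_amplitude Amplitude of the trend (sqrt-biomass units).
#' @param beta_precip,beta_temp Effects of the standardized LSEA
#'   precipitation and mean temperature on sqrt biomass.
#' @param precip_elev_slope Increase of mean LSEA precipitation with
#'   elevation, mm per m.
#' @param lsea_precip_base_mm Mean LSEA precipitation at the lowest plot.
#' @param sd_log_precip_year,sd_log_precip_noise Log-scale SDs of the shared
#'   inter-annual precipitation anomaly and of plot-month noise.
#' @param temp_base_c Mean annual temperature at the lowest plot, degrees C.
#' @param temp_lapse_c_per_m Temperature lapse rate with elevation.
#' @param sd_temp_year,sd_temp_noise SDs of the shared annual temperature
#'   anomaly and plot-month noise.
#' @param species_pool Named integer vector: pool sizes for the
#'   mycorrhizal and saprotrophic guilds.
#' @param lognormal_shape Log-scale SD of the lognormal species-abundance
#'   weights used to split guild biomass among species.
#' @param myco_share Expected mycorrhizal share of total biomass.
#' @param myco_share_conc Beta concentration of the per-plot-year share.
#' @param richness_base Named vector, expected species counts per plot-year
#'   and guild at the mean latent biomass.
#' @param richness_coupling Slope of log expected richness per unit latent
#'   sqrt-biomass (couples richness to the same predictors as biomass).
#' @param sporocarp_mass_g Named vector, mean fresh mass per sporocarp by
#'   guild (mycorrhizal sporocarps heavier).
#' @param year_sd_elev_gradient Relative increase of the year-effect and
#'   residual SD from the bottom to the top of the elevation gradient
#'   (0 = homoscedastic; 1 = SD doubles).
#' @param ar1_rho Lag-1 autocorrelation of the residual within each plot's
#'   yearly series (0 = independent errors); marginal variance stays
#'   \code{sigma2_error}.
#' @param seed Integer seed; regeneration with the same config is
#'   bit-identical.
#' @return A list of class \code{"survey_config"}.
#' @export
survey_config <- function(n_localities = 4,
                          plots_per_locality = c(4, 5, 5, 5),
                          years = 2007:2014,
                          elevation_range_m = c(684, 1615),
                          locality_elev_m = c(785, 1180, 1422, 1604),
                          sigma2_year = 4.2, sigma2_locality = 1.7,
                          sigma2_plot = 3.4, sigma2_error = 0.7,
                          intercept = 8,
                          trend = c("hump", "flat", "linear"),
                          trend_amplitude = 4,
                          beta_precip = 2, beta_temp = 0.5,
                          precip_elev_slope = 0.075,
                          lsea_precip_base_mm = 138,
                          sd_log_precip_year = 0.35,
                          sd_log_precip_noise = 0.25,
                          temp_base_c = 12, temp_lapse_c_per_m = -0.0055,
                          sd_temp_year = 0.5, sd_temp_noise = 0.8,
                          species_pool = c(mycorrhizal = 349,
                                           saprotrophic = 231),
                          lognormal_shape = 1,
                          myco_share = 0.94, myco_share_conc = 60,
                          richness_base = c(mycorrhizal = 12,
                                            saprotrophic = 5),
                          richness_coupling = 0.15,
                          sporocarp_mass_g = c(mycorrhizal = 12,
                                               saprotrophic = 4),
                          year_sd_elev_gradient = 0,
                          ar1_rho = 0,
                          seed = 1L) {
  trend <- match.arg(trend)
  cfg <- as.list(environment())
  if (abs(ar1_rho) >= 1) {
    stop_sporoscale("ar1_rho must lie in (-1, 1)", "sporoscale_config_error")
  }
  v <- c(sigma2_year, sigma2_locality, sigma2_plot, sigma2_error)
  if (any(v < 0) || anyNA(v)) {
    stop_sporoscale("variance components must be non-negative",
                    "sporoscale_config_error")
  }
  if (length(years) < 1L) {
    stop_sporoscale("at least one survey year is required",
                    "sporoscale_config_error")
  }
  if (length(plots_per_locality) != n_localities) {
    stop_sporoscale(
      "plots_per_locality must have one entry per locality",
      "sporoscale_config_error")
  }
  if (any(plots_per_locality < 1L)) {
    stop_sporoscale("each locality needs at least one plot",
                    "sporoscale_config_error")
  }
  if (diff(elevation_range_m) <= 0) {
    stop_sporoscale("elevation_range_m must be increasing",
                    "sporoscale_config_error")
  }
  if (length(locality_elev_m) != n_localities) {
    cfg$locality_elev_m <- seq(elevation_range_m[1] + 100,
                               elevation_range_m[2] - 10,
                               length.out = n_localities)
  }
  class(cfg) <- "survey_config"
  cfg
}

# Deterministic plot layout: plots spread evenly within each locality band,
# with the global lowest and highest plot pinned exactly to the configured
# elevation endpoints.
survey_layout <- function(cfg) {
  n_loc <- cfg$n_localities
  ord <- order(cfg$locality_elev_m)
  meta <- NULL
  p <- 0L
  for (j in seq_len(n_loc)) {
    i <- ord[j]
    n_i <- cfg$plots_per_locality[i]
    lo <- cfg$locality_elev_m[i] - 60
    hi <- cfg$locality_elev_m[i] + 60
    if (j == 1L) lo <- cfg$elevation_range_m[1]
    if (j == n_loc) hi <- cfg$elevation_range_m[2]
    ele <- if (n_i == 1L) (lo + hi) / 2 else seq(lo, hi, length.out = n_i)
    if (j == 1L) ele[1L] <- cfg$elevation_range_m[1]
    if (j == n_loc) ele[n_i] <- cfg$elevation_range_m[2]
    meta <- rbind(meta, data.frame(
      plot_id = sprintf("p%02d", p + seq_len(n_i)),
      locality_id = sprintf("loc%d", j),
      elevation_m = ele, area_m2 = 100,
      stringsAsFactors = FALSE))
    p <- p + n_i
  }
  meta
}

trend_function <- function(cfg) {
  rng <- range(cfg$years)
  span <- max(1, diff(rng))
  amp <- cfg$trend_amplitude
  switch(cfg$trend,
         flat = function(year) rep(0, length(year)),
         linear = function(year) amp * ((year - rng[1]) / span - 0.5),
         hump = function(year) amp * sin(pi * (year - rng[1]) / span))
}

# Independent substreams: changing one generator component's parameters
# leaves the draws of the others untouched.
stage_seed <- function(seed, stage) {
  off <- c(climate = 101L, effects = 211L, species = 307L, weeks = 401L)
  as.integer((seed + off[[stage]]) %% .Machine$integer.max)
}

#' Generate a synthetic sporocarp survey with known ground truth
#'
#' Simulates a full nested survey under the design described in
#' \code{\link{survey_config}}. The latent plot-year mean on the
#' square-root biomass scale is
#' intercept + trend(year) + beta_precip z(LSEA precip) +
#' beta_temp z(LSEA temp) + year effect + locality effect + plot effect +
#' error, with all random effects drawn from zero-mean Gaussians at the
#' configured variances. Square-root biomass is truncated at zero and
#' squared back to kg/ha; richness per guild is Poisson with log mean
#' linear in the same latent predictor; guild biomass is split among
#' species by a lognormal abundance distribution and across September to
#' December sampling weeks by a seasonal multinomial.
#'
#' @param config A \code{\link{survey_config}} object.
#' @param detail \code{"records"} (default) expands to weekly sporocarp
#'   records; \code{"plot_year"} stops at the plot-year analysis table
#'   (biomass and richness; evenness requires the species-level expansion
#'   and is \code{NA} on this path), which is much faster for Monte-Carlo
#'   studies.
#' @return A list of class \code{"sporoscale_survey"} with elements
#'   \code{records} (weekly records, \code{NULL} for
#'   \code{detail = "plot_year"}), \code{meta} (plot metadata),
#'   \code{climate} (monthly climate), \code{lsea}, \code{plot_year}
#'   (analysis table in \code{\link{aggregate_plot_year}} schema, scope
#'   total, plus guild biomass/richness columns) and \code{truth}
#'   (realized random effects, expected variance shares, trend function,
#'   true coefficients).
#' @export
generate_survey <- function(config = survey_config(),
                            detail = c("records", "plot_year")) {
  detail <- match.arg(detail)
  cfg <- config
  if (!inherits(cfg, "survey_config")) {
    stop_sporoscale("config must be a survey_config object",
                    "sporoscale_config_error")
  }
  meta <- survey_layout(cfg)
  years <- sort(unique(as.integer(cfg$years)))
  n_plot <- nrow(meta)
  n_year <- length(years)

  ## --- climate stream -----------------------------------------------------
  set.seed(stage_seed(cfg$seed, "climate"))
  e_rel <- meta$elevation_m - cfg$elevation_range_m[1]
  lsea_target <- cfg$lsea_precip_base_mm + cfg$precip_elev_slope * e_rel
  month_grid <- expand.grid(month = 1:12, year = years,
                            plot = seq_len(n_plot),
                            KEEP.OUT.ATTRS = FALSE)
  a_precip <- stats::rnorm(n_year, 0, cfg$sd_log_precip_year)
  a_temp <- stats::rnorm(n_year, 0, cfg$sd_temp_year)
  yi <- match(month_grid$year, years)
  pi_ <- month_grid$plot
  in_lsea <- month_grid$month %in% 8:10
  base_mm <- ifelse(in_lsea, lsea_target[pi_] / 3, 0.8 * lsea_target[pi_] / 3)
  # lognormal mean correction keeps the expected LSEA total on target
  corr <- -(cfg$sd_log_precip_year^2 + cfg$sd_log_precip_noise^2) / 2
  precip <- base_mm * exp(a_precip[yi] + corr +
                          stats::rnorm(nrow(month_grid), 0,
                                       cfg$sd_log_precip_noise))
  seasonal <- 7.5 * cos(2 * pi * (month_grid$month - 7) / 12)
  tmean <- cfg$temp_base_c + cfg$temp_lapse_c_per_m * e_rel[pi_] + seasonal +
    a_temp[yi] + stats::rnorm(nrow(month_grid), 0, cfg$sd_temp_noise)
  climate <- data.frame(plot_id = meta$plot_id[pi_],
                        year = month_grid$year,
                        month = month_grid$month,
                        precip_mm = precip, tmean_c = tmean,
                        stringsAsFactors = FALSE)
  lsea <- compute_lsea_climate(climate, years)

  ## --- latent effects stream ---------------------------------------------
  set.seed(stage_seed(cfg$seed, "effects"))
  u_year <- stats::rnorm(n_year, 0, sqrt(cfg$sigma2_year))
  u_loc <- stats::rnorm(cfg$n_localities, 0, sqrt(cfg$sigma2_locality))
  u_plot <- stats::rnorm(n_plot, 0, sqrt(cfg$sigma2_plot))
  sde <- sqrt(cfg$sigma2_error)
  if (cfg$ar1_rho == 0 || n_year == 1L) {
    eps <- stats::rnorm(n_plot * n_year, 0, sde)
  } else {
    # stationary AR(1) within each plot's yearly series
    E <- matrix(0, n_plot, n_year)
    E[, 1L] <- stats::rnorm(n_plot, 0, sde)
    innov_sd <- sde * sqrt(1 - cfg$ar1_rho^2)
    for (t in 2:n_year) {
      E[, t] <- cfg$ar1_rho * E[, t - 1L] + stats::rnorm(n_plot, 0, innov_sd)
    }
    eps <- as.vector(E)  # plot varies fastest, matching the plot-year grid
  }

  py <- expand.grid(plot = seq_len(n_plot), year = years,
                    KEEP.OUT.ATTRS = FALSE)
  li <- match(meta$locality_id[py$plot], unique(meta$locality_id))
  yi2 <- match(py$year, years)
  lkey <- paste(lsea$plot_id, lsea$year)
  pkey <- paste(meta$plot_id[py$plot], py$year)
  lp <- lsea$lsea_precip_mm[match(pkey, lkey)]
  lt <- lsea$lsea_tmean_c[match(pkey, lkey)]
  zp <- as.vector(scale(lp))
  zt <- as.vector(scale(lt))
  if (anyNA(zp)) zp <- rep(0, length(lp))
  if (anyNA(zt)) zt <- rep(0, length(lt))

  tr_fun <- trend_function(cfg)
  tr <- tr_fun(py$year)
  scale_elev <- 1 + cfg$year_sd_elev_gradient *
    (meta$elevation_m[py$plot] - cfg$elevation_range_m[1]) /
    diff(cfg$elevation_range_m)
  latent <- cfg$intercept + tr + cfg$beta_precip * zp + cfg$beta_temp * zt +
    u_loc[li] + u_plot[py$plot] +
    scale_elev * (u_year[yi2] + eps)
  sqrt_biomass <- pmax(latent, 0)
  biomass <- sqrt_biomass^2

  # guild richness: Poisson, log mean linear in the latent predictor
  mu_m <- cfg$richness_base[["mycorrhizal"]] *
    exp(cfg$richness_coupling * (latent - cfg$intercept))
  mu_s <- cfg$richness_base[["saprotrophic"]] *
    exp(cfg$richness_coupling * (latent - cfg$intercept))
  S_m <- pmin(stats::rpois(length(mu_m), mu_m),
              cfg$species_pool[["mycorrhizal"]])
  S_s <- pmin(stats::rpois(length(mu_s), mu_s),
              cfg$species_pool[["saprotrophic"]])
  S_m[biomass == 0] <- 0L
  S_s[biomass == 0] <- 0L
  S_m[biomass > 0 & (S_m + S_s) == 0L] <- 1L

  # guild share of biomass
  a <- cfg$myco_share * cfg$myco_share_conc
  b <- (1 - cfg$myco_share) * cfg$myco_share_conc
  share <- stats::rbeta(length(biomass), a, b)
  share[S_s == 0L] <- 1
  share[S_m == 0L & S_s > 0L] <- 0
  biomass_m <- biomass * share
  biomass_s <- biomass * (1 - share)
  S_m[biomass_m == 0] <- 0L
  S_s[biomass_s == 0] <- 0L

  plot_year <- data.frame(
    plot_id = meta$plot_id[py$plot],
    locality_id = meta$locality_id[py$plot],
    year = py$year,
    elevation_m = meta$elevation_m[py$plot],
    scope = "total",
    biomass_kg_ha = biomass,
    richness_S = as.integer(S_m + S_s),
    evenness_J = NA_real_,
    lsea_precip_mm = lp, lsea_tmean_c = lt,
    biomass_myco_kg_ha = biomass_m,
    biomass_sapro_kg_ha = biomass_s,
    richness_myco = as.integer(S_m),
    richness_sapro = as.integer(S_s),
    stringsAsFactors = FALSE)

  total <- cfg$sigma2_year + cfg$sigma2_locality + cfg$sigma2_plot +
    cfg$sigma2_error
  truth <- list(
    config = cfg,
    u_year = stats::setNames(u_year, years),
    u_locality = stats::setNames(u_loc, unique(meta$locality_id)),
    u_plot = stats::setNames(u_plot, meta$plot_id),
    expected_pct = c(year = 100 * cfg$sigma2_year / total,
                     locality = 100 * cfg$sigma2_locality / total,
                     plot = 100 * cfg$sigma2_plot / total,
                     error = 100 * cfg$sigma2_error / total),
    trend_fun = tr_fun,
    trend_values = stats::setNames(tr_fun(years), years),
    beta = c(precip = cfg$beta_precip, temp = cfg$beta_temp),
    latent = latent)
  class(truth) <- "sporoscale_truth"

  records <- NULL
  if (detail == "records") {
    records <- expand_records(cfg, meta, years, plot_year)
    # evenness is defined by the realized species split
    ev <- aggregate_plot_year(records, meta, lsea = NULL, scope = "total")
    ik <- match(paste(plot_year$plot_id, plot_year$year),
                paste(ev$plot_id, ev$year))
    plot_year$evenness_J <- ev$evenness_J[ik]
  }

  structure(list(records = records, meta = meta, climate = climate,
                 lsea = lsea, plot_year = plot_year, truth = truth),
            class = "sporoscale_survey")
}

# Expand the latent plot-year table into weekly taxon-level records.
expand_records <- function(cfg, meta, years, plot_year) {
  set.seed(stage_seed(cfg$seed, "species"))
  pools <- list(
    mycorrhizal = exp(stats::rnorm(cfg$species_pool[["mycorrhizal"]], 0,
                                   cfg$lognormal_shape)),
    saprotrophic = exp(stats::rnorm(cfg$species_pool[["saprotrophic"]], 0,
                                    cfg$lognormal_shape)))
  taxa <- list(
    mycorrhizal = sprintf("myc_%03d", seq_along(pools$mycorrhizal)),
    saprotrophic = sprintf("sap_%03d", seq_along(pools$saprotrophic)))

  # species choice + within-plot-year shares (species stream)
  split_species <- function(guild, S, mass_g) {
    if (S == 0L || mass_g <= 0) return(NULL)
    w <- pools[[guild]]
    idx <- sample.int(length(w), S, replace = FALSE, prob = w)
    sh <- w[idx] * exp(stats::rnorm(S, 0, 0.5))
    data.frame(taxon = taxa[[guild]][idx], guild = guild,
               mass_g = mass_g * sh / sum(sh), stringsAsFactors = FALSE)
  }
  n_py <- nrow(plot_year)
  area <- meta$area_m2[match(plot_year$plot_id, meta$plot_id)]
  sp_list <- vector("list", n_py)
  for (i in seq_len(n_py)) {
    m <- split_species("mycorrhizal", plot_year$richness_myco[i],
                       plot_year$biomass_myco_kg_ha[i] * area[i] / 10)
    s <- split_species("saprotrophic", plot_year$richness_sapro[i],
                       plot_year$biomass_sapro_kg_ha[i] * area[i] / 10)
    sp_list[[i]] <- if (is.null(m) && is.null(s)) NULL else rbind(m, s)
  }

  # weekly allocation (weeks stream): Sept 1 to late December, 7-day steps
  set.seed(stage_seed(cfg$seed, "weeks"))
  week_offsets <- seq(0, 118, by = 7)
  n_w <- length(week_offsets)
  w_weights <- exp(-0.5 * ((seq_len(n_w) - 8.5) / 3)^2)
  w_weights <- w_weights / sum(w_weights)

  out <- vector("list", n_py)
  for (i in seq_len(n_py)) {
    week_dates <- as.character(
      as.Date(sprintf("%d-09-01", plot_year$year[i])) + week_offsets)
    sp <- sp_list[[i]]
    if (is.null(sp)) {
      out[[i]] <- data.frame(plot_id = plot_year$plot_id[i],
                             sample_date = week_dates[1L], taxon = "",
                             guild = "", count = 0L, fresh_mass_g = 0,
                             stringsAsFactors = FALSE)
      next
    }
    mass_per <- cfg$sporocarp_mass_g[sp$guild]
    n_sporo <- pmax(1L, stats::rpois(nrow(sp), sp$mass_g / mass_per))
    counts <- vapply(seq_len(nrow(sp)), function(j) {
      stats::rmultinom(1, n_sporo[j], w_weights)[, 1L]
    }, integer(n_w))
    nz <- which(counts > 0L, arr.ind = TRUE)
    wk <- nz[, 1L]
    spi <- nz[, 2L]
    out[[i]] <- data.frame(
      plot_id = plot_year$plot_id[i],
      sample_date = week_dates[wk],
      taxon = sp$taxon[spi], guild = sp$guild[spi],
      count = counts[nz],
      fresh_mass_g = sp$mass_g[spi] * counts[nz] / n_sporo[spi],
      stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, out)
  rownames(rec) <- NULL
  rec
}

#' Expected variance decomposition and trend descriptor of a ground truth
#'
#' @param truth The \code{truth} element of a generated survey.
#' @return List with \code{expected_pct} (analytic percentage of variance
#'   per scale, sigma2_scale / sum(sigma2) * 100), \code{sigma2} (the
#'   configured components) and \code{trend_periods} (maximal monotone
#'   intervals of the true trend: year start, year end, direction).
#' @export
truth_summary <- function(truth) {
  if (!inherits(truth, "sporoscale_truth")) {
    stop_sporoscale("truth must come from generate_survey",
                    "sporoscale_config_error")
  }
  cfg <- truth$config
  yrs <- range(cfg$years)
  grid <- seq(yrs[1], yrs[2], length.out = 201)
  tv <- truth$trend_fun(grid)
  d <- diff(tv)
  dir <- ifelse(d > 1e-12, "increase", ifelse(d < -1e-12, "decrease", "none"))
  r <- rle(dir)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  keep <- r$values != "none"
  periods <- data.frame(start = grid[starts[keep]],
                        end = grid[ends[keep] + 1L],
                        direction = r$values[keep],
                        stringsAsFactors = FALSE)
  list(expected_pct = truth$expected_pct,
       sigma2 = c(year = cfg$sigma2_year, locality = cfg$sigma2_locality,
                  plot = cfg$sigma2_plot, error = cfg$sigma2_error),
       trend_periods = periods)
}

#' Write a generated survey to CSV inputs plus a truth sidecar
#'
#' Writes \code{records.csv}, \code{plots.csv}, \code{climate.csv} and
#' \code{truth.json} into \code{dir}, the on-disk form consumed by
#' \code{\link{read_sporocarp_table}} and friends.
#'
#' @param survey A \code{\link{generate_survey}} result (detail
#'   \code{"records"}).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the vector of paths written.
#' @export
write_survey <- function(survey, dir) {
  if (is.null(survey$records)) {
    stop_sporoscale("survey was generated without records; use detail='records'",
                    "sporoscale_config_error")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("records.csv", "plots.csv", "climate.csv",
                            "truth.json"))
  write_result_table(survey$records, paths[1])
  write_result_table(survey$meta, paths[2])
  write_result_table(survey$climate, paths[3])
  tr <- survey$truth
  jsonlite::write_json(
    list(expected_pct = as.list(tr$expected_pct),
         u_year = as.list(tr$u_year),
         u_locality = as.list(tr$u_locality),
         u_plot = as.list(tr$u_plot),
         beta = as.list(tr$beta),
         trend = tr$config$trend,
         trend_values = as.list(tr$trend_values),
         seed = tr$config$seed),
    paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
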