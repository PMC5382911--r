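#' Pielou's evenness from a species biomass vector
#'
#' Computes Pielou's evenness J = H'/ln(S), where H' is the Shannon entropy
#' of the biomass shares p_i and S the number of species. J equals 1 when
#' all species contribute equal biomass, and is undefined (returned as
#' \code{NA}) for communities of fewer than two species, where ln(S) = 0.
#'
#' @param x Numeric vector of per-species annual biomass, all entries
#'   strictly positive (zero-biomass species must be dropped beforehand).
#'   Units cancel; any common scale may be used.
#' @return A single numeric value in [0, 1], or \code{NA_real_} when
#'   \code{length(x) <= 1}.
#' @examples
#' pielou_evenness(c(10, 10, 10, 10))  # 1
#' pielou_evenness(c(3, 1))
#' @export
pielou_evenness <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  if (anyNA(x) || any(x <= 0)) {
    bad <- which(is.na(x) | x <= 0)[1L]
    stop_sporoscale(
      sprintf("species biomass must be positive; entry %d is %s",
              bad, format(x[bad])),
      "sporoscale_domain_error")
  }
  s <- length(x)
  if (s < 2L) return(NA_real_)
  p <- x / sum(x)
  -sum(p * log(p)) / log(s)
}

#' Elementwise response transformations
#'
#' Variance-stabilising transformations used before model fitting: square
#' root for biomass, log(1 + x) for richness counts, arcsine-square-root
#' for evenness proportions. \code{arcsine_sqrt(x)} is arcsin(sqrt(x)); a
#' plain \code{arcsine} variant is also available.
#'
#' @param x Numeric vector. \code{NA}s pass through untouched.
#' @param kind One of \code{"identity"}, \code{"sqrt"}, \code{"log1p"},
#'   \code{"arcsine_sqrt"}, \code{"arcsine"}.
#' @return Numeric vector of the same length.
#' @export
transform_response <- function(x, kind = c("identity", "sqrt", "log1p",
                                           "arcsine_sqrt", "arcsine")) {
  kind <- match.arg(kind)
  ok <- !is.na(x)
  check_domain <- function(cond, need) {
    bad <- which(ok & !cond)
    if (length(bad) > 0L) {
      stop_sporoscale(
        sprintf("transform '%s' requires %s; violated at index %d (value %s)",
                kind, need, bad[1L], format(x[bad[1L]])),
        "sporoscale_domain_error")
    }
  }
  switch(kind,
    identity = x,
    sqrt = { check_domain(x >= 0, "non-negative input"); sqrt(x) },
    log1p = { check_domain(x >= 0, "non-negative input"); log1p(x) },
    arcsine_sqrt = {
      check_domain(x >= 0 & x <= 1, "input in [0, 1]")
      asin(sqrt(x))
    },
    arcsine = {
      check_domain(x >= -1 & x <= 1, "input in [-1, 1]")
      asin(x)
    })
}

#' Aggregate weekly sporocarp records into the plot-by-year analysis table
#'
#' Collapses weekly collection records to one row per plot and year: total
#' fresh biomass scaled to kg per hectare, species richness S (number of
#' distinct taxa with positive biomass) and Pielou evenness J computed from
#' the annual per-species biomass. Restricting \code{scope} to one trophic
#' guild aggregates only that guild's records. Plot-years that were sampled
#' but yielded no collections (or none in the requested scope) are retained
#' with biomass 0, S = 0 and J undefined.
#'
#' @param records Data frame of sporocarp records with columns
#'   \code{plot_id}, \code{sample_date} (ISO 8601), \code{taxon},
#'   \code{guild} ("mycorrhizal"/"saprotrophic"), \code{count},
#'   \code{fresh_mass_g}. Zero-collection sampling events may be recorded
#'   as rows with count 0, mass 0 and empty taxon.
#' @param meta Plot metadata with columns \code{plot_id},
#'   \code{locality_id}, \code{elevation_m} and \code{area_m2}.
#' @param lsea Optional late-summer/early-autumn climate table
#'   (\code{plot_id}, \code{year}, \code{lsea_precip_mm},
#'   \code{lsea_tmean_c}), as produced by \code{\link{compute_lsea_climate}};
#'   merged onto the output when given.
#' @param scope \code{"total"}, \code{"mycorrhizal"} or
#'   \code{"saprotrophic"}.
#' @param plot_years Optional data frame (\code{plot_id}, \code{year})
#'   enumerating the sampled plot-years. Default: every plot in \code{meta}
#'   crossed with every year observed in \code{records} (the complete
#'   permanent-plot design).
#' @param drop_empty If \code{TRUE}, plot-years with no collections are
#'   dropped instead of retained as zeros.
#' @return Data frame with one row per plot-year: \code{plot_id},
#'   \code{locality_id}, \code{year}, \code{elevation_m}, \code{scope},
#'   \code{biomass_kg_ha}, \code{richness_S}, \code{evenness_J} and, when
#'   \code{lsea} is supplied, \code{lsea_precip_mm}, \code{lsea_tmean_c}.
#' @export
aggregate_plot_year <- function(records, meta, lsea = NULL,
                                scope = c("total", "mycorrhizal",
                                          "saprotrophic"),
                                plot_years = NULL, drop_empty = FALSE) {
  scope <- match.arg(scope)
  assert_cols(records, c("plot_id", "sample_date", "taxon", "guild",
                         "count", "fresh_mass_g"), "records")
  assert_cols(meta, c("plot_id", "locality_id", "elevation_m", "area_m2"),
              "meta")

  unknown <- setdiff(unique(records$plot_id), meta$plot_id)
  if (length(unknown) > 0L) {
    stop_sporoscale(
      sprintf("records reference plot(s) absent from metadata: %s",
              paste(unknown, collapse = ", ")),
      "sporoscale_referential_error")
  }

  year <- as.integer(format(as.Date(records$sample_date), "%Y"))
  if (is.null(plot_years)) {
    plot_years <- expand.grid(plot_id = unique(meta$plot_id),
                              year = sort(unique(year)),
                              KEEP.OUT.ATTRS = FALSE,
                              stringsAsFactors = FALSE)
  }

  live <- !is.na(records$taxon) & records$taxon != "" &
    records$fresh_mass_g > 0
  if (scope != "total") live <- live & records$guild == scope
  rec <- records[live, , drop = FALSE]
  rec$year <- year[live]

  key <- function(p, y) paste(p, y, sep = "\r")
  # annual biomass per plot-year-taxon, then per plot-year
  if (nrow(rec) > 0L) {
    tkey <- paste(key(rec$plot_id, rec$year), rec$taxon, sep = "\r")
    sp_mass <- rowsum(rec$fresh_mass_g, tkey)
    parts <- strsplit(rownames(sp_mass), "\r", fixed = TRUE)
    sp_py <- vapply(parts, function(z) paste(z[1L], z[2L], sep = "\r"),
                    character(1))
    py_mass <- rowsum(as.vector(sp_mass), sp_py)
    species_by_py <- split(as.vector(sp_mass), sp_py)
  } else {
    py_mass <- matrix(numeric(0))
    species_by_py <- list()
  }

  out <- plot_years
  m_idx <- match(out$plot_id, meta$plot_id)
  out$locality_id <- meta$locality_id[m_idx]
  out$elevation_m <- meta$elevation_m[m_idx]
  out$scope <- scope
  area <- meta$area_m2[m_idx]

  k <- key(out$plot_id, out$year)
  mass_g <- as.vector(py_mass)[match(k, rownames(py_mass))]
  mass_g[is.na(mass_g)] <- 0
  out$biomass_kg_ha <- (mass_g / 1000) * (10000 / area)
  sp <- species_by_py[k]
  out$richness_S <- vapply(sp, function(v) if (is.null(v)) 0L else length(v),
                           integer(1))
  out$evenness_J <- vapply(sp, function(v) {
    if (is.null(v) || length(v) < 2L) NA_real_ else pielou_evenness(v)
  }, numeric(1))

  if (drop_empty) out <- out[out$richness_S > 0L, , drop = FALSE]

  if (!is.null(lsea)) {
    assert_cols(lsea, c("plot_id", "year", "lsea_precip_mm", "lsea_tmean_c"),
                "lsea")
    li <- match(key(out$plot_id, out$year), key(lsea$plot_id, lsea$year))
    out$lsea_precip_mm <- lsea$lsea_precip_mm[li]
    out$lsea_tmean_c <- lsea$lsea_tmean_c[li]
  }
  cols <- c("plot_id", "locality_id", "year", "elevation_m", "scope",
            "biomass_kg_ha", "richness_S", "evenness_J")
  if (!is.null(lsea)) cols <- c(cols, "lsea_precip_mm", "lsea_tmean_c")
  rownames(out) <- NULL
  out[order(out$plot_id, out$year), cols]
}
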