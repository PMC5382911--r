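# Reading/validation of the three survey input tables and result output.
#
# All tables are plain delimited text (comma by default) with a header row.
# Column names can be remapped and guild labels aliased through the YAML
# run configuration (see read_run_config).

read_delim_table <- function(path, delim = ",", col_map = NULL, what) {
  if (!file.exists(path)) {
    stop_sporoscale(sprintf("%s file not found: %s", what, path),
                    "sporoscale_io_error")
  }
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", na.strings = c("NA", ""))
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(df)) {
        names(df)[names(df) == col_map[[canon]]] <- canon
      }
    }
  }
  df
}

row_errors <- function(bad, field, values, what) {
  if (!any(bad)) return(invisible(NULL))
  lines <- which(bad) + 1L  # +1 for the header line
  shown <- utils::head(lines, 5L)
  stop_sporoscale(
    sprintf("%s: invalid %s at line(s) %s%s (e.g. value '%s')",
            what, field, paste(shown, collapse = ", "),
            if (length(lines) > 5L) sprintf(" and %d more", length(lines) - 5L)
            else "",
            format(values[which(bad)[1L]])),
    "sporoscale_row_error")
}

#' Read a sporocarp collection table
#'
#' Reads and validates weekly sporocarp records: one row per plot, sampling
#' date and taxon with the number of sporocarps collected and their total
#' fresh mass in grams. Rows with count 0, mass 0 and an empty taxon mark
#' sampling events without collections and are accepted. Sampling dates
#' outside the September-December survey window raise a warning (the design
#' being emulated samples weekly within that window), not an error.
#'
#' @param path Path to a delimited text file with header columns
#'   \code{plot_id}, \code{sample_date}, \code{taxon}, \code{guild},
#'   \code{count}, \code{fresh_mass_g} (renameable via \code{col_map}).
#' @param delim Field delimiter, default comma.
#' @param col_map Named list mapping canonical column names to the names
#'   used in the file, e.g. \code{list(taxon = "species")}.
#' @param guild_aliases Named character vector mapping file guild labels to
#'   \code{"mycorrhizal"}/\code{"saprotrophic"}, e.g.
#'   \code{c(ecto = "mycorrhizal")}.
#' @return Data frame of validated records.
#' @export
read_sporocarp_table <- function(path, delim = ",", col_map = NULL,
                                 guild_aliases = NULL) {
  df <- read_delim_table(path, delim, col_map, "sporocarp table")
  assert_cols(df, c("plot_id", "sample_date", "taxon", "guild", "count",
                    "fresh_mass_g"), "sporocarp table")
  what <- "sporocarp table"

  d <- as.Date(as.character(df$sample_date), format = "%Y-%m-%d")
  row_errors(is.na(d), "sample_date", df$sample_date, what)
  df$sample_date <- as.character(d)

  cnt <- suppressWarnings(as.numeric(df$count))
  row_errors(is.na(cnt) | cnt < 0 | cnt != round(cnt), "count", df$count, what)
  df$count <- as.integer(cnt)

  m <- suppressWarnings(as.numeric(df$fresh_mass_g))
  row_errors(is.na(m) | m < 0, "fresh_mass_g", df$fresh_mass_g, what)
  df$fresh_mass_g <- m

  g <- as.character(df$guild)
  if (!is.null(guild_aliases)) {
    hit <- g %in% names(guild_aliases)
    g[hit] <- unname(guild_aliases[g[hit]])
  }
  empty_marker <- (is.na(df$taxon) | df$taxon == "") & df$count == 0L &
    df$fresh_mass_g == 0
  row_errors(!(g %in% c("mycorrhizal", "saprotrophic")) & !empty_marker,
             "guild", df$guild, what)
  df$guild <- g
  df$taxon <- ifelse(is.na(df$taxon), "", as.character(df$taxon))
  df$plot_id <- as.character(df$plot_id)

  mo <- as.integer(format(d, "%m"))
  n_off <- sum(!(mo %in% 9:12))
  if (n_off > 0L) {
    warning(sprintf(
      "%d record(s) dated outside the September-December sampling window",
      n_off), call. = FALSE)
  }
  df
}

#' Read the plot metadata table
#'
#' @param path Delimited file with columns \code{plot_id},
#'   \code{locality_id}, \code{elevation_m} and optionally \code{area_m2}
#'   (default 100 m^2 when absent).
#' @inheritParams read_sporocarp_table
#' @return Data frame of plot metadata, one row per plot.
#' @export
read_plot_meta <- function(path, delim = ",", col_map = NULL) {
  df <- read_delim_table(path, delim, col_map, "plot metadata")
  assert_cols(df, c("plot_id", "locality_id", "elevation_m"), "plot metadata")
  if (!"area_m2" %in% names(df)) df$area_m2 <- 100
  what <- "plot metadata"
  e <- suppressWarnings(as.numeric(df$elevation_m))
  row_errors(is.na(e) | e <= 0, "elevation_m", df$elevation_m, what)
  df$elevation_m <- e
  a <- suppressWarnings(as.numeric(df$area_m2))
  row_errors(is.na(a) | a <= 0, "area_m2", df$area_m2, what)
  df$area_m2 <- a
  df$plot_id <- as.character(df$plot_id)
  df$locality_id <- as.character(df$locality_id)
  if (anyDuplicated(df$plot_id)) {
    stop_sporoscale("plot metadata has duplicated plot_id rows",
                    "sporoscale_schema_error")
  }
  df
}

#' Read a monthly climate table
#'
#' Climate is keyed per plot (each plot carries its nearest station's
#' series); a table keyed by locality can be broadcast to member plots with
#' \code{broadcast_meta}.
#'
#' @param path Delimited file with columns \code{plot_id}, \code{year},
#'   \code{month}, \code{precip_mm}, \code{tmean_c}.
#' @param broadcast_meta Optional plot metadata; when the file's
#'   \code{plot_id} values are locality ids, rows are replicated to every
#'   plot of the locality.
#' @inheritParams read_sporocarp_table
#' @return Data frame of monthly climate, one row per plot, year and month.
#' @export
read_climate_monthly <- function(path, delim = ",", col_map = NULL,
                                 broadcast_meta = NULL) {
  df <- read_delim_table(path, delim, col_map, "climate table")
  assert_cols(df, c("plot_id", "year", "month", "precip_mm", "tmean_c"),
              "climate table")
  what <- "climate table"
  for (fld in c("year", "month", "precip_mm", "tmean_c")) {
    v <- suppressWarnings(as.numeric(df[[fld]]))
    row_errors(is.na(v), fld, df[[fld]], what)
    df[[fld]] <- v
  }
  row_errors(df$month < 1 | df$month > 12 | df$month != round(df$month),
             "month", df$month, what)
  row_errors(df$precip_mm < 0, "precip_mm", df$precip_mm, what)
  df$year <- as.integer(df$year)
  df$month <- as.integer(df$month)
  df$plot_id <- as.character(df$plot_id)

  if (!is.null(broadcast_meta) &&
      any(df$plot_id %in% broadcast_meta$locality_id)) {
    by_loc <- split(broadcast_meta$plot_id, broadcast_meta$locality_id)
    pieces <- lapply(seq_len(nrow(df)), function(i) {
      id <- df$plot_id[i]
      if (id %in% names(by_loc)) {
        out <- df[rep(i, length(by_loc[[id]])), , drop = FALSE]
        out$plot_id <- by_loc[[id]]
        out
      } else df[i, , drop = FALSE]
    })
    df <- do.call(rbind, pieces)
    rownames(df) <- NULL
  }
  k <- paste(df$plot_id, df$year, df$month)
  if (anyDuplicated(k)) {
    stop_sporoscale("climate table has duplicated plot x year x month rows",
                    "sporoscale_schema_error")
  }
  df
}

#' Late-summer/early-autumn climate covariates
#'
#' Collapses monthly climate into the LSEA window: accumulated August to
#' October precipitation and the unweighted mean of the three monthly mean
#' temperatures, per plot and year. Missing months are an error — no
#' imputation is performed.
#'
#' @param monthly Monthly climate data frame (see
#'   \code{\link{read_climate_monthly}}).
#' @param years Integer vector of years to cover; default all years present.
#' @return Data frame with columns \code{plot_id}, \code{year},
#'   \code{lsea_precip_mm}, \code{lsea_tmean_c}.
#' @export
compute_lsea_climate <- function(monthly, years = NULL) {
  assert_cols(monthly, c("plot_id", "year", "month", "precip_mm", "tmean_c"),
              "climate table")
  years <- as.integer(years %||% sort(unique(monthly$year)))
  plots <- unique(monthly$plot_id)
  sub <- monthly[monthly$month %in% 8:10 & monthly$year %in% years, ]

  grid <- expand.grid(plot_id = plots, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  k_grid <- paste(grid$plot_id, grid$year)
  k_sub <- paste(sub$plot_id, sub$year)
  n_mo <- rowsum(rep(1L, nrow(sub)), k_sub)
  got <- as.vector(n_mo)[match(k_grid, rownames(n_mo))]
  got[is.na(got)] <- 0L
  if (any(got < 3L)) {
    bad <- which(got < 3L)[1L]
    have <- sort(sub$month[k_sub == k_grid[bad]])
    stop_sporoscale(
      sprintf(
        "LSEA months missing for plot %s, year %d: need months 8-10, have {%s}",
        grid$plot_id[bad], grid$year[bad], paste(have, collapse = ",")),
      "sporoscale_missing_month_error")
  }
  ps <- rowsum(sub$precip_mm, k_sub)
  tm <- rowsum(sub$tmean_c, k_sub) / 3
  grid$lsea_precip_mm <- as.vector(ps)[match(k_grid, rownames(ps))]
  grid$lsea_tmean_c <- as.vector(tm)[match(k_grid, rownames(tm))]
  grid[order(grid$plot_id, grid$year), ]
}

#' Write a result table to delimited text
#'
#' Writes any of the package's tabular results with a deterministic column
#' order and enough digits that reading the file back reproduces the values
#' to at least 12 significant digits.
#'
#' @param result Data frame (or an object with an \code{as.data.frame}
#'   method, e.g. a \code{varcomp} fit's component table).
#' @param path Output file path.
#' @param delim Field delimiter, default comma.
#' @return Invisibly, the data frame written.
#' @export
write_result_table <- function(result, path, delim = ",") {
  df <- as.data.frame(result)
  num <- vapply(df, function(v) is.double(v), logical(1))
  out <- df
  out[num] <- lapply(df[num], function(v) {
    ifelse(is.na(v), NA, format(v, digits = 15, scientific = TRUE,
                                trim = TRUE))
  })
  ok <- tryCatch({
    utils::write.table(out, path, sep = delim, row.names = FALSE,
                       quote = TRUE, qmethod = "double")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_sporoscale(sprintf("cannot write result table to '%s': %s",
                            path, conditionMessage(ok)),
                    "sporoscale_io_error")
  }
  invisible(df)
}

#' Read a YAML run configuration
#'
#' The run configuration maps input column names, guild aliases, delimiters,
#' the analyses to run and their options. See the packaged example
#' \code{system.file("extdata", "demo-config.yaml", package = "sporoscale")}.
#'
#' @param path Path to a YAML file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop_sporoscale(sprintf("config file not found: %s", path),
                    "sporoscale_io_error")
  }
  yaml::read_yaml(path)
}
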