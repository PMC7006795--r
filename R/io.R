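# CSV interchange. All tables are plain data frames; readers validate the
# schema and value constraints so that downstream code can assume clean input.

.plot_cols <- c("plot_id", "latitude", "longitude", "area_m2",
                "tree_layer_cover", "continent", "species_id", "cover",
                "woody", "alien_here")
.trait_cols <- c("species_id", "sla_cm2_g", "height_m", "seed_mass_mg",
                 "wood_density_g_cm3")
.climate_cols <- c("plot_id", "latitude", "year", "month", "tmean_c",
                   "prec_mm")

.check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}

#' Read a long-format vegetation-plot table
#'
#' One row per species record. Expected columns:
#' \code{plot_id, latitude, longitude, area_m2, tree_layer_cover, continent,
#' species_id, cover, woody, alien_here}. \code{cover} is percent canopy
#' cover in (0, 100]; \code{woody} and \code{alien_here} are logical (or 0/1);
#' \code{alien_here} flags whether the species is alien in the plot's region.
#'
#' @param file path to a CSV file, or a data frame already in this schema.
#' @return a validated data frame of species records.
#' @export
read_veg_plots <- function(file) {
  df <- if (is.data.frame(file)) file else read.csv(file, stringsAsFactors = FALSE)
  .check_cols(df, .plot_cols, "plot table")
  df$woody <- as.logical(df$woody)
  df$alien_here <- as.logical(df$alien_here)
  bad <- which(!is.finite(df$cover) | df$cover <= 0)
  if (length(bad))
    stop(sprintf("non-positive cover in plot table row(s): %s",
                 paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
  bad <- which(!is.finite(df$latitude) | abs(df$latitude) > 90)
  if (length(bad))
    stop(sprintf("invalid latitude in row(s): %s",
                 paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
  dup <- duplicated(df[, c("plot_id", "species_id")])
  if (any(dup)) {
    # a species recorded in several vegetation layers: pool its cover,
    # keeping the first record's flags (richness counts it once)
    agg <- aggregate(cover ~ plot_id + species_id, data = df, FUN = sum)
    df <- df[!dup, ]
    key <- paste(df$plot_id, df$species_id, sep = "\r")
    df$cover <- agg$cover[match(key, paste(agg$plot_id, agg$species_id, sep = "\r"))]
  }
  df
}

#' Read a species-level trait table
#'
#' Expected columns: \code{species_id, sla_cm2_g, height_m, seed_mass_mg,
#' wood_density_g_cm3}. All trait values must be strictly positive (they are
#' log-transformed downstream); \code{NA} marks a missing trait.
#'
#' @param file path to a CSV file, or a data frame already in this schema.
#' @return a validated data frame, one row per species.
#' @export
read_trait_table <- function(file) {
  df <- if (is.data.frame(file)) file else read.csv(file, stringsAsFactors = FALSE)
  .check_cols(df, .trait_cols, "trait table")
  if (anyDuplicated(df$species_id))
    stop("trait table has duplicated species_id", call. = FALSE)
  for (tc in .trait_cols[-1]) {
    bad <- which(!is.na(df[[tc]]) & df[[tc]] <= 0)
    if (length(bad))
      stop(sprintf("non-positive %s in trait table row(s): %s", tc,
                   paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read per-plot monthly climate series
#'
#' Expected columns: \code{plot_id, latitude, year, month, tmean_c, prec_mm}.
#' Months must be contiguous within a plot and precipitation non-negative.
#'
#' @param file path to a CSV file, or a data frame already in this schema.
#' @return a validated data frame ordered by plot, year, month.
#' @export
read_climate_series <- function(file) {
  df <- if (is.data.frame(file)) file else read.csv(file, stringsAsFactors = FALSE)
  .check_cols(df, .climate_cols, "climate table")
  if (any(df$prec_mm < 0, na.rm = TRUE))
    stop("negative precipitation in climate table", call. = FALSE)
  df <- df[order(df$plot_id, df$year, df$month), ]
  for (pid in unique(df$plot_id)) {
    sub <- df[df$plot_id == pid, ]
    idx <- sub$year * 12L + sub$month
    if (nrow(sub) > 1L && any(diff(idx) != 1L))
      stop(sprintf("climate series for plot %s has gaps", pid), call. = FALSE)
  }
  df
}
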