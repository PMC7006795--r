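# Plot selection and per-plot quantities. Vegetation data are long-format
# data frames (one row per species record, see read_veg_plots); plot-level
# attributes (area, tree-layer cover, continent, latitude) repeat on each
# record of a plot.

.plot_meta <- function(plots) {
  meta <- plots[!duplicated(plots$plot_id),
                c("plot_id", "latitude", "longitude", "area_m2",
                  "tree_layer_cover", "continent")]
  rownames(meta) <- NULL
  meta
}

#' Count distinct woody species in each plot
#'
#' Species recorded with positive cover and \code{woody = TRUE} count once
#' each, regardless of how many vegetation layers they were recorded in.
#'
#' @param plots long-format plot records (see \code{\link{read_veg_plots}}).
#' @return named integer vector of woody richness, one element per plot
#'   (plots with no woody record get 0).
#' @export
woody_richness <- function(plots) {
  ids <- unique(plots$plot_id)
  w <- plots[plots$woody & plots$cover > 0, c("plot_id", "species_id")]
  w <- w[!duplicated(w), ]
  n <- table(factor(w$plot_id, levels = ids))
  setNames(as.integer(n), ids)
}

#' Filter vegetation plots by forest cover, woody richness and area
#'
#' Retains plots that are forest (tree-layer cover at or above
#' \code{min_tree_cover} percent), contain at least \code{min_woody_richness}
#' woody species (a guard against plantations), and are at least
#' \code{min_area} m2. All thresholds are inclusive minima. Removals are
#' logged per rule: a plot failing several rules is logged once per rule
#' it fails.
#'
#' @param plots long-format plot records.
#' @param min_tree_cover minimum tree-layer cover, percent. Default 25.
#' @param min_woody_richness minimum number of woody species. Default 3.
#' @param min_area minimum plot area, m2. Default 100.
#' @return the retained records (original order), with attribute
#'   \code{"removal_log"}: a data frame \code{plot_id, rule} with one row per
#'   (removed plot, violated rule).
#' @export
filter_plots <- function(plots, min_tree_cover = 25, min_woody_richness = 3,
                         min_area = 100) {
  meta <- .plot_meta(plots)
  bad <- meta$plot_id[!is.finite(meta$area_m2) | !is.finite(meta$tree_layer_cover)]
  if (length(bad))
    stop(sprintf("plot(s) missing area or tree_layer_cover: %s",
                 paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
  rich <- woody_richness(plots)[meta$plot_id]
  fail_cover <- meta$tree_layer_cover < min_tree_cover
  fail_rich <- rich < min_woody_richness
  fail_area <- meta$area_m2 < min_area
  rule_rows <- function(fail, rule)
    data.frame(plot_id = meta$plot_id[fail], rule = rep(rule, sum(fail)))
  log <- rbind(rule_rows(fail_cover, "tree_layer_cover"),
               rule_rows(fail_rich, "woody_richness"),
               rule_rows(fail_area, "area"))
  rownames(log) <- NULL
  keep_ids <- meta$plot_id[!(fail_cover | fail_rich | fail_area)]
  out <- plots[plots$plot_id %in% keep_ids, ]
  rownames(out) <- NULL
  attr(out, "removal_log") <- log
  out
}

#' Exclude a focal species' alien plots that lie on its native continents
#'
#' When a species has alien-range plots on the same continent as its native
#' range, those alien plots are dropped so that native and alien ranges
#' compared downstream lie on disjoint continents.
#'
#' @param plots long-format plot records.
#' @param focal_species species identifier of the focal species.
#' @param native_continents character vector of the focal species' native
#'   continents.
#' @return the retained records, same schema and order.
#' @export
exclude_same_continent_aliens <- function(plots, focal_species,
                                          native_continents) {
  if (any(is.na(plots$continent)) || !all(nzchar(plots$continent)))
    stop("plot(s) with unknown continent", call. = FALSE)
  foc <- plots$species_id == focal_species & plots$alien_here
  drop_ids <- unique(plots$plot_id[foc & plots$continent %in% native_continents])
  out <- plots[!(plots$plot_id %in% drop_ids), ]
  rownames(out) <- NULL
  out
}

#' Relative abundance of a focal species in one plot
#'
#' The focal species' share of the total woody canopy cover: its cover divided
#' by the summed cover of all woody species in the plot. Non-woody species are
#' excluded from the denominator.
#'
#' @param plot records of a single plot (long format).
#' @param focal_species species identifier; must be present, woody, with
#'   positive cover.
#' @return a fraction in (0, 1].
#' @export
relative_abundance <- function(plot, focal_species) {
  if (length(unique(plot$plot_id)) > 1L)
    stop("relative_abundance expects records of a single plot", call. = FALSE)
  w <- plot[plot$woody & plot$cover > 0, ]
  i <- match(focal_species, w$species_id)
  if (is.na(i))
    stop(sprintf("focal species %s absent or non-woody in plot %s",
                 focal_species, plot$plot_id[1L]), call. = FALSE)
  w$cover[i] / sum(w$cover)
}

#' Select focal species with enough plots in both ranges
#'
#' A candidate focal species is retained when it occurs (with positive cover)
#' in at least \code{min_plots_per_range} plots where it is native and at
#' least as many where it is alien.
#'
#' @param plots long-format plot records (after filtering).
#' @param candidates character vector of candidate species identifiers, or a
#'   data frame with a \code{species_id} column (extra columns pass through).
#' @param min_plots_per_range minimum plots required in each range. Default 3.
#' @return the retained candidates (same type as given), with attribute
#'   \code{"range_counts"}: data frame \code{species_id, n_native, n_alien}
#'   for all candidates.
#' @export
select_focal_species <- function(plots, candidates, min_plots_per_range = 3) {
  ids <- if (is.data.frame(candidates)) candidates$species_id else candidates
  occ <- plots[plots$species_id %in% ids & plots$cover > 0, ]
  cnt <- function(flag) {
    sub <- occ[occ$alien_here == flag, ]
    tab <- table(factor(sub$species_id, levels = ids))
    as.integer(tab)
  }
  counts <- data.frame(species_id = ids, n_native = cnt(FALSE),
                       n_alien = cnt(TRUE))
  keep <- counts$n_native >= min_plots_per_range &
    counts$n_alien >= min_plots_per_range
  out <- if (is.data.frame(candidates)) candidates[keep, , drop = FALSE]
         else ids[keep]
  attr(out, "range_counts") <- counts
  out
}
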