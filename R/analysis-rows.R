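# Assembly of the analysis table: one row per focal species x plot, carrying
# the response (relative abundance) and every level-1 predictor.

#' Build the focal-species x plot analysis table
#'
#' For every focal species and every filtered plot in which it occurs as a
#' woody species with positive cover, computes: relative abundance, the
#' range label (native/alien from the plot's \code{alien_here} flag), the
#' community-weighted mean of co-occurring species' log traits, Gower and
#' Euclidean dissimilarity to that mean, the four competitive trait
#' differences, and woody richness. Optional per-plot covariates (human
#' influence index, mean 12-month SPEI) are joined by \code{plot_id}.
#'
#' Rows with no eligible co-occurring species (or whose co-occurring species
#' all lack traits) and focal species lacking any trait are dropped; the
#' drops are recorded in attribute \code{"dropped"} as
#' \code{focal_species, plot_id, reason}.
#'
#' @param plots filtered long-format plot records.
#' @param trait_table trait table.
#' @param focal_species character vector of focal species ids.
#' @param plot_covariates optional data frame \code{plot_id, hii, spei}.
#' @param ranges per-trait log-trait ranges; default computed over all
#'   species occurring in \code{plots} that have complete traits.
#' @return data frame with columns \code{focal_species, plot_id, range,
#'   rel_abund, dissim, dissim_euclidean, d_sla, d_height, d_sm, d_wd, hii,
#'   spei, richness} (covariates \code{NA} when not supplied).
#' @export
build_analysis_rows <- function(plots, trait_table, focal_species,
                                plot_covariates = NULL, ranges = NULL) {
  lt <- log_traits(trait_table)
  if (is.null(ranges)) {
    present <- intersect(unique(plots$species_id[plots$woody]), rownames(lt))
    present <- present[complete.cases(lt[present, , drop = FALSE])]
    ranges <- trait_ranges(trait_table, present)
  }
  rich <- woody_richness(plots)
  by_plot <- split(plots, plots$plot_id)
  rows <- list(); dropped <- list(); k <- 0L; kd <- 0L
  for (f in focal_species) {
    f_lt <- if (f %in% rownames(lt)) lt[f, ] else rep(NA_real_, 4L)
    if (anyNA(f_lt)) {
      kd <- kd + 1L
      dropped[[kd]] <- data.frame(focal_species = f, plot_id = NA,
                                  reason = "focal_traits_missing")
      next
    }
    occ <- plots[plots$species_id == f & plots$woody & plots$cover > 0, ]
    for (pid in occ$plot_id) {
      plot <- by_plot[[as.character(pid)]]
      rec <- plot[plot$species_id == f, ]
      range <- if (rec$alien_here[1L]) "alien" else "native"
      w <- community_weights(plot, f, range)
      cwm <- if (is.null(w)) NULL else cwm_log_traits(w, trait_table)
      if (is.null(cwm)) {
        kd <- kd + 1L
        dropped[[kd]] <- data.frame(focal_species = f, plot_id = pid,
                                    reason = "no_eligible_co_occurring")
        next
      }
      dd <- competitive_differences(f_lt, cwm)
      k <- k + 1L
      rows[[k]] <- data.frame(
        focal_species = f, plot_id = pid, range = range,
        rel_abund = relative_abundance(plot, f),
        dissim = gower_dissimilarity(f_lt, cwm, ranges),
        dissim_euclidean = euclidean_dissimilarity(f_lt, cwm, ranges),
        d_sla = dd[["d_sla"]], d_height = dd[["d_height"]],
        d_sm = dd[["d_sm"]], d_wd = dd[["d_wd"]],
        richness = as.integer(rich[[as.character(pid)]]))
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no analysis rows could be built", call. = FALSE)
  if (!is.null(plot_covariates)) {
    m <- match(out$plot_id, plot_covariates$plot_id)
    out$hii <- if ("hii" %in% names(plot_covariates)) plot_covariates$hii[m] else NA_real_
    out$spei <- if ("spei" %in% names(plot_covariates)) plot_covariates$spei[m] else NA_real_
  } else {
    out$hii <- NA_real_
    out$spei <- NA_real_
  }
  out <- out[, c("focal_species", "plot_id", "range", "rel_abund", "dissim",
                 "dissim_euclidean", "d_sla", "d_height", "d_sm", "d_wd",
                 "hii", "spei", "richness")]
  rownames(out) <- NULL
  attr(out, "dropped") <- if (kd) do.call(rbind, dropped) else
    data.frame(focal_species = character(), plot_id = character(),
               reason = character())
  attr(out, "trait_ranges") <- ranges
  out
}
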