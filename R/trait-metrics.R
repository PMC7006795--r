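# Community trait metrics. All metrics operate on natural-log trait values of
# the four focal traits: specific leaf area (sla, cm2/g), adult height
# (height, m), seed mass (sm, mg) and wood density (wd, g/cm3).

.trait_names <- c("sla", "height", "sm", "wd")

#' Log-trait matrix from a trait table
#'
#' @param trait_table data frame from \code{\link{read_trait_table}}.
#' @return numeric matrix (species x 4) of natural-log trait values, rownames
#'   are species ids, columns \code{sla, height, sm, wd}.
#' @export
log_traits <- function(trait_table) {
  m <- log(as.matrix(trait_table[, c("sla_cm2_g", "height_m", "seed_mass_mg",
                                     "wood_density_g_cm3")]))
  dimnames(m) <- list(trait_table$species_id, .trait_names)
  m
}

#' Per-trait ranges of log trait values
#'
#' Range (max minus min) of the natural-log trait values over a reference
#' species set, used to normalise the Gower dissimilarity. Computed once per
#' dataset over all species appearing in analysed plots, so dissimilarities
#' are comparable across plots.
#'
#' @param trait_table trait table.
#' @param species_subset optional character vector restricting the reference
#'   set (default: all species in the table).
#' @return named numeric 4-vector of ranges, all strictly positive.
#' @export
trait_ranges <- function(trait_table, species_subset = NULL) {
  lt <- log_traits(trait_table)
  if (!is.null(species_subset)) lt <- lt[rownames(lt) %in% species_subset, , drop = FALSE]
  if (nrow(lt) < 2L) stop("need at least two species to form trait ranges", call. = FALSE)
  r <- apply(lt, 2L, function(x) diff(range(x, na.rm = TRUE)))
  if (any(!is.finite(r) | r <= 0))
    stop(sprintf("degenerate trait range for: %s",
                 paste(.trait_names[!is.finite(r) | r <= 0], collapse = ", ")),
         call. = FALSE)
  r
}

#' Cover weights over a focal species' co-occurring woody species
#'
#' Weights are proportional to canopy cover over the eligible co-occurring
#' woody species and sum to 1. The focal species itself is excluded, as are
#' non-woody species. Alien species are excluded in native-range plots; in
#' alien-range plots all alien species other than the focal are excluded —
#' the community reference is always the native woody flora. Both angiosperms
#' and gymnosperms are retained (no taxonomic filtering).
#'
#' @param plot records of a single plot.
#' @param focal_species focal species identifier.
#' @param range_of_plot \code{"native"} or \code{"alien"}: the focal species'
#'   status in this plot.
#' @return named numeric vector of weights summing to 1, or \code{NULL} when
#'   no eligible co-occurring species remains (callers log and drop the row).
#' @export
community_weights <- function(plot, focal_species,
                              range_of_plot = c("native", "alien")) {
  range_of_plot <- match.arg(range_of_plot)
  co <- plot[plot$woody & plot$cover > 0 & plot$species_id != focal_species, ]
  co <- co[!co$alien_here, ]  # same rule in both ranges: non-focal aliens out
  if (nrow(co) == 0L) return(NULL)
  setNames(co$cover / sum(co$cover), co$species_id)
}

#' Abundance-weighted community mean of log traits
#'
#' Community-weighted mean (CWM): the weighted average of co-occurring
#' species' natural-log trait values. Species missing any trait are dropped
#' and the weights renormalised; the number dropped is recorded in attribute
#' \code{"n_dropped"}.
#'
#' @param weights named weight vector from \code{\link{community_weights}}.
#' @param trait_table trait table covering the weighted species.
#' @return named numeric 4-vector (CWM of ln sla, height, sm, wd) with
#'   attributes \code{"n_co_occurring"} and \code{"n_dropped"}, or \code{NULL}
#'   when every weighted species lacks a trait.
#' @export
cwm_log_traits <- function(weights, trait_table) {
  lt <- log_traits(trait_table)
  lt <- lt[match(names(weights), rownames(lt)), , drop = FALSE]
  ok <- complete.cases(lt)
  if (!any(ok)) return(NULL)
  w <- weights[ok] / sum(weights[ok])
  out <- as.vector(w %*% lt[ok, , drop = FALSE])
  names(out) <- .trait_names
  attr(out, "n_co_occurring") <- sum(ok)
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Range-normalised Gower dissimilarity between focal and community traits
#'
#' Mean over the four traits of the range-normalised absolute difference
#' between the focal species' log traits and the community-weighted mean:
#' \deqn{d = \frac{1}{4}\sum_t |f_t - c_t| / R_t.}
#' 0 means the focal species is functionally identical to its community; 1
#' means maximally distinct over the reference ranges. Values can only leave
#' [0, 1] if a CWM falls outside the global range, in which case the result is
#' clipped with a warning.
#'
#' @param focal_lntraits numeric 4-vector of the focal species' log traits.
#' @param cwm numeric 4-vector of community-weighted mean log traits.
#' @param ranges numeric 4-vector of positive per-trait ranges
#'   (\code{\link{trait_ranges}}).
#' @return dissimilarity in [0, 1].
#' @export
gower_dissimilarity <- function(focal_lntraits, cwm, ranges) {
  if (any(!is.finite(ranges) | ranges <= 0))
    stop("trait ranges must be positive", call. = FALSE)
  d <- mean(abs(focal_lntraits - cwm) / ranges)
  if (d > 1) {
    warning("Gower dissimilarity exceeded 1 (CWM outside global trait range); clipped")
    d <- 1
  }
  d
}

#' Euclidean analogue of the Gower dissimilarity
#'
#' \eqn{\sqrt{\sum_t ((f_t - c_t)/R_t)^2}} over the four traits. Used to check
#' the structural property that the Manhattan-based (Gower) and
#' Euclidean-based indices are strongly correlated across plots.
#'
#' @inheritParams gower_dissimilarity
#' @return non-negative dissimilarity.
#' @export
euclidean_dissimilarity <- function(focal_lntraits, cwm, ranges) {
  if (any(!is.finite(ranges) | ranges <= 0))
    stop("trait ranges must be positive", call. = FALSE)
  sqrt(sum(((focal_lntraits - cwm) / ranges)^2))
}

#' Competitive trait differences
#'
#' Focal log trait minus community-weighted mean log trait, per trait.
#' A positive value means the focal species exceeds its co-occurring
#' community on that trait (taller, denser wood, ...), i.e. is the more
#' competitive on the conventional reading of these traits.
#'
#' @inheritParams gower_dissimilarity
#' @return named numeric 4-vector \code{(d_sla, d_height, d_sm, d_wd)}.
#' @export
competitive_differences <- function(focal_lntraits, cwm) {
  setNames(as.numeric(focal_lntraits - cwm),
           paste0("d_", .trait_names))
}
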