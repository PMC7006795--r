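# Plot-level synthetic data: multi-species vegetation plots with covers,
# native/alien labels on two continents, log-normal traits and seasonal
# climate series, for end-to-end pipeline tests. The communities emulate the
# statistical structure the pipeline consumes (cover fractions, trait
# correlations under 0.4, forest plots that pass the selection filters by
# construction); they do not attempt realistic biogeography.

#' Configuration for the plot-level generator
#'
#' @param n_plots number of plots (split evenly over two continents).
#' @param n_species_pool woody species in the pool (split evenly over the
#'   continents as native ranges).
#' @param n_nonwoody non-woody (herb) species in the pool.
#' @param richness_mean woody richness per plot is
#'   \code{3 + Poisson(richness_mean)}.
#' @param alien_mix probability that a community slot is filled by a species
#'   native to the other continent (recorded as alien there).
#' @param dirichlet_conc concentration of the Dirichlet cover fractions.
#' @param trait_meanlog,trait_sdlog log-scale means and standard deviations
#'   of the four traits (sla cm2/g, height m, seed mass mg, wood density
#'   g/cm3).
#' @param trait_rho common pairwise correlation of log traits (kept under
#'   the 0.4 cap observed for these traits).
#' @param years length of each plot's monthly climate series.
#' @return list of class \code{"plot_gen_config"}.
#' @export
plot_gen_config <- function(n_plots = 240, n_species_pool = 60,
                            n_nonwoody = 10, richness_mean = 3,
                            alien_mix = 0.25, dirichlet_conc = 1,
                            trait_meanlog = log(c(sla = 120, height = 15,
                                                  sm = 50, wd = 0.55)),
                            trait_sdlog = c(0.5, 0.6, 1.2, 0.25),
                            trait_rho = 0.2, years = 30) {
  stopifnot(n_plots >= 2, n_species_pool >= 8, trait_rho >= 0,
            trait_rho < 0.4, alien_mix > 0, alien_mix < 1)
  structure(as.list(environment()), class = "plot_gen_config")
}

.rdirichlet <- function(k, conc) {
  g <- rgamma(k, conc, 1)
  g / sum(g)
}

#' Simulate vegetation plots, traits and climate series
#'
#' Generates a two-continent system: woody species with correlated
#' log-normal traits and a native continent each, forest plots whose
#' tree-layer cover, woody richness and area satisfy the selection filters
#' by construction, Dirichlet cover fractions, occasional non-woody records,
#' per-plot human-influence values, and seasonal monthly climate series
#' (sinusoidal temperature, gamma-distributed precipitation) driven by
#' latitude. Species placed on the continent where they are not native are
#' flagged \code{alien_here}. The first pool species is guaranteed at least
#' three native-range and three alien-range plots, so a focal set is always
#' non-empty.
#'
#' @param config a \code{\link{plot_gen_config}}.
#' @param seed integer seed; same seed, same output.
#' @return list of class \code{"plot_sim"}: \code{plots} (long-format
#'   records), \code{traits} (raw-scale trait table), \code{climate}
#'   (monthly series), \code{hii} (\code{plot_id, hii}), \code{config},
#'   \code{seed}.
#' @export
gen_plots <- function(config = plot_gen_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  cfg <- config
  conts <- c("ContA", "ContB")
  n_woody <- cfg$n_species_pool
  woody_ids <- sprintf("w%03d", seq_len(n_woody))
  herb_ids <- if (cfg$n_nonwoody > 0) sprintf("h%03d", seq_len(cfg$n_nonwoody))
              else character()
  native_cont <- setNames(rep(conts, length.out = n_woody), woody_ids)

  S <- matrix(cfg$trait_rho, 4L, 4L); diag(S) <- 1
  S <- S * tcrossprod(cfg$trait_sdlog)
  n_sp <- n_woody + cfg$n_nonwoody
  lt <- matrix(rnorm(n_sp * 4L), n_sp, 4L) %*% chol(S)
  lt <- sweep(lt, 2L, cfg$trait_meanlog, `+`)
  traits <- data.frame(species_id = c(woody_ids, herb_ids),
                       sla_cm2_g = exp(lt[, 1L]), height_m = exp(lt[, 2L]),
                       seed_mass_mg = exp(lt[, 3L]),
                       wood_density_g_cm3 = exp(lt[, 4L]))

  plot_ids <- sprintf("plot%04d", seq_len(cfg$n_plots))
  plot_cont <- rep(conts, length.out = cfg$n_plots)
  lat <- ifelse(plot_cont == "ContA", runif(cfg$n_plots, 35, 55),
                runif(cfg$n_plots, -45, -25))
  lon <- runif(cfg$n_plots, -180, 180)
  area <- 100 + rgamma(cfg$n_plots, shape = 2, scale = 150)
  tlc <- runif(cfg$n_plots, 30, 95)

  draw_members <- function(cont) {
    k <- 3L + rpois(1L, cfg$richness_mean)
    own <- woody_ids[native_cont == cont]
    oth <- woody_ids[native_cont != cont]
    alien <- runif(k) < cfg$alien_mix
    k_o <- min(sum(alien), length(oth)); k_n <- min(k - k_o, length(own))
    c(sample(own, k_n), sample(oth, k_o))
  }
  members <- lapply(plot_cont, draw_members)

  # guarantee the designated focal species has >= 3 plots in each range
  focal <- woody_ids[1L]
  for (cont in conts) {
    idx <- which(plot_cont == cont)
    has <- idx[vapply(members[idx], function(m) focal %in% m, logical(1L))]
    need <- 3L - length(has)
    if (need > 0L)
      for (i in sample(setdiff(idx, has), need))
        members[[i]] <- c(members[[i]], focal)
  }

  recs <- vector("list", cfg$n_plots)
  for (i in seq_len(cfg$n_plots)) {
    m <- unique(members[[i]])
    cov_w <- .rdirichlet(length(m), cfg$dirichlet_conc) * tlc[i]
    cov_w <- pmax(cov_w, 0.1)
    sp <- m; cov <- cov_w; woody <- rep(TRUE, length(m))
    if (length(herb_ids) && runif(1L) < 0.5) {
      h <- sample(herb_ids, 1L)
      sp <- c(sp, h); cov <- c(cov, runif(1L, 5, 60))
      woody <- c(woody, FALSE)
    }
    recs[[i]] <- data.frame(
      plot_id = plot_ids[i], latitude = lat[i], longitude = lon[i],
      area_m2 = area[i], tree_layer_cover = tlc[i],
      continent = plot_cont[i], species_id = sp, cover = cov, woody = woody,
      alien_here = unname(woody & native_cont[sp] != plot_cont[i] &
                            !is.na(native_cont[sp])))
  }
  plots <- do.call(rbind, recs)
  rownames(plots) <- NULL

  climate <- gen_climate_series(plot_ids, lat, years = cfg$years)
  hii <- data.frame(plot_id = plot_ids, hii = runif(cfg$n_plots, 0, 64))
  structure(list(plots = plots, traits = traits, climate = climate,
                 hii = hii, config = cfg, seed = seed),
            class = "plot_sim")
}

#' Seasonal monthly climate series
#'
#' Temperature follows a latitude-dependent sinusoid (warmer means and
#' smaller amplitude towards the equator, season phase flipped across
#' hemispheres) with normal noise; monthly precipitation is gamma
#' distributed around a weakly seasonal mean, modulated by a log-normal
#' year-level wetness factor. The interannual factor gives multi-month
#' water-balance sums the right skew real drought series show (wet years
#' lift whole twelve-month windows), which the log-logistic standardisation
#' assumes.
#'
#' @param plot_ids plot identifiers.
#' @param latitudes decimal latitudes, one per plot.
#' @param years series length in years (starting in year 1, month 1).
#' @param t_noise_sd,prec_shape noise parameters.
#' @param annual_wet_sdlog log-scale sd of the year-level wetness factor.
#' @return climate data frame in the \code{\link{read_climate_series}}
#'   schema.
#' @export
gen_climate_series <- function(plot_ids, latitudes, years = 30,
                               t_noise_sd = 0.8, prec_shape = 2,
                               annual_wet_sdlog = 0.35) {
  months <- seq_len(years * 12L)
  mon <- (months - 1L) %% 12L + 1L
  yr <- (months - 1L) %/% 12L + 1L
  out <- vector("list", length(plot_ids))
  for (i in seq_along(plot_ids)) {
    lat <- latitudes[i]
    base <- 26 - 0.4 * abs(lat)
    amp <- 3 + 0.25 * abs(lat)
    peak <- if (lat >= 0) 7 else 1
    tm <- base + amp * cos(2 * pi * (mon - peak) / 12) +
      rnorm(length(mon), 0, t_noise_sd)
    wet <- exp(rnorm(years, -annual_wet_sdlog^2 / 2, annual_wet_sdlog))
    pmean <- (70 + 25 * cos(2 * pi * (mon - peak) / 12)) * wet[yr]
    pr <- rgamma(length(mon), shape = prec_shape, scale = pmean / prec_shape)
    out[[i]] <- data.frame(plot_id = plot_ids[i], latitude = lat, year = yr,
                           month = mon, tmean_c = tm, prec_mm = pr)
  }
  do.call(rbind, out)
}
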