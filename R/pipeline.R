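# End-to-end orchestration: filter -> focal selection -> trait metrics ->
# SPEI -> hierarchical fit -> range comparison -> summaries, with a manifest
# tying every artifact to the configuration and seed.

#' Pipeline configuration
#'
#' Inputs may be file paths (CSV in the documented schemas) or data frames.
#'
#' @param plots vegetation-plot table (\code{\link{read_veg_plots}} schema).
#' @param traits trait table.
#' @param climate monthly climate table (optional; SPEI is skipped without).
#' @param hii data frame \code{plot_id, hii} (optional).
#' @param out_dir output directory (created if missing).
#' @param min_tree_cover,min_woody_richness,min_area plot filters.
#' @param min_plots_per_range focal-species threshold.
#' @param chains,iterations,burn_in MCMC protocol.
#' @param seed integer seed for the whole run.
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(plots, traits, climate = NULL, hii = NULL,
                            out_dir = tempfile("trabund_run_"),
                            min_tree_cover = 25, min_woody_richness = 3,
                            min_area = 100, min_plots_per_range = 3,
                            chains = 3, iterations = 10000, burn_in = 1000,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

.fingerprint <- function(df) {
  num <- vapply(df, is.numeric, logical(1L))
  list(rows = nrow(df), cols = names(df),
       checksum = if (any(num)) sum(vapply(df[num], function(x)
         sum(as.numeric(x), na.rm = TRUE), numeric(1L))) else 0)
}

#' Run the full abundance-analysis pipeline
#'
#' Executes, in order: input validation, plot filtering, focal-species
#' selection, exclusion of a focal species' same-continent alien plots,
#' per-plot SPEI (when climate data are supplied), analysis-row assembly,
#' standardisation and hierarchical model fitting, convergence/VIF
#' diagnostics, the native-vs-alien mixed-model comparison and per-species
#' contrasts. Writes CSV/JSON artifacts plus a manifest into
#' \code{config$out_dir}; a rerun with the same configuration and seed
#' reproduces them byte for byte.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return (invisibly) list with the fitted model (\code{fit}), analysis
#'   rows, range comparison, per-species contrasts, SPEI table and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  plots <- read_veg_plots(config$plots)
  traits <- read_trait_table(config$traits)
  manifest <- list(seed = config$seed,
                   inputs = list(plots = .fingerprint(plots),
                                 traits = .fingerprint(traits)))

  filtered <- filter_plots(plots, config$min_tree_cover,
                           config$min_woody_richness, config$min_area)
  write.csv(attr(filtered, "removal_log"), out("removal_log.csv"),
            row.names = FALSE)
  write.csv(filtered, out("plots_filtered.csv"), row.names = FALSE)
  manifest$stages <- list(
    input_plots = length(unique(plots$plot_id)),
    filtered_plots = length(unique(filtered$plot_id)))

  woody_sp <- unique(filtered$species_id[filtered$woody])
  focal <- select_focal_species(filtered, woody_sp,
                                config$min_plots_per_range)
  if (!length(focal)) stop("no focal species meets the plot thresholds",
                           call. = FALSE)
  # native continents per focal species, from its non-alien occurrences
  nat_cont <- lapply(setNames(focal, focal), function(f)
    unique(filtered$continent[filtered$species_id == f & !filtered$alien_here]))
  manifest$stages$focal_species <- length(focal)

  covars <- data.frame(plot_id = unique(filtered$plot_id))
  if (!is.null(config$hii)) {
    covars$hii <- config$hii$hii[match(covars$plot_id, config$hii$plot_id)]
  }
  spei_tab <- NULL
  if (!is.null(config$climate)) {
    climate <- read_climate_series(config$climate)
    spei_tab <- spei12(climate)
    write.csv(spei_tab, out("spei12.csv"), row.names = FALSE)
    ms <- mean_spei(spei_tab)
    covars$spei <- ms$spei[match(covars$plot_id, ms$plot_id)]
  }

  rows <- build_analysis_rows(filtered, traits, focal, covars)
  # same-continent alien exclusion, per focal species
  cont <- filtered$continent[match(rows$plot_id, filtered$plot_id)]
  keep <- !(rows$range == "alien" &
              mapply(function(f, cc) cc %in% nat_cont[[f]],
                     rows$focal_species, cont))
  rows <- rows[keep, ]
  write.csv(rows, out("analysis_rows.csv"), row.names = FALSE)
  manifest$stages$analysis_rows <- nrow(rows)

  # predictors without data (no climate table, no HII column) leave the model
  absent <- c("hii", "spei")[c(all(is.na(rows$hii)), all(is.na(rows$spei)))]
  spec <- hbm_spec(main_effects = setdiff(.main_effects, absent),
                   interactions = setdiff(.interacting, absent))
  manifest$stages$model_predictors <- spec$main_effects
  fit <- fit_abundance_hbm(rows, traits, spec = spec,
                           chains = config$chains,
                           iterations = config$iterations,
                           burn_in = config$burn_in, seed = config$seed)
  eff <- summarize_effects(fit, grep("^(gamma|delta|sigma)_",
                                     fit$param_names, value = TRUE))
  write.csv(eff, out("effect_summary.csv"), row.names = FALSE)
  diag <- list(psrf = as.list(fit$psrf$psrf), mpsrf = fit$psrf$mpsrf,
               vif = as.list(fit$vif), converged =
                 max(fit$psrf$psrf, fit$psrf$mpsrf, na.rm = TRUE) <= 1.01)
  jsonlite::write_json(diag, out("diagnostics.json"), auto_unbox = TRUE,
                       digits = NA)

  rc <- fit_range_lmm(rows)
  jsonlite::write_json(list(means = as.list(rc$means),
                            medians = as.list(rc$medians),
                            estimate = rc$estimate, chisq = rc$chisq,
                            p_value = rc$p_value),
                       out("range_comparison.json"), auto_unbox = TRUE,
                       digits = NA)
  contrasts <- per_species_contrasts(rows, seed = config$seed)
  write.csv(contrasts, out("species_contrasts.csv"), row.names = FALSE)

  manifest$outputs <- union(list.files(config$out_dir), "manifest.json")
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(fit = fit, rows = rows, range_comparison = rc,
                 contrasts = contrasts, spei = spei_tab,
                 manifest = manifest, out_dir = config$out_dir))
}

#' Composed effect report (native vs alien, and trait moderation)
#'
#' Recomposes the fitted posteriors into the two standard result tables:
#' per predictor, the across-species mean effect in the native range
#' (\eqn{\gamma_{k0}}) and in the alien range (\eqn{\gamma_{k0} + \delta_k}
#' where an interaction exists), and the trait-moderation coefficients
#' (\eqn{\gamma_{km}}) describing how species traits shift each
#' species-varying slope.
#'
#' @param fit a fitted \code{\link{fit_abundance_hbm}} object.
#' @return list of class \code{"hbm_report"}: \code{range_effects} and
#'   \code{trait_moderation} data frames (posterior medians and 95%
#'   credible intervals).
#' @export
report_effects <- function(fit) {
  spec <- fit$spec
  pooled <- do.call(rbind, fit$draws)
  q <- function(x) quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
  re <- lapply(spec$main_effects, function(k) {
    g <- pooled[, paste0("gamma_", k, ".1")]
    a <- if (k %in% spec$interactions) g + pooled[, paste0("delta_", k)] else g
    qn <- q(g); qa <- q(a)
    data.frame(predictor = k, native_median = qn[2L], native_lower = qn[1L],
               native_upper = qn[3L], alien_median = qa[2L],
               alien_lower = qa[1L], alien_upper = qa[3L])
  })
  tm <- summarize_effects(fit, grep("^gamma_(?!intercept).*\\.(?!1$)",
                                    fit$param_names, value = TRUE,
                                    perl = TRUE))
  tm$slope <- sub("^gamma_(.*)\\..*$", "\\1", tm$parameter)
  tm$trait <- sub("^gamma_.*\\.", "", tm$parameter)
  out <- list(range_effects = do.call(rbind, re), trait_moderation = tm)
  class(out) <- "hbm_report"
  out
}

#' @export
print.hbm_report <- function(x, ...) {
  cat("Across-species mean effects by range (median [95% CrI]):\n")
  r <- x$range_effects
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %-10s native %7.3f [%7.3f,%7.3f]  alien %7.3f [%7.3f,%7.3f]\n",
                r$predictor[i], r$native_median[i], r$native_lower[i],
                r$native_upper[i], r$alien_median[i], r$alien_lower[i],
                r$alien_upper[i]))
  cat("Trait moderation of species slopes (median [95% CrI], * excludes 0):\n")
  t <- x$trait_moderation
  for (i in seq_len(nrow(t)))
    cat(sprintf("  %-10s x %-7s %7.3f [%7.3f,%7.3f]%s\n", t$slope[i],
                t$trait[i], t$median[i], t$lower[i], t$upper[i],
                if (t$significant[i]) " *" else ""))
  invisible(x)
}
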