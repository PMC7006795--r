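# Model specification, variable standardisation and the joint log density of
# the two-level hierarchical abundance model.
#
# Level 1 (rows i, species j = j(i), plots p = p(i)):
#   y_i ~ N(alpha_j + sum_k beta_jk x_ik + sum_k' delta_k' x_ik' r_i + u_p,
#           sigma_eps^2)
# with y the (scaled) ln relative abundance, x the main-effect predictors
# (dissimilarity, four competitive differences, HII, SPEI, range indicator,
# woody richness) and x_k' r the range interactions (no richness x range).
# Level 2 (slopes-as-outcomes): each species-varying coefficient (intercept
# and every main-effect slope) is regressed on the species' own standardised
# log traits:
#   theta_jc ~ N(gamma_c0 + sum_m gamma_cm T_jm, sigma_c^2).
# Plot effects u_p ~ N(0, sigma_u^2). Priors: all location parameters
# N(0, 10^3); all standard deviations Uniform(0, 100).

.main_effects <- c("dissim", "d_sla", "d_height", "d_sm", "d_wd",
                   "hii", "spei", "range", "spr")
.interacting <- c("dissim", "d_sla", "d_height", "d_sm", "d_wd", "hii", "spei")
.l2_covs <- c("sla", "height", "sm", "wd")

#' Hierarchical abundance model specification
#'
#' Collects the model structure and MCMC protocol. Defaults follow the
#' standard protocol for this analysis: nine main effects with
#' species-varying coefficients, seven range interactions with global
#' coefficients (no richness-by-range interaction), four species traits as
#' level-2 predictors of every species-varying coefficient, normal(0, 1000)
#' priors on location parameters, uniform(0, 100) priors on standard
#' deviations, and 3 chains of 10,000 retained iterations after 1,000
#' burn-in, unthinned.
#'
#' @param main_effects names of level-1 main-effect predictors (all get
#'   species-varying slopes).
#' @param interactions subset of \code{main_effects} interacting with the
#'   range indicator (global coefficients).
#' @param level2_covariates names of species traits predicting the
#'   species-varying coefficients.
#' @param chains,iterations,burn_in MCMC protocol (retained iterations per
#'   chain after burn-in).
#' @param prior_location_variance prior variance of location parameters.
#' @param prior_sigma_upper upper bound of the uniform priors on standard
#'   deviations.
#' @return an object of class \code{"hbm_spec"}.
#' @export
hbm_spec <- function(main_effects = .main_effects,
                     interactions = .interacting,
                     level2_covariates = .l2_covs,
                     chains = 3, iterations = 10000, burn_in = 1000,
                     prior_location_variance = 1000,
                     prior_sigma_upper = 100) {
  stopifnot(all(interactions %in% main_effects), chains >= 1,
            iterations >= 1, burn_in >= 0,
            prior_location_variance > 0, prior_sigma_upper > 0)
  structure(list(main_effects = main_effects,
                 interactions = interactions,
                 level2_covariates = level2_covariates,
                 coefs = c("intercept", main_effects),
                 chains = chains, iterations = iterations, burn_in = burn_in,
                 prior_location_variance = prior_location_variance,
                 prior_sigma_upper = prior_sigma_upper),
            class = "hbm_spec")
}

#' Standardise model variables
#'
#' Centres and scales the named columns to mean 0, standard deviation 1
#' (denominator n-1), storing the centring parameters for back-transformation.
#' All model variables, including the 0/1 range indicator and, by default,
#' the ln response, are standardised; reported effects are therefore
#' standardised effect sizes.
#'
#' @param df data frame.
#' @param vars columns to standardise.
#' @return \code{df} with the columns replaced, plus attribute
#'   \code{"standardization"}: data frame \code{variable, center, scale}.
#' @export
standardize_cols <- function(df, vars) {
  if (nrow(df) < 2L) stop("need at least two rows to standardise", call. = FALSE)
  ctr <- scl <- numeric(length(vars))
  for (k in seq_along(vars)) {
    x <- df[[vars[k]]]
    if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", vars[k]), call. = FALSE)
    ctr[k] <- mean(x); scl[k] <- sd(x)
    if (!is.finite(scl[k]) || scl[k] == 0)
      stop(sprintf("zero-variance variable: %s", vars[k]), call. = FALSE)
    df[[vars[k]]] <- (x - ctr[k]) / scl[k]
  }
  attr(df, "standardization") <- data.frame(variable = vars, center = ctr,
                                            scale = scl)
  df
}

#' Invert a standardisation
#'
#' @param x standardised values.
#' @param params the \code{"standardization"} attribute from
#'   \code{\link{standardize_cols}}.
#' @param var variable name.
#' @return values on the original scale.
#' @export
unstandardize <- function(x, params, var) {
  i <- match(var, params$variable)
  if (is.na(i)) stop(sprintf("no standardization recorded for %s", var), call. = FALSE)
  x * params$scale[i] + params$center[i]
}

# Turn an analysis-row table into the model frame the sampler consumes:
# y = ln relative abundance, spr = woody richness, range = 0/1 indicator.
.model_frame <- function(rows) {
  if (!is.null(rows$y)) return(rows)
  stopifnot(all(rows$rel_abund > 0 & rows$rel_abund <= 1))
  rows$y <- log(rows$rel_abund)
  rows$spr <- as.numeric(rows$richness)
  rows$range <- as.numeric(rows$range == "alien")
  rows
}

# Species-trait design for level 2: a J x (1 + M) matrix [1, T_jm] with
# standardised (log, for raw tables) trait values, rows ordered as `species`.
.level2_design <- function(traits, species, l2_covs) {
  if (all(c("sla_cm2_g", "height_m") %in% names(traits))) {
    Tm <- log_traits(traits)
  } else {
    Tm <- as.matrix(traits[, .trait_names])
    rownames(Tm) <- traits$species_id
  }
  Tm <- Tm[match(species, rownames(Tm)), l2_covs, drop = FALSE]
  if (anyNA(Tm))
    stop("missing species traits for level-2 design", call. = FALSE)
  Tm <- scale(Tm)
  if (any(!is.finite(attr(Tm, "scaled:scale"))) ||
      any(attr(Tm, "scaled:scale") == 0))
    stop("zero-variance species trait in level-2 design", call. = FALSE)
  cbind(`1` = 1, Tm[, , drop = FALSE])
}

# Assemble the numeric arrays the sampler and the log density share.
.hbm_data <- function(rows, traits, spec, standardize = TRUE) {
  df <- .model_frame(rows)
  need <- c("y", spec$main_effects)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("analysis rows missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (standardize) df <- standardize_cols(df, need)
  sp_f <- factor(df$focal_species)
  pl_f <- factor(df$plot_id)
  W <- cbind(intercept = 1,
             as.matrix(df[, spec$main_effects, drop = FALSE]))
  Z <- as.matrix(df[, spec$interactions, drop = FALSE]) * df$range
  colnames(Z) <- spec$interactions
  list(y = df$y, W = W, Z = Z,
       sp = as.integer(sp_f), pl = as.integer(pl_f),
       species = levels(sp_f), plots = levels(pl_f),
       Ttil = .level2_design(traits, levels(sp_f), spec$level2_covariates),
       standardization = attr(df, "standardization"))
}

#' Joint log density of the hierarchical abundance model
#'
#' Sum of the level-1 normal likelihood, the level-2 normal regressions of
#' every species-varying coefficient on species traits, the plot-effect
#' normals, and the priors (normal with variance
#' \code{prior_location_variance} on all location parameters, uniform on
#' \code{(0, prior_sigma_upper)} on all standard deviations). Returns
#' \code{-Inf} when any standard deviation is outside its prior support.
#'
#' Used as the sampler's reference target in tests; the Gibbs sampler in
#' \code{\link{fit_abundance_hbm}} is derived from the same factorisation.
#'
#' @param params list with \code{gamma} ((1+M) x C matrix, level-2
#'   coefficients per species-varying coefficient c), \code{delta}
#'   (interaction coefficients), \code{theta} (J x C species coefficients),
#'   \code{u} (plot effects), \code{sigma_theta} (length C), \code{sigma_u},
#'   \code{sigma_eps}.
#' @param data list as built internally from rows and traits (elements
#'   \code{y, W, Z, sp, pl, Ttil}).
#' @param spec an \code{\link{hbm_spec}}.
#' @return the joint log density (a scalar).
#' @export
model_logdensity <- function(params, data, spec = hbm_spec()) {
  sd_ok <- function(s) all(is.finite(s) & s > 0 & s < spec$prior_sigma_upper)
  if (!sd_ok(params$sigma_theta) || !sd_ok(params$sigma_u) ||
      !sd_ok(params$sigma_eps)) return(-Inf)
  mu1 <- rowSums(data$W * params$theta[data$sp, , drop = FALSE]) +
    as.vector(data$Z %*% params$delta) + params$u[data$pl]
  ll <- sum(dnorm(data$y, mu1, params$sigma_eps, log = TRUE))
  Mu <- data$Ttil %*% params$gamma
  for (c in seq_len(ncol(params$theta)))
    ll <- ll + sum(dnorm(params$theta[, c], Mu[, c], params$sigma_theta[c],
                         log = TRUE))
  ll <- ll + sum(dnorm(params$u, 0, params$sigma_u, log = TRUE))
  psd <- sqrt(spec$prior_location_variance)
  ll <- ll + sum(dnorm(params$gamma, 0, psd, log = TRUE)) +
    sum(dnorm(params$delta, 0, psd, log = TRUE))
  nsd <- length(params$sigma_theta) + 2L
  ll - nsd * log(spec$prior_sigma_upper)
}
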