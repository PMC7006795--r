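# Design-level synthetic data: analysis-row tables simulated directly from
# the hierarchical model with known parameter values, the testbed for
# parameter-recovery and convergence checks.

#' Default generator truth
#'
#' The known parameter values used by \code{\link{gen_design}}. Signs follow
#' the qualitative structure the model is meant to detect: a negative
#' across-species effect of trait dissimilarity, positive effects of height
#' and wood-density differences, a positive seed-mass difference effect in
#' the native range weakened in the alien range (negative seed-mass
#' interaction), a negative richness effect, and positive trait moderation
#' of the SLA-difference slope by SLA and of the wood-density-difference
#' slope by wood density. Magnitudes are invented test defaults (flagged in
#' the \code{magnitudes} field), not estimates. The alien fraction defaults
#' to 0.068, the alien share of plots in the global tree dataset this
#' pipeline targets (15,584 of 228,943).
#'
#' @param n_species number of focal species. Default 40.
#' @param n_plots number of plots. Default 1250.
#' @param species_per_plot focal species drawn per plot (rows =
#'   \code{n_plots * species_per_plot}). Default 4.
#' @param alien_fraction probability a row is in the alien range.
#' @return object of class \code{"hbm_truth"}: \code{gamma} (level-2
#'   coefficient matrix, covariates x coefficients), \code{delta}
#'   (interactions), \code{sigma_theta}, \code{sigma_u}, \code{sigma_eps},
#'   sizes, and metadata.
#' @export
default_truth <- function(n_species = 40, n_plots = 1250,
                          species_per_plot = 4, alien_fraction = 0.068) {
  spec <- hbm_spec()
  covs <- c("1", spec$level2_covariates)
  gamma <- matrix(0, length(covs), length(spec$coefs),
                  dimnames = list(covs, spec$coefs))
  gamma["1", ] <- c(intercept = -2.0, dissim = -0.30, d_sla = 0.00,
                    d_height = 0.25, d_sm = 0.15, d_wd = 0.30, hii = 0.00,
                    spei = 0.10, range = -0.10, spr = -0.30)
  gamma["sla", "d_sla"] <- 0.15
  gamma["wd", "d_wd"] <- 0.15
  gamma["sm", "hii"] <- -0.10
  delta <- c(dissim = 0.05, d_sla = 0.00, d_height = 0.05, d_sm = -0.10,
             d_wd = 0.05, hii = 0.02, spei = 0.05)
  sigma_theta <- setNames(c(0.4, rep(0.15, length(spec$coefs) - 1L)),
                          spec$coefs)
  structure(list(gamma = gamma, delta = delta, sigma_theta = sigma_theta,
                 sigma_u = 0.3, sigma_eps = 0.7,
                 predictor_cor = 0.2,
                 alien_fraction = alien_fraction,
                 n_species = n_species, n_plots = n_plots,
                 species_per_plot = species_per_plot,
                 magnitudes = "invented default"),
            class = "hbm_truth")
}

#' Serialise / restore a generator truth
#'
#' @param truth an \code{"hbm_truth"} object.
#' @param path JSON file path.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  x$delta <- as.list(truth$delta)
  x$sigma_theta <- as.list(truth$sigma_theta)
  x$gamma <- list(values = as.vector(truth$gamma),
                  rows = rownames(truth$gamma),
                  cols = colnames(truth$gamma))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @return \code{read_truth}: the restored \code{"hbm_truth"} object.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- matrix(x$gamma$values, length(x$gamma$rows), length(x$gamma$cols),
              dimnames = list(x$gamma$rows, x$gamma$cols))
  structure(list(gamma = g, delta = unlist(x$delta),
                 sigma_theta = unlist(x$sigma_theta),
                 sigma_u = x$sigma_u, sigma_eps = x$sigma_eps,
                 predictor_cor = x$predictor_cor,
                 alien_fraction = x$alien_fraction,
                 n_species = x$n_species, n_plots = x$n_plots,
                 species_per_plot = x$species_per_plot,
                 magnitudes = x$magnitudes), class = "hbm_truth")
}

#' Simulate an analysis table from the hierarchical model
#'
#' Forward simulation at the design level: standardised species traits,
#' correlated standardised predictors (compound-symmetric correlation
#' \code{truth$predictor_cor} among the seven continuous predictors, well
#' under the 0.4 cap the trait set is built to respect), a standardised
#' Bernoulli range indicator, species coefficients drawn from the level-2
#' trait regressions, plot effects, and the response from level 1. All
#' predictor columns are empirically standardised, so the table is already
#' on the model scale (fit with \code{standardize = FALSE} to recover
#' \code{truth} on its own scale).
#'
#' @param truth a \code{\link{default_truth}} object.
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @return object of class \code{"abund_design"}: \code{rows} (model frame
#'   with \code{focal_species, plot_id, y} and the nine predictors),
#'   \code{traits} (standardised species trait table), \code{truth}, and
#'   \code{latent} (the drawn species coefficients \code{theta} and plot
#'   effects \code{u}).
#' @export
gen_design <- function(truth = default_truth(), seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  spec <- hbm_spec()
  J <- truth$n_species; P <- truth$n_plots; spp <- truth$species_per_plot
  stopifnot(spp <= J)
  n <- P * spp
  species <- sprintf("sp%03d", seq_len(J))
  plots <- sprintf("p%05d", seq_len(P))

  Tm <- scale(matrix(rnorm(J * 4L), J, 4L))
  dimnames(Tm) <- list(species, spec$level2_covariates)
  Ttil <- cbind(`1` = 1, Tm)

  sp <- as.vector(vapply(seq_len(P), function(p) sample.int(J, spp),
                         integer(spp)))
  pl <- rep(seq_len(P), each = spp)

  n_cont <- length(spec$interactions)
  S <- matrix(truth$predictor_cor, n_cont, n_cont); diag(S) <- 1
  X <- matrix(rnorm(n * n_cont), n, n_cont) %*% chol(S)
  spr <- rpois(n, 5) + 3
  range01 <- rbinom(n, 1L, truth$alien_fraction)
  if (length(unique(range01)) == 1L) range01[1L] <- 1L - range01[1L]
  Xall <- cbind(X, range01, spr)
  Xall <- scale(Xall)
  colnames(Xall) <- c(spec$interactions, "range", "spr")
  Xall <- Xall[, spec$main_effects, drop = FALSE]

  C <- length(spec$coefs)
  theta <- Ttil %*% truth$gamma +
    matrix(rnorm(J * C), J, C) * rep(truth$sigma_theta, each = J)
  u <- rnorm(P, 0, truth$sigma_u)
  W <- cbind(intercept = 1, Xall)
  Z <- Xall[, spec$interactions, drop = FALSE] * Xall[, "range"]
  y <- rowSums(W * theta[sp, , drop = FALSE]) + as.vector(Z %*% truth$delta) +
    u[pl] + rnorm(n, 0, truth$sigma_eps)

  rows <- data.frame(focal_species = species[sp], plot_id = plots[pl], y = y)
  rows <- cbind(rows, as.data.frame(Xall))
  traits <- data.frame(species_id = species, as.data.frame(unclass(Tm)))
  structure(list(rows = rows, traits = traits, truth = truth,
                 latent = list(theta = theta, u = setNames(u, plots)),
                 seed = seed),
            class = "abund_design")
}

#' Flat named vector of a truth's level-2 and interaction parameters
#'
#' Names match the sampler's stored parameter names
#' (\code{gamma_<coef>.<cov>}, \code{delta_<predictor>}), for coverage and
#' sign-recovery checks.
#'
#' @param truth an \code{"hbm_truth"} object.
#' @return named numeric vector.
#' @export
truth_params <- function(truth) {
  g <- truth$gamma
  nm <- as.vector(outer(rownames(g), colnames(g),
                        function(m, c) paste0("gamma_", c, ".", m)))
  setNames(c(as.vector(g), truth$delta),
           c(nm, paste0("delta_", names(truth$delta))))
}
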