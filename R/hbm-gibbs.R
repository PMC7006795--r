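# Blocked Gibbs sampler for the hierarchical abundance model. Every full
# conditional is conjugate under the normal/uniform prior structure:
# multivariate normal blocks for the species coefficient vectors, the
# interaction coefficients and the level-2 regressions; independent normals
# for the plot effects; truncated inverse-gamma draws (on the variance) for
# the uniform-prior standard deviations.

# Draw from N(A^-1 b, A^-1) given precision A and linear term b.
.rmvn_prec <- function(A, b) {
  R <- chol(A)
  mu <- backsolve(R, backsolve(R, b, transpose = TRUE))
  as.vector(mu + backsolve(R, rnorm(length(b))))
}

# sigma^2 | SS, n under a Uniform(0, upper) prior on sigma: the precision
# phi = 1/sigma^2 has a Gamma((n-1)/2, SS/2) conditional truncated to
# phi > upper^-2.
.draw_sigma2 <- function(ss, n, upper) {
  shape <- (n - 1) / 2
  rate <- max(ss, 1e-300) / 2
  if (shape <= 0) return(runif(1, 0, upper)^2)
  lo <- pgamma(upper^-2, shape, rate)
  u <- runif(1, lo, 1)
  phi <- qgamma(min(max(u, 1e-300), 1 - 1e-16), shape, rate)
  1 / phi
}

.gibbs_chain <- function(d, spec, iterations, burn_in,
                         store_species, store_plot) {
  y <- d$y; W <- d$W; Z <- d$Z; sp <- d$sp; pl <- d$pl; Ttil <- d$Ttil
  N <- length(y); C <- ncol(W); K <- ncol(Z)
  J <- nrow(Ttil); M1 <- ncol(Ttil); P <- max(pl)
  psd2 <- spec$prior_location_variance
  up <- spec$prior_sigma_upper
  rows_j <- split(seq_len(N), sp)
  W_j <- lapply(rows_j, function(ix) W[ix, , drop = FALSE])
  WtW_j <- lapply(W_j, crossprod)
  ZtZ <- crossprod(Z)
  TtT <- crossprod(Ttil)
  n_p <- tabulate(pl, P)
  Ik <- diag(K); Im <- diag(M1)

  # overdispersed chain-specific start
  theta <- matrix(rnorm(J * C, 0, 0.5), J, C)
  gamma <- matrix(rnorm(M1 * C, 0, 0.5), M1, C)
  delta <- rnorm(K, 0, 0.5)
  u <- rnorm(P, 0, 0.5)
  s2_theta <- runif(C, 0.25, 2)
  s2_u <- runif(1, 0.25, 2)
  s2_eps <- runif(1, 0.25, 2)

  nstore <- C * M1 + K + C + 2L +
    (if (store_species) J * C else 0L) + (if (store_plot) P else 0L)
  draws <- matrix(NA_real_, iterations, nstore)
  theta_sum <- matrix(0, J, C); u_sum <- numeric(P)

  fit_sp <- rowSums(W * theta[sp, , drop = FALSE])
  zd <- as.vector(Z %*% delta)

  for (it in seq_len(burn_in + iterations)) {
    # interaction coefficients delta | .
    r <- y - fit_sp - u[pl]
    A <- ZtZ / s2_eps + Ik / psd2
    delta <- .rmvn_prec(A, crossprod(Z, r) / s2_eps)
    zd <- as.vector(Z %*% delta)

    # plot effects u | .
    r <- y - fit_sp - zd
    s_p <- rowsum(r, pl)  # pl is 1..P so rows come back ordered
    prec <- n_p / s2_eps + 1 / s2_u
    u <- rnorm(P, (s_p / s2_eps) / prec, sqrt(1 / prec))

    # species coefficient vectors theta_j | .
    Mu <- Ttil %*% gamma
    Dprec <- 1 / s2_theta
    r <- y - zd - u[pl]
    for (j in seq_len(J)) {
      bj <- crossprod(W_j[[j]], r[rows_j[[j]]]) / s2_eps + Dprec * Mu[j, ]
      A <- WtW_j[[j]] / s2_eps
      diag(A) <- diag(A) + Dprec
      theta[j, ] <- .rmvn_prec(A, bj)
    }
    fit_sp <- rowSums(W * theta[sp, , drop = FALSE])

    # level-2 regressions gamma_c | . and variances sigma_c^2 | .
    for (c in seq_len(C)) {
      A <- TtT / s2_theta[c] + Im / psd2
      gamma[, c] <- .rmvn_prec(A, crossprod(Ttil, theta[, c]) / s2_theta[c])
    }
    Mu <- Ttil %*% gamma
    ss_c <- colSums((theta - Mu)^2)
    for (c in seq_len(C)) s2_theta[c] <- .draw_sigma2(ss_c[c], J, up)

    # variance components
    s2_u <- .draw_sigma2(sum(u^2), P, up)
    e <- y - fit_sp - zd - u[pl]
    s2_eps <- .draw_sigma2(sum(e * e), N, up)

    if (it > burn_in) {
      v <- c(as.vector(gamma), delta,
             sqrt(c(s2_theta, s2_u, s2_eps)))
      if (store_species) v <- c(v, as.vector(theta))
      if (store_plot) v <- c(v, u)
      draws[it - burn_in, ] <- v
      theta_sum <- theta_sum + theta
      u_sum <- u_sum + u
    }
  }
  list(draws = draws, theta_mean = theta_sum / iterations,
       u_mean = u_sum / iterations)
}

.param_names <- function(spec, d, store_species, store_plot) {
  C <- length(spec$coefs); covs <- c("1", spec$level2_covariates)
  nm <- c(as.vector(outer(covs, spec$coefs,
                          function(m, c) paste0("gamma_", c, ".", m))),
          paste0("delta_", spec$interactions),
          paste0("sigma_", spec$coefs), "sigma_plot", "sigma_resid")
  if (store_species)
    nm <- c(nm, as.vector(outer(d$species, spec$coefs,
                                function(s, c) paste0("theta_", s, ".", c))))
  if (store_plot) nm <- c(nm, paste0("u_", d$plots))
  nm
}

#' Fit the hierarchical Bayesian abundance model
#'
#' Fits the two-level model described in \code{\link{model_logdensity}} by a
#' blocked Gibbs sampler: species-varying intercepts and slopes for every
#' main effect, species traits as level-2 predictors of each of those
#' coefficients, global range-interaction coefficients, plot random effects,
#' normal(0, 1000) priors on locations and uniform(0, 100) priors on
#' standard deviations. By default all variables (response included) are
#' standardised first, so coefficients are standardised effect sizes.
#'
#' @param rows analysis-row table (\code{\link{build_analysis_rows}} output
#'   with \code{rel_abund}/\code{richness}/\code{range}, or a model frame
#'   with a \code{y} column as produced by \code{\link{gen_design}}).
#' @param traits species trait table covering every focal species (raw
#'   scale, or already log-scale columns \code{sla, height, sm, wd}).
#' @param spec model specification from \code{\link{hbm_spec}}; its
#'   \code{chains}/\code{iterations}/\code{burn_in} can be overridden here.
#' @param chains,iterations,burn_in MCMC protocol overrides.
#' @param seed integer seed making the whole run reproducible.
#' @param standardize standardise response and predictors first
#'   (default TRUE; set FALSE for data already on the model scale).
#' @param store_species,store_plot also store per-iteration species
#'   coefficients / plot effects (memory-heavy at scale; posterior means are
#'   always available).
#' @return object of class \code{"abund_hbm"}: chains of posterior draws for
#'   the level-2 coefficients (\code{gamma_<coef>.<trait>}, with \code{.1}
#'   the across-species mean), interaction coefficients
#'   (\code{delta_<predictor>}), standard deviations, plus posterior-mean
#'   species coefficients and plot effects, convergence diagnostics and
#'   variance-inflation factors.
#' @seealso \code{\link{summary.abund_hbm}}, \code{\link{gelman_rubin}},
#'   \code{\link{summarize_effects}}
#' @export
fit_abundance_hbm <- function(rows, traits, spec = hbm_spec(),
                              chains = spec$chains,
                              iterations = spec$iterations,
                              burn_in = spec$burn_in,
                              seed = NULL, standardize = TRUE,
                              store_species = FALSE, store_plot = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  if (!is.null(seed)) set.seed(as.integer(seed))
  d <- .hbm_data(rows, traits, spec, standardize)
  nm <- .param_names(spec, d, store_species, store_plot)
  res <- lapply(seq_len(chains), function(ch)
    .gibbs_chain(d, spec, iterations, burn_in, store_species, store_plot))
  draw_list <- lapply(res, function(r) {
    colnames(r$draws) <- nm
    r$draws
  })
  C <- length(spec$coefs)
  theta_mean <- Reduce(`+`, lapply(res, `[[`, "theta_mean")) / chains
  u_mean <- Reduce(`+`, lapply(res, `[[`, "u_mean")) / chains
  dimnames(theta_mean) <- list(d$species, spec$coefs)
  fit <- structure(list(
    draws = draw_list, param_names = nm, spec = spec,
    chains = chains, iterations = iterations, burn_in = burn_in,
    seed = seed,
    species = d$species, plots = d$plots,
    theta_mean = theta_mean, u_mean = setNames(u_mean, d$plots),
    data = d, standardization = d$standardization,
    n_obs = length(d$y),
    elapsed = NA_real_), class = "abund_hbm")
  core <- grep("^(gamma|delta)_", nm, value = TRUE)
  fit$psrf <- if (chains >= 2) gelman_rubin(fit, pars = core) else NULL
  fit$vif <- vif(cbind(d$W[, -1L, drop = FALSE], d$Z))
  fit$elapsed <- proc.time()[["elapsed"]] - t0
  fit
}
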