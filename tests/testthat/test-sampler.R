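# Posterior correctness of the blocked Gibbs sampler, checked against an
# independent MCMC engine (JAGS) targeting the same joint density, plus
# determinism and invariance properties.

test_that("Gibbs posterior agrees with an independent JAGS fit of the same model", {
  skip_if_not_installed("rjags")
  set.seed(61)
  des <- gen_design(default_truth(n_species = 8, n_plots = 80,
                                  species_per_plot = 3), seed = 62)
  fit <- fit_abundance_hbm(des$rows, des$traits, chains = 2,
                           iterations = 2500, burn_in = 500, seed = 63,
                           standardize = FALSE)
  spec <- fit$spec
  d <- fit$data
  jm <- "model {
    for (i in 1:N) {
      mu[i] <- inprod(W[i,], theta[sp[i],]) + inprod(Z[i,], delta) + u[pl[i]]
      y[i] ~ dnorm(mu[i], tau_eps)
    }
    for (j in 1:J) { for (c in 1:C) {
      theta[j,c] ~ dnorm(inprod(Ttil[j,], gam[,c]), tau_th[c])
    } }
    for (p in 1:P) { u[p] ~ dnorm(0, tau_u) }
    for (m in 1:M1) { for (c in 1:C) { gam[m,c] ~ dnorm(0, 0.001) } }
    for (k in 1:K) { delta[k] ~ dnorm(0, 0.001) }
    for (c in 1:C) { sig_th[c] ~ dunif(0, 100); tau_th[c] <- pow(sig_th[c], -2) }
    sig_u ~ dunif(0, 100); tau_u <- pow(sig_u, -2)
    sig_e ~ dunif(0, 100); tau_eps <- pow(sig_e, -2)
  }"
  dat <- list(y = d$y, W = d$W, Z = d$Z, sp = d$sp, pl = d$pl,
              Ttil = d$Ttil, N = length(d$y), J = nrow(d$Ttil),
              C = ncol(d$W), P = max(d$pl), M1 = ncol(d$Ttil),
              K = ncol(d$Z))
  m <- rjags::jags.model(textConnection(jm), data = dat, n.chains = 2,
                         inits = list(.RNG.name = "base::Mersenne-Twister",
                                      .RNG.seed = 64),
                         quiet = TRUE)
  update(m, 1000, progress.bar = "none")
  s <- rjags::jags.samples(m, c("gam", "delta", "sig_e"), 2500,
                           progress.bar = "none")
  jags_gamma <- apply(s$gam, c(1, 2), mean)       # M1 x C means
  jags_delta <- apply(s$delta, 1, mean)
  covs <- c("1", spec$level2_covariates)
  my <- colMeans(do.call(rbind, fit$draws))
  my_gamma <- matrix(my[as.vector(outer(covs, spec$coefs, function(m, c)
    paste0("gamma_", c, ".", m)))], length(covs), length(spec$coefs))
  my_delta <- my[paste0("delta_", spec$interactions)]
  pooled <- do.call(rbind, fit$draws)
  sd_gamma <- matrix(apply(pooled[, as.vector(outer(covs, spec$coefs,
    function(m, c) paste0("gamma_", c, ".", m)))], 2, sd),
    length(covs), length(spec$coefs))
  # agreement within a conservative Monte-Carlo margin: 0.25 posterior sds
  expect_lt(max(abs(my_gamma - jags_gamma) / pmax(sd_gamma, 0.02)), 0.25)
  expect_lt(max(abs(my_delta - jags_delta)), 0.05)
  expect_equal(mean(pooled[, "sigma_resid"]), mean(s$sig_e),
               tolerance = 0.05)
})

test_that("fits are reproducible under a seed and MC error shrinks with length", {
  des <- gen_design(default_truth(n_species = 6, n_plots = 50,
                                  species_per_plot = 3), seed = 71)
  f1 <- fit_abundance_hbm(des$rows, des$traits, chains = 2, iterations = 400,
                          burn_in = 100, seed = 72, standardize = FALSE)
  f2 <- fit_abundance_hbm(des$rows, des$traits, chains = 2, iterations = 400,
                          burn_in = 100, seed = 72, standardize = FALSE)
  expect_identical(f1$draws, f2$draws)
  # square-root law: block means of length L vary ~2x more than length 2L
  f3 <- fit_abundance_hbm(des$rows, des$traits, chains = 1,
                          iterations = 4096, burn_in = 200, seed = 73,
                          standardize = FALSE)
  x <- f3$draws[[1]][, "gamma_dissim.1"]
  bm <- function(L) {
    blocks <- matrix(x, nrow = L)
    var(colMeans(blocks))
  }
  ratio <- bm(64) / bm(128)
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 3.2)
})

test_that("permuting species labels permutes species posteriors but not gamma", {
  set.seed(81)
  des <- gen_design(default_truth(n_species = 15, n_plots = 100,
                                  species_per_plot = 4), seed = 82)
  rows <- des$rows; traits <- des$traits
  # relabel species by a fixed random permutation everywhere
  old <- sort(unique(rows$focal_species))
  perm <- setNames(paste0("sp_", sample(LETTERS, length(old))), old)
  rows2 <- rows; rows2$focal_species <- unname(perm[rows$focal_species])
  traits2 <- traits; traits2$species_id <- unname(perm[traits$species_id])
  f1 <- fit_abundance_hbm(rows, traits, chains = 2, iterations = 2000,
                          burn_in = 500, seed = 83, standardize = FALSE,
                          store_species = TRUE)
  f2 <- fit_abundance_hbm(rows2, traits2, chains = 2, iterations = 2000,
                          burn_in = 500, seed = 83, standardize = FALSE,
                          store_species = TRUE)
  g <- grep("^(gamma|delta)_", f1$param_names, value = TRUE)
  p1 <- do.call(rbind, f1$draws); p2 <- do.call(rbind, f2$draws)
  # gamma/delta posteriors unchanged to Monte-Carlo error, measured in
  # posterior-sd units
  dev <- abs(colMeans(p1)[g] - colMeans(p2)[g]) /
    pmax(apply(p1[, g], 2, sd), 0.02)
  expect_lt(max(dev), 0.35)
  # species-level posterior means follow their labels
  i1 <- colMeans(p1)[paste0("theta_", old, ".intercept")]
  i2 <- colMeans(p2)[paste0("theta_", perm[old], ".intercept")]
  expect_lt(max(abs(unname(i1) - unname(i2))), 0.1)
})
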