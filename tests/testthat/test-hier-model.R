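test_that("standardisation is exact, reversible, and rejects constants", {
  df <- data.frame(a = rnorm(50, 5, 3), b = runif(50), c = 1)
  s <- standardize_cols(df, c("a", "b"))
  for (v in c("a", "b")) {
    expect_lt(abs(mean(s[[v]])), 1e-12)
    expect_lt(abs(sd(s[[v]]) - 1), 1e-12)
  }
  pars <- attr(s, "standardization")
  expect_equal(unstandardize(s$a, pars, "a"), df$a, tolerance = 1e-12)
  expect_error(standardize_cols(df, "c"), "zero-variance.*c")
  expect_error(standardize_cols(df[1, ], "a"), "two rows")
})

test_that("model log density equals a hand-coded sum of normal densities", {
  # toy: 3 rows, 2 species, 1 main-effect predictor, 1 level-2 trait,
  # 1 interaction, 2 plots
  spec <- hbm_spec(main_effects = "dissim", interactions = "dissim",
                   level2_covariates = "sla")
  rows <- data.frame(focal_species = c("s1", "s1", "s2"),
                     plot_id = c("p1", "p2", "p1"),
                     y = c(-1.2, -0.5, -2.0),
                     dissim = c(0.3, -0.2, 0.9),
                     range = c(-0.5, 1.8, -0.5))
  traits <- data.frame(species_id = c("s1", "s2"), sla = c(-1, 1),
                       height = c(1, -1), sm = c(-1, 1), wd = c(1, -1))
  d <- trabund:::.hbm_data(rows, traits, spec, standardize = FALSE)
  params <- list(gamma = matrix(c(-1.5, 0.2, -0.3, 0.1), 2, 2),
                 delta = 0.25, theta = matrix(c(-1, -2, 0.1, -0.4), 2, 2),
                 u = c(0.2, -0.1), sigma_theta = c(0.5, 0.3),
                 sigma_u = 0.4, sigma_eps = 0.7)
  got <- model_logdensity(params, d, spec)

  # oracle: fully written out, term by term
  tj <- c(-1, 1)  # standardised sla for s1, s2 (sd over 2 species is 1... )
  tj <- (tj - mean(tj)) / sd(tj)
  z <- rows$dissim * rows$range
  mu <- c(params$theta[1, 1] + params$theta[1, 2] * rows$dissim[1] +
            params$delta * z[1] + params$u[1],
          params$theta[1, 1] + params$theta[1, 2] * rows$dissim[2] +
            params$delta * z[2] + params$u[2],
          params$theta[2, 1] + params$theta[2, 2] * rows$dissim[3] +
            params$delta * z[3] + params$u[1])
  want <- sum(dnorm(rows$y, mu, 0.7, log = TRUE)) +
    sum(dnorm(params$theta[, 1], params$gamma[1, 1] + params$gamma[2, 1] * tj,
              0.5, log = TRUE)) +
    sum(dnorm(params$theta[, 2], params$gamma[1, 2] + params$gamma[2, 2] * tj,
              0.3, log = TRUE)) +
    sum(dnorm(params$u, 0, 0.4, log = TRUE)) +
    sum(dnorm(c(params$gamma, params$delta), 0, sqrt(1000), log = TRUE)) -
    4 * log(100)
  expect_equal(got, want, tolerance = 1e-8)

  # density decreases as an observation moves away from its mean
  far <- d; far$y[1] <- far$y[1] + 5
  expect_lt(model_logdensity(params, far, spec), got)
  # sigma outside the uniform prior support is impossible
  bad <- params; bad$sigma_eps <- 101
  expect_identical(model_logdensity(bad, d, spec), -Inf)
  bad$sigma_eps <- -0.1
  expect_identical(model_logdensity(bad, d, spec), -Inf)
})

test_that("model log density is finite at interior points of a random fixture", {
  set.seed(21)
  des <- gen_design(default_truth(n_species = 5, n_plots = 10,
                                  species_per_plot = 2), seed = 22)
  spec <- hbm_spec()
  d <- trabund:::.hbm_data(des$rows, des$traits, spec, standardize = FALSE)
  params <- list(gamma = matrix(rnorm(50), 5, 10), delta = rnorm(7),
                 theta = matrix(rnorm(50), 5, 10), u = rnorm(10),
                 sigma_theta = runif(10, 0.1, 2), sigma_u = 0.5,
                 sigma_eps = 0.8)
  expect_true(is.finite(model_logdensity(params, d, spec)))
})

test_that("VIF matches a brute-force regression oracle", {
  set.seed(31)
  n <- 400
  # exactly uncorrelated columns: successive centred regression residuals
  q1 <- scale(rnorm(n), scale = FALSE)
  q2 <- resid(lm(rnorm(n) ~ q1))
  q3 <- resid(lm(rnorm(n) ~ q1 + q2))
  Q <- cbind(q1 = as.numeric(q1), q2 = q2, q3 = q3)
  expect_equal(unname(vif(Q)), rep(1, 3), tolerance = 1e-10)
  # known structure: x2 built from x1 with correlation ~0.6
  x1 <- rnorm(n); x2 <- 0.6 * x1 + sqrt(1 - 0.36) * rnorm(n); x3 <- rnorm(n)
  X <- cbind(x1 = x1, x2 = x2, x3 = x3)
  got <- vif(X)
  for (k in 1:3) {
    r2 <- summary(lm(X[, k] ~ X[, -k]))$r.squared
    expect_equal(unname(got[k]), 1 / (1 - r2), tolerance = 1e-10)
  }
  expect_error(vif(cbind(x1 = x1, dup = x1)), "rank deficient")
})

test_that("PSRF separates mixed from unmixed chains and honours its closed form", {
  set.seed(41)
  n <- 10000
  same <- lapply(1:3, function(i) matrix(rnorm(n), ncol = 1,
                                         dimnames = list(NULL, "x")))
  gr <- gelman_rubin(same)
  expect_lt(gr$psrf[["x"]], 1.01)
  expect_lt(gr$mpsrf, 1.01)
  apart <- list(matrix(rnorm(n, 0), ncol = 1),
                matrix(rnorm(n, 10), ncol = 1))
  expect_gt(gelman_rubin(apart)$psrf[[1]], 1.1)
  # duplicated chain: B = 0, so R-hat = sqrt((n-1)/n) exactly
  one <- matrix(rnorm(500), ncol = 1)
  dup <- gelman_rubin(list(one, one))
  expect_equal(unname(dup$psrf[1]), sqrt(499 / 500), tolerance = 1e-12)
  expect_error(gelman_rubin(list(one)), "2 chains")
})

test_that("effect summaries match a sorting-based quantile oracle", {
  set.seed(51)
  x <- matrix(rnorm(3000), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  x[, "c"] <- 4  # constant draws give a degenerate interval
  s <- summarize_effects(list(x))
  oracle_q <- function(v, p) {  # linear interpolation of order statistics
    v <- sort(v); h <- (length(v) - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    v[lo] + (h - lo) * (v[hi] - v[lo])
  }
  for (par in c("a", "b")) {
    i <- which(s$parameter == par)
    expect_equal(s$median[i], oracle_q(x[, par], 0.5), tolerance = 1e-12)
    expect_equal(s$lower[i], oracle_q(x[, par], 0.025), tolerance = 1e-12)
    expect_equal(s$upper[i], oracle_q(x[, par], 0.975), tolerance = 1e-12)
  }
  i <- which(s$parameter == "c")
  expect_equal(c(s$median[i], s$lower[i], s$upper[i]), c(4, 4, 4))
  expect_true(s$significant[i])
  # symmetric draws straddle zero and are not flagged
  i <- which(s$parameter == "a")
  expect_lt(abs(s$median[i]), 0.1)
  expect_false(s$significant[i])
})
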