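# Diagnostics and S3 methods for fitted hierarchical abundance models.

# Coerce draws into a list of iteration x parameter chain matrices.
.chain_list <- function(x, pars = NULL) {
  ch <- if (inherits(x, "abund_hbm")) x$draws
        else if (is.list(x)) x
        else if (is.array(x) && length(dim(x)) == 3L)
          lapply(seq_len(dim(x)[1L]), function(i) x[i, , , drop = TRUE])
        else stop("cannot interpret draws", call. = FALSE)
  ch <- lapply(ch, as.matrix)
  if (!is.null(pars)) ch <- lapply(ch, function(m) m[, pars, drop = FALSE])
  ch
}

#' Gelman-Rubin convergence diagnostics
#'
#' Univariate potential scale reduction factor per parameter,
#' \deqn{\hat R = \sqrt{((n-1)/n \; W + B/n)/W},}
#' with W the mean within-chain variance and B/n the variance of the chain
#' means, and the multivariate version
#' \eqn{\sqrt{(n-1)/n + \lambda_{max}(W^{-1}B)/n}} from the largest
#' eigenvalue of the within/between covariance ratio. Values near 1 indicate
#' the chains have mixed; identical duplicated chains give exactly
#' \eqn{\sqrt{(n-1)/n}}.
#'
#' @param x a fitted \code{\link{fit_abundance_hbm}} object, a list of
#'   iteration-by-parameter chain matrices, or a (chain, iteration,
#'   parameter) array. At least 2 chains.
#' @param pars optional parameter names to restrict to.
#' @return list with \code{psrf} (named vector) and \code{mpsrf} (scalar;
#'   \code{NA} when the within-chain covariance is singular).
#' @export
gelman_rubin <- function(x, pars = NULL) {
  ch <- .chain_list(x, pars)
  m <- length(ch)
  if (m < 2L) stop("Gelman-Rubin diagnostics need at least 2 chains", call. = FALSE)
  n <- nrow(ch[[1L]])
  means <- do.call(rbind, lapply(ch, colMeans))
  Wd <- Reduce(`+`, lapply(ch, function(x) apply(x, 2L, var))) / m
  Bn <- apply(means, 2L, var)                  # B/n
  psrf <- sqrt(((n - 1) / n * Wd + Bn) / Wd)
  names(psrf) <- colnames(ch[[1L]])
  mpsrf <- NA_real_
  Wm <- Reduce(`+`, lapply(ch, function(x) cov(x))) / m
  Bm <- cov(means) * n                         # B
  ev <- try(suppressWarnings(
    max(Re(eigen(solve(Wm, Bm), only.values = TRUE)$values))), silent = TRUE)
  if (!inherits(ev, "try-error") && is.finite(ev))
    mpsrf <- sqrt((n - 1) / n + max(ev, 0) / n)
  list(psrf = psrf, mpsrf = mpsrf)
}

#' Variance inflation factors
#'
#' \eqn{VIF_k = 1/(1 - R^2_k)} where \eqn{R^2_k} comes from regressing
#' predictor k (with intercept) on all the others; computed via the inverse
#' of the predictor correlation matrix. Values below about 4 are the
#' conventional all-clear for collinearity.
#'
#' @param X numeric matrix or data frame of predictors (columns named).
#' @return named vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) return(setNames(rep(1, ncol(X)), colnames(X)))
  R <- cor(X)
  Rinv <- tryCatch(solve(R), error = function(e)
    stop("design is rank deficient (perfectly collinear predictors)",
         call. = FALSE))
  setNames(diag(Rinv), colnames(X))
}

#' Posterior effect summaries
#'
#' Posterior median and central 95% credible interval per parameter, pooled
#' over chains, with a reporting flag for intervals excluding zero.
#'
#' @param x fitted model, chain list or draws array (see
#'   \code{\link{gelman_rubin}}).
#' @param pars optional parameter subset.
#' @param prob interval mass. Default 0.95.
#' @return data frame \code{parameter, median, lower, upper, significant}.
#' @export
summarize_effects <- function(x, pars = NULL, prob = 0.95) {
  ch <- .chain_list(x, pars)
  pooled <- do.call(rbind, ch)
  a <- (1 - prob) / 2
  q <- t(apply(pooled, 2L, quantile, probs = c(a, 0.5, 1 - a), names = FALSE))
  out <- data.frame(parameter = colnames(pooled), median = q[, 2L],
                    lower = q[, 1L], upper = q[, 3L])
  out$significant <- out$lower > 0 | out$upper < 0
  rownames(out) <- NULL
  out
}

#' @export
print.abund_hbm <- function(x, ...) {
  cat("Hierarchical Bayesian abundance model (blocked Gibbs)\n")
  cat(sprintf("  %d rows, %d species, %d plots\n",
              x$n_obs, length(x$species), length(x$plots)))
  cat(sprintf("  %d chains x %d iterations (burn-in %d)\n",
              x$chains, x$iterations, x$burn_in))
  if (!is.null(x$psrf)) {
    mx <- max(x$psrf$psrf, na.rm = TRUE)
    cat(sprintf("  max univariate PSRF %.4f, multivariate PSRF %.4f%s\n",
                mx, x$psrf$mpsrf,
                if (max(mx, x$psrf$mpsrf) <= 1.01) " (converged)" else
                  " (NOT converged at the 1.01 threshold)"))
  }
  cat(sprintf("  max VIF %.2f\n", max(x$vif)))
  cat("Across-species mean effects (posterior median [95% CrI]):\n")
  s <- summarize_effects(x, pars = grep("^gamma_.*\\.1$", x$param_names,
                                        value = TRUE))
  s$parameter <- sub("^gamma_(.*)\\.1$", "\\1", s$parameter)
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-10s %8.3f [%7.3f, %7.3f]%s\n", s$parameter[i],
                s$median[i], s$lower[i], s$upper[i],
                if (s$significant[i]) " *" else ""))
  invisible(x)
}

#' Summarise a fitted abundance model
#'
#' @param object fitted model.
#' @param ... unused.
#' @return list of class \code{"summary.abund_hbm"} with effect tables for
#'   the across-species means, trait moderation of each slope, range
#'   interactions and variance components, plus diagnostics and an
#'   approximate Bayesian R-squared
#'   (\eqn{1 - E[\sigma_\varepsilon^2]/\mathrm{var}(y)}, conditional on the
#'   species and plot effects).
#' @export
summary.abund_hbm <- function(object, ...) {
  nm <- object$param_names
  eff <- summarize_effects(object, grep("^gamma_.*\\.1$", nm, value = TRUE))
  mod <- summarize_effects(object, grep("^gamma_.*\\.(?!1$)", nm,
                                        value = TRUE, perl = TRUE))
  del <- summarize_effects(object, grep("^delta_", nm, value = TRUE))
  sig <- summarize_effects(object, grep("^sigma_", nm, value = TRUE))
  s2e <- mean(do.call(rbind, .chain_list(object, "sigma_resid"))^2)
  out <- list(mean_effects = eff, trait_moderation = mod,
              interactions = del, sds = sig,
              r2 = 1 - s2e / var(object$data$y),
              psrf = object$psrf, vif = object$vif,
              chains = object$chains, iterations = object$iterations)
  class(out) <- "summary.abund_hbm"
  out
}

#' @export
print.summary.abund_hbm <- function(x, ...) {
  pr <- function(tab, title) {
    cat(title, "\n")
    print(format(tab, digits = 3), row.names = FALSE)
  }
  pr(x$mean_effects, "Across-species mean effects:")
  pr(x$interactions, "Range interactions (alien minus native shift):")
  pr(x$trait_moderation, "Trait moderation of species slopes:")
  pr(x$sds, "Standard deviations:")
  cat(sprintf("Approximate Bayesian R2: %.3f\n", x$r2))
  if (!is.null(x$psrf))
    cat(sprintf("Max PSRF %.4f (multivariate %.4f); max VIF %.2f\n",
                max(x$psrf$psrf, na.rm = TRUE), x$psrf$mpsrf, max(x$vif)))
  invisible(x)
}

#' @export
coef.abund_hbm <- function(object, ...) {
  s <- summarize_effects(object,
                         grep("^(gamma|delta)_", object$param_names,
                              value = TRUE))
  setNames(s$median, s$parameter)
}

#' @export
fitted.abund_hbm <- function(object, ...) {
  d <- object$data
  delta <- coef(object)[paste0("delta_", object$spec$interactions)]
  rowSums(d$W * object$theta_mean[d$sp, , drop = FALSE]) +
    as.vector(d$Z %*% delta) + object$u_mean[d$pl]
}

#' @export
residuals.abund_hbm <- function(object, ...) {
  object$data$y - fitted(object)
}

#' Dot-and-interval plot of standardised effects
#'
#' Posterior medians with 95% credible intervals for the across-species mean
#' effect of each predictor in the native range and its alien-range
#' counterpart (mean plus the range interaction), in the style of the usual
#' forest-plot presentation of this model.
#'
#' @param x fitted model.
#' @param ... passed to \code{plot}.
#' @export
plot.abund_hbm <- function(x, ...) {
  comp <- report_effects(x)$range_effects
  k <- nrow(comp)
  ys <- rev(seq_len(k))
  rng <- range(comp$native_lower, comp$native_upper,
               comp$alien_lower, comp$alien_upper, 0)
  graphics::plot(NA, xlim = rng, ylim = c(0.5, k + 0.5), yaxt = "n",
                 xlab = "standardised effect on ln relative abundance",
                 ylab = "", ...)
  graphics::axis(2, at = ys, labels = comp$predictor, las = 1)
  graphics::abline(v = 0, lty = 3)
  graphics::segments(comp$native_lower, ys + 0.12, comp$native_upper, ys + 0.12)
  graphics::points(comp$native_median, ys + 0.12, pch = 16)
  graphics::segments(comp$alien_lower, ys - 0.12, comp$alien_upper, ys - 0.12,
                     col = 2)
  graphics::points(comp$alien_median, ys - 0.12, pch = 17, col = 2)
  graphics::legend("topright", pch = c(16, 17), col = c(1, 2),
                   legend = c("native", "alien"), bty = "n")
  invisible(x)
}
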