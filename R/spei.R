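# 12-month standardised precipitation-evapotranspiration index (SPEI).
# Pipeline: Thornthwaite PET from monthly temperature and latitude ->
# k-month rolling water balance (P - PET) -> per-calendar-month
# three-parameter log-logistic fit by unbiased probability-weighted moments
# -> normal quantile transform of the fitted CDF. Positive SPEI = humid,
# negative = dry, relative to the plot's own calibration period.

.days_in_month <- c(31, 28.25, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
.mid_month_day <- cumsum(.days_in_month) - .days_in_month / 2

#' Monthly Thornthwaite potential evapotranspiration
#'
#' Standard Thornthwaite method. The annual heat index is computed from the
#' series' per-calendar-month mean temperatures,
#' \eqn{I = \sum_m (T_m/5)^{1.514}} over months with positive mean; the
#' exponent is \eqn{a = 6.75\times10^{-7} I^3 - 7.71\times10^{-5} I^2 +
#' 1.792\times10^{-2} I + 0.49239}; monthly PET is
#' \eqn{16 K_m (10 T_m / I)^a} mm for \eqn{T_m > 0} and 0 otherwise, where
#' \eqn{K_m} corrects for day length (from mid-month solar declination and
#' latitude) and days in the month. PET depends only on temperature and
#' latitude, never on precipitation.
#'
#' @param series climate records of a single plot: data frame with columns
#'   \code{latitude, year, month, tmean_c} (contiguous months).
#' @return numeric vector of PET (mm/month) aligned with the rows of
#'   \code{series}; all zero (with a warning) when every monthly normal is
#'   at or below 0 degrees C.
#' @export
thornthwaite_pet <- function(series) {
  lat <- series$latitude[1L]
  if (!is.finite(lat) || abs(lat) > 90) stop("invalid latitude", call. = FALSE)
  tm <- series$tmean_c
  normals <- tapply(tm, factor(series$month, levels = 1:12), mean)
  normals[is.na(normals)] <- 0
  I <- sum(pmax(normals, 0)^1.514 / 5^1.514)
  if (I <= 0) {
    warning("all monthly temperature normals <= 0 degrees C; PET set to 0")
    return(rep(0, nrow(series)))
  }
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  m <- series$month
  decl <- 0.4093 * sin(2 * pi * .mid_month_day[m] / 365 - 1.405)
  h <- -tan(lat * pi / 180) * tan(decl)
  h <- pmin(pmax(h, -1), 1)
  daylen <- 24 / pi * acos(h)
  K <- (daylen / 12) * (.days_in_month[m] / 30)
  pet <- ifelse(tm > 0, 16 * K * (10 * tm / I)^a, 0)
  as.numeric(pet)
}

#' Rolling k-month water balance
#'
#' \eqn{X_m = \sum_{i=0}^{k-1} (P_{m-i} - PET_{m-i})}: the climatic water
#' balance summed over the month and the k-1 preceding months. The first
#' k-1 months carry no value.
#'
#' @param prec numeric vector of monthly precipitation (mm), contiguous.
#' @param pet numeric vector of monthly PET (mm), same length.
#' @param scale window length in months. Default 12.
#' @return numeric vector of length \code{length(prec) - scale + 1}, aligned
#'   to months \code{scale, ..., n}.
#' @export
water_balance <- function(prec, pet, scale = 12) {
  if (length(prec) != length(pet)) stop("prec and pet differ in length", call. = FALSE)
  n <- length(prec)
  if (n < scale) stop(sprintf("need at least %d months", scale), call. = FALSE)
  if (anyNA(prec) || anyNA(pet)) stop("water balance input has gaps", call. = FALSE)
  d <- prec - pet
  cs <- cumsum(c(0, d))
  cs[(scale + 1):(n + 1)] - cs[1:(n - scale + 1)]
}

#' Fit a three-parameter log-logistic distribution by probability-weighted moments
#'
#' Unbiased sample probability-weighted moments with decreasing weights,
#' \eqn{a_s = E[X(1-F(X))^s]}, give the shape
#' \eqn{\beta = (2a_1 - a_0)/(6a_1 - a_0 - 6a_2)}, scale
#' \eqn{\alpha = (a_0 - 2a_1)\beta / (\Gamma(1+1/\beta)\Gamma(1-1/\beta))}
#' and origin \eqn{\gamma = a_0 - \alpha\Gamma(1+1/\beta)\Gamma(1-1/\beta)}.
#' This is the standard parameter estimator in SPEI construction.
#'
#' When the sample's third L-moment is non-positive (left skew, outside the
#' family's support) the distribution is fitted to the negated sample and
#' the result flagged \code{reflected}; \code{\link{spei_from_balance}}
#' undoes the reflection so the standardised index keeps its orientation.
#'
#' @param x numeric vector of (water-balance) values.
#' @return list with elements \code{shape} (\eqn{\beta}), \code{scale}
#'   (\eqn{\alpha}), \code{origin} (\eqn{\gamma}) and \code{reflected}.
#' @export
fit_loglogistic_pwm <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4L) stop("need at least 4 values to fit a log-logistic", call. = FALSE)
  if (n < 10L) warning("fewer than 10 values; log-logistic fit will be unstable")
  if (diff(range(x)) == 0) stop("degenerate (constant) sample", call. = FALSE)
  pwm_fit <- function(x) {
    xs <- sort(x)
    i <- seq_along(xs)
    a0 <- mean(xs)
    a1 <- sum((n - i) / (n - 1) * xs) / n
    a2 <- sum((n - i) * (n - i - 1) / ((n - 1) * (n - 2)) * xs) / n
    l2 <- a0 - 2 * a1          # second L-moment
    l3 <- a0 - 6 * a1 + 6 * a2 # third L-moment
    list(a0 = a0, l2 = l2, l3 = l3)
  }
  m <- pwm_fit(x)
  if (!is.finite(m$l2) || m$l2 <= 0)
    stop("degenerate sample (non-positive L-scale)", call. = FALSE)
  # the log-logistic covers positive L-skew only; a left-skewed sample is
  # fitted through its mirror image and flagged, so the CDF stays valid
  reflected <- m$l3 <= 0
  if (reflected) m <- pwm_fit(-x)
  beta <- m$l2 / m$l3
  if (!is.finite(beta) || beta <= 1)
    stop("log-logistic PWM fit failed (shape <= 1)", call. = FALSE)
  g <- gamma(1 + 1 / beta) * gamma(1 - 1 / beta)
  alpha <- m$l2 * beta / g
  if (!is.finite(alpha) || alpha <= 0)
    stop("log-logistic PWM fit failed (non-positive scale)", call. = FALSE)
  list(shape = beta, scale = alpha, origin = m$a0 - alpha * g,
       reflected = reflected)
}

#' Rational approximation to the standard normal quantile
#'
#' Abramowitz-Stegun style approximation used in standard SPEI
#' implementations; maximum absolute error about 4.5e-4 against the exact
#' quantile.
#'
#' @param p probabilities in (0, 1).
#' @return approximate \eqn{\Phi^{-1}(p)}.
#' @export
normal_quantile_approx <- function(p) {
  stopifnot(all(p > 0 & p < 1))
  lower <- p <= 0.5
  pp <- ifelse(lower, p, 1 - p)
  w <- sqrt(-2 * log(pp))
  num <- 2.515517 + 0.802853 * w + 0.010328 * w^2
  den <- 1 + 1.432788 * w + 0.189269 * w^2 + 0.001308 * w^3
  z <- w - num / den
  ifelse(lower, -z, z)
}

#' Standardise water-balance values through a fitted log-logistic
#'
#' \eqn{SPEI = \Phi^{-1}(F(X))} with F the fitted log-logistic CDF
#' \eqn{F(x) = [1 + (\alpha/(x-\gamma))^{\beta}]^{-1}}. Values at or below
#' the fitted origin (where F is 0) are clamped to \code{-clamp} with a
#' warning; all outputs are clamped to \code{[-clamp, clamp]}. For a
#' \code{reflected} fit (left-skewed calibration sample) the transform is
#' applied on the mirrored scale and negated, preserving orientation
#' (wetter is always larger).
#'
#' @param x water-balance values.
#' @param params fit from \code{\link{fit_loglogistic_pwm}}.
#' @param clamp extreme value bound. Default 3.
#' @return standardised values, monotone increasing in \code{x}.
#' @export
spei_from_balance <- function(x, params, clamp = 3) {
  refl <- isTRUE(params$reflected)
  v <- if (refl) -x else x
  z <- rep(-clamp, length(v))
  above <- v > params$origin
  if (any(!above))
    warning(sprintf("%d value(s) beyond the fitted origin; clamped to %g",
                    sum(!above), if (refl) clamp else -clamp))
  if (any(above)) {
    Fx <- 1 / (1 + (params$scale / (v[above] - params$origin))^params$shape)
    Fx <- pmin(pmax(Fx, 1e-12), 1 - 1e-12)
    z[above] <- normal_quantile_approx(Fx)
  }
  if (refl) z <- -z
  pmin(pmax(z, -clamp), clamp)
}

#' 12-month SPEI series per plot
#'
#' Full construction for one or many plots: Thornthwaite PET, rolling
#' \code{scale}-month water balance, separate log-logistic fits per calendar
#' month (of the window's final month) over the whole supplied series (the
#' calibration period), then the normal-quantile transform.
#'
#' @param climate climate table (\code{\link{read_climate_series}} schema),
#'   one or more plots.
#' @param scale window length in months. Default 12.
#' @param clamp extreme value bound passed to
#'   \code{\link{spei_from_balance}}.
#' @return data frame \code{plot_id, year, month, spei} covering months from
#'   the \code{scale}-th onward per plot.
#' @export
spei12 <- function(climate, scale = 12, clamp = 3) {
  out <- lapply(split(climate, climate$plot_id), function(sub) {
    sub <- sub[order(sub$year, sub$month), ]
    pet <- thornthwaite_pet(sub)
    wb <- water_balance(sub$prec_mm, pet, scale)
    idx <- seq.int(scale, nrow(sub))
    mon <- sub$month[idx]
    z <- rep(NA_real_, length(wb))
    for (m in unique(mon)) {
      sel <- mon == m
      pars <- fit_loglogistic_pwm(wb[sel])
      z[sel] <- spei_from_balance(wb[sel], pars, clamp)
    }
    data.frame(plot_id = sub$plot_id[idx], year = sub$year[idx],
               month = mon, spei = z)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Mean SPEI per plot
#'
#' Temporal average of the monthly SPEI series, the per-plot climate
#' covariate used in the abundance model.
#'
#' @param spei_table output of \code{\link{spei12}}.
#' @return data frame \code{plot_id, spei}.
#' @export
mean_spei <- function(spei_table) {
  agg <- aggregate(spei ~ plot_id, data = spei_table, FUN = mean)
  agg[order(agg$plot_id), , drop = FALSE]
}

#' Species' optimal SPEI and local dissimilarity to it
#'
#' The optimum is the mean SPEI over the plots where the species occurs in
#' its native range; the dissimilarity of a plot is the absolute difference
#' between its local SPEI and that optimum.
#'
#' @param spei per-row local SPEI values.
#' @param range per-row range labels (\code{"native"}/\code{"alien"}).
#' @return the optimal SPEI (scalar mean over native rows).
#' @export
optimal_spei <- function(spei, range) {
  nat <- spei[range == "native"]
  if (!length(nat)) stop("no native-range rows to define an optimal SPEI", call. = FALSE)
  mean(nat)
}

#' @rdname optimal_spei
#' @param local local SPEI value(s).
#' @param optimum the species' optimal SPEI.
#' @return \code{spei_dissimilarity}: absolute difference.
#' @export
spei_dissimilarity <- function(local, optimum) abs(local - optimum)
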