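# Fixed-period cosinor fitting and the circular statistics run on the
# resulting acrophases: Watson-Williams multi-sample test, paired circular
# correlation, model-free time-of-day peaks, and day-of-week analysis.
#
# Orientation convention: for the latency parameters (TS, US, ALS) values are
# negated before fitting, so the acrophase always means "time of best
# performance" (fastest processing). Angles are carried in radians and
# reported in clock hours or days.

#' Fixed-period cosinor fit
#'
#' Least-squares fit of `x(t) = M + beta*cos(wt) + gamma*sin(wt)` with
#' `w = 2*pi/period`. Amplitude `A = sqrt(beta^2 + gamma^2)`; acrophase is
#' the local clock time of the fitted maximum, in `[0, period)`. The
#' zero-amplitude p-value is the F-test of `beta = gamma = 0` on
#' (2, n - 3) degrees of freedom.
#'
#' @param series A [binned_series].
#' @param period_h Fixed period in hours (default 24).
#' @param orientation `"amplitude"` (peak = largest value; usage, activity,
#'   lux) or `"latency"` (values negated so the peak marks the fastest
#'   performance). Defaults to `"latency"` for TS/US/ALS, else
#'   `"amplitude"`.
#' @return List of class `cosinor_fit`: `parameter`, `period_h`, `mesor`,
#'   `amplitude`, `acrophase_h`, `p_zero_amplitude`, `n_obs`, `orientation`.
#' @export
fit_cosinor <- function(series, period_h = 24, orientation = NULL) {
  stopifnot(inherits(series, "binned_series"))
  parameter <- attr(series, "parameter")
  if (is.null(orientation)) {
    orientation <- if (parameter %in% LATENCY_PARAMETERS) "latency"
                   else "amplitude"
  }
  orientation <- match.arg(orientation, c("amplitude", "latency"))
  ok <- !is.na(series$value)
  n <- sum(ok)
  if (n < 4) stop("cosinor fit needs at least 4 non-missing bins")
  t_h <- (series$t_start[ok] + (attr(series, "utc_offset") %||% 0)) / 3600
  if (diff(range(t_h)) <= period_h)
    stop("cosinor fit needs data spanning more than one period")
  x <- series$value[ok]
  if (orientation == "latency") x <- -x
  w <- 2 * pi / period_h
  C <- cos(w * t_h); S <- sin(w * t_h)
  fit <- stats::lm(x ~ C + S)
  beta <- stats::coef(fit)[["C"]]; gam <- stats::coef(fit)[["S"]]
  A <- sqrt(beta^2 + gam^2)
  acro <- (atan2(gam, beta) / w) %% period_h
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((x - mean(x))^2)
  if (sst <= 0) {
    p <- 1; A <- 0; acro <- NA_real_
  } else if (ssr <= .Machine$double.eps * sst) {
    p <- 0
  } else {
    F <- ((sst - ssr) / 2) / (ssr / (n - 3))
    p <- stats::pf(F, 2, n - 3, lower.tail = FALSE)
  }
  structure(list(parameter = parameter, period_h = period_h,
                 mesor = unname(stats::coef(fit)[1]) *
                   (if (orientation == "latency") -1 else 1),
                 amplitude = A, acrophase_h = acro,
                 p_zero_amplitude = p, n_obs = n,
                 orientation = orientation,
                 subject_id = attr(series, "subject_id")),
            class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "<cosinor_fit> '%s' subject '%s' (period %g h, %s orientation)\n",
    x$parameter, x$subject_id, x$period_h, x$orientation))
  cat(sprintf("  mesor %.4g  amplitude %.4g  acrophase %.2f h  p(A=0) %.3g  n %d\n",
              x$mesor, x$amplitude, x$acrophase_h, x$p_zero_amplitude,
              x$n_obs))
  invisible(x)
}

#' Collect significant acrophases into a circular sample
#'
#' Subjects whose individual zero-amplitude test is not significant at
#' `alpha` are excluded (no detectable 24-h rhythm); the excluded fraction is
#' itself a reported quantity.
#'
#' @param fits List of `cosinor_fit` for one parameter.
#' @param alpha Per-fit significance threshold (default 0.05).
#' @return List of class `angle_sample`: `parameter`, `angles` (radians in
#'   `[0, 2*pi)`), `subject_id`, `excluded_fraction`, `n`.
#' @export
acrophase_sample <- function(fits, alpha = 0.05) {
  stopifnot(length(fits) >= 1)
  param <- fits[[1]]$parameter
  p <- vapply(fits, function(f) f$p_zero_amplitude, numeric(1))
  keep <- p < alpha
  if (!any(keep)) stop("no subject has a detectable rhythm at this alpha")
  acro <- vapply(fits[keep], function(f) f$acrophase_h, numeric(1))
  per <- fits[[1]]$period_h
  structure(list(parameter = param,
                 angles = (acro * 2 * pi / per) %% (2 * pi),
                 subject_id = vapply(fits[keep],
                                     function(f) f$subject_id %||% NA_character_,
                                     character(1)),
                 excluded_fraction = mean(!keep),
                 n = sum(keep)),
            class = "angle_sample")
}

#' Build an angle sample directly from values on a circular scale
#'
#' @param values Clock hours (period 24) or peak days (period 7), etc.
#' @param period Circular period of `values`.
#' @param parameter Label.
#' @param subject_id Optional subject labels.
#' @return An `angle_sample`.
#' @export
angle_sample <- function(values, period, parameter = "x",
                         subject_id = NULL) {
  structure(list(parameter = parameter,
                 angles = (values * 2 * pi / period) %% (2 * pi),
                 subject_id = subject_id,
                 excluded_fraction = 0, n = length(values)),
            class = "angle_sample")
}

circ_mean <- function(a) atan2(mean(sin(a)), mean(cos(a)))

resultant_length <- function(a) sqrt(sum(cos(a))^2 + sum(sin(a))^2)

# maximum-likelihood-style estimate of the von Mises concentration from the
# mean resultant length (Fisher 1993 approximation)
kappa_from_rbar <- function(rbar) {
  if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
}

#' Watson-Williams multi-sample test for equal mean directions
#'
#' Circular analogue of one-way ANOVA: with per-group resultant lengths
#' `R_j` and the pooled resultant `R`,
#' \deqn{F = K \frac{(N-k)\,(\sum_j R_j - R)}{(k-1)\,(N - \sum_j R_j)}}
#' with the correction `K = 1 + 3/(8*kappa)`, `kappa` estimated from the
#' weighted mean resultant length. Assumes von Mises samples with common,
#' sufficiently large concentration; a warning is issued when the estimated
#' mean resultant length is below 0.45.
#'
#' @param samples List of at least 2 `angle_sample` objects.
#' @return List: `F`, `df1`, `df2`, `p`, `kappa`, `K`, `n`.
#' @export
watson_williams <- function(samples) {
  stopifnot(length(samples) >= 2)
  groups <- lapply(samples, function(s) s$angles)
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("each group needs at least 2 angles")
  k <- length(groups)
  N <- sum(sizes)
  Rj <- vapply(groups, resultant_length, numeric(1))
  if (any(Rj < 1e-12)) stop("a group has zero resultant length (uniform)")
  all_a <- unlist(groups)
  R <- resultant_length(all_a)
  rbar_w <- sum(Rj) / N
  if (rbar_w < 0.45)
    warning("low concentration (mean resultant length < 0.45); ",
            "the Watson-Williams F approximation may be unreliable")
  kappa <- kappa_from_rbar(rbar_w)
  K <- 1 + 3 / (8 * kappa)
  num <- sum(Rj) - R
  den <- N - sum(Rj)
  if (num < 0) num <- 0          # numerical guard: identical groups
  F <- K * ((N - k) * num) / ((k - 1) * den)
  p <- stats::pf(F, k - 1, N - k, lower.tail = FALSE)
  list(F = F, df1 = k - 1, df2 = N - k, p = p, kappa = kappa, K = K, n = N)
}

#' Paired circular correlation (Jammalamadaka-SenGupta)
#'
#' \deqn{r = \frac{\sum \sin(a_i-\bar a)\sin(b_i-\bar b)}
#'   {\sqrt{\sum\sin^2(a_i-\bar a)\,\sum\sin^2(b_i-\bar b)}}}
#' with circular means \eqn{\bar a, \bar b}; the p-value comes from the
#' standard asymptotic normal approximation.
#'
#' @param a,b `angle_sample` objects (or numeric radian vectors) paired by
#'   position.
#' @return List: `r`, `statistic` (z), `p`, `n`.
#' @export
circ_corr <- function(a, b) {
  aa <- if (inherits(a, "angle_sample")) a$angles else as.numeric(a)
  bb <- if (inherits(b, "angle_sample")) b$angles else as.numeric(b)
  if (length(aa) != length(bb)) stop("samples must be paired")
  n <- length(aa)
  if (n < 4) stop("need at least 4 paired subjects")
  sa <- sin(aa - circ_mean(aa))
  sb <- sin(bb - circ_mean(bb))
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den == 0) stop("zero circular variance: correlation undefined")
  r <- sum(sa * sb) / den
  l20 <- mean(sa^2); l02 <- mean(sb^2); l22 <- mean(sa^2 * sb^2)
  z <- sqrt(n * l20 * l02 / l22) * r
  list(r = r, statistic = z, p = 2 * stats::pnorm(-abs(z)), n = n)
}

#' Mean value at the acrophase versus the bathyphase clock hour
#'
#' Pools the raw values of the 1-h clock bin containing the acrophase and the
#' bin containing the bathyphase (acrophase + 12 h) over all recorded days.
#' Raw values are compared (not fitted values), so for latency parameters the
#' "peak" mean is expected to be *smaller* than the off-peak mean.
#'
#' @param series The [binned_series] the fit came from (hourly bins).
#' @param fit Its `cosinor_fit`.
#' @return List: `peak_mean`, `offpeak_mean`, `peak_hour`, `offpeak_hour`,
#'   `n_peak`, `n_offpeak`.
#' @export
peak_vs_offpeak <- function(series, fit) {
  stopifnot(inherits(series, "binned_series"), inherits(fit, "cosinor_fit"))
  if (is.na(fit$acrophase_h)) stop("fit has no acrophase")
  off <- attr(series, "utc_offset") %||% 0
  hr <- floor(clock_hour(series$t_start, off))
  # tiny tolerance so an acrophase of 16 - eps still lands in the [16, 17) bin
  peak_hour <- floor(fit$acrophase_h %% 24 + 1e-9) %% 24
  offpeak_hour <- (peak_hour + 12) %% 24
  pv <- series$value[hr == peak_hour & !is.na(series$value)]
  ov <- series$value[hr == offpeak_hour & !is.na(series$value)]
  if (!length(pv) || !length(ov))
    stop("no data in the acrophase or bathyphase clock bin")
  list(peak_mean = mean(pv), offpeak_mean = mean(ov),
       peak_hour = peak_hour, offpeak_hour = offpeak_hour,
       n_peak = length(pv), n_offpeak = length(ov))
}

#' Model-free time-of-day peak
#'
#' Mean value per clock-hour bin averaged over all days; returns the hour
#' with the maximal mean (minimal for latency orientation) — an estimate of
#' the daily peak that does not assume a sinusoid.
#'
#' @inheritParams fit_cosinor
#' @return Integer clock hour in 0..23.
#' @export
model_free_peak <- function(series, orientation = NULL) {
  stopifnot(inherits(series, "binned_series"))
  parameter <- attr(series, "parameter")
  if (is.null(orientation)) {
    orientation <- if (parameter %in% LATENCY_PARAMETERS) "latency"
                   else "amplitude"
  }
  orientation <- match.arg(orientation, c("amplitude", "latency"))
  off <- attr(series, "utc_offset") %||% 0
  ok <- !is.na(series$value)
  if (!any(ok)) stop("all bins missing")
  hr <- floor(clock_hour(series$t_start[ok], off))
  prof <- tapply(series$value[ok], hr, mean)
  hours <- as.integer(names(prof))
  best <- if (orientation == "latency") which.min(prof) else which.max(prof)
  hours[best]
}

#' Day-of-week analysis of a cohort of binned series
#'
#' Per subject, the mean value on each local weekday; across subjects, a
#' one-way repeated-measures ANOVA for a day-of-week effect; per subject,
#' the peak weekday mapped to an angle `2*pi*d/7` for circular comparison
#' across parameters.
#'
#' @param series_list List of per-subject [binned_series] of one parameter.
#' @param orientation As in [fit_cosinor]; the peak day minimises latency
#'   parameters.
#' @return List of class `day_of_week_analysis`: `day_means` (subject x 7
#'   matrix, columns Mon..Sun), `anova` (`F`, `df1`, `df2`, `p`),
#'   `peak_days` (0 = Mon), `peak_angles` (`angle_sample`).
#' @export
day_of_week_analysis <- function(series_list, orientation = NULL) {
  stopifnot(length(series_list) >= 2)
  parameter <- attr(series_list[[1]], "parameter")
  if (is.null(orientation)) {
    orientation <- if (parameter %in% LATENCY_PARAMETERS) "latency"
                   else "amplitude"
  }
  rows <- lapply(series_list, function(s) {
    off <- attr(s, "utc_offset") %||% 0
    span_d <- nrow(s) * attr(s, "bin_width") / 86400
    if (span_d < 14) stop("day-of-week analysis needs at least 2 full weeks")
    ok <- !is.na(s$value)
    wd <- weekday_index(s$t_start[ok], off)
    m <- tapply(s$value[ok], factor(wd, levels = 0:6), mean)
    as.numeric(m)
  })
  M <- do.call(rbind, rows)
  colnames(M) <- WEEKDAY_NAMES
  if (anyNA(M)) stop("some subject lacks data on some weekday")
  res <- rm_anova(M)
  pick <- if (orientation == "latency") function(r) which.min(r) - 1
          else function(r) which.max(r) - 1
  peak_days <- apply(M, 1, pick)
  structure(list(parameter = parameter, day_means = M, anova = res,
                 peak_days = peak_days,
                 peak_angles = angle_sample(peak_days, 7, parameter)),
            class = "day_of_week_analysis")
}
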