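# Spectral rhythm analysis: classical Lomb-Scargle periodograms of binned
# parameters (missing bins simply excluded, i.e. the unevenly-sampled
# formulation), cohort-level periodogram statistics with BH-FDR against the
# zero-amplitude expectation, band-limited peak estimates, and the tests run
# on the peaks.

#' Classical normalized Lomb-Scargle periodogram
#'
#' Computes the standard-normalized power
#' \deqn{P_N(\omega) = \frac{1}{2\sigma^2}\left[
#'   \frac{(\sum (x-\bar x)\cos\omega(t-\tau))^2}{\sum\cos^2\omega(t-\tau)} +
#'   \frac{(\sum (x-\bar x)\sin\omega(t-\tau))^2}{\sum\sin^2\omega(t-\tau)}
#'   \right]}
#' with \eqn{\tan(2\omega\tau) = \sum\sin 2\omega t / \sum\cos 2\omega t} and
#' \eqn{\sigma^2} the sample variance. Under white Gaussian noise each power
#' is approximately Exp(1), so 1 is the zero-amplitude expectation used by
#' [population_periodogram]. Missing bins are excluded before the transform.
#'
#' The frequency grid is uniform with spacing `1 / (oversampling * span)`,
#' spanning periods from `min_period_h` up to `max_period_h` (default half
#' the record length).
#'
#' @param series A [binned_series] (missing values allowed).
#' @param min_period_h Shortest period of the grid, hours.
#' @param max_period_h Longest period, hours; default `span_h / 2`.
#' @param oversampling Frequency oversampling factor.
#' @param span_h Record length (hours) defining the grid spacing; defaults
#'   to the observed span. Fix it across subjects (e.g. to the nominal
#'   recording length) so cohort periodograms share one grid.
#' @return Object of class `periodogram`: data frame with `period_h` and
#'   `power` (periods increasing, i.e. frequency decreasing); attributes
#'   `n_obs`, `parameter`, `subject_id`.
#' @export
lomb_scargle <- function(series, min_period_h = 3, max_period_h = NULL,
                         oversampling = 4, span_h = NULL) {
  stopifnot(inherits(series, "binned_series"))
  ok <- !is.na(series$value)
  if (sum(ok) < 2) stop("need at least 2 non-missing bins")
  t <- series$t_start[ok] / 3600              # hours
  x <- series$value[ok]
  t <- t - min(t)
  span <- if (is.null(span_h)) max(t) else span_h
  if (is.null(max_period_h)) max_period_h <- span / 2
  if (max_period_h <= min_period_h)
    stop("record too short for the requested period grid")
  xc <- x - mean(x)
  ssx <- sum(xc^2)
  if (ssx == 0) stop("constant series: normalized power undefined")
  sigma2 <- ssx / (length(x) - 1)

  df <- 1 / (oversampling * span)
  k_lo <- max(1, ceiling(1 / (max_period_h * df) - 1e-9))
  k_hi <- floor(1 / (min_period_h * df) + 1e-9)
  if (k_hi < k_lo) stop("empty frequency grid")
  freq <- (k_lo:k_hi) * df
  omega <- 2 * pi * freq

  wt <- outer(t, omega)                       # n x m
  s2 <- colSums(sin(2 * wt)); c2 <- colSums(cos(2 * wt))
  tau_w <- atan2(s2, c2) / 2                  # omega * tau
  cw <- cos(sweep(wt, 2, tau_w))
  sw <- sin(sweep(wt, 2, tau_w))
  power <- (colSums(xc * cw)^2 / colSums(cw^2) +
            colSums(xc * sw)^2 / colSums(sw^2)) / (2 * sigma2)

  out <- data.frame(period_h = rev(1 / freq), power = rev(power))
  structure(out, class = c("periodogram", "data.frame"),
            n_obs = length(x),
            parameter = attr(series, "parameter"),
            subject_id = attr(series, "subject_id"))
}

#' @export
print.periodogram <- function(x, ...) {
  pk <- x$period_h[which.max(x$power)]
  cat(sprintf(
    "<periodogram> '%s' subject '%s': %d periods in [%.2f, %.2f] h, peak %.2f h (power %.2f)\n",
    attr(x, "parameter") %||% "?", attr(x, "subject_id") %||% "?",
    nrow(x), min(x$period_h), max(x$period_h), pk, max(x$power)))
  invisible(x)
}

#' Cohort mean periodogram with FDR-controlled zero-amplitude test
#'
#' Across subjects sharing one period grid: per-period mean power, t-based
#' 95% confidence interval, one-sample t-test of the powers against the
#' white-noise (zero-amplitude) expectation of 1, and a Benjamini-Hochberg
#' significance mask across the whole grid at rate `q`.
#'
#' @param periodograms List of `periodogram` objects on a common grid.
#' @param q FDR level.
#' @param conf_level Confidence level of the CI.
#' @return Data frame of class `population_periodogram` with columns
#'   `period_h`, `mean_power`, `ci_lo`, `ci_hi`, `p`, `p_adj`, `significant`;
#'   attribute `n_subjects`.
#' @export
population_periodogram <- function(periodograms, q = 0.05,
                                   conf_level = 0.95) {
  n <- length(periodograms)
  if (n < 3) stop("need at least 3 subjects for a population periodogram")
  grid <- periodograms[[1]]$period_h
  for (pg in periodograms[-1]) {
    if (length(pg$period_h) != length(grid) ||
        any(abs(pg$period_h - grid) > 1e-8))
      stop("periodograms are not on a common period grid")
  }
  P <- do.call(rbind, lapply(periodograms, function(pg) pg$power))
  m <- colMeans(P)
  s <- apply(P, 2, stats::sd)
  se <- s / sqrt(n)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  tstat <- ifelse(se > 0, (m - 1) / se, ifelse(m == 1, 0, Inf))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  p_adj <- stats::p.adjust(p, method = "BH")
  structure(data.frame(period_h = grid, mean_power = m,
                       ci_lo = m - tcrit * se, ci_hi = m + tcrit * se,
                       p = p, p_adj = p_adj,
                       significant = p_adj < q),
            class = c("population_periodogram", "data.frame"),
            n_subjects = n, q = q)
}

#' Band-limited periodogram peak
#'
#' Period and power of the maximum power inside a band. Exact power ties are
#' broken toward the period nearest 24 h when the band contains 24 h (the
#' diurnal band), otherwise toward the band center.
#'
#' @param pg A `periodogram`.
#' @param band_h Numeric length-2, band limits in hours.
#' @return List of class `peak_estimate`: `parameter`, `peak_period_h`,
#'   `peak_power`.
#' @export
peak_in_band <- function(pg, band_h) {
  stopifnot(inherits(pg, "periodogram"), length(band_h) == 2)
  if (band_h[2] <= band_h[1]) stop("empty peak band")
  inb <- pg$period_h >= band_h[1] & pg$period_h <= band_h[2]
  if (!any(inb)) stop("band outside the period grid")
  per <- pg$period_h[inb]; pow <- pg$power[inb]
  best <- which(pow == max(pow))
  if (length(best) > 1) {
    anchor <- if (band_h[1] <= 24 && band_h[2] >= 24) 24 else mean(band_h)
    best <- best[which.min(abs(per[best] - anchor))]
  }
  structure(list(parameter = attr(pg, "parameter"),
                 peak_period_h = per[best], peak_power = pow[best]),
            class = "peak_estimate")
}

#' One-sample t-test of peak periods against 24 h
#'
#' @param peaks Numeric vector of per-subject peak periods (hours).
#' @param mu Reference period (24 h).
#' @param alpha_fwer Family-wise corrected significance level.
#' @return List: `mean`, `t`, `df`, `p`, `significant`, `n`. Zero-variance
#'   samples are guarded: all peaks equal to `mu` gives t = 0, p = 1;
#'   all equal but different from `mu` is reported as p = 0.
#' @export
test_peaks_vs_24 <- function(peaks, mu = 24, alpha_fwer = 0.0083) {
  peaks <- peaks[!is.na(peaks)]
  n <- length(peaks)
  if (n < 3) stop("need at least 3 subjects")
  if (stats::sd(peaks) == 0) {
    hit <- mean(peaks) != mu
    return(list(mean = mean(peaks), t = if (hit) Inf else 0, df = n - 1,
                p = if (hit) 0 else 1, significant = hit, n = n))
  }
  tt <- stats::t.test(peaks, mu = mu)
  list(mean = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value,
       significant = tt$p.value < alpha_fwer, n = n)
}

#' One-way ANOVA comparing peak periods or powers across parameters
#'
#' @param values Numeric vector of per-subject values (peak periods or peak
#'   powers).
#' @param group Factor/character of the same length: the parameter each value
#'   belongs to.
#' @return List: `F`, `df1`, `df2`, `p`, `group_means`.
#' @export
compare_parameters <- function(values, group) {
  group <- factor(group)
  ok <- !is.na(values)
  values <- values[ok]; group <- droplevels(group[ok])
  sizes <- table(group)
  if (length(sizes) < 2) stop("need at least 2 parameter groups")
  if (any(sizes < 2))
    stop(sprintf("group '%s' has fewer than 2 members",
                 names(sizes)[sizes < 2][1]))
  fit <- stats::anova(stats::lm(values ~ group))
  list(F = fit[["F value"]][1], df1 = fit$Df[1], df2 = fit$Df[2],
       p = fit[["Pr(>F)"]][1],
       group_means = tapply(values, group, mean))
}
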