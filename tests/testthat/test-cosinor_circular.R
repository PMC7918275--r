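# Fixed-period cosinor fits and circular statistics.

# Brute-force textbook Watson-Williams: straight transcription of the
# formula, independent of the package's helpers.
ww_oracle <- function(groups) {
  k <- length(groups); N <- sum(lengths(groups))
  Rj <- sapply(groups, function(a) {
    sqrt(sum(cos(a))^2 + sum(sin(a))^2)
  })
  all_a <- unlist(groups)
  R <- sqrt(sum(cos(all_a))^2 + sum(sin(all_a))^2)
  rw <- sum(Rj) / N
  kap <- if (rw < 0.53) 2 * rw + rw^3 + 5 * rw^5 / 6
         else if (rw < 0.85) -0.4 + 1.39 * rw + 0.43 / (1 - rw)
         else 1 / (rw^3 - 4 * rw^2 + 3 * rw)
  K <- 1 + 3 / (8 * kap)
  K * ((N - k) * (sum(Rj) - R)) / ((k - 1) * (N - sum(Rj)))
}

# Brute-force Jammalamadaka-SenGupta circular correlation
cc_oracle <- function(a, b) {
  am <- atan2(mean(sin(a)), mean(cos(a)))
  bm <- atan2(mean(sin(b)), mean(cos(b)))
  sum(sin(a - am) * sin(b - bm)) /
    sqrt(sum(sin(a - am)^2) * sum(sin(b - bm)^2))
}

test_that("a noise-free cosinor is recovered to machine precision", {
  s <- make_cosine_series(mesor = 10, amp = 2, acro = 16, days = 21)
  fit <- fit_cosinor(s, 24, orientation = "amplitude")
  expect_equal(fit$mesor, 10, tolerance = 1e-10)
  expect_equal(fit$amplitude, 2, tolerance = 1e-10)
  expect_equal(fit$acrophase_h, 16, tolerance = 1e-9)
  expect_lt(fit$p_zero_amplitude, 1e-12)
})

test_that("constant series yields zero amplitude and p = 1", {
  s <- binned_series(seq(0, 30 * 3600, 3600), rep(5, 31), "usage", 3600)
  fit <- fit_cosinor(s, 24)
  expect_equal(fit$amplitude, 0)
  expect_equal(fit$p_zero_amplitude, 1)
})

test_that("acrophase is equivariant and amplitude shift-invariant", {
  s <- make_cosine_series(mesor = 10, amp = 2, acro = 16, days = 14,
                          noise_sd = 0.3, seed = 4)
  fit <- fit_cosinor(s, 24, orientation = "amplitude")
  # shift timestamps by 5 h: acrophase shifts by 5 h mod 24
  s2 <- binned_series(s$t_start + 5 * 3600, s$value, "usage", 3600)
  fit2 <- fit_cosinor(s2, 24, orientation = "amplitude")
  expect_equal(fit2$acrophase_h, (fit$acrophase_h + 5) %% 24,
               tolerance = 1e-8)
  # adding a constant changes neither amplitude nor p
  s3 <- s; s3$value <- s$value + 50
  fit3 <- fit_cosinor(s3, 24, orientation = "amplitude")
  expect_equal(fit3$amplitude, fit$amplitude, tolerance = 1e-10)
  expect_equal(fit3$p_zero_amplitude, fit$p_zero_amplitude,
               tolerance = 1e-10)
})

test_that("latency orientation equals fitting the negated series", {
  s <- make_cosine_series(mesor = 400, amp = 30, acro = 4, days = 14,
                          parameter = "TS", noise_sd = 5, seed = 9)
  lat <- fit_cosinor(s, 24)                   # defaults to latency for TS
  neg <- s; neg$value <- -neg$value + 1000    # affine trick to stay valid
  amp <- fit_cosinor(
    binned_series(neg$t_start, neg$value, "usage", 3600), 24,
    orientation = "amplitude")
  expect_equal(lat$orientation, "latency")
  expect_equal(lat$amplitude, amp$amplitude, tolerance = 1e-10)
  expect_equal(lat$acrophase_h, amp$acrophase_h, tolerance = 1e-8)
  # fastest time is 12 h from the slowest (value peak at acro = 4)
  expect_equal(lat$acrophase_h, 16, tolerance = 0.2)
})

test_that("acrophase_sample filters by the zero-amplitude test", {
  mkfit <- function(p, acro) {
    structure(list(parameter = "TS", period_h = 24, mesor = 1, amplitude = 1,
                   acrophase_h = acro, p_zero_amplitude = p, n_obs = 100,
                   orientation = "latency", subject_id = "x"),
              class = "cosinor_fit")
  }
  fits <- list(mkfit(0.001, 15), mkfit(0.2, 3), mkfit(0.01, 17),
               mkfit(0.9, 9))
  as <- acrophase_sample(fits, alpha = 0.05)
  expect_equal(as$n, 2)
  expect_equal(as$excluded_fraction, 0.5)
  expect_equal(sort(as$angles), sort(c(15, 17) * 2 * pi / 24))
  expect_error(acrophase_sample(list(mkfit(0.5, 1)), 0.05), "no subject")
})

test_that("Watson-Williams matches the brute-force oracle on small sets", {
  set.seed(21)
  for (rep in 1:5) {
    g <- lapply(1:3, function(i) (0.4 * i + rnorm(3 + rep %% 2, 0, 0.3)))
    res <- watson_williams(lapply(g, function(a) angle_sample(a, 2 * pi)))
    expect_equal(res$F, ww_oracle(g), tolerance = 1e-8)
    expect_equal(res$df1, length(g) - 1)
    expect_equal(res$df2, sum(lengths(g)) - length(g))
  }
})

test_that("Watson-Williams degenerate and separated cases behave", {
  a <- c(0.1, 0.2, 0.3, 0.15)
  same <- watson_williams(list(angle_sample(a, 2 * pi),
                               angle_sample(a, 2 * pi)))
  expect_equal(same$F, 0, tolerance = 1e-10)
  expect_equal(same$p, 1, tolerance = 1e-10)

  set.seed(8)
  g1 <- rnorm(20, 0, 0.05); g2 <- rnorm(20, pi / 2, 0.05)
  sep <- watson_williams(list(angle_sample(g1, 2 * pi),
                              angle_sample(g2, 2 * pi)))
  expect_gt(sep$F, 100)
  expect_lt(sep$p, 1e-10)

  expect_error(watson_williams(list(
    angle_sample(c(0, pi), 2 * pi), angle_sample(c(0, 0.1), 2 * pi))),
    "zero resultant")
})

test_that("circular correlation matches its oracle and the exact cases", {
  set.seed(13)
  a <- runif(8, 0, 2 * pi)
  b <- (a + rnorm(8, 0, 0.2)) %% (2 * pi)
  res <- circ_corr(a, b)
  expect_equal(res$r, cc_oracle(a, b), tolerance = 1e-8)

  expect_equal(circ_corr(a, a)$r, 1, tolerance = 1e-12)
  expect_equal(circ_corr(a, -a)$r, -1, tolerance = 1e-12)

  # independent angles: r small, p roughly uniform
  set.seed(14)
  r0 <- circ_corr(runif(200, 0, 2 * pi), runif(200, 0, 2 * pi))
  expect_lt(abs(r0$r), 0.2)
  expect_error(circ_corr(rep(0.3, 5), runif(5)), "zero circular variance")
})

test_that("peak versus off-peak means bracket the fitted amplitude", {
  # noise-free cosine sampled hourly, acrophase on a sample point:
  # peak mean - offpeak mean = 2A exactly
  s <- make_cosine_series(mesor = 10, amp = 2, acro = 16, days = 7)
  fit <- fit_cosinor(s, 24, orientation = "amplitude")
  pv <- peak_vs_offpeak(s, fit)
  expect_equal(pv$peak_hour, 16)
  expect_equal(pv$offpeak_hour, 4)
  expect_equal(pv$peak_mean - pv$offpeak_mean, 4, tolerance = 1e-9)

  # flat-with-noise series: difference near 0
  set.seed(6)
  s2 <- make_cosine_series(mesor = 10, amp = 0.001, acro = 16, days = 21,
                           noise_sd = 0)
  fit2 <- fit_cosinor(s2, 24, orientation = "amplitude")
  pv2 <- peak_vs_offpeak(s2, fit2)
  expect_lt(abs(pv2$peak_mean - pv2$offpeak_mean), 0.01)
})

test_that("model-free peak finds the right hour without a sinusoid", {
  s <- make_cosine_series(mesor = 10, amp = 2, acro = 16, days = 7)
  expect_equal(model_free_peak(s, "amplitude"), 16)

  # bimodal profile: the larger lobe at 9 h wins
  t_start <- seq(0, 7 * 86400 - 3600, 3600)
  h <- (t_start / 3600) %% 24
  v <- 10 + 3 * exp(-((h - 9)^2) / 4) + 2 * exp(-((h - 20)^2) / 4)
  s2 <- binned_series(t_start, v, "usage", 3600)
  expect_equal(model_free_peak(s2, "amplitude"), 9)

  # latency orientation returns the fastest hour
  v3 <- 500 - 100 * exp(-((h - 17)^2) / 2)
  s3 <- binned_series(t_start, v3, "TS", 3600)
  expect_equal(model_free_peak(s3), 17)
})

test_that("day-of-week analysis detects weekly structure", {
  mk_weekly <- function(amp_wd, peak_day, seed, parameter = "usage") {
    set.seed(seed)
    t_start <- seq(4 * 86400, 4 * 86400 + 21 * 86400 - 3600, 3600)
    wd <- weekday_index(t_start)
    v <- 50 + amp_wd * cos(2 * pi * (wd - peak_day) / 7) +
      rnorm(length(t_start), 0, 1)
    binned_series(t_start, v, parameter, 3600)
  }
  # no day effect by construction: opposite subject patterns cancel, so the
  # between-day sum of squares is exactly zero while residual variance is not
  t_start <- seq(4 * 86400, 4 * 86400 + 14 * 86400 - 3600, 3600)
  wd <- weekday_index(t_start)
  pattern <- cos(2 * pi * wd / 7)
  flat <- lapply(c(1, -1, 2, -2), function(sgn) {
    binned_series(t_start, 50 + sgn * pattern, "usage", 3600)
  })
  res0 <- day_of_week_analysis(flat)
  expect_equal(res0$anova$F, 0, tolerance = 1e-12)

  # weekend-peaked activity: significant day effect, peak on Sat/Sun
  act <- lapply(1:6, function(i) mk_weekly(10, 5.5, i, "activity"))
  res <- day_of_week_analysis(act)
  expect_lt(res$anova$p, 0.001)
  expect_true(all(res$peak_days %in% c(5, 6)))

  # weekday-peaked usage: peak day lands Monday-Friday
  use <- lapply(1:6, function(i) mk_weekly(10, 2, 10 + i))
  res2 <- day_of_week_analysis(use)
  expect_true(all(res2$peak_days %in% 0:4))

  short <- list(make_cosine_series(days = 7), make_cosine_series(days = 7))
  expect_error(day_of_week_analysis(short), "2 full weeks")
})
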