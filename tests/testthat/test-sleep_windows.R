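# Pre-bed / bed / rise window pooling and comparisons.

# sleep_periods object built directly
make_periods <- function(onsets, offsets, t0_weekday = 0) {
  structure(data.frame(night_index = seq_along(onsets),
                       onset = onsets, offset = offsets,
                       onset_weekday = weekday_index(onsets)),
            class = c("sleep_periods", "data.frame"),
            subject_id = "s1", utc_offset = 0)
}

# event stream with unlock episodes of given latencies (ms) at given times
unlock_stream <- function(times, latencies_ms, subject_id = "s1") {
  t <- c(rbind(times - latencies_ms / 1000, times))
  k <- rep(c("screen_on", "unlock_complete"), length(times))
  event_stream(t, k, subject_id = subject_id)
}

test_that("windows are labeled around each sleep period", {
  # onset 23:00, offset 07:00 (Monday-based origin)
  on <- 4 * 86400 + 23 * 3600; off <- on + 8 * 3600
  w <- segment_windows(make_periods(on, off))
  expect_equal(nrow(w), 3)
  pre <- w[w$window == "pre_bed", ]
  expect_equal(c(pre$start, pre$end), c(on - 3600, on))
  bed <- w[w$window == "bed", ]
  expect_equal(c(bed$start, bed$end), c(on, off))
  rise <- w[w$window == "rise", ]
  expect_equal(c(rise$start, rise$end), c(off, off + 3600))

  # configurable pre-window length
  w2 <- segment_windows(make_periods(on, off), pre_len_s = 1800)
  expect_equal(w2$start[w2$window == "pre_bed"], on - 1800)
})

test_that("many nights give non-overlapping labeled intervals", {
  set.seed(17)
  ons <- 4 * 86400 + (0:99) * 86400 + 23.5 * 3600 + rnorm(100, 0, 1200)
  offs <- ons + 8 * 3600 + rnorm(100, 0, 1200)
  w <- segment_windows(make_periods(ons, offs))
  expect_equal(nrow(w), 300)
  iv <- w[order(w$start), ]
  expect_true(all(iv$start[-1] >= iv$end[-nrow(iv)] - 1e-9))

  # nights too close together are rejected
  expect_error(segment_windows(make_periods(c(0, 9 * 3600),
                                            c(8 * 3600, 17 * 3600))),
               "overlap")
})

test_that("pooling follows the complete-case rule per parameter", {
  on <- 4 * 86400 + 23 * 3600; off <- on + 8 * 3600
  w <- segment_windows(make_periods(on, off))

  # episodes in all three windows -> US reported
  st <- unlock_stream(c(on - 1800, on - 1700, on - 1600,      # pre_bed
                        on + 3600, on + 3700, on + 3800,      # bed
                        off + 600, off + 700, off + 800),     # rise
                      rep(2000, 9))
  ws <- pool_window_params(st, w, min_episodes = 3)
  expect_equal(sort(unique(ws$parameter)), "US")
  expect_equal(ws$value[ws$window == "bed"], 2000)
  expect_equal(ws$n_episodes, rep(3L, 3))

  # no in-bed episodes -> excluded entirely
  st2 <- unlock_stream(c(on - 1800, on - 1700, on - 1600,
                         off + 600, off + 700, off + 800), rep(1500, 6))
  expect_equal(nrow(pool_window_params(st2, w, min_episodes = 3)), 0)

  # exclusion is monotone in min_episodes
  ws1 <- pool_window_params(st, w, min_episodes = 1)
  ws4 <- pool_window_params(st, w, min_episodes = 4)
  expect_true(all(unique(ws4$parameter) %in% unique(ws1$parameter)))
  expect_equal(nrow(ws4), 0)
})

test_that("pooled episodes land in exactly one window each", {
  on <- 4 * 86400 + 23 * 3600; off <- on + 8 * 3600
  w <- segment_windows(make_periods(c(on, on + 86400),
                                    c(off, off + 86400)))
  set.seed(23)
  times <- sort(c(runif(50, on - 3600, off + 3600),
                  runif(50, on + 86400 - 3600, off + 86400 + 3600)))
  st <- unlock_stream(times, runif(100, 800, 3000))
  obs <- latency_observations(st)
  hits <- sapply(obs$t[obs$kind == "unlock"], function(tt) {
    sum(tt >= w$start & tt < w$end)
  })
  expect_true(all(hits <= 1))
  ws <- pool_window_params(st, w, min_episodes = 1)
  expect_equal(sum(ws$n_episodes[ws$parameter == "US"]), sum(hits == 1))
})

test_that("window comparison matches a hand-computed paired t", {
  # 5 subjects, bed slower than pre-bed by a noisy shift
  set.seed(31)
  pre <- c(1900, 2100, 2000, 2050, 1950)
  bed <- pre + c(350, 420, 380, 300, 450)
  rise <- pre + c(20, -30, 10, 0, -10)
  samp <- do.call(rbind, lapply(1:5, function(i) {
    data.frame(subject = paste0("s", i), parameter = "US",
               window = c("pre_bed", "bed", "rise"),
               value = c(pre[i], bed[i], rise[i]), n_episodes = 10L)
  }))
  class(samp) <- c("window_samples", "data.frame")
  res <- compare_windows(samp, "US")
  d <- bed - pre
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  row <- res$paired[res$paired$contrast == "bed_vs_pre_bed", ]
  expect_equal(row$t, t_hand, tolerance = 1e-12)
  expect_equal(row$df, 4)
  expect_equal(row$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
  expect_lt(res$anova$p, 0.01)
  expect_equal(res$anova$df1, 2)
  expect_equal(res$anova$df2, 8)

  # identical windows: F = 0, all t = 0
  same <- samp; same$value <- rep(pre, each = 3)
  class(same) <- c("window_samples", "data.frame")
  res0 <- compare_windows(same, "US")
  expect_equal(res0$anova$F, 0, tolerance = 1e-12)
  expect_true(all(res0$paired$t == 0))
  expect_true(all(res0$paired$p == 1))
})

test_that("weekday/weekend split reports concordance", {
  # synthetic nights across 3 weeks; US latencies slower in bed everywhere
  set.seed(41)
  t0 <- 4 * 86400
  ons <- t0 + (0:20) * 86400 + 23 * 3600
  offs <- ons + 8 * 3600
  periods <- make_periods(ons, offs)
  w <- segment_windows(periods)
  mk_subject <- function(sid, bed_shift) {
    times <- c(); lats <- c()
    for (i in seq_along(ons)) {
      times <- c(times, ons[i] - c(900, 1800, 2700),
                 ons[i] + 3600 * c(1, 2, 3),
                 offs[i] + c(900, 1800, 2700))
      # all three contrasts have a true nonzero difference, so the sign
      # pattern is stable in both night subsets
      lats <- c(lats, rnorm(3, 2000, 100),
                rnorm(3, 2000 + bed_shift, 100),
                rnorm(3, 2150, 100))
    }
    unlock_stream(times, lats, subject_id = sid)
  }
  streams <- lapply(1:6, function(i) mk_subject(paste0("s", i), 400))
  wins <- rep(list(w), 6)
  split <- weekday_weekend_split(streams, wins, "US")
  expect_true(split$concordant)
  expect_lt(split$weekend$paired$p[1], 0.05)

  # all nights on weekdays -> weekend subset errors
  wd_only <- periods[periods$onset_weekday %in% 0:3, ]
  class(wd_only) <- class(periods)
  attr(wd_only, "subject_id") <- "s1"
  w_wd <- segment_windows(wd_only)
  expect_error(weekday_weekend_split(streams[1:3], rep(list(w_wd), 3), "US"),
               "empty night subset")
})

test_that("sign-flipped weekend penalties break concordance", {
  set.seed(43)
  t0 <- 4 * 86400
  ons <- t0 + (0:20) * 86400 + 23 * 3600
  offs <- ons + 8 * 3600
  w <- segment_windows(make_periods(ons, offs))
  wd <- weekday_index(ons)
  mk_subject <- function(sid) {
    times <- c(); lats <- c()
    for (i in seq_along(ons)) {
      shift <- if (wd[i] %in% c(4, 5, 6)) -400 else 400
      times <- c(times, ons[i] - c(900, 1800, 2700),
                 ons[i] + 3600 * c(1, 2, 3),
                 offs[i] + c(900, 1800, 2700))
      lats <- c(lats, rnorm(3, 2000, 50),
                rnorm(3, 2000 + shift, 50), rnorm(3, 2000, 50))
    }
    unlock_stream(times, lats, subject_id = sid)
  }
  streams <- lapply(1:6, function(i) mk_subject(paste0("s", i)))
  split <- weekday_weekend_split(streams, rep(list(w), 6), "US")
  expect_false(split$concordant)
})
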