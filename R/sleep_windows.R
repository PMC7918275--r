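# Cognitive performance around actigraphy-defined sleep: label pre-bed / bed
# / rise intervals from consolidated sleep periods, pool latency episodes
# into per-subject window summaries, and run the repeated-measures ANOVA plus
# paired follow-ups, including the weekday/weekend split.

WINDOW_LEVELS <- c("pre_bed", "bed", "rise")

# One-way repeated-measures ANOVA on a subjects x conditions matrix,
# computed from the balanced-design sums of squares so degenerate inputs
# (zero between-condition or zero residual variance) have defined results.
rm_anova <- function(M) {
  n <- nrow(M); k <- ncol(M)
  grand <- mean(M)
  ss_cond <- n * sum((colMeans(M) - grand)^2)
  ss_subj <- k * sum((rowMeans(M) - grand)^2)
  ss_tot <- sum((M - grand)^2)
  ss_res <- max(0, ss_tot - ss_cond - ss_subj)
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  if (ss_cond <= 1e-12 * max(ss_tot, 1)) {
    F <- 0; p <- 1
  } else if (ss_res <= 1e-12 * ss_cond) {
    F <- Inf; p <- 0
  } else {
    F <- (ss_cond / df1) / (ss_res / df2)
    p <- stats::pf(F, df1, df2, lower.tail = FALSE)
  }
  list(F = F, df1 = df1, df2 = df2, p = p)
}

#' Label pre-bed, bed and rise intervals around each sleep period
#'
#' Per night: `pre_bed = [onset - pre_len, onset)`, `bed = [onset, offset)`,
#' `rise = [offset, offset + post_len)`.
#'
#' @param periods A `sleep_periods` data frame (see [consolidate_sleep]).
#' @param pre_len_s Pre-bed window length, seconds (default 1 h).
#' @param post_len_s Rise window length, seconds (default 1 h).
#' @return Data frame of class `sleep_windows`: `night_index`, `window`,
#'   `start`, `end`, `onset_weekday`.
#' @export
segment_windows <- function(periods, pre_len_s = 3600, post_len_s = 3600) {
  stopifnot(inherits(periods, "sleep_periods"))
  if (nrow(periods) == 0) stop("no sleep periods to segment")
  if (nrow(periods) > 1) {
    gap_ok <- periods$onset[-1] - pre_len_s >=
      periods$offset[-nrow(periods)] + post_len_s
    if (!all(gap_ok))
      stop("consecutive sleep periods too close: windows would overlap")
  }
  out <- do.call(rbind, lapply(seq_len(nrow(periods)), function(i) {
    p <- periods[i, ]
    data.frame(night_index = p$night_index,
               window = WINDOW_LEVELS,
               start = c(p$onset - pre_len_s, p$onset, p$offset),
               end = c(p$onset, p$offset, p$offset + post_len_s),
               onset_weekday = p$onset_weekday)
  }))
  structure(out, class = c("sleep_windows", "data.frame"),
            subject_id = attr(periods, "subject_id"))
}

#' Pool latency episodes of one subject into window summaries
#'
#' Episode latencies (from [latency_observations]) completing inside any
#' interval of a window type are pooled over the whole recording. The
#' per-subject summary is the median for US and ALS; for TS it is the 25th
#' percentile of the pooled inter-touch intervals (the windowed analogue of
#' the per-bin tapping-speed construct; set `ts_summary = "median"` to pool
#' TS like the other parameters). A parameter is reported only if all three
#' windows reach `min_episodes` (complete case).
#'
#' @param stream The subject's [event_stream].
#' @param windows A `sleep_windows` data frame from [segment_windows].
#' @param min_episodes Minimum pooled episodes per window type.
#' @param max_gap_s,max_duration_s Passed to [latency_observations].
#' @param ts_summary `"quartile"` (default) or `"median"`.
#' @return Data frame of class `window_samples`: `subject`, `parameter`,
#'   `window`, `value` (ms), `n_episodes`. Incomplete parameters are absent.
#' @export
pool_window_params <- function(stream, windows, min_episodes = 3,
                               max_gap_s = 30, max_duration_s = 60,
                               ts_summary = c("quartile", "median")) {
  stopifnot(inherits(stream, "event_stream"),
            inherits(windows, "sleep_windows"))
  ts_summary <- match.arg(ts_summary)
  obs <- latency_observations(stream, max_gap_s = max_gap_s,
                              max_duration_s = max_duration_s)
  kinds <- c(TS = "inter_touch", US = "unlock", ALS = "app_locate")
  subject <- attr(stream, "subject_id")
  out <- list()
  for (param in names(kinds)) {
    o <- obs[obs$kind == kinds[[param]], , drop = FALSE]
    pooled <- lapply(WINDOW_LEVELS, function(wn) {
      iv <- windows[windows$window == wn, , drop = FALSE]
      hit <- rep(FALSE, nrow(o))
      for (i in seq_len(nrow(iv)))
        hit <- hit | (o$t >= iv$start[i] & o$t < iv$end[i])
      o$value[hit]
    })
    names(pooled) <- WINDOW_LEVELS
    if (any(lengths(pooled) < min_episodes)) next   # complete-case rule
    summ <- function(v) {
      if (param == "TS" && ts_summary == "quartile")
        stats::quantile(v, 0.25, names = FALSE, type = 7)
      else stats::median(v)
    }
    out[[param]] <- data.frame(subject = subject, parameter = param,
                               window = WINDOW_LEVELS,
                               value = vapply(pooled, summ, numeric(1)),
                               n_episodes = unname(lengths(pooled)))
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(subject = character(0), parameter = character(0),
               window = character(0), value = numeric(0),
               n_episodes = integer(0))
  rownames(res) <- NULL
  structure(res, class = c("window_samples", "data.frame"))
}

#' Combine per-subject window samples into one cohort table
#' @param samples_list List of `window_samples`.
#' @return A single `window_samples` data frame.
#' @export
bind_window_samples <- function(samples_list) {
  out <- do.call(rbind, lapply(samples_list, as.data.frame))
  structure(out, class = c("window_samples", "data.frame"))
}

#' Repeated-measures comparison of pre-bed, bed and rise performance
#'
#' One-way repeated-measures ANOVA of the per-subject window summaries over
#' the three windows, followed by the three paired t-tests (bed vs pre-bed,
#' bed vs rise, pre-bed vs rise). Only complete-case subjects (a value in
#' all three windows) enter.
#'
#' @param samples A `window_samples` data frame (cohort level).
#' @param parameter Which latency parameter to analyse ("TS"/"US"/"ALS").
#' @return List of class `window_comparison`: `parameter`, `n`,
#'   `window_means`, `anova` (`F`, `df1`, `df2`, `p`) and `paired`
#'   (data frame with one row per contrast: `contrast`, `mean_diff`, `t`,
#'   `df`, `p`).
#' @export
compare_windows <- function(samples, parameter) {
  s <- samples[samples$parameter == parameter, , drop = FALSE]
  wide <- stats::reshape(s[, c("subject", "window", "value")],
                         idvar = "subject", timevar = "window",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide <- wide[stats::complete.cases(wide[, WINDOW_LEVELS]), , drop = FALSE]
  n <- nrow(wide)
  if (n < 3) stop("need at least 3 complete-case subjects")
  an <- rm_anova(as.matrix(wide[, WINDOW_LEVELS]))
  paired_t <- function(a, b, label) {
    d <- wide[[a]] - wide[[b]]
    if (stats::sd(d) == 0) {
      list(contrast = label, mean_diff = mean(d),
           t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
           df = n - 1, p = if (mean(d) == 0) 1 else 0)
    } else {
      tt <- stats::t.test(wide[[a]], wide[[b]], paired = TRUE)
      list(contrast = label, mean_diff = unname(tt$estimate),
           t = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value)
    }
  }
  paired <- rbind(
    as.data.frame(paired_t("bed", "pre_bed", "bed_vs_pre_bed")),
    as.data.frame(paired_t("bed", "rise", "bed_vs_rise")),
    as.data.frame(paired_t("pre_bed", "rise", "pre_bed_vs_rise")))
  structure(list(parameter = parameter, n = n,
                 window_means = colMeans(wide[, WINDOW_LEVELS]),
                 anova = an, paired = paired),
            class = "window_comparison")
}

#' @export
print.window_comparison <- function(x, ...) {
  cat(sprintf("<window_comparison> %s, n = %d complete-case subjects\n",
              x$parameter, x$n))
  cat(sprintf("  means (ms): pre_bed %.1f  bed %.1f  rise %.1f\n",
              x$window_means[["pre_bed"]], x$window_means[["bed"]],
              x$window_means[["rise"]]))
  cat(sprintf("  RM-ANOVA: F(%d,%d) = %.2f, p = %.3g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  for (i in seq_len(nrow(x$paired)))
    cat(sprintf("  %-16s diff %8.1f ms  t(%d) = %6.2f  p = %.3g\n",
                x$paired$contrast[i], x$paired$mean_diff[i],
                x$paired$df[i], x$paired$t[i], x$paired$p[i]))
  invisible(x)
}

#' Weekday/weekend split of the sleep-window comparison
#'
#' Re-runs the pooling and comparison separately for nights whose sleep
#' onset falls on Friday/Saturday/Sunday versus Monday--Thursday, and flags
#' concordance when the sign pattern of the three paired contrasts matches
#' across the two subsets.
#'
#' @param streams Named list of per-subject [event_stream]s.
#' @param windows_list List (same order) of per-subject `sleep_windows`.
#' @param parameter Latency parameter to analyse.
#' @param min_episodes,max_gap_s,max_duration_s As in [pool_window_params].
#' @return List: `weekend` and `weekday` (`window_comparison` objects) and
#'   `concordant` (logical).
#' @export
weekday_weekend_split <- function(streams, windows_list, parameter = "US",
                                  min_episodes = 3, max_gap_s = 30,
                                  max_duration_s = 60) {
  stopifnot(length(streams) == length(windows_list))
  subset_run <- function(days) {
    samp <- lapply(seq_along(streams), function(i) {
      w <- windows_list[[i]]
      w2 <- w[w$onset_weekday %in% days, , drop = FALSE]
      if (nrow(w2) == 0) return(NULL)
      class(w2) <- class(w)
      pool_window_params(streams[[i]], w2, min_episodes = min_episodes,
                         max_gap_s = max_gap_s,
                         max_duration_s = max_duration_s)
    })
    samp <- samp[!vapply(samp, is.null, logical(1))]
    if (!length(samp)) stop("empty night subset: no nights with onset on ",
                            "the requested weekdays")
    compare_windows(bind_window_samples(samp), parameter)
  }
  weekend <- subset_run(c(4, 5, 6))   # Fri, Sat, Sun onsets
  weekday <- subset_run(c(0, 1, 2, 3))
  concordant <- all(sign(weekend$paired$mean_diff) ==
                    sign(weekday$paired$mean_diff))
  list(weekend = weekend, weekday = weekday, concordant = concordant)
}
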