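# Actigraphy: acceleration -> activity counts -> Cole-Kripke sleep/wake
# labels -> consolidated nightly sleep periods.

#' Convert wrist acceleration to per-epoch activity counts
#'
#' Per epoch, count = `gain * sum(max(0, |a| - 1))` over the epoch's samples
#' (gravity-subtracted magnitude, in g). If the input already carries counts
#' they are passed through unchanged (re-epoched by summation if the epoch
#' lengths differ). This is a stated approximation of device-side count
#' generation, which is proprietary for most actigraphs.
#'
#' @param series A [wearable_series] with `accel` and/or `counts`.
#' @param epoch_s Target epoch length in seconds (default 60).
#' @param gain Scale factor applied to the summed supra-1 g magnitude.
#' @return A data frame of class `activity_counts` with columns `t_start`,
#'   `count`; attributes `epoch_s`, `subject_id`, `utc_offset`.
#' @export
accel_to_counts <- function(series, epoch_s = 60, gain = 100) {
  stopifnot(inherits(series, "wearable_series"))
  in_epoch <- attr(series, "epoch_s")
  if (!is.null(series$counts)) {
    val <- series$counts
    t0 <- series$t_start
  } else if (!is.null(series$accel)) {
    val <- gain * pmax(0, series$accel - 1)
    t0 <- series$t_start
  } else {
    stop("wearable series has neither acceleration nor counts")
  }
  if (abs(in_epoch - epoch_s) > 1e-9) {
    if (epoch_s < in_epoch || abs(epoch_s %% in_epoch) > 1e-6)
      stop(sprintf("cannot re-epoch %g s input to %g s", in_epoch, epoch_s))
    grid <- bin_grid(min(t0), max(t0), epoch_s,
                     attr(series, "utc_offset") %||% 0)
    idx <- floor((t0 - grid[1]) / epoch_s) + 1
    agg <- tapply(val, idx, sum)
    out_t <- grid
    out_v <- rep(0, length(grid))
    out_v[as.integer(names(agg))] <- as.numeric(agg)
  } else {
    out_t <- t0; out_v <- val
  }
  out_v[is.na(out_v)] <- 0
  structure(data.frame(t_start = out_t, count = pmax(0, out_v)),
            class = c("activity_counts", "data.frame"),
            epoch_s = epoch_s,
            subject_id = attr(series, "subject_id"),
            utc_offset = attr(series, "utc_offset") %||% 0)
}

#' Cole-Kripke sleep/wake scoring of one-minute activity counts
#'
#' Scores each epoch as `S_i = P * sum(w_k * count_{i+k})` over the window
#' k = -4 ... +2 (counts outside the record treated as 0) and labels the
#' epoch sleep iff `S_i < threshold`. Defaults are the published 1992
#' one-minute-epoch weights with P = 0.001 and threshold 1; all three are
#' configurable because calibration is device dependent.
#'
#' @param counts An `activity_counts` object at 1-min epochs (re-epoched via
#'   [accel_to_counts] if necessary).
#' @param weights Seven non-negative weights for minutes -4 ... +2.
#' @param scale Scale factor P.
#' @param threshold Sleep iff score < threshold.
#' @return Data frame of class `sleep_labels` with columns `t_start`,
#'   `score`, `state` ("sleep"/"wake"); attributes as the input.
#' @export
cole_kripke <- function(counts, weights = c(106, 54, 58, 76, 230, 74, 67),
                        scale = 0.001, threshold = 1) {
  stopifnot(inherits(counts, "activity_counts"), length(weights) == 7,
            all(weights >= 0))
  epoch_s <- attr(counts, "epoch_s")
  if (abs(epoch_s - 60) > 1e-6)
    stop(sprintf("Cole-Kripke needs 1-min epochs, got %g s; re-epoch first",
                 epoch_s))
  x <- counts$count
  n <- length(x)
  score <- numeric(n)
  for (k in -4:2) {
    w <- weights[k + 5]
    if (w == 0) next
    idx <- seq_len(n) + k
    ok <- idx >= 1 & idx <= n
    score[ok] <- score[ok] + w * x[idx[ok]]
  }
  score <- scale * score
  structure(data.frame(t_start = counts$t_start, score = score,
                       state = ifelse(score < threshold, "sleep", "wake")),
            class = c("sleep_labels", "data.frame"),
            epoch_s = epoch_s,
            subject_id = attr(counts, "subject_id"),
            utc_offset = attr(counts, "utc_offset") %||% 0)
}

#' Consolidate epoch labels into one main sleep period per day
#'
#' Sleep bouts shorter than `min_bout_min` are relabelled wake; bouts
#' separated by less than `merge_gap_min` of wake are merged; the longest
#' merged bout whose onset falls in each noon-to-noon (local time) day is
#' that day's main sleep period.
#'
#' @param labels A `sleep_labels` data frame from [cole_kripke].
#' @param min_bout_min Minimum bout length kept, minutes.
#' @param merge_gap_min Maximum wake gap merged, minutes.
#' @return Data frame of class `sleep_periods` with columns `night_index`,
#'   `onset`, `offset` (seconds since epoch) and `onset_weekday` (0 = Mon).
#' @export
consolidate_sleep <- function(labels, min_bout_min = 20, merge_gap_min = 60) {
  stopifnot(inherits(labels, "sleep_labels"))
  epoch_s <- attr(labels, "epoch_s")
  off <- attr(labels, "utc_offset") %||% 0
  r <- rle(labels$state == "sleep")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  bouts <- data.frame(start = labels$t_start[starts[r$values]],
                      end = labels$t_start[ends[r$values]] + epoch_s)
  bouts <- bouts[(bouts$end - bouts$start) >= min_bout_min * 60, ,
                 drop = FALSE]
  empty <- data.frame(night_index = integer(0), onset = numeric(0),
                      offset = numeric(0), onset_weekday = integer(0))
  if (nrow(bouts) == 0)
    return(structure(empty, class = c("sleep_periods", "data.frame"),
                     subject_id = attr(labels, "subject_id"),
                     utc_offset = off))
  # merge bouts separated by short wake
  merged <- bouts[1, ]
  if (nrow(bouts) > 1) {
    for (i in 2:nrow(bouts)) {
      j <- nrow(merged)
      if (bouts$start[i] - merged$end[j] < merge_gap_min * 60) {
        merged$end[j] <- bouts$end[i]
      } else {
        merged <- rbind(merged, bouts[i, ])
      }
    }
  }
  # longest merged bout per noon-to-noon local day (day of the bout's onset)
  day <- floor((merged$start + off - 12 * 3600) / 86400)
  dur <- merged$end - merged$start
  keep <- unlist(lapply(split(seq_len(nrow(merged)), day),
                        function(ix) ix[which.max(dur[ix])]))
  main <- merged[sort(keep), , drop = FALSE]
  out <- data.frame(night_index = seq_len(nrow(main)),
                    onset = main$start, offset = main$end,
                    onset_weekday = weekday_index(main$start, off))
  structure(out, class = c("sleep_periods", "data.frame"),
            subject_id = attr(labels, "subject_id"), utc_offset = off)
}

#' Bin wearable channels for rhythm analysis
#'
#' Hourly (or configurable) [binned_series] of the two wearable channels:
#' activity counts are summed per bin, luminescence averaged.
#'
#' @param series A [wearable_series].
#' @param bin_width Bin width in seconds.
#' @return Named list with `activity` and (if present) `lux` binned series.
#' @export
wearable_binned <- function(series, bin_width = 3600) {
  stopifnot(inherits(series, "wearable_series"))
  off <- attr(series, "utc_offset") %||% 0
  sid <- attr(series, "subject_id")
  grid <- bin_grid(min(series$t_start), max(series$t_start), bin_width, off)
  idx <- floor((series$t_start - grid[1]) / bin_width) + 1
  out <- list()
  cnt <- if (!is.null(series$counts)) series$counts
         else accel_to_counts(series, epoch_s = attr(series, "epoch_s"))$count
  agg <- tapply(cnt, idx, sum)
  v <- rep(NA_real_, length(grid)); v[as.integer(names(agg))] <- agg
  out$activity <- binned_series(grid, v, "activity", bin_width,
                                subject_id = sid, utc_offset = off)
  if (!is.null(series$lux)) {
    agg <- tapply(series$lux, idx, mean)
    v <- rep(NA_real_, length(grid)); v[as.integer(names(agg))] <- agg
    out$lux <- binned_series(grid, v, "lux", bin_width,
                             subject_id = sid, utc_offset = off)
  }
  out
}

#' Full actigraphy sleep pipeline
#'
#' Acceleration/counts to consolidated sleep periods with configuration
#' defaults.
#'
#' @param series A [wearable_series].
#' @param config An [analysis_config].
#' @return A `sleep_periods` data frame (see [consolidate_sleep]).
#' @export
score_sleep <- function(series, config = analysis_config()) {
  counts <- accel_to_counts(series, epoch_s = 60)
  labels <- cole_kripke(counts, weights = config$ck_weights,
                        scale = config$ck_scale,
                        threshold = config$ck_threshold)
  consolidate_sleep(labels, min_bout_min = config$min_bout_min,
                    merge_gap_min = config$merge_gap_min)
}
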