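# Tappigraphy parameter extraction: turn a raw event stream into hourly (or
# configurable) binned series of smartphone usage and the three proxy measures
# of cognitive processing speed.
#
# Conventions fixed here because exact tests need them:
#  * an interval/episode belongs to the bin of its COMPLETING event;
#  * bin boundaries are half-open [t, t + w): an event exactly on a boundary
#    counts in the later bin;
#  * the TS percentile uses linear interpolation between order statistics
#    (quantile type 7).

#' Extract latency observations from an event stream
#'
#' Produces the episode-level observations behind the three latency
#' parameters:
#' \describe{
#'   \item{inter_touch}{interval between consecutive touches, kept only if
#'     at most `max_gap_s` (longer gaps are session breaks, not taps).}
#'   \item{unlock}{`unlock_complete` minus the most recent `screen_on`;
#'     episodes with an intervening `screen_off` (screen went dark before the
#'     unlock) or longer than `max_duration_s` are discarded.}
#'   \item{app_locate}{`app_launch` minus the most recent `home_shown`, same
#'     discard rules.}
#' }
#' Orphan completions (no preceding opener) are skipped; their count is kept
#' in the `n_orphans` attribute.
#'
#' @param stream An [event_stream].
#' @param max_gap_s Maximum inter-touch interval treated as continuous
#'   tapping (seconds).
#' @param max_duration_s Maximum unlock / app-locating episode length
#'   (seconds).
#' @return Data frame with columns `t` (completion time, s), `kind`
#'   (`inter_touch`/`unlock`/`app_locate`) and `value` (ms); attribute
#'   `n_orphans`.
#' @export
latency_observations <- function(stream, max_gap_s = 30, max_duration_s = 60) {
  stopifnot(inherits(stream, "event_stream"))
  n_orphans <- 0L
  obs <- list()

  tt <- stream$t[stream$kind == "touch"]
  if (length(tt) >= 2) {
    gaps <- diff(tt)
    keep <- gaps <= max_gap_s & gaps > 0
    if (any(keep)) {
      obs$inter_touch <- data.frame(t = tt[-1][keep], kind = "inter_touch",
                                    value = gaps[keep] * 1000)
    }
  }

  pair_episodes <- function(opener, closer, label) {
    idx_open <- which(stream$kind == opener)
    idx_close <- which(stream$kind == closer)
    idx_off <- which(stream$kind == "screen_off")
    if (!length(idx_close)) return(NULL)
    # row index (within idx_open) of the latest opener strictly before each
    # closer; 0 = orphan
    last_open <- findInterval(idx_close - 0.5, idx_open)
    n_orphans <<- n_orphans + sum(last_open == 0)
    ok <- last_open > 0
    idx_close <- idx_close[ok]
    io <- idx_open[last_open[ok]]
    # discard episodes with a screen_off between opener and closer
    if (length(idx_off)) {
      last_off <- findInterval(idx_close - 0.5, idx_off)
      off_pos <- ifelse(last_off > 0, idx_off[pmax(last_off, 1)], 0L)
      keep <- off_pos < io
      idx_close <- idx_close[keep]; io <- io[keep]
    }
    dur <- stream$t[idx_close] - stream$t[io]
    keep <- dur > 0 & dur <= max_duration_s
    if (!any(keep)) return(NULL)
    data.frame(t = stream$t[idx_close][keep], kind = label,
               value = dur[keep] * 1000)
  }

  obs$unlock <- pair_episodes("screen_on", "unlock_complete", "unlock")
  obs$app <- pair_episodes("home_shown", "app_launch", "app_locate")

  out <- do.call(rbind, obs[!vapply(obs, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(t = numeric(0), kind = character(0),
                      value = numeric(0))
  }
  out <- out[order(out$t), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_orphans") <- n_orphans
  out
}

# shared binning over the span of a stream
stream_bins <- function(stream, bin_width) {
  if (nrow(stream) == 0) stop("empty event stream")
  bin_grid(min(stream$t), max(stream$t), bin_width,
           attr(stream, "utc_offset") %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assign_bins <- function(t, grid, bin_width) {
  i <- floor((t - grid[1]) / bin_width) + 1
  i[i < 1 | i > length(grid)] <- NA
  i
}

#' Smartphone usage: touches per bin
#'
#' @param stream An [event_stream].
#' @param bin_width Bin width in seconds.
#' @return A [binned_series] of parameter `usage`; empty bins are 0.
#' @export
usage_counts <- function(stream, bin_width = 3600) {
  grid <- stream_bins(stream, bin_width)
  tt <- stream$t[stream$kind == "touch"]
  cnt <- tabulate(assign_bins(tt, grid, bin_width), nbins = length(grid))
  binned_series(grid, cnt, "usage", bin_width,
                subject_id = attr(stream, "subject_id"),
                utc_offset = attr(stream, "utc_offset") %||% 0)
}

#' Tapping speed: fastest quartile of inter-touch intervals per bin
#'
#' Per bin, the 25th percentile (linear interpolation) of the inter-touch
#' intervals whose completing touch falls in the bin, after removing
#' session-break gaps longer than `max_gap_s`. Bins with fewer than
#' `min_intervals` intervals are missing.
#'
#' @inheritParams usage_counts
#' @inheritParams latency_observations
#' @param min_intervals Minimum number of intervals per bin.
#' @return A [binned_series] of parameter `TS` in ms.
#' @export
tapping_speed <- function(stream, bin_width = 3600, max_gap_s = 30,
                          min_intervals = 5) {
  obs <- latency_observations(stream, max_gap_s = max_gap_s)
  obs <- obs[obs$kind == "inter_touch", , drop = FALSE]
  bin_aggregate(stream, obs, bin_width, "TS",
                function(v) if (length(v) >= min_intervals)
                  stats::quantile(v, 0.25, names = FALSE, type = 7)
                else NA_real_)
}

#' Unlocking speed: median screen-on-to-unlock latency per bin
#'
#' @inheritParams tapping_speed
#' @param max_duration_s Episodes longer than this are discarded (seconds).
#' @param min_episodes Minimum episodes per bin (default 1).
#' @return A [binned_series] of parameter `US` in ms.
#' @export
unlocking_speed <- function(stream, bin_width = 3600, max_duration_s = 60,
                            min_episodes = 1) {
  obs <- latency_observations(stream, max_duration_s = max_duration_s)
  obs <- obs[obs$kind == "unlock", , drop = FALSE]
  bin_aggregate(stream, obs, bin_width, "US",
                function(v) if (length(v) >= min_episodes)
                  stats::median(v) else NA_real_)
}

#' App-locating speed: median home-screen-to-launch latency per bin
#'
#' @inheritParams unlocking_speed
#' @return A [binned_series] of parameter `ALS` in ms.
#' @export
app_locating_speed <- function(stream, bin_width = 3600, max_duration_s = 60,
                               min_episodes = 1) {
  obs <- latency_observations(stream, max_duration_s = max_duration_s)
  obs <- obs[obs$kind == "app_locate", , drop = FALSE]
  bin_aggregate(stream, obs, bin_width, "ALS",
                function(v) if (length(v) >= min_episodes)
                  stats::median(v) else NA_real_)
}

bin_aggregate <- function(stream, obs, bin_width, parameter, fun) {
  grid <- stream_bins(stream, bin_width)
  val <- rep(NA_real_, length(grid))
  if (nrow(obs)) {
    idx <- assign_bins(obs$t, grid, bin_width)
    ok <- !is.na(idx)
    got <- tapply(obs$value[ok], idx[ok], fun)
    val[as.integer(names(got))] <- as.numeric(got)
  }
  binned_series(grid, val, parameter, bin_width,
                subject_id = attr(stream, "subject_id"),
                utc_offset = attr(stream, "utc_offset") %||% 0)
}

#' Extract all four smartphone parameters at once
#'
#' Convenience wrapper returning `usage`, `TS`, `US` and `ALS` on a common
#' bin grid.
#'
#' @inheritParams usage_counts
#' @param config An [analysis_config] supplying gap/duration/minimum
#'   thresholds.
#' @return Named list of four [binned_series].
#' @export
extract_parameters <- function(stream, config = analysis_config(),
                               bin_width = config$bin_width) {
  list(
    usage = usage_counts(stream, bin_width),
    TS = tapping_speed(stream, bin_width, config$max_gap_s,
                       config$min_intervals),
    US = unlocking_speed(stream, bin_width, config$max_duration_s),
    ALS = app_locating_speed(stream, bin_width, config$max_duration_s)
  )
}
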