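# Data model, file I/O and shared time conventions.
#
# All internal times are numeric seconds since the Unix epoch. A per-subject
# UTC offset (seconds) converts to local clock time, so "hour of day" always
# means local clock hour; hour-of-day bins are half-open [h, h + 1).

#' Event kinds recognised in a touchscreen event stream
#'
#' The closed vocabulary of smartphone events: raw screen touches plus the
#' screen/unlock/home/app lifecycle events from which unlocking speed and
#' app-locating speed episodes are assembled.
#'
#' @format A character vector of length 6.
#' @export
EVENT_KINDS <- c("touch", "screen_on", "unlock_complete",
                 "home_shown", "app_launch", "screen_off")

#' Smartphone parameters produced by the tappigraphy extractors
#'
#' `usage` (touches per bin), `TS` (tapping speed), `US` (unlocking speed),
#' `ALS` (app-locating speed), plus the wearable channels `activity` and
#' `lux`. The three latency parameters are in milliseconds; lower is faster.
#'
#' @format A character vector of length 6.
#' @export
PARAMETERS <- c("usage", "TS", "US", "ALS", "activity", "lux")

#' Parameters that measure a latency (lower = better performance)
#' @format A character vector.
#' @export
LATENCY_PARAMETERS <- c("TS", "US", "ALS")

# ---- time helpers -----------------------------------------------------------

#' Local clock hour of day
#'
#' @param t Numeric seconds since the Unix epoch.
#' @param utc_offset Seconds to add to obtain local time.
#' @return Clock hour in `[0, 24)` (fractional).
#' @export
clock_hour <- function(t, utc_offset = 0) {
  ((t + utc_offset) / 3600) %% 24
}

#' Local weekday index
#'
#' @inheritParams clock_hour
#' @return Integer day of week, 0 = Monday ... 6 = Sunday.
#' @export
weekday_index <- function(t, utc_offset = 0) {
  # Unix day 0 (1970-01-01) was a Thursday, i.e. weekday 3 in Mon = 0 terms.
  (floor((t + utc_offset) / 86400) + 3) %% 7
}

#' Names of the weekday indices used throughout the package
#' @format Character vector, element i + 1 names weekday index i (0 = Mon).
#' @export
WEEKDAY_NAMES <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")

# ---- EventStream ------------------------------------------------------------

#' Construct a validated smartphone event stream
#'
#' An `event_stream` is a data frame with columns `t` (seconds since epoch)
#' and `kind` (one of [EVENT_KINDS]), sorted by time, carrying the subject
#' label and UTC offset as attributes. It is the raw substrate for all
#' tappigraphy parameters.
#'
#' @param t Numeric timestamps (seconds since epoch).
#' @param kind Character event kinds, from [EVENT_KINDS].
#' @param subject_id Opaque subject label.
#' @param utc_offset Seconds added to `t` for local clock time.
#' @param strict If `TRUE` (default) unknown kinds are an error; otherwise
#'   they are dropped with a message.
#' @return An object of class `event_stream`.
#' @export
event_stream <- function(t, kind, subject_id = "s1", utc_offset = 0,
                         strict = TRUE) {
  if (length(t) != length(kind))
    stop("`t` and `kind` must have equal length")
  t <- as.numeric(t)
  if (anyNA(t)) stop("event timestamps contain missing/unparseable values")
  kind <- as.character(kind)
  bad <- !(kind %in% EVENT_KINDS)
  if (any(bad)) {
    if (strict) {
      stop(sprintf("unknown event kind '%s' at row %d",
                   kind[which(bad)[1]], which(bad)[1]))
    }
    t <- t[!bad]; kind <- kind[!bad]
  }
  o <- order(t)
  out <- data.frame(t = t[o], kind = kind[o], stringsAsFactors = FALSE)
  structure(out, class = c("event_stream", "data.frame"),
            subject_id = subject_id, utc_offset = utc_offset)
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("<event_stream> subject '%s': %d events", attr(x, "subject_id"),
              nrow(x)))
  if (nrow(x)) {
    cat(sprintf(", spanning %.2f days", (max(x$t) - min(x$t)) / 86400))
  }
  cat("\n")
  tab <- table(factor(x$kind, levels = EVENT_KINDS))
  print(tab)
  invisible(x)
}

# ---- WearableSeries ---------------------------------------------------------

#' Construct a validated wrist wearable series
#'
#' Uniform epochs of either raw acceleration magnitude (`accel`, in g) or
#' pre-computed activity `counts`, plus ambient luminescence `lux`. At least
#' one of `accel`/`counts` must be present.
#'
#' @param t_start Epoch start times (seconds since epoch), uniformly spaced.
#' @param accel Optional per-epoch acceleration magnitude (g).
#' @param counts Optional per-epoch non-negative activity counts.
#' @param lux Optional per-epoch luminescence.
#' @param epoch_s Epoch length in seconds; inferred from `t_start` if `NULL`.
#' @inheritParams event_stream
#' @return An object of class `wearable_series`.
#' @export
wearable_series <- function(t_start, accel = NULL, counts = NULL, lux = NULL,
                            epoch_s = NULL, subject_id = "s1",
                            utc_offset = 0) {
  t_start <- as.numeric(t_start)
  if (is.null(accel) && is.null(counts))
    stop("wearable series needs acceleration or activity counts")
  if (anyDuplicated(t_start)) {
    d <- t_start[duplicated(t_start)][1]
    stop(sprintf("duplicate wearable epoch at t = %s", format(d)))
  }
  o <- order(t_start)
  t_start <- t_start[o]
  if (is.null(epoch_s)) {
    if (length(t_start) < 2) stop("cannot infer epoch length from one epoch")
    epoch_s <- diff(t_start)[1]
  }
  if (length(t_start) > 1) {
    steps <- diff(t_start)
    if (any(abs(steps %% epoch_s) > 1e-6 & abs(steps %% epoch_s - epoch_s) > 1e-6))
      stop("non-uniform wearable sampling cannot be regularized to epoch_s")
  }
  out <- data.frame(t_start = t_start)
  if (!is.null(counts)) {
    counts <- as.numeric(counts)[o]
    if (any(counts < 0, na.rm = TRUE)) stop("activity counts must be >= 0")
    out$counts <- counts
  }
  if (!is.null(accel)) out$accel <- as.numeric(accel)[o]
  if (!is.null(lux)) {
    lux <- as.numeric(lux)[o]
    if (any(lux < 0, na.rm = TRUE)) stop("lux must be >= 0")
    out$lux <- lux
  }
  structure(out, class = c("wearable_series", "data.frame"),
            subject_id = subject_id, utc_offset = utc_offset,
            epoch_s = epoch_s)
}

#' @export
print.wearable_series <- function(x, ...) {
  cat(sprintf("<wearable_series> subject '%s': %d epochs of %g s (%s)\n",
              attr(x, "subject_id"), nrow(x), attr(x, "epoch_s"),
              paste(setdiff(names(x), "t_start"), collapse = ", ")))
  invisible(x)
}

# ---- BinnedSeries -----------------------------------------------------------

#' Construct a regular time-binned series of one parameter
#'
#' The unit of all rhythm analyses: contiguous, uniform bins of one smartphone
#' or wearable parameter. Missing values are `NA`: latency parameters carry
#' `NA` for bins with no episodes (speed is undefined there), count
#' parameters carry 0 (absence of touches is informative).
#'
#' @param t_start Bin start times (seconds since epoch), contiguous.
#' @param value Per-bin values (`NA` allowed).
#' @param parameter One of [PARAMETERS].
#' @param bin_width Bin width in seconds.
#' @inheritParams event_stream
#' @return An object of class `binned_series`.
#' @export
binned_series <- function(t_start, value, parameter, bin_width,
                          subject_id = "s1", utc_offset = 0) {
  parameter <- match.arg(parameter, PARAMETERS)
  t_start <- as.numeric(t_start)
  value <- as.numeric(value)
  if (length(t_start) != length(value)) stop("t_start/value length mismatch")
  if (length(t_start) > 1 && any(abs(diff(t_start) - bin_width) > 1e-6))
    stop("bins must be contiguous and uniform")
  if (parameter %in% LATENCY_PARAMETERS &&
      any(value <= 0 & !is.na(value)))
    stop("latency values must be strictly positive where present")
  if (!(parameter %in% LATENCY_PARAMETERS) && any(value < 0, na.rm = TRUE))
    stop("count/intensity values must be nonnegative")
  structure(data.frame(t_start = t_start, value = value),
            class = c("binned_series", "data.frame"),
            parameter = parameter, bin_width = bin_width,
            subject_id = subject_id, utc_offset = utc_offset)
}

#' @export
print.binned_series <- function(x, ...) {
  cat(sprintf(
    "<binned_series> '%s', subject '%s': %d bins of %g s, %d missing\n",
    attr(x, "parameter"), attr(x, "subject_id"), nrow(x),
    attr(x, "bin_width"), sum(is.na(x$value))))
  invisible(x)
}

# Bin grid covering [t_min, t_max] inclusively, aligned to multiples of
# bin_width in LOCAL time so hourly bins line up with clock hours. Bins are
# half-open [t, t + w): a t_max exactly on a boundary opens one more bin.
bin_grid <- function(t_min, t_max, bin_width, utc_offset = 0) {
  lo <- floor((t_min + utc_offset) / bin_width) * bin_width - utc_offset
  hi <- (floor((t_max + utc_offset) / bin_width) + 1) * bin_width - utc_offset
  seq(lo, hi - bin_width, by = bin_width)
}

# ---- configuration ----------------------------------------------------------

#' Analysis configuration with study defaults
#'
#' Central container for every tunable of the pipeline. Defaults encode the
#' study conventions: hour-long bins, a period grid from 3 h to half the
#' record length at 4x oversampling, a diurnal peak band of 16--32 h and an
#' infradian band of 5--9 days, `alpha_fwer = 0.0083` for the family of
#' peak-vs-24 h tests, Benjamini-Hochberg FDR at q = 0.05 across the
#' frequency grid, published 1992 minute-epoch Cole-Kripke weights, and 1-h
#' pre-bed/rise windows.
#'
#' @param bin_width Bin width in seconds (3600 = hourly).
#' @param min_period_h Shortest period on the Lomb-Scargle grid (hours).
#' @param oversampling Frequency oversampling factor of the period grid.
#' @param diurnal_band_h Band searched for the diurnal peak, hours.
#' @param infradian_band_d Band searched for the circaseptan peak, days.
#' @param ultradian_band_h Band for the 90-min analysis (15-min bins), hours.
#' @param alpha Per-test significance level (cosinor fits, follow-ups).
#' @param alpha_fwer Family-wise corrected level for the peak-vs-24 h family.
#' @param fdr_q Benjamini-Hochberg q for the periodogram grid.
#' @param ck_weights Cole-Kripke 7-term weights (minutes -4 ... +2).
#' @param ck_scale Cole-Kripke scale factor P.
#' @param ck_threshold Score threshold; an epoch is sleep iff score < it.
#' @param epoch_s Actigraphy epoch length in seconds.
#' @param min_bout_min Minimum sleep-bout length kept (minutes).
#' @param merge_gap_min Wake gaps shorter than this merge adjacent bouts.
#' @param window_len_s Length of pre-bed and rise windows (seconds).
#' @param max_gap_s Inter-touch intervals above this are session breaks.
#' @param max_duration_s Unlock/app episodes longer than this are discarded.
#' @param min_intervals Minimum inter-touch intervals per bin for TS.
#' @param min_episodes Minimum episodes per sleep window for inclusion.
#' @param utc_offset Default UTC offset (seconds) for local clock time.
#' @param seed RNG seed recorded in result manifests.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(bin_width = 3600,
                            min_period_h = 3,
                            oversampling = 4,
                            diurnal_band_h = c(16, 32),
                            infradian_band_d = c(5, 9),
                            ultradian_band_h = c(1, 3),
                            alpha = 0.05,
                            alpha_fwer = 0.0083,
                            fdr_q = 0.05,
                            ck_weights = c(106, 54, 58, 76, 230, 74, 67),
                            ck_scale = 0.001,
                            ck_threshold = 1,
                            epoch_s = 60,
                            min_bout_min = 20,
                            merge_gap_min = 60,
                            window_len_s = 3600,
                            max_gap_s = 30,
                            max_duration_s = 60,
                            min_intervals = 5,
                            min_episodes = 3,
                            utc_offset = 0,
                            seed = 1L) {
  stopifnot(bin_width > 0, min_period_h > 0, oversampling > 0,
            length(diurnal_band_h) == 2, diff(diurnal_band_h) > 0,
            diurnal_band_h[1] <= 24, diurnal_band_h[2] >= 24,
            length(infradian_band_d) == 2, diff(infradian_band_d) > 0,
            alpha > 0, alpha_fwer > 0, fdr_q > 0,
            length(ck_weights) == 7, all(ck_weights >= 0),
            ck_scale > 0, epoch_s > 0, window_len_s > 0,
            max_gap_s > 0, max_duration_s > 0,
            min_intervals >= 1, min_episodes >= 1)
  structure(as.list(environment()), class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-18s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

# ---- readers ----------------------------------------------------------------

#' Read a smartphone event stream from CSV
#'
#' Expects at least a timestamp and a kind column; names are remappable via
#' `column_map` for foreign dialects.
#'
#' @param path CSV file path.
#' @param column_map Named character vector mapping internal names (`t`,
#'   `kind`) to file column names.
#' @inheritParams event_stream
#' @return An [event_stream].
#' @export
read_event_stream <- function(path, column_map = c(t = "t", kind = "kind"),
                              subject_id = NULL, utc_offset = 0,
                              strict = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop(sprintf("empty event file: %s", path))
  miss <- setdiff(unname(column_map[c("t", "kind")]), names(df))
  if (length(miss))
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(miss, collapse = ", ")))
  tt <- suppressWarnings(as.numeric(df[[column_map[["t"]]]]))
  if (anyNA(tt)) {
    stop(sprintf("unparseable timestamp at row %d of %s",
                 which(is.na(tt))[1], path))
  }
  if (is.null(subject_id)) {
    subject_id <- if ("subject" %in% names(df)) as.character(df$subject[1])
                  else sub("\\.csv$", "", basename(path))
  }
  event_stream(tt, df[[column_map[["kind"]]]], subject_id = subject_id,
               utc_offset = utc_offset, strict = strict)
}

#' Read a wearable series from CSV
#'
#' Accepts either pre-computed `counts` or tri-axial `ax, ay, az` (collapsed
#' to magnitude) or a single `accel` column, plus optional `lux`. Input
#' sampled faster than `epoch_s` is aggregated (counts summed, accel and lux
#' averaged); gaps become missing epochs.
#'
#' @param path CSV file path.
#' @param epoch_s Target epoch length in seconds.
#' @inheritParams event_stream
#' @return A [wearable_series].
#' @export
read_wearable <- function(path, epoch_s = 60, subject_id = NULL,
                          utc_offset = 0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop(sprintf("empty wearable file: %s", path))
  if (!"t" %in% names(df)) stop("wearable CSV needs a 't' column")
  tt <- suppressWarnings(as.numeric(df$t))
  if (anyNA(tt)) stop(sprintf("unparseable timestamp at row %d of %s",
                              which(is.na(tt))[1], path))
  if (anyDuplicated(tt))
    stop(sprintf("duplicate timestamp %s in %s",
                 format(tt[duplicated(tt)][1]), path))
  if (is.null(subject_id)) subject_id <- sub("\\.csv$", "", basename(path))
  if (all(c("ax", "ay", "az") %in% names(df))) {
    df$accel <- sqrt(df$ax^2 + df$ay^2 + df$az^2)
  }
  has_counts <- "counts" %in% names(df)
  has_accel <- "accel" %in% names(df)
  if (!has_counts && !has_accel)
    stop("wearable CSV needs 'counts', 'accel' or 'ax/ay/az' columns")

  o <- order(tt)
  df <- df[o, , drop = FALSE]; tt <- tt[o]
  steps <- diff(tt)
  native <- if (length(steps)) stats::median(steps) else epoch_s
  if (native > epoch_s + 1e-9)
    stop(sprintf("native sampling (%g s) coarser than epoch_s (%g s)",
                 native, epoch_s))
  grid <- bin_grid(min(tt), max(tt), epoch_s, utc_offset)
  idx <- findInterval(tt, c(grid, grid[length(grid)] + epoch_s))
  agg <- function(x, fun) {
    out <- rep(NA_real_, length(grid))
    got <- tapply(x, idx, fun)
    out[as.integer(names(got))] <- as.numeric(got)
    out
  }
  wearable_series(
    t_start = grid,
    counts = if (has_counts) agg(as.numeric(df$counts), sum) else NULL,
    accel = if (has_accel) agg(as.numeric(df$accel), mean) else NULL,
    lux = if ("lux" %in% names(df)) agg(as.numeric(df$lux), mean) else NULL,
    epoch_s = epoch_s, subject_id = subject_id, utc_offset = utc_offset)
}

# ---- writers ----------------------------------------------------------------

#' Write result tables plus a run manifest
#'
#' Each table goes to `<name>.csv` with a deterministic column order; a
#' `manifest.json` records the file list, configuration and seed so a run can
#' be reproduced byte-for-byte.
#'
#' @param tables Named list of data frames.
#' @param dir Output directory (created if needed).
#' @param config An [analysis_config] (or any list) embedded in the manifest.
#' @return Invisibly, the manifest list.
#' @export
write_results <- function(tables = list(), dir, config = analysis_config()) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop(sprintf("cannot create '%s'", dir))
  }
  files <- character(0)
  for (nm in names(tables)) {
    df <- as.data.frame(tables[[nm]])
    df <- df[, sort(names(df)), drop = FALSE]
    f <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(df, f, row.names = FALSE)
    files <- c(files, basename(f))
  }
  manifest <- list(files = as.list(files),
                   config = unclass(config),
                   seed = config$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write an event stream back to the package's CSV dialect
#' @param stream An [event_stream].
#' @param path Output CSV path.
#' @export
write_event_stream <- function(stream, path) {
  utils::write.csv(data.frame(t = stream$t, kind = stream$kind),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a wearable series back to the package's CSV dialect
#' @param series A [wearable_series].
#' @param path Output CSV path.
#' @export
write_wearable <- function(series, path) {
  df <- as.data.frame(series)
  names(df)[names(df) == "t_start"] <- "t"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
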