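# Shared builders for fixtures generated in code.

# Hourly-sampled cosinor series: value = mesor + amp * cos(2*pi*(h - acro)/24)
make_cosine_series <- function(mesor = 10, amp = 2, acro = 16, days = 21,
                               bin_width = 3600, parameter = "usage",
                               noise_sd = 0, t0 = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t_start <- seq(t0, t0 + days * 86400 - bin_width, by = bin_width)
  h <- (t_start / 3600) %% 24
  v <- mesor + amp * cos(2 * pi * (h - acro) / 24)
  if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
  binned_series(t_start, v, parameter, bin_width)
}

# Event stream of bare touches at the given times (seconds)
make_touch_stream <- function(times, subject_id = "s1") {
  event_stream(times, rep("touch", length(times)), subject_id = subject_id)
}

# Activity-count object built directly (bypassing acceleration)
make_counts <- function(counts, epoch_s = 60, t0 = 0) {
  structure(data.frame(t_start = seq(t0, by = epoch_s,
                                     length.out = length(counts)),
                       count = counts),
            class = c("activity_counts", "data.frame"),
            epoch_s = epoch_s, subject_id = "s1", utc_offset = 0)
}

# Sleep-labels object built directly from a logical sleep vector
make_labels <- function(asleep, epoch_s = 60, t0 = 0) {
  structure(data.frame(t_start = seq(t0, by = epoch_s,
                                     length.out = length(asleep)),
                       score = as.numeric(!asleep),
                       state = ifelse(asleep, "sleep", "wake")),
            class = c("sleep_labels", "data.frame"),
            epoch_s = epoch_s, subject_id = "s1", utc_offset = 0)
}
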