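# Synthetic cohort generator: coupled touchscreen event streams, wrist
# actigraphy and luminescence with known ground truth, emulating ~21-day
# recordings with diurnal (~24 h) and weekly (~7 d) intensity rhythms,
# time-of-day- and sleep-modulated latencies, consolidated nocturnal sleep
# visible as near-zero activity counts, and day/night luminescence.
#
# The touch process is an inhomogeneous Poisson process with intensity
#   lambda(t) = base * (1 + a24 cos(2pi (h(t) - phi24)/24))
#                    * (1 + a7 cos(2pi (d(t) - phi7)/7)),
# clipped at 0 and zeroed during sleep except for explicit in-bed use bouts.
# Latency draws are lognormal with a multiplicative location:
#   baseline * diurnal * bed-window * sleep-inertia multipliers * exp(sigma Z),
# so penalties read directly as fractional slowing and the in-bed/pre-bed
# mean ratio equals (1 + bed_penalty) exactly.

#' Latency generating model for one parameter
#'
#' @param baseline_ms Location of the lognormal latency at no modulation.
#' @param diurnal_amplitude Fractional amplitude of the time-of-day
#'   modulation (location multiplier `1 + a cos(...)`).
#' @param diurnal_acrophase_h Clock hour of *slowest* performance (the
#'   fastest hour is 12 h away).
#' @param bed_penalty Fractional slowing while in the actigraphy-defined
#'   sleep window.
#' @param inertia_penalty Fractional slowing immediately after waking,
#'   decaying exponentially.
#' @param inertia_decay_min Exponential decay constant of sleep inertia,
#'   minutes.
#' @param sigma Lognormal noise sigma.
#' @return A validated list.
#' @export
latency_model <- function(baseline_ms, diurnal_amplitude = 0.1,
                          diurnal_acrophase_h = 4, bed_penalty = 0,
                          inertia_penalty = 0.1, inertia_decay_min = 45,
                          sigma = 0.3) {
  stopifnot(baseline_ms > 0, diurnal_amplitude >= 0, diurnal_amplitude < 1,
            bed_penalty >= 0, inertia_penalty >= 0, inertia_decay_min > 0,
            sigma >= 0)
  list(baseline_ms = baseline_ms, diurnal_amplitude = diurnal_amplitude,
       diurnal_acrophase_h = diurnal_acrophase_h, bed_penalty = bed_penalty,
       inertia_penalty = inertia_penalty,
       inertia_decay_min = inertia_decay_min, sigma = sigma)
}

#' Synthetic cohort configuration
#'
#' Defaults state the emulated world: 21-day recordings, a touch process of
#' 60 touches/h at the waking mean with an 80% diurnal modulation peaking
#' mid-afternoon and a 20% weekly modulation peaking midweek, ~23:30--07:30
#' sleep with 30-min night-to-night jitter and a 60-min weekend delay,
#' latency baselines of 300/2000/1200 ms (TS/US/ALS) with 10% diurnal
#' modulation slowest near 04:00, a 20% in-bed penalty on US, and actigraphy
#' counts high-mean in wake and near zero in sleep.
#'
#' @param n_subjects Number of subjects.
#' @param days Recording length in days.
#' @param base_rate_per_h Mean waking touch intensity (touches/h).
#' @param diurnal_amplitude,diurnal_acrophase_h Touch-intensity diurnal
#'   modulation (fraction in `[0, 1)`) and its peak clock hour.
#' @param weekly_amplitude,weekly_peak_day Touch-intensity weekly modulation
#'   and its peak day (0 = Mon ... 6 = Sun).
#' @param latency Named list of [latency_model]s for `TS`, `US`, `ALS`.
#' @param sleep_onset_h,sleep_offset_h Mean local onset/offset clock hours.
#' @param sleep_jitter_min Night-to-night SD of onset and offset, minutes.
#' @param weekend_shift_min Delay of onset/offset on Friday and Saturday
#'   nights, minutes.
#' @param p_inbed_use Probability per night of at least one in-bed phone-use
#'   bout (0--3 bouts at physical rest).
#' @param wake_count_mean,wake_count_shape Gamma model of waking activity
#'   counts per minute.
#' @param sleep_count_mean Mean of the (exponential) sleeping counts.
#' @param activity_diurnal_amplitude,activity_acrophase_h Diurnal modulation
#'   of the waking count mean.
#' @param activity_weekly_amplitude,activity_weekly_peak_day Weekly
#'   modulation of the waking count mean (default peaks Saturday).
#' @param lux_day,lux_night Day plateau and night floor of luminescence.
#' @param lux_sigma Lognormal noise sigma of lux.
#' @param session_gap_s Touch gaps above this start a new phone session
#'   (each session carries one unlock episode).
#' @param p_home Probability a session includes a home-screen app launch.
#' @param rate_log_sd Between-subject SD of log touch rate.
#' @param phase_sd_h Between-subject SD (hours) of a common phase shift
#'   applied to all of a subject's acrophases.
#' @param seed Master seed; per-subject seeds derive deterministically.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 20,
                         days = 21,
                         base_rate_per_h = 60,
                         diurnal_amplitude = 0.8,
                         diurnal_acrophase_h = 15,
                         weekly_amplitude = 0.2,
                         weekly_peak_day = 2,
                         latency = list(
                           TS = latency_model(300, bed_penalty = 0.05),
                           US = latency_model(2000, bed_penalty = 0.2),
                           ALS = latency_model(1200, bed_penalty = 0,
                                               inertia_penalty = 0.05)),
                         sleep_onset_h = 23.5,
                         sleep_offset_h = 7.5,
                         sleep_jitter_min = 30,
                         weekend_shift_min = 60,
                         p_inbed_use = 0.8,
                         wake_count_mean = 50,
                         wake_count_shape = 2,
                         sleep_count_mean = 0.5,
                         activity_diurnal_amplitude = 0.3,
                         activity_acrophase_h = 14,
                         activity_weekly_amplitude = 0.2,
                         activity_weekly_peak_day = 5,
                         lux_day = 500,
                         lux_night = 1,
                         lux_sigma = 0.3,
                         session_gap_s = 60,
                         p_home = 0.7,
                         rate_log_sd = 0.2,
                         phase_sd_h = 1,
                         seed = 1L) {
  stopifnot(n_subjects >= 1, days >= 1, base_rate_per_h >= 0,
            diurnal_amplitude >= 0, diurnal_amplitude < 1,
            weekly_amplitude >= 0, weekly_amplitude < 1,
            all(c("TS", "US", "ALS") %in% names(latency)),
            sleep_jitter_min >= 0, weekend_shift_min >= 0,
            p_inbed_use >= 0, p_inbed_use <= 1,
            wake_count_mean > 0, wake_count_shape > 0, sleep_count_mean > 0,
            lux_day > lux_night, lux_night >= 0,
            session_gap_s > 0, p_home >= 0, p_home <= 1,
            rate_log_sd >= 0, phase_sd_h >= 0)
  if (base_rate_per_h == 0 && p_inbed_use > 0)
    stop("zero base touch rate is incompatible with in-bed phone use")
  if (((sleep_offset_h - sleep_onset_h) %% 24) <= 0)
    stop("sleep onset must precede offset modulo 24 h")
  structure(as.list(environment()), class = "synth_config")
}

# recording origin: a Monday local midnight (Unix day 4 = 1970-01-05)
SYNTH_T0 <- 4 * 86400

# deterministic per-subject seed below 2^31
subject_seed <- function(master, index) {
  (as.numeric(master) + 1000003 * index) %% 2147483629
}

#' Generate one synthetic subject
#'
#' @param cfg A [synth_config].
#' @param subject_index 1-based subject index (determines the subject seed).
#' @return List with `events` ([event_stream]), `wearable`
#'   ([wearable_series]) and `truth` (every realized generating parameter
#'   plus the per-night sleep table).
#' @export
generate_subject <- function(cfg, subject_index = 1) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(subject_seed(cfg$seed, subject_index))
  sid <- sprintf("synth%03d", subject_index)
  t0 <- SYNTH_T0
  t_end <- t0 + cfg$days * 86400

  # subject-level realized parameters
  phase_shift <- stats::rnorm(1, 0, cfg$phase_sd_h)
  base_rate <- cfg$base_rate_per_h * exp(stats::rnorm(1, 0, cfg$rate_log_sd))
  touch_acro <- (cfg$diurnal_acrophase_h + phase_shift) %% 24
  lat <- lapply(cfg$latency, function(m) {
    m$diurnal_acrophase_h <- (m$diurnal_acrophase_h + phase_shift) %% 24
    m
  })

  # ---- sleep schedule -------------------------------------------------------
  dur_h <- (cfg$sleep_offset_h - cfg$sleep_onset_h) %% 24
  nights <- lapply(seq(-1, cfg$days - 1), function(d) {
    onset <- t0 + d * 86400 + cfg$sleep_onset_h * 3600 +
      stats::rnorm(1, 0, cfg$sleep_jitter_min * 60)
    offset <- t0 + d * 86400 + (cfg$sleep_onset_h + dur_h) * 3600 +
      stats::rnorm(1, 0, cfg$sleep_jitter_min * 60)
    if (weekday_index(onset) %in% c(4, 5)) {      # Fri/Sat night: later
      onset <- onset + cfg$weekend_shift_min * 60
      offset <- offset + cfg$weekend_shift_min * 60
    }
    c(onset, offset)
  })
  onsets <- vapply(nights, `[`, numeric(1), 1)
  offsets <- vapply(nights, `[`, numeric(1), 2)
  truth_sleep <- data.frame(night_index = seq(-1, cfg$days - 1),
                            onset = onsets, offset = offsets)
  onsets_c <- pmax(onsets, t0); offsets_c <- pmin(offsets, t_end)
  keepn <- offsets_c > onsets_c
  onsets_c <- onsets_c[keepn]; offsets_c <- offsets_c[keepn]

  in_bed <- function(t) {
    i <- findInterval(t, onsets_c)
    i >= 1 & t < c(offsets_c, Inf)[pmax(i, 1)] & i <= length(offsets_c)
  }
  mins_since_wake <- function(t) {
    i <- findInterval(t, offsets_c)
    out <- rep(Inf, length(t))
    ok <- i >= 1
    out[ok] <- (t[ok] - offsets_c[i[ok]]) / 60
    out[in_bed(t)] <- Inf
    out
  }

  # latency draws (ms) for parameter `param` at times `t`
  draw_latency <- function(param, t) {
    m <- lat[[param]]
    h <- clock_hour(t)
    mult <- 1 + m$diurnal_amplitude *
      cos(2 * pi * (h - m$diurnal_acrophase_h) / 24)
    mult <- mult * (1 + m$bed_penalty * in_bed(t))
    mult <- mult * (1 + m$inertia_penalty *
                      exp(-mins_since_wake(t) / m$inertia_decay_min))
    m$baseline_ms * mult * exp(m$sigma * stats::rnorm(length(t)))
  }

  # ---- wake touch process (inhomogeneous Poisson by thinning) ---------------
  lambda <- function(t) {        # touches per hour at time t (wake)
    h <- clock_hour(t)
    d7 <- (t - t0) / 86400
    pmax(0, base_rate *
           (1 + cfg$diurnal_amplitude *
              cos(2 * pi * (h - touch_acro) / 24)) *
           (1 + cfg$weekly_amplitude *
              cos(2 * pi * (d7 - cfg$weekly_peak_day) / 7)))
  }
  lam_max <- base_rate * (1 + cfg$diurnal_amplitude) *
    (1 + cfg$weekly_amplitude)
  bounds <- sort(c(t0, t_end, onsets_c, offsets_c))
  wake_iv <- cbind(bounds[-length(bounds)], bounds[-1])
  wake_iv <- wake_iv[!in_bed((wake_iv[, 1] + wake_iv[, 2]) / 2) &
                       wake_iv[, 2] > wake_iv[, 1], , drop = FALSE]
  touches <- unlist(apply(wake_iv, 1, function(iv) {
    len_h <- (iv[2] - iv[1]) / 3600
    n_cand <- stats::rpois(1, lam_max * len_h)
    if (n_cand == 0) return(numeric(0))
    tc <- sort(stats::runif(n_cand, iv[1], iv[2]))
    tc[stats::runif(n_cand) < lambda(tc) / lam_max]
  }))
  touches <- sort(touches)

  # ---- sessions: split at gaps, re-draw intra-session gaps from TS model ---
  make_session <- function(t_start, n_touch, bed_bout = FALSE) {
    gaps <- if (n_touch > 1) draw_latency("TS", rep(t_start, n_touch - 1)) / 1000
            else numeric(0)
    tt <- t_start + c(0, cumsum(gaps))
    us <- draw_latency("US", t_start)
    ev_t <- c(t_start - us / 1000 - 0.1, t_start - 0.1)
    ev_k <- c("screen_on", "unlock_complete")
    if (stats::runif(1) < cfg$p_home) {
      als <- draw_latency("ALS", t_start)
      ev_t <- c(t_start - als / 1000 - 0.3 - us / 1000 - 0.1,
                t_start - als / 1000 - 0.3 - 0.1,
                t_start - als / 1000 - 0.05, t_start - 0.05)
      ev_k <- c("screen_on", "unlock_complete", "home_shown", "app_launch")
    }
    list(t = c(ev_t, tt, max(tt) + 1),
         k = c(ev_k, rep("touch", n_touch), "screen_off"))
  }

  sess_events <- list()
  if (length(touches)) {
    brk <- c(0, which(diff(touches) > cfg$session_gap_s), length(touches))
    for (j in seq_len(length(brk) - 1)) {
      idx <- (brk[j] + 1):brk[j + 1]
      sess_events[[j]] <- make_session(touches[idx[1]], length(idx))
    }
  }

  # ---- in-bed use bouts at physical rest ------------------------------------
  n_bouts_total <- 0L
  for (i in seq_along(onsets_c)) {
    if (stats::runif(1) >= cfg$p_inbed_use) next
    slack <- offsets_c[i] - onsets_c[i] - 900
    if (slack <= 300) next    # truncated night: too short for a use bout
    n_b <- sample.int(3, 1)
    starts <- onsets_c[i] + stats::runif(n_b, 300, pmin(slack, 2 * 3600))
    for (s in starts) {
      n_touch <- 5 + stats::rpois(1, 10)
      sess_events[[length(sess_events) + 1]] <- make_session(s, n_touch,
                                                             bed_bout = TRUE)
      n_bouts_total <- n_bouts_total + 1L
    }
  }

  ev_t <- unlist(lapply(sess_events, `[[`, "t"))
  ev_k <- unlist(lapply(sess_events, `[[`, "k"))
  events <- event_stream(ev_t, ev_k, subject_id = sid, utc_offset = 0)

  # ---- wearable: activity counts + lux --------------------------------------
  ep <- seq(t0, t_end - 60, by = 60)
  asleep <- in_bed(ep + 30)
  h <- clock_hour(ep)
  d7 <- (ep - t0) / 86400
  wake_mean <- cfg$wake_count_mean *
    (1 + cfg$activity_diurnal_amplitude *
       cos(2 * pi * (h - cfg$activity_acrophase_h) / 24)) *
    (1 + cfg$activity_weekly_amplitude *
       cos(2 * pi * (d7 - cfg$activity_weekly_peak_day) / 7))
  counts <- numeric(length(ep))
  counts[!asleep] <- stats::rgamma(sum(!asleep), shape = cfg$wake_count_shape,
                                   scale = wake_mean[!asleep] /
                                     cfg$wake_count_shape)
  counts[asleep] <- stats::rexp(sum(asleep), rate = 1 / cfg$sleep_count_mean)
  lux_mean <- cfg$lux_night + (cfg$lux_day - cfg$lux_night) *
    pmax(0, cos(2 * pi * (h - 13) / 24))^2
  lux <- lux_mean * exp(cfg$lux_sigma * stats::rnorm(length(ep)))
  wear <- wearable_series(ep, counts = counts, lux = lux, epoch_s = 60,
                          subject_id = sid, utc_offset = 0)

  truth <- list(subject_id = sid, seed = subject_seed(cfg$seed, subject_index),
                base_rate_per_h = base_rate,
                phase_shift_h = phase_shift,
                touch_acrophase_h = touch_acro,
                weekly_amplitude = cfg$weekly_amplitude,
                weekly_peak_day = cfg$weekly_peak_day,
                latency = lat,
                sleep = truth_sleep,
                n_inbed_bouts = n_bouts_total,
                t0 = t0, t_end = t_end)
  list(events = events, wearable = wear, truth = truth)
}

#' Generate a synthetic cohort
#'
#' Reproducible given the master seed: each subject's stream depends only on
#' the master seed and its index.
#'
#' @param cfg A [synth_config].
#' @return List of class `synth_cohort`: `subjects` (list of
#'   [generate_subject] triples) and `truth` (list of per-subject truth
#'   records).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  subjects <- lapply(seq_len(cfg$n_subjects),
                     function(i) generate_subject(cfg, i))
  structure(list(subjects = subjects,
                 truth = lapply(subjects, `[[`, "truth")),
            class = "synth_cohort")
}

#' Write a synthetic cohort to the package's CSV dialects
#'
#' One events CSV and one wearable CSV per subject, plus `truth.json`.
#'
#' @param cohort A `synth_cohort`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in cohort$subjects) {
    sid <- attr(s$events, "subject_id")
    write_event_stream(s$events, file.path(dir, paste0(sid, "_events.csv")))
    write_wearable(s$wearable, file.path(dir, paste0(sid, "_wearable.csv")))
  }
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(dir)
}
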