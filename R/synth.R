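# Parse "HH:MM" / "HH:MM:SS" to seconds since local midnight.
tod_seconds <- function(x) {
  if (is.numeric(x)) return(x)
  p <- as.integer(strsplit(x, ":", fixed = TRUE)[[1]])
  if (length(p) == 2L) p <- c(p, 0L)
  p[1] * 3600 + p[2] * 60 + p[3]
}

in_any_interval <- function(sec, intervals) {
  for (iv in intervals) {
    if (sec >= tod_seconds(iv$start) && sec < tod_seconds(iv$end)) return(iv)
  }
  NULL
}

#' Configure the daily-schedule simulator
#'
#' The simulator draws a participant's day from a latent routine: she is at
#' home except during configured trips, with her infant except during
#' separation episodes, still except during activity bouts, and speech
#' occurs in her environment during speech episodes with a per-clip
#' probability. Sensors sample this routine the way the collector app does:
#' proximity scans, activity readings and 30-second audio clips on a fixed
#' cadence, and GPS fixes at phone-use events drawn from a Poisson process.
#'
#' The default audio capture window spans 10 daytime hours, so at the
#' 15-minute cadence a day yields 40 clips and a week 280.
#'
#' @param seed integer seed; identical seeds give identical output.
#' @param participant_id participant code (collector convention).
#' @param start_date first simulated `Date`.
#' @param n_days number of days, default 7.
#' @param interval_min sampling cadence in minutes for proximity, activity
#'   and audio, default 15.
#' @param audio_window `c(start, end)` times of day bounding audio capture.
#' @param clip_duration_s audio clip length in seconds, default 30.
#' @param home `c(lat, lon)` of the home in decimal degrees.
#' @param beacon_id infant beacon identifier written into proximity records.
#' @param trips list of `list(start, end, dest_offset_m = c(north, east))`
#'   away-from-home episodes.
#' @param separations list of `list(start, end)` mother-infant separation
#'   episodes (scans complete but do not detect the beacon).
#' @param speech_episodes list of `list(start, end, p)` windows in which each
#'   clip contains speech with probability `p`.
#' @param activity_bouts list of `list(start, end, label)` not-still bouts.
#' @param dropout named per-sensor outage probabilities in `[0, 1)`: each
#'   (sensor, hour) of the day independently loses all its records with this
#'   rate, emulating contiguous collection gaps.
#' @param gps_rate_awake,gps_rate_night phone-use event rates (fixes/hour).
#' @param awake half-open `c(start, end)` times of day treated as awake.
#' @param gps_jitter_m standard deviation of per-fix position noise, meters.
#' @param unknown_rate probability an activity reading is `unknown`.
#' @return an object of class `schedule_config`.
#' @export
schedule_config <- function(seed = 1L,
                            participant_id = "SS0001",
                            start_date = as.Date("2019-06-05"),
                            n_days = 7L,
                            interval_min = 15,
                            audio_window = c("08:00", "18:00"),
                            clip_duration_s = 30,
                            home = c(lat = 27.6829, lon = 84.4350),
                            beacon_id = "RB0001",
                            trips = list(list(start = "10:00", end = "12:00",
                                              dest_offset_m = c(north = 800, east = 350))),
                            separations = list(list(start = "13:00", end = "15:00")),
                            speech_episodes = list(
                              list(start = "07:00", end = "09:00", p = 0.9),
                              list(start = "16:00", end = "19:00", p = 0.8)),
                            activity_bouts = list(
                              list(start = "08:00", end = "08:30", label = "walking"),
                              list(start = "17:00", end = "17:30", label = "walking")),
                            dropout = c(gps = 0, proximity = 0, activity = 0, audio = 0),
                            gps_rate_awake = 4,
                            gps_rate_night = 0.2,
                            awake = c("06:00", "22:00"),
                            gps_jitter_m = 8,
                            unknown_rate = 0.02) {
  stopifnot(n_days >= 1, interval_min > 0, clip_duration_s > 0,
            all(dropout >= 0), all(dropout < 1), gps_jitter_m >= 0,
            unknown_rate >= 0, unknown_rate < 1)
  if (tod_seconds(audio_window[1]) >= tod_seconds(audio_window[2])) {
    stop("audio capture window start must precede its end")
  }
  check_iv <- function(ivs, what) {
    for (iv in ivs) {
      s <- tod_seconds(iv$start); e <- tod_seconds(iv$end)
      if (s >= e || s < 0 || e > 86400) stop("invalid ", what, " interval")
    }
  }
  check_iv(trips, "trip"); check_iv(separations, "separation")
  check_iv(speech_episodes, "speech episode"); check_iv(activity_bouts, "activity bout")
  for (ep in speech_episodes) stopifnot(ep$p >= 0, ep$p < 1 || ep$p == 1)
  dropout <- dropout[c("gps", "proximity", "activity", "audio")]
  dropout[is.na(dropout)] <- 0
  names(dropout) <- c("gps", "proximity", "activity", "audio")
  structure(list(seed = as.integer(seed), participant_id = participant_id,
                 start_date = as.Date(start_date), n_days = as.integer(n_days),
                 interval_min = interval_min, audio_window = audio_window,
                 clip_duration_s = clip_duration_s, home = home,
                 beacon_id = beacon_id, trips = trips, separations = separations,
                 speech_episodes = speech_episodes, activity_bouts = activity_bouts,
                 dropout = dropout, gps_rate_awake = gps_rate_awake,
                 gps_rate_night = gps_rate_night, awake = awake,
                 gps_jitter_m = gps_jitter_m, unknown_rate = unknown_rate),
            class = "schedule_config")
}

# meters -> degrees at the home latitude
offset_to_deg <- function(north_m, east_m, lat) {
  c(dlat = north_m / 111320, dlon = east_m / (111320 * cos(lat * pi / 180)))
}

latent_position <- function(config, sec) {
  trip <- in_any_interval(sec, config$trips)
  if (is.null(trip)) {
    c(config$home[["lat"]], config$home[["lon"]], away = 0)
  } else {
    d <- offset_to_deg(trip$dest_offset_m[["north"]], trip$dest_offset_m[["east"]],
                       config$home[["lat"]])
    c(config$home[["lat"]] + d[["dlat"]], config$home[["lon"]] + d[["dlon"]], away = 1)
  }
}

day_seed <- function(config, date) {
  as.integer((config$seed * 100003 + as.integer(as.Date(date)) * 7919) %% 2147483399L)
}

#' Simulate one day of sensor records with ground truth
#'
#' Generates the four record streams for one day of the configured routine,
#' applies per-sensor dropout, and returns the pre-dropout ground truth:
#' per-hour true proximity/activity/speech labels (what a perfect coder
#' would produce from the complete record stream), the true home, and the
#' realized per-day fraction of observed 15-minute bins away from home.
#'
#' @param config a `schedule_config`.
#' @param date the `Date` to simulate; the RNG seed is derived from
#'   `config$seed` and the date, so any day is reproducible in isolation.
#' @return `list(records = list(gps, proximity, activity, audio), truth)`
#'   where `truth` has `hour_labels` (24-row data frame), `home`,
#'   `outside_fraction`, `n_clips`.
#' @export
simulate_day <- function(config, date) {
  stopifnot(inherits(config, "schedule_config"))
  date <- as.Date(date)
  set.seed(day_seed(config, date))
  midnight <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC")
  step <- config$interval_min * 60
  cadence <- seq(0, 86399, by = step)
  pid <- config$participant_id

  # proximity: one completed scan per cadence tick; no detection during separations
  sep <- vapply(cadence, function(s) !is.null(in_any_interval(s, config$separations)),
                logical(1))
  proximity <- data.frame(
    participant_id = pid, timestamp = midnight + cadence,
    beacon_id = config$beacon_id, detected = !sep,
    rssi = ifelse(!sep, round(stats::runif(length(cadence), -75, -55)), NA_real_)
  )
  attr(proximity, "datatype") <- "PROXIMITY"

  # activity: cadence readings labeled by the active bout, else still;
  # a small fraction come back unknown from the recognizer
  act_label <- vapply(cadence, function(s) {
    b <- in_any_interval(s, config$activity_bouts)
    if (is.null(b)) "still" else b$label
  }, character(1))
  unk <- stats::runif(length(cadence)) < config$unknown_rate
  act_label[unk] <- "unknown"
  activity <- data.frame(participant_id = pid, timestamp = midnight + cadence,
                         label = act_label)
  attr(activity, "datatype") <- "ACTIVITY"

  # audio: one clip per cadence tick inside the capture window
  w0 <- tod_seconds(config$audio_window[1]); w1 <- tod_seconds(config$audio_window[2])
  clip_secs <- cadence[cadence >= w0 & cadence < w1]
  background <- c("Music", "Vehicle", "Insects", "Wind")
  audio_rows <- lapply(clip_secs, function(s) {
    ep <- in_any_interval(s, config$speech_episodes)
    rows <- list()
    if (!is.null(ep) && stats::runif(1) < ep$p) {
      rows[[length(rows) + 1L]] <- c("Speech", round(stats::runif(1, 0.6, 0.98), 4))
    }
    if (stats::runif(1) < 0.4) {
      rows[[length(rows) + 1L]] <- c(sample(background, 1),
                                     round(stats::runif(1, 0.5, 0.9), 4))
    }
    if (!length(rows)) rows[[1L]] <- c(NA_character_, NA_real_)  # silent clip
    data.frame(participant_id = pid, clip_start = midnight + s,
               duration = config$clip_duration_s,
               label = vapply(rows, `[`, "", 1L),
               score = as.numeric(vapply(rows, `[`, "", 2L)))
  })
  audio <- do.call(rbind, c(audio_rows,
                            list(empty_records("AUDIO"))))
  attr(audio, "datatype") <- "AUDIO"

  # GPS: Poisson phone-use events, position from the latent schedule + jitter
  awake0 <- tod_seconds(config$awake[1]); awake1 <- tod_seconds(config$awake[2])
  fix_secs <- numeric(0)
  for (h in 0:23) {
    rate <- if (h * 3600 >= awake0 && h * 3600 < awake1) config$gps_rate_awake
            else config$gps_rate_night
    n <- stats::rpois(1, rate)
    if (n > 0) fix_secs <- c(fix_secs, sort(h * 3600 + floor(stats::runif(n, 0, 3600))))
  }
  if (length(fix_secs)) {
    pos <- t(vapply(fix_secs, function(s) latent_position(config, s), numeric(3)))
    jd <- offset_to_deg(config$gps_jitter_m, config$gps_jitter_m, config$home[["lat"]])
    lat <- round(pos[, 1] + stats::rnorm(length(fix_secs), 0, jd[["dlat"]]), 6)
    lon <- round(pos[, 2] + stats::rnorm(length(fix_secs), 0, jd[["dlon"]]), 6)
    gps <- data.frame(participant_id = pid, timestamp = midnight + fix_secs,
                      lat = lat, lon = lon)
    away <- pos[, 3] == 1
  } else {
    gps <- empty_records("GPS")
    away <- logical(0)
  }
  attr(gps, "datatype") <- "GPS"

  truth <- list(
    hour_labels = true_hour_labels(proximity, activity, audio),
    home = config$home,
    outside_fraction = true_outside_fraction(fix_secs, away),
    n_clips = length(clip_secs)
  )

  # Dropout models sensor outages: each (sensor, hour) independently loses
  # all its records with the configured rate. Outages are contiguous the way
  # real collection gaps are (phone off, app killed), and they degrade an
  # hour's code to no_data without ever fabricating a wrong observed state.
  records <- list(gps = gps, proximity = proximity, activity = activity,
                  audio = audio)
  for (sensor in names(records)) {
    rate <- config$dropout[[sensor]]
    if (rate > 0 && nrow(records[[sensor]]) > 0L) {
      out_hours <- (0:23)[stats::runif(24) < rate]
      tscol <- if (sensor == "audio") "clip_start" else "timestamp"
      hrs <- as.POSIXlt(records[[sensor]][[tscol]], tz = "UTC")$hour
      keep <- !(hrs %in% out_hours)
      dt <- attr(records[[sensor]], "datatype")
      records[[sensor]] <- records[[sensor]][keep, , drop = FALSE]
      rownames(records[[sensor]]) <- NULL
      attr(records[[sensor]], "datatype") <- dt
    }
  }
  list(records = records, truth = truth)
}

# True hour labels from the complete (pre-dropout) record stream, computed
# directly per hour without the 15-minute grid.
true_hour_labels <- function(proximity, activity, audio) {
  hr <- function(ts) as.POSIXlt(ts, tz = "UTC")$hour
  ph <- hr(proximity$timestamp); ah <- hr(activity$timestamp)
  sh <- hr(audio$clip_start)
  lab <- data.frame(hour = 0:23, proximity = "no_data", activity = "no_data",
                    speech = "no_data")
  for (h in 0:23) {
    p <- proximity[ph == h, , drop = FALSE]
    if (nrow(p)) lab$proximity[h + 1] <- if (any(p$detected)) "together" else "apart"
    a <- setdiff(activity$label[ah == h], "unknown")
    if (length(a)) {
      lab$activity[h + 1] <- if (any(a %in% ACTIVE_LABELS)) "active" else "inactive"
    }
    s <- audio[sh == h, , drop = FALSE]
    if (nrow(s)) {
      qual <- !is.na(s$label) & s$label == "Speech" & !is.na(s$score) & s$score >= 0.5
      lab$speech[h + 1] <- if (any(qual)) "speech" else "no_speech"
    }
  }
  lab
}

# Realized outside fraction: among 15-minute bins with at least one fix, the
# fraction whose last fix was drawn away from home in the latent schedule.
true_outside_fraction <- function(fix_secs, away) {
  if (!length(fix_secs)) return(NA_real_)
  bins <- floor(fix_secs / 900)
  last_away <- tapply(away, bins, function(a) a[length(a)])
  mean(unlist(last_away))
}

#' Simulate a week and write it as an inbound folder
#'
#' Writes one GPS, one PROXIMITY and one ACTIVITY file per day plus the
#' weekly audio-prediction table, all named in the collector convention, so
#' the folder can be ingested by [scan_inbound()] exactly like device data.
#'
#' @param config a `schedule_config`.
#' @param dir output folder (created if needed).
#' @return `list(dir, files, truth, config)` invisibly; `truth` is a named
#'   (by date) list of per-day ground truths.
#' @export
simulate_week <- function(config, dir) {
  stopifnot(inherits(config, "schedule_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dates <- config$start_date + seq_len(config$n_days) - 1L
  truth <- list()
  files <- character(0)
  audio_all <- empty_records("AUDIO")
  for (d in seq_along(dates)) {
    day <- simulate_day(config, dates[d])
    truth[[format(dates[d])]] <- day$truth
    for (sensor in c("gps", "proximity", "activity")) {
      meta <- write_sensor_file(day$records[[sensor]], dir,
                                datatype = toupper(sensor),
                                participant_id = config$participant_id,
                                date = dates[d])
      files <- c(files, build_sensor_filename(meta))
    }
    audio_all <- rbind(audio_all, day$records$audio)
  }
  attr(audio_all, "datatype") <- "AUDIO"
  meta <- write_sensor_file(audio_all, dir, datatype = "AUDIO",
                            participant_id = config$participant_id)
  files <- c(files, build_sensor_filename(meta))
  invisible(list(dir = dir, files = files, truth = truth, config = config))
}

#' Load a simulator scenario from a YAML file
#'
#' Top-level keys mirror the [schedule_config()] arguments.
#'
#' @param path YAML file.
#' @param seed optional seed overriding the file's.
#' @return a `schedule_config`.
#' @export
read_scenario <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$home)) raw$home <- unlist(raw$home)
  if (!is.null(raw$dropout)) raw$dropout <- unlist(raw$dropout)
  if (!is.null(raw$audio_window)) raw$audio_window <- unlist(raw$audio_window)
  if (!is.null(raw$awake)) raw$awake <- unlist(raw$awake)
  if (!is.null(raw$start_date)) raw$start_date <- as.Date(raw$start_date)
  for (f in c("trips", "separations", "speech_episodes", "activity_bouts")) {
    if (!is.null(raw[[f]])) {
      raw[[f]] <- lapply(raw[[f]], function(iv) {
        if (!is.null(iv$dest_offset_m)) iv$dest_offset_m <- unlist(iv$dest_offset_m)
        iv
      })
    }
  }
  if (!is.null(seed)) raw$seed <- seed
  do.call(schedule_config, raw)
}
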