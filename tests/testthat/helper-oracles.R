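# Test-side oracles, independent of the package's 15-minute-grid path:
# everything here scans raw records per hour directly.

ACTIVE_SET <- c("walking", "running", "in_vehicle", "cycling")

hour_of <- function(ts) as.POSIXlt(ts, tz = "UTC")$hour

# Brute-force daily coder straight from raw record tables.
bf_code_day <- function(records, date, speech_classes = "Speech", threshold = 0.5) {
  date <- as.Date(date)
  on_date <- function(df, col) df[as.Date(df[[col]]) == date, , drop = FALSE]
  prox <- on_date(records$proximity, "timestamp")
  act <- on_date(records$activity, "timestamp")
  aud <- on_date(records$audio, "clip_start")
  out <- data.frame(hour = 0:23, proximity = "no_data", activity = "no_data",
                    speech = "no_data")
  for (h in 0:23) {
    p <- prox[hour_of(prox$timestamp) == h, , drop = FALSE]
    if (nrow(p)) out$proximity[h + 1] <- if (any(p$detected)) "together" else "apart"
    labs <- setdiff(act$label[hour_of(act$timestamp) == h], "unknown")
    if (length(labs)) {
      out$activity[h + 1] <- if (any(labs %in% ACTIVE_SET)) "active" else "inactive"
    }
    s <- aud[hour_of(aud$clip_start) == h, , drop = FALSE]
    if (nrow(s)) {
      q <- !is.na(s$label) & s$label %in% speech_classes &
        !is.na(s$score) & s$score >= threshold
      out$speech[h + 1] <- if (any(q)) "speech" else "no_speech"
    }
  }
  out
}

# Naive mobility recomputations (plain loops, planar-free haversine copy of
# the textbook formula rather than the package path).
bf_haversine <- function(lat1, lon1, lat2, lon2, r = 6371000) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

bf_radius <- function(fixes) {
  if (nrow(fixes) == 0) return(NA_real_)
  la <- fixes$lat * pi / 180
  lo <- fixes$lon * pi / 180
  x <- mean(cos(la) * cos(lo)); y <- mean(cos(la) * sin(lo)); z <- mean(sin(la))
  clat <- atan2(z, sqrt(x^2 + y^2)) * 180 / pi
  clon <- atan2(y, x) * 180 / pi
  d <- numeric(nrow(fixes))
  for (i in seq_len(nrow(fixes))) {
    d[i] <- bf_haversine(fixes$lat[i], fixes$lon[i], clat, clon)
  }
  sqrt(mean(d^2))
}

bf_farthest <- function(fixes, home) {
  m <- -Inf
  for (i in seq_len(nrow(fixes))) {
    m <- max(m, bf_haversine(fixes$lat[i], fixes$lon[i], home$lat, home$lon))
  }
  m
}

bf_fraction_outside <- function(fixes, home, radius_m = 100) {
  if (nrow(fixes) == 0) return(NA_real_)
  fixes <- fixes[order(fixes$timestamp), , drop = FALSE]
  lt <- as.POSIXlt(fixes$timestamp, tz = "UTC")
  bins <- (lt$hour * 60 + lt$min) %/% 15
  outside <- logical(0)
  for (b in unique(bins)) {
    rows <- which(bins == b)
    i <- rows[length(rows)]
    outside <- c(outside, bf_haversine(fixes$lat[i], fixes$lon[i],
                                       home$lat, home$lon) > radius_m)
  }
  mean(outside)
}

# Wrap simulated per-day records as a participant store without the ingest
# path (tables are plain data frames keyed by the schemas).
as_store <- function(records, participant_id = "SS0001") {
  store <- participant_store(participant_id)
  store$tables$gps <- records$gps
  store$tables$proximity <- records$proximity
  store$tables$activity <- records$activity
  store$tables$audio <- records$audio
  store
}

# A randomized one-day routine: episode boundaries land on arbitrary
# minutes, so grid-vs-direct coding is exercised off the hour lattice.
random_day_config <- function(seed, dropout = NULL) {
  set.seed(seed)
  rand_iv <- function() {
    start <- sample(0:1350, 1)
    end <- min(1440, start + sample(15:240, 1))
    list(start = sprintf("%02d:%02d", start %/% 60, start %% 60),
         end = sprintf("%02d:%02d", end %/% 60, end %% 60))
  }
  n_iv <- function(n) lapply(seq_len(sample(0:n, 1)), function(i) rand_iv())
  speech <- lapply(n_iv(3), function(iv) c(iv, list(p = round(runif(1, 0.3, 0.95), 2))))
  bouts <- lapply(n_iv(3), function(iv) c(iv, list(label = sample(ACTIVE_SET, 1))))
  if (is.null(dropout)) dropout <- round(runif(4, 0, 0.4), 2)
  schedule_config(
    seed = seed, n_days = 1L,
    trips = lapply(n_iv(2), function(iv) {
      c(iv, list(dest_offset_m = c(north = sample(200:3000, 1),
                                   east = sample(-2000:2000, 1))))
    }),
    separations = n_iv(3),
    speech_episodes = speech,
    activity_bouts = bouts,
    dropout = c(gps = dropout[1], proximity = dropout[2],
                activity = dropout[3], audio = dropout[4]),
    unknown_rate = 0.05
  )
}

# Offset a point by meters (small-offset equirectangular construction, used
# to build fixtures at known distances).
offset_point <- function(lat, lon, north_m, east_m) {
  c(lat = lat + north_m / 111320, lon = lon + east_m / (111320 * cos(lat * pi / 180)))
}

make_gps <- function(secs, lat, lon, date = as.Date("2019-06-05"), pid = "SS0001") {
  midnight <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC")
  data.frame(participant_id = rep(pid, length(secs)), timestamp = midnight + secs,
             lat = rep_len(lat, length(secs)), lon = rep_len(lon, length(secs)))
}
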