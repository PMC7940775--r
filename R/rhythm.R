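# Hour coding enums. Three states per channel: the counselor charts
# distinguish "apart"/"inactive"/"no speech" from hours with no data at all.
PROXIMITY_STATES <- c("together", "apart", "no_data")
ACTIVITY_STATES <- c("active", "inactive", "no_data")
SPEECH_STATES <- c("speech", "no_speech", "no_data")
ACTIVE_LABELS <- c("walking", "running", "in_vehicle", "cycling")

#' 15-minute bin index of a timestamp
#'
#' Bin `k` covers the half-open interval `[k*15, (k+1)*15)` minutes from
#' local midnight, so a day is 96 bins and `23:59:59` falls in bin 95.
#'
#' @param ts POSIXct vector (local clock).
#' @return integer vector in `0..95`.
#' @export
bin_index <- function(ts) {
  lt <- as.POSIXlt(ts, tz = "UTC")
  (lt$hour * 60L + lt$min) %/% 15L
}

#' Build one day's 15-minute grid for a sensor channel
#'
#' Quantizes a record stream down to the 96-bin 15-minute level, keeping
#' missing data explicit: a bin with zero records is `missing`, never
#' silently imputed. Per-bin values by channel: `proximity` — was the beacon
#' detected in any scan in the bin; `activity` — the set of labels observed;
#' `speech` — the clip label rows starting in the bin; `gps_presence` — the
#' fix count.
#'
#' @param records a record data frame of the matching datatype (off-date rows
#'   are ignored).
#' @param date the `Date` of the grid.
#' @param channel one of `"proximity"`, `"activity"`, `"speech"`,
#'   `"gps_presence"`.
#' @return an object of class `day_grid`: list with `participant_id`, `date`,
#'   `channel`, `observed` (logical 96) and `values` (list of 96 per-bin
#'   aggregates, `NULL` where missing).
#' @export
build_day_grid <- function(records, date, channel) {
  channel <- match.arg(channel, c("proximity", "activity", "speech", "gps_presence"))
  date <- as.Date(date)
  tscol <- if (channel == "speech") "clip_start" else "timestamp"
  if (!tscol %in% names(records)) {
    stop("records lack a ", tscol, " column for channel ", channel)
  }
  pid <- if (nrow(records)) records$participant_id[1] else NA_character_
  records <- records[as.Date(records[[tscol]]) == date, , drop = FALSE]
  idx <- bin_index(records[[tscol]])
  observed <- logical(96)
  values <- vector("list", 96)
  for (k in unique(idx)) {
    rows <- records[idx == k, , drop = FALSE]
    observed[k + 1L] <- TRUE
    values[[k + 1L]] <- switch(channel,
      proximity = any(rows$detected),
      activity = unique(rows$label),
      speech = rows[c("clip_start", "label", "score")],
      gps_presence = nrow(rows)
    )
  }
  structure(list(participant_id = pid, date = date, channel = channel,
                 observed = observed, values = values),
            class = "day_grid")
}

#' @export
print.day_grid <- function(x, ...) {
  cat("<day_grid>", x$channel, format(x$date), "-",
      sum(x$observed), "/96 bins observed\n")
  invisible(x)
}

hour_slice <- function(grid, hour) {
  k <- hour * 4L + 1:4
  list(values = grid$values[k], observed = grid$observed[k])
}

#' Code one hour of proximity scans
#'
#' An hour is `together` when at least one scan in it detected the infant's
#' beacon; `apart` when scans completed but none detected it; `no_data` when
#' no scan ran.
#'
#' @param values list of 4 per-bin values (logical any-detected), `NULL`
#'   where missing.
#' @param observed logical vector of 4.
#' @return `"together"`, `"apart"` or `"no_data"`.
#' @export
code_proximity_hour <- function(values, observed) {
  stopifnot(length(values) == 4L, length(observed) == 4L)
  det <- vapply(seq_len(4L), function(i) isTRUE(values[[i]]), logical(1))
  if (any(observed & det)) "together"
  else if (any(observed)) "apart"
  else "no_data"
}

#' Code one hour of activity labels
#'
#' `active` when any reading in the hour is not-still (walking, running,
#' in_vehicle, cycling); `inactive` when readings exist but all observed
#' labels are `still`; `unknown` labels carry no evidence either way, so an
#' hour with only `unknown` readings is `no_data`.
#'
#' @param values list of 4 character vectors of observed labels.
#' @param observed logical vector of 4.
#' @export
code_activity_hour <- function(values, observed) {
  stopifnot(length(values) == 4L, length(observed) == 4L)
  labels <- unlist(values[observed])
  labels <- setdiff(labels, "unknown")
  if (any(labels %in% ACTIVE_LABELS)) "active"
  else if (length(labels)) "inactive"
  else "no_data"
}

#' Code one hour of audio clip predictions
#'
#' `speech` when at least one 30-second clip in the hour carries a
#' speech-class label at or above the score threshold; `no_speech` when clips
#' exist but none qualifies; `no_data` when no clip was captured.
#'
#' @param values list of 4 data frames of clip label rows
#'   (`clip_start,label,score`).
#' @param observed logical vector of 4.
#' @param speech_classes sound-class labels counted as speech.
#' @param threshold minimum prediction score, default 0.5.
#' @export
code_speech_hour <- function(values, observed, speech_classes = "Speech",
                             threshold = 0.5) {
  stopifnot(length(values) == 4L, length(observed) == 4L)
  if (!any(observed)) return("no_data")
  rows <- do.call(rbind, values[observed])
  qual <- !is.na(rows$label) & rows$label %in% speech_classes &
    !is.na(rows$score) & rows$score >= threshold
  if (any(qual)) "speech" else "no_speech"
}

clip_qualifies <- function(audio, speech_classes = "Speech", threshold = 0.5) {
  qual_row <- !is.na(audio$label) & audio$label %in% speech_classes &
    !is.na(audio$score) & audio$score >= threshold
  tapply(qual_row, format_timestamp(audio$clip_start), any)
}

#' Daily speech count percentage
#'
#' The fraction (as a percentage) of a day's audio clips in which speech was
#' detected — a proxy for social interaction in the mother's environment. A
#' clip counts as speech when any of its sound-class labels is in
#' `speech_classes` with score at or above `threshold`.
#'
#' @param audio AUDIO records for one participant-day (one row per clip
#'   label; multi-label clips contribute one clip).
#' @inheritParams code_speech_hour
#' @return percentage in `[0, 100]`, or `NA` when the day has no clips.
#' @export
speech_percentage <- function(audio, speech_classes = "Speech", threshold = 0.5) {
  if (nrow(audio) == 0L) return(NA_real_)
  qual <- clip_qualifies(audio, speech_classes, threshold)
  100 * sum(qual) / length(qual)
}

#' Code a full day from a participant store
#'
#' Runs the three hour coders over the day's 15-minute grids, producing the
#' 24 hour codes for proximity, activity and speech plus the daily speech
#' count percentage. An empty day codes every hour `no_data` with a missing
#' speech percentage.
#'
#' @param store a `participant_store` (see [scan_inbound()]).
#' @param date the `Date` to code.
#' @inheritParams code_speech_hour
#' @return an object of class `daily_codes`: a 24-row data frame
#'   (`hour`, `proximity`, `activity`, `speech`) with attributes
#'   `participant_id`, `date` and `speech_pct`.
#' @export
code_day <- function(store, date, speech_classes = "Speech", threshold = 0.5) {
  stopifnot(inherits(store, "participant_store"))
  date <- as.Date(date)
  gp <- build_day_grid(store$tables$proximity, date, "proximity")
  ga <- build_day_grid(store$tables$activity, date, "activity")
  gs <- build_day_grid(store$tables$audio, date, "speech")
  codes <- data.frame(
    hour = 0:23,
    proximity = vapply(0:23, function(h) {
      s <- hour_slice(gp, h); code_proximity_hour(s$values, s$observed)
    }, character(1)),
    activity = vapply(0:23, function(h) {
      s <- hour_slice(ga, h); code_activity_hour(s$values, s$observed)
    }, character(1)),
    speech = vapply(0:23, function(h) {
      s <- hour_slice(gs, h)
      code_speech_hour(s$values, s$observed, speech_classes, threshold)
    }, character(1))
  )
  day_audio <- store$tables$audio[as.Date(store$tables$audio$clip_start) == date, ,
                                  drop = FALSE]
  structure(codes,
            participant_id = store$participant_id, date = date,
            speech_pct = speech_percentage(day_audio, speech_classes, threshold),
            class = c("daily_codes", "data.frame"))
}

#' @export
print.daily_codes <- function(x, ...) {
  cat("<daily_codes>", attr(x, "participant_id"), format(attr(x, "date")), "\n")
  for (ch in c("proximity", "activity", "speech")) {
    tab <- table(factor(x[[ch]], levels = get(switch(ch,
      proximity = "PROXIMITY_STATES", activity = "ACTIVITY_STATES",
      speech = "SPEECH_STATES"))))
    cat(sprintf("  %-9s %s\n", ch,
                paste(names(tab), tab, sep = "=", collapse = " ")))
  }
  sp <- attr(x, "speech_pct")
  cat("  speech_pct:", if (is.na(sp)) "missing" else sprintf("%.1f%%", sp), "\n")
  invisible(x)
}

#' Counts behind the daily proximity bar chart
#'
#' The counselor-facing proximity chart shows hours together with the child,
#' apart, and without data; the three counts always sum to 24.
#'
#' @param codes a `daily_codes` object.
#' @return named integer vector `(together, apart, no_data)`.
#' @export
proximity_chart_data <- function(codes) {
  tab <- table(factor(codes$proximity, levels = PROXIMITY_STATES))
  stats::setNames(as.integer(tab), PROXIMITY_STATES)
}

#' @rdname proximity_chart_data
#' @export
activity_chart_data <- function(codes) {
  tab <- table(factor(codes$activity, levels = ACTIVITY_STATES))
  stats::setNames(as.integer(tab), ACTIVITY_STATES)
}

#' @rdname proximity_chart_data
#' @export
speech_chart_data <- function(codes) {
  tab <- table(factor(codes$speech, levels = SPEECH_STATES))
  stats::setNames(as.integer(tab), SPEECH_STATES)
}

#' Tidy table of one or more coded days
#'
#' @param codes_list a `daily_codes` or a list of them.
#' @return data frame with columns participant, date, hour, proximity,
#'   activity, speech.
#' @export
codes_to_table <- function(codes_list) {
  if (inherits(codes_list, "daily_codes")) codes_list <- list(codes_list)
  do.call(rbind, lapply(codes_list, function(cd) {
    data.frame(participant_id = attr(cd, "participant_id"),
               date = format(attr(cd, "date")),
               hour = cd$hour, proximity = cd$proximity,
               activity = cd$activity, speech = cd$speech)
  }))
}

#' Chart-ready JSON for one coded day
#'
#' Serializes the per-hour codes and the three chart count blocks
#' (proximity, activity, speech) for the counselor app visualizations.
#'
#' @param codes a `daily_codes` object.
#' @return a JSON string.
#' @export
codes_chart_json <- function(codes) {
  payload <- list(
    participant_id = attr(codes, "participant_id"),
    date = format(attr(codes, "date")),
    hours = codes[c("hour", "proximity", "activity", "speech")],
    proximity_chart = as.list(proximity_chart_data(codes)),
    activity_chart = as.list(activity_chart_data(codes)),
    speech_chart = as.list(speech_chart_data(codes)),
    speech_pct = attr(codes, "speech_pct")
  )
  jsonlite::toJSON(payload, auto_unbox = TRUE, dataframe = "columns",
                   na = "null", digits = NA)
}

#' Plot a coded day as a three-channel hour strip
#'
#' @param x a `daily_codes` object.
#' @param ... ignored.
#' @export
plot.daily_codes <- function(x, ...) {
  chans <- c("proximity", "activity", "speech")
  cols <- c(positive = "#2c7fb8", negative = "#fdae61", no_data = "grey85")
  graphics::plot(NA, xlim = c(0, 24), ylim = c(0, 3), xlab = "hour of day",
                 ylab = "", yaxt = "n", xaxs = "i", yaxs = "i",
                 main = paste(attr(x, "participant_id"), format(attr(x, "date"))))
  graphics::axis(2, at = 1:3 - 0.5, labels = chans, las = 1, tick = FALSE)
  for (i in seq_along(chans)) {
    st <- x[[chans[i]]]
    cls <- ifelse(st == "no_data", cols["no_data"],
                  ifelse(st %in% c("together", "active", "speech"),
                         cols["positive"], cols["negative"]))
    graphics::rect(x$hour, i - 1, x$hour + 1, i, col = cls, border = "white")
  }
  invisible(x)
}
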