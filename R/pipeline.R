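#' Run the weekly preparation pipeline for one participant
#'
#' Mirrors the counselor's weekly session preparation: ingest the inbound
#' folder, code each day of the week, derive GPS mobility features (home
#' estimated from the whole week's fixes), evaluate award rules, and collect
#' the per-day chart data plus a per-sensor data-completeness summary.
#'
#' @param inbound inbound folder of sensor files.
#' @param participant_id participant code; an error if the folder holds no
#'   files for it.
#' @param week_start first `Date` of the 7-day window.
#' @param rules award rules, default [default_award_rules()].
#' @param speech_classes,threshold speech qualification, see
#'   [code_speech_hour()].
#' @param home_radius_m,cell_deg mobility parameters, see
#'   [fraction_time_outside_home()] and [estimate_home()].
#' @param goals optional list of `weekly_goal`s to evaluate against the week.
#' @return an object of class `week_report`.
#' @export
run_week <- function(inbound, participant_id, week_start,
                     rules = default_award_rules(),
                     speech_classes = "Speech", threshold = 0.5,
                     home_radius_m = 100, cell_deg = 0.0005,
                     goals = list()) {
  week_start <- as.Date(week_start)
  scan <- scan_inbound(inbound)
  store <- scan$stores[[participant_id]]
  if (is.null(store)) {
    stop("participant ", participant_id, " not found in inbound folder ", inbound)
  }
  dates <- week_start + 0:6
  codes <- lapply(dates, function(d) code_day(store, d, speech_classes, threshold))
  names(codes) <- format(dates)

  week_fixes <- store$tables$gps[as.Date(store$tables$gps$timestamp) %in% dates, ,
                                 drop = FALSE]
  home <- estimate_home(week_fixes, cell_deg)
  mobility <- do.call(rbind, lapply(dates, function(d) {
    fx <- week_fixes[as.Date(week_fixes$timestamp) == d, , drop = FALSE]
    mobility_features(fx, d, home, home_radius_m)
  }))

  awards <- evaluate_rules(codes, mobility, rules)
  goals <- lapply(goals, goal_progress, codes_list = codes, mobility = mobility,
                  rules = rules)

  observed_hours <- function(ch) {
    100 * sum(vapply(codes, function(cd) sum(cd[[ch]] != "no_data"), 0L)) /
      (24L * length(codes))
  }
  gps_hours <- sum(vapply(dates, function(d) {
    length(unique(as.POSIXlt(
      week_fixes$timestamp[as.Date(week_fixes$timestamp) == d], tz = "UTC")$hour))
  }, 0L))
  completeness <- c(proximity = observed_hours("proximity"),
                    activity = observed_hours("activity"),
                    speech = observed_hours("speech"),
                    gps = 100 * gps_hours / (24L * length(dates)))

  charts <- lapply(codes, function(cd) {
    list(proximity = proximity_chart_data(cd),
         activity = activity_chart_data(cd),
         speech = speech_chart_data(cd))
  })

  all_nodata <- all(vapply(codes, function(cd)
    all(cd$proximity == "no_data" & cd$activity == "no_data" &
        cd$speech == "no_data"), logical(1)))
  if (all_nodata) {
    warning("no observed data for ", participant_id, " in week starting ",
            format(week_start))
  }

  structure(list(participant_id = participant_id, week_start = week_start,
                 dates = dates, codes = codes, mobility = mobility,
                 home = home, charts = charts, awards = awards, goals = goals,
                 completeness = completeness,
                 ingest_report = scan$report),
            class = "week_report")
}

#' @export
print.week_report <- function(x, ...) {
  cat("<week_report>", x$participant_id, "week of", format(x$week_start), "\n")
  cat("  completeness (% observed hours):",
      paste(sprintf("%s %.0f%%", names(x$completeness), x$completeness),
            collapse = ", "), "\n")
  cat("  awards:", nrow(x$awards), " goals met:",
      sum(vapply(x$goals, function(g) g$status == "met", logical(1))), "\n")
  invisible(x)
}

#' @export
summary.week_report <- function(object, ...) {
  cat("Participant", object$participant_id, "- week of",
      format(object$week_start), "\n\n")
  tab <- codes_to_table(object$codes)
  for (ch in c("proximity", "activity", "speech")) {
    cat(sprintf("%-10s", ch))
    print(table(tab$date, tab[[ch]]))
    cat("\n")
  }
  cat("Mobility:\n"); print(object$mobility)
  cat("\nAwards:\n")
  if (nrow(object$awards)) print(object$awards) else cat("  (none)\n")
  invisible(object)
}

#' Export a week report as JSON plus delimited tables
#'
#' Writes `report.json` (the full report), `codes.csv` (tidy hour codes),
#' `mobility.csv` and `awards.csv` into `dir`. Output is byte-stable:
#' rerunning on the same inputs reproduces identical files.
#'
#' @param report a `week_report`.
#' @param dir output directory (created if needed).
#' @return the paths written, invisibly.
#' @export
write_week_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  codes_tab <- codes_to_table(report$codes)
  paths <- file.path(dir, c("report.json", "codes.csv", "mobility.csv",
                            "awards.csv"))
  payload <- list(
    participant_id = report$participant_id,
    week_start = format(report$week_start),
    dates = format(report$dates),
    completeness = as.list(report$completeness),
    speech_pct = lapply(report$codes, function(cd) attr(cd, "speech_pct")),
    charts = report$charts,
    home = if (is.null(report$home)) NULL else
      report$home[c("lat", "lon", "support")],
    mobility = report$mobility,
    awards = report$awards,
    goals = lapply(report$goals, unclass)
  )
  jsonlite::write_json(payload, paths[1], auto_unbox = TRUE, na = "null",
                       digits = NA, pretty = TRUE)
  utils::write.csv(codes_tab, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(report$mobility, paths[3], row.names = FALSE, quote = FALSE)
  utils::write.csv(report$awards, paths[4], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Re-import exported hour codes
#'
#' Reads a `codes.csv` written by [write_week_report()] back into a list of
#' `daily_codes` (chart data recomputed from it is identical to the
#' original's).
#'
#' @param path the `codes.csv` file.
#' @return list of `daily_codes`, named by date.
#' @export
read_codes_table <- function(path) {
  tab <- utils::read.csv(path, colClasses = "character")
  tab$hour <- as.integer(tab$hour)
  out <- lapply(split(tab, tab$date), function(dd) {
    dd <- dd[order(dd$hour), , drop = FALSE]
    structure(data.frame(hour = dd$hour, proximity = dd$proximity,
                         activity = dd$activity, speech = dd$speech),
              participant_id = dd$participant_id[1],
              date = as.Date(dd$date[1]), speech_pct = NA_real_,
              class = c("daily_codes", "data.frame"))
  })
  out[order(names(out))]
}
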