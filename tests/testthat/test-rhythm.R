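ts_at <- function(hms, date = "2019-06-05") {
  as.POSIXct(paste0(date, " ", hms), tz = "UTC")
}

test_that("timestamps map to half-open 15-minute bins", {
  expect_equal(bin_index(ts_at("00:00:00")), 0L)
  expect_equal(bin_index(ts_at("10:07:30")), 40L)
  expect_equal(bin_index(ts_at("23:59:59")), 95L)
  expect_equal(bin_index(ts_at("09:15:00")), 37L)  # boundary opens the next bin
})

test_that("day grids keep missing bins explicit", {
  date <- as.Date("2019-06-05")
  empty <- build_day_grid(rhythmgrid:::empty_records("PROXIMITY"), date, "proximity")
  expect_length(empty$observed, 96L)
  expect_false(any(empty$observed))

  one <- data.frame(participant_id = "SS0001", timestamp = ts_at("09:02:00"),
                    beacon_id = "RB1", detected = TRUE, rssi = -60)
  g <- build_day_grid(one, date, "proximity")
  expect_equal(which(g$observed), 37L)  # bin 36, one-based slot 37
  expect_true(g$values[[37]])

  # a full simulated day at the 15-minute cadence leaves no missing bin
  cfg <- schedule_config(seed = 4, n_days = 1)
  day <- simulate_day(cfg, date)
  gp <- build_day_grid(day$records$proximity, date, "proximity")
  expect_equal(sum(gp$observed), 96L)

  # off-date records are ignored
  g2 <- build_day_grid(one, date + 1, "proximity")
  expect_false(any(g2$observed))
  expect_error(build_day_grid(one, date, "heartrate"), "arg")
})

test_that("hour coders implement the at-least-one-reading rules", {
  obs1 <- c(TRUE, FALSE, FALSE, FALSE)
  expect_equal(code_proximity_hour(list(TRUE, NULL, NULL, NULL), obs1), "together")
  expect_equal(code_proximity_hour(list(FALSE, FALSE, FALSE, FALSE), rep(TRUE, 4)),
               "apart")
  expect_equal(code_proximity_hour(vector("list", 4), rep(FALSE, 4)), "no_data")

  expect_equal(code_activity_hour(list("walking", NULL, NULL, NULL), obs1), "active")
  expect_equal(code_activity_hour(as.list(rep("still", 4)), rep(TRUE, 4)), "inactive")
  expect_equal(code_activity_hour(vector("list", 4), rep(FALSE, 4)), "no_data")
  # unknown is no evidence either way
  expect_equal(code_activity_hour(list("unknown", NULL, NULL, NULL), obs1), "no_data")
  expect_equal(code_activity_hour(list(c("unknown", "still"), NULL, NULL, NULL), obs1),
               "inactive")

  clip <- function(lab, sc) data.frame(clip_start = ts_at("09:00:00"),
                                       label = lab, score = sc)
  expect_equal(code_speech_hour(list(clip("Speech", 0.9), NULL, NULL, NULL), obs1),
               "speech")
  expect_equal(code_speech_hour(list(clip("Music", 0.8), NULL, NULL, NULL), obs1),
               "no_speech")
  expect_equal(code_speech_hour(list(clip("Speech", 0.4), NULL, NULL, NULL), obs1),
               "no_speech")  # below threshold
  expect_equal(code_speech_hour(vector("list", 4), rep(FALSE, 4)), "no_data")
})

test_that("speech percentage counts qualifying clips over all clips", {
  aud <- data.frame(
    participant_id = "SS0001",
    clip_start = ts_at("09:00:00") + c(0, 900, 1800, 2700),
    duration = 30,
    label = c("Speech", "Music", NA, "Insects"),
    score = c(0.9, 0.8, NA, 0.6)
  )
  expect_equal(speech_percentage(aud), 25.0)
  expect_true(is.na(speech_percentage(rhythmgrid:::empty_records("AUDIO"))))

  # multi-label clips still count once
  aud2 <- rbind(aud, data.frame(participant_id = "SS0001",
                                clip_start = ts_at("09:00:00"), duration = 30,
                                label = "Music", score = 0.7))
  expect_equal(speech_percentage(aud2), 25.0)

  # brute-force count on a generated day agrees
  cfg <- schedule_config(seed = 19, n_days = 1)
  day <- simulate_day(cfg, cfg$start_date)
  aud <- day$records$audio
  qual <- tapply(!is.na(aud$label) & aud$label == "Speech" & aud$score >= 0.5,
                 format(aud$clip_start), any)
  expect_equal(speech_percentage(aud), 100 * sum(qual) / length(qual))
})

test_that("code_day recovers a constructed schedule", {
  date <- as.Date("2019-06-05")
  store <- as_store(list(
    gps = rhythmgrid:::empty_records("GPS"),
    proximity = data.frame(
      participant_id = "SS0001",
      timestamp = ts_at("00:00:00") + seq(0, 86399, by = 900),
      beacon_id = "RB1",
      detected = !(seq(0, 86399, by = 900) >= 13 * 3600 &
                     seq(0, 86399, by = 900) < 15 * 3600),
      rssi = -60),
    activity = data.frame(
      participant_id = "SS0001",
      timestamp = ts_at(c("08:10:00", "08:20:00", "09:00:00")),
      label = c("walking", "walking", "still")),
    audio = rhythmgrid:::empty_records("AUDIO")
  ))
  cd <- code_day(store, date)
  expect_equal(cd$proximity[cd$hour %in% c(13, 14)], c("apart", "apart"))
  expect_equal(sum(cd$proximity == "together"), 22L)
  expect_equal(cd$activity[cd$hour == 8], "active")
  expect_equal(cd$activity[cd$hour == 9], "inactive")
  expect_equal(cd$activity[cd$hour == 10], "no_data")
  expect_true(is.na(attr(cd, "speech_pct")))

  # empty store codes everything no_data
  cd0 <- code_day(participant_store("SS0001"), date)
  expect_true(all(cd0$proximity == "no_data"))
  expect_true(all(cd0$activity == "no_data"))
  expect_true(all(cd0$speech == "no_data"))
})

test_that("per-channel hour counts always sum to 24", {
  for (seed in c(101, 102, 103, 104, 105)) {
    cfg <- random_day_config(seed)
    day <- simulate_day(cfg, cfg$start_date)
    cd <- code_day(as_store(day$records), cfg$start_date)
    expect_equal(sum(proximity_chart_data(cd)), 24L)
    expect_equal(sum(activity_chart_data(cd)), 24L)
    expect_equal(sum(speech_chart_data(cd)), 24L)
  }
})

test_that("adding qualifying records never demotes an hour code", {
  cfg <- random_day_config(301)
  day <- simulate_day(cfg, cfg$start_date)
  store <- as_store(day$records)
  before <- code_day(store, cfg$start_date)
  for (h in c(3, 9, 14, 21)) {
    ts <- ts_at(sprintf("%02d:05:00", h))
    store2 <- store
    store2$tables$proximity <- rbind(
      store2$tables$proximity,
      data.frame(participant_id = "SS0001", timestamp = ts, beacon_id = "RB1",
                 detected = TRUE, rssi = -58))
    store2$tables$activity <- rbind(
      store2$tables$activity,
      data.frame(participant_id = "SS0001", timestamp = ts, label = "running"))
    after <- code_day(store2, cfg$start_date)
    expect_equal(after$proximity[h + 1], "together")
    expect_equal(after$activity[h + 1], "active")
    # untouched hours unchanged
    expect_equal(after$proximity[-(h + 1)], before$proximity[-(h + 1)])
    expect_equal(after$activity[-(h + 1)], before$activity[-(h + 1)])
  }
})

test_that("grid coding equals direct per-hour scanning on random days", {
  for (seed in 201:220) {
    cfg <- random_day_config(seed)
    day <- simulate_day(cfg, cfg$start_date)
    cd <- code_day(as_store(day$records), cfg$start_date)
    oracle <- bf_code_day(day$records, cfg$start_date)
    expect_equal(cd$proximity, oracle$proximity, info = paste("seed", seed))
    expect_equal(cd$activity, oracle$activity, info = paste("seed", seed))
    expect_equal(cd$speech, oracle$speech, info = paste("seed", seed))
  }
})

test_that("chart data and exports are consistent with the codes", {
  cfg <- schedule_config(seed = 8, n_days = 2)
  day <- simulate_day(cfg, cfg$start_date)
  cd <- code_day(as_store(day$records), cfg$start_date)
  triple <- proximity_chart_data(cd)
  expect_equal(unname(triple["together"]), sum(cd$proximity == "together"))
  expect_equal(sum(triple), 24L)

  tab <- codes_to_table(cd)
  expect_equal(names(tab), c("participant_id", "date", "hour", "proximity",
                             "activity", "speech"))
  expect_equal(nrow(tab), 24L)

  js <- jsonlite::fromJSON(codes_chart_json(cd))
  expect_equal(js$proximity_chart$together, unname(triple["together"]))
  expect_equal(js$speech_pct, attr(cd, "speech_pct"))
})
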