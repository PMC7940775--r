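# Sensor datatypes handled by the collector naming convention.
SENSOR_TYPES <- c("GPS", "PROXIMITY", "ACTIVITY", "EAR", "AUDIO")

# Logical store tables (EAR clips are registered in provenance only; their
# audio content is consumed through the weekly AUDIO prediction table).
TABLE_TYPES <- c("GPS", "PROXIMITY", "ACTIVITY", "AUDIO")

ACTIVITY_LABELS <- c("still", "walking", "running", "in_vehicle", "cycling", "unknown")

#' Parse and format local-clock timestamps
#'
#' All analysis runs on the participant's local clock; timestamps are
#' ISO-8601 without a zone designator and are represented internally as
#' POSIXct in UTC (used purely as a zone-free carrier).
#'
#' @param x character vector of `YYYY-MM-DDTHH:MM:SS` (a space separator is
#'   also accepted).
#' @return POSIXct vector; unparseable elements are `NA`.
#' @export
parse_timestamp <- function(x) {
  x <- sub("T", " ", x, fixed = TRUE)
  as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
}

#' @rdname parse_timestamp
#' @param ts POSIXct vector.
#' @export
format_timestamp <- function(ts) {
  format(ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

#' Parse a collector filename into its metadata
#'
#' Filenames follow `<ID>-<TYPE>_<DATE>.<ext>`: the participant code (`SS`
#' followed by uppercase alphanumerics), a dash, the sensor datatype, an
#' underscore, and a date token (`YYYYMMDD`, or `YYYYMMDDHHMMSS` for raw EAR
#' audio clips). Weekly audio-prediction tables are the one exception and
#' carry no date: `<ID>-AUDIO.csv`.
#'
#' @param name bare filename, no directory parts.
#' @return an object of class `file_meta`: a list with `participant_id`,
#'   `datatype`, `date` (a `Date`, or `NA` for AUDIO), `clip_time` (POSIXct,
#'   EAR only) and `extension`.
#' @examples
#' parse_sensor_filename("SSXXXX-PROXIMITY_20190605.txt")
#' parse_sensor_filename("SSXXXX-AUDIO.csv")
#' @export
parse_sensor_filename <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (name != basename(name)) {
    stop("expected a bare filename without directory parts: ", name)
  }
  m <- regmatches(name, regexec("^([^-]+)-([^_.]+)(_([0-9]+))?\\.([A-Za-z0-9]+)$", name))[[1]]
  if (length(m) == 0L) {
    stop("malformed sensor filename (expected <ID>-<TYPE>_<DATE>.<ext>): ", name)
  }
  id <- m[2]; type <- m[3]; datetok <- m[5]; ext <- m[6]
  if (!grepl("^SS[A-Z0-9]+$", id)) {
    stop("malformed participant segment '", id, "' in ", name)
  }
  if (!type %in% SENSOR_TYPES) {
    stop("unsupported datatype token '", type, "' in ", name)
  }
  date <- as.Date(NA)
  clip_time <- as.POSIXct(NA)
  if (type == "AUDIO") {
    if (nzchar(datetok)) {
      stop("weekly AUDIO files carry no date token: ", name)
    }
  } else if (type == "EAR") {
    if (nchar(datetok) != 14L) {
      stop("malformed EAR date segment '", datetok, "' (need YYYYMMDDHHMMSS) in ", name)
    }
    clip_time <- as.POSIXct(datetok, tz = "UTC", format = "%Y%m%d%H%M%S")
    if (is.na(clip_time)) stop("malformed EAR date segment '", datetok, "' in ", name)
    date <- as.Date(clip_time)
  } else {
    if (nchar(datetok) != 8L) {
      stop("malformed date segment '", datetok, "' (need YYYYMMDD) in ", name)
    }
    date <- as.Date(datetok, format = "%Y%m%d")
    if (is.na(date)) stop("malformed date segment '", datetok, "' in ", name)
  }
  structure(
    list(participant_id = id, datatype = type, date = date,
         clip_time = clip_time, extension = ext),
    class = "file_meta"
  )
}

#' Build the filename a `file_meta` describes
#'
#' Inverse of [parse_sensor_filename()]: `build_sensor_filename()` followed by
#' `parse_sensor_filename()` is the identity on valid metadata.
#'
#' @param meta a `file_meta`, or the fields given separately.
#' @export
build_sensor_filename <- function(meta) {
  stopifnot(inherits(meta, "file_meta"))
  if (meta$datatype == "AUDIO") {
    return(paste0(meta$participant_id, "-AUDIO.", meta$extension))
  }
  tok <- if (meta$datatype == "EAR") {
    format(meta$clip_time, "%Y%m%d%H%M%S", tz = "UTC")
  } else {
    format(meta$date, "%Y%m%d")
  }
  paste0(meta$participant_id, "-", meta$datatype, "_", tok, ".", meta$extension)
}

#' @export
print.file_meta <- function(x, ...) {
  cat("<file_meta>", x$participant_id, x$datatype,
      if (!is.na(x$date)) format(x$date) else "(no date)",
      paste0(".", x$extension), "\n")
  invisible(x)
}

file_meta <- function(participant_id, datatype, date = as.Date(NA),
                      clip_time = as.POSIXct(NA), extension = "txt") {
  structure(list(participant_id = participant_id, datatype = datatype,
                 date = date, clip_time = clip_time, extension = extension),
            class = "file_meta")
}

# Column schema per datatype (timestamps stored as ISO strings on disk).
sensor_schema <- function(datatype) {
  switch(datatype,
    GPS = c("timestamp", "lat", "lon"),
    PROXIMITY = c("timestamp", "beacon_id", "detected", "rssi"),
    ACTIVITY = c("timestamp", "label"),
    AUDIO = c("clip_start", "duration", "label", "score"),
    stop("no record schema for datatype ", datatype)
  )
}

empty_records <- function(datatype, participant_id = character(0)) {
  df <- switch(datatype,
    GPS = data.frame(participant_id = character(0),
                     timestamp = as.POSIXct(character(0), tz = "UTC"),
                     lat = numeric(0), lon = numeric(0)),
    PROXIMITY = data.frame(participant_id = character(0),
                           timestamp = as.POSIXct(character(0), tz = "UTC"),
                           beacon_id = character(0), detected = logical(0),
                           rssi = numeric(0)),
    ACTIVITY = data.frame(participant_id = character(0),
                          timestamp = as.POSIXct(character(0), tz = "UTC"),
                          label = character(0)),
    AUDIO = data.frame(participant_id = character(0),
                       clip_start = as.POSIXct(character(0), tz = "UTC"),
                       duration = numeric(0), label = character(0),
                       score = numeric(0)),
    stop("no record schema for datatype ", datatype)
  )
  attr(df, "datatype") <- datatype
  df
}

#' Read one sensor record file
#'
#' Reads a delimited (comma-separated, header row) sensor file into a typed
#' record data frame. Rows that fail the schema — unparseable timestamps,
#' out-of-bounds coordinates, unknown activity labels, scores outside `[0,1]`
#' — are skipped and counted in the parse report attached as the
#' `"parse_report"` attribute. A file whose data rows are more than half
#' malformed is rejected outright.
#'
#' Schemas: GPS `timestamp,lat,lon`; PROXIMITY
#' `timestamp,beacon_id,detected,rssi` (rssi empty when not detected);
#' ACTIVITY `timestamp,label`; AUDIO `clip_start,duration,label,score`, one
#' row per (clip, label) with an empty label/score pair marking a silent
#' clip.
#'
#' @param path file path.
#' @param meta optional `file_meta`; parsed from `basename(path)` if omitted.
#' @return data frame of records in timestamp order, with `participant_id` as
#'   first column and attributes `datatype` and `parse_report`
#'   (`list(n_rows, n_kept, n_skipped)`).
#' @export
read_sensor_file <- function(path, meta = NULL) {
  if (is.null(meta)) meta <- parse_sensor_filename(basename(path))
  if (!file.exists(path)) stop("cannot read sensor file: ", path)
  if (!meta$datatype %in% TABLE_TYPES) {
    stop("datatype ", meta$datatype, " has no parseable record schema")
  }
  cols <- sensor_schema(meta$datatype)
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (!identical(names(raw), cols)) {
    stop("unexpected header in ", path, ": got [", paste(names(raw), collapse = ","),
         "], expected [", paste(cols, collapse = ","), "]")
  }
  n <- nrow(raw)
  if (n == 0L) {
    out <- empty_records(meta$datatype)
    attr(out, "parse_report") <- list(n_rows = 0L, n_kept = 0L, n_skipped = 0L)
    return(out)
  }
  ok <- rep(TRUE, n)
  out <- switch(meta$datatype,
    GPS = {
      ts <- parse_timestamp(raw$timestamp)
      lat <- suppressWarnings(as.numeric(raw$lat))
      lon <- suppressWarnings(as.numeric(raw$lon))
      ok <- !is.na(ts) & !is.na(lat) & !is.na(lon) &
        lat >= -90 & lat <= 90 & lon >= -180 & lon <= 180
      data.frame(participant_id = meta$participant_id, timestamp = ts,
                 lat = lat, lon = lon)[ok, , drop = FALSE]
    },
    PROXIMITY = {
      ts <- parse_timestamp(raw$timestamp)
      det <- tolower(raw$detected)
      detected <- det == "true"
      rssi <- suppressWarnings(as.numeric(raw$rssi))
      ok <- !is.na(ts) & det %in% c("true", "false") &
        (raw$rssi == "" | !is.na(rssi))
      # a scan without detection never carries a signal strength
      rssi[!detected] <- NA_real_
      data.frame(participant_id = meta$participant_id, timestamp = ts,
                 beacon_id = raw$beacon_id, detected = detected,
                 rssi = rssi)[ok, , drop = FALSE]
    },
    ACTIVITY = {
      ts <- parse_timestamp(raw$timestamp)
      ok <- !is.na(ts) & raw$label %in% ACTIVITY_LABELS
      data.frame(participant_id = meta$participant_id, timestamp = ts,
                 label = raw$label)[ok, , drop = FALSE]
    },
    AUDIO = {
      ts <- parse_timestamp(raw$clip_start)
      dur <- suppressWarnings(as.numeric(raw$duration))
      score <- suppressWarnings(as.numeric(raw$score))
      label <- raw$label
      silent <- label == "" & raw$score == ""
      label[silent] <- NA_character_
      ok <- !is.na(ts) & !is.na(dur) & dur > 0 &
        (silent | (!is.na(score) & score >= 0 & score <= 1 & label != ""))
      data.frame(participant_id = meta$participant_id, clip_start = ts,
                 duration = dur, label = label, score = score)[ok, , drop = FALSE]
    }
  )
  n_kept <- nrow(out)
  if (n_kept * 2L < n) {
    stop("corrupt sensor file (", n - n_kept, "/", n, " rows malformed): ", path)
  }
  tscol <- if (meta$datatype == "AUDIO") "clip_start" else "timestamp"
  out <- out[order(out[[tscol]]), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "datatype") <- meta$datatype
  attr(out, "parse_report") <- list(n_rows = n, n_kept = n_kept,
                                    n_skipped = n - n_kept)
  out
}

infer_datatype <- function(records) {
  dt <- attr(records, "datatype")
  if (!is.null(dt)) return(dt)
  for (d in TABLE_TYPES) {
    if (identical(setdiff(names(records), "participant_id"), sensor_schema(d))) return(d)
  }
  stop("cannot infer sensor datatype from columns: ",
       paste(names(records), collapse = ","))
}

#' Write sensor records to a file in the collector convention
#'
#' The emitted file re-reads (via [read_sensor_file()]) to records identical
#' field-for-field. When `path` is a directory, the filename is derived from
#' the records: `<ID>-<TYPE>_<YYYYMMDD>.txt` for daily sensors,
#' `<ID>-AUDIO.csv` for the weekly audio table.
#'
#' @param records a record data frame (one datatype, one participant).
#' @param path output file path, or an existing directory.
#' @param datatype,participant_id,date required only when `records` is empty.
#' @return the `file_meta` of the written file, invisibly.
#' @export
write_sensor_file <- function(records, path, datatype = NULL,
                              participant_id = NULL, date = NULL) {
  if (is.null(datatype)) datatype <- infer_datatype(records)
  if (!datatype %in% TABLE_TYPES) stop("cannot write datatype ", datatype)
  if (nrow(records) > 0L) {
    got <- infer_datatype(records)
    if (!identical(got, datatype)) {
      stop("mixed or mismatched datatypes: records are ", got, ", asked for ", datatype)
    }
    ids <- unique(records$participant_id)
    if (length(ids) != 1L) stop("records span multiple participants: ",
                                paste(ids, collapse = ", "))
    participant_id <- ids
    tscol <- if (datatype == "AUDIO") "clip_start" else "timestamp"
    if (is.null(date) && datatype != "AUDIO") {
      dates <- unique(as.Date(records[[tscol]]))
      if (length(dates) != 1L) stop("daily sensor file spans multiple dates")
      date <- dates
    }
  }
  if (is.null(participant_id)) stop("participant_id required for empty record sets")
  if (is.null(date) && datatype != "AUDIO") stop("date required for empty record sets")
  ext <- if (datatype == "AUDIO") "csv" else "txt"
  meta <- file_meta(participant_id, datatype,
                    date = if (datatype == "AUDIO") as.Date(NA) else as.Date(date),
                    extension = ext)
  if (dir.exists(path)) path <- file.path(path, build_sensor_filename(meta))
  cols <- sensor_schema(datatype)
  out <- records[setdiff(names(records), "participant_id")]
  if (nrow(out) > 0L) {
    tscol <- if (datatype == "AUDIO") "clip_start" else "timestamp"
    out[[tscol]] <- format_timestamp(out[[tscol]])
    if (datatype == "PROXIMITY") {
      out$detected <- ifelse(out$detected, "true", "false")
    }
  } else {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(meta)
}

#' Per-participant record store
#'
#' Mirrors the platform's four logical tables (gps, proximity, activity,
#' audio) for one participant, plus the provenance of every ingested file.
#'
#' @param participant_id participant code.
#' @export
participant_store <- function(participant_id) {
  structure(
    list(
      participant_id = participant_id,
      tables = list(
        gps = empty_records("GPS"),
        proximity = empty_records("PROXIMITY"),
        activity = empty_records("ACTIVITY"),
        audio = empty_records("AUDIO")
      ),
      provenance = data.frame(file = character(0), datatype = character(0),
                              date = as.Date(character(0)),
                              n_records = integer(0))
    ),
    class = "participant_store"
  )
}

#' @export
print.participant_store <- function(x, ...) {
  cat("<participant_store>", x$participant_id, "\n")
  for (tb in names(x$tables)) {
    cat(sprintf("  %-9s %6d records\n", tb, nrow(x$tables[[tb]])))
  }
  cat("  provenance:", nrow(x$provenance), "files\n")
  invisible(x)
}

store_add_records <- function(store, datatype, records) {
  tb <- tolower(datatype)
  combined <- rbind(store$tables[[tb]], records)
  # duplicate-suppression key: datatype + timestamp + full payload
  # (weekly re-uploads overlap, so re-ingest must be a no-op)
  keep <- !duplicated(combined)
  combined <- combined[keep, , drop = FALSE]
  tscol <- if (datatype == "AUDIO") "clip_start" else "timestamp"
  combined <- combined[order(combined[[tscol]]), , drop = FALSE]
  rownames(combined) <- NULL
  attr(combined, "datatype") <- datatype
  store$tables[[tb]] <- combined
  store
}

#' Ingest an inbound folder of sensor files
#'
#' Scans `folder`, parses every filename that matches the collector
#' convention, loads parseable datatypes into the matching participant's
#' store table, and registers raw EAR clips in provenance without decoding
#' them. Re-running the scan on the same folder is idempotent: the duplicate
#' key (datatype, timestamp, payload) suppresses re-ingested rows.
#'
#' @param folder inbound directory.
#' @param stores optional named list of existing `participant_store`s to
#'   extend.
#' @param unknown_participants `"auto-create"` (default) creates a store for
#'   any new participant code; `"reject"` skips their files (reported).
#' @return `list(stores = named list of participant_store, report)`; the
#'   report holds per-participant per-datatype file and record counts, the
#'   unparsed filenames, and total skipped rows.
#' @export
scan_inbound <- function(folder, stores = list(),
                         unknown_participants = c("auto-create", "reject")) {
  unknown_participants <- match.arg(unknown_participants)
  if (!dir.exists(folder)) stop("inbound folder does not exist: ", folder)
  files <- sort(list.files(folder, full.names = FALSE))
  unparsed <- character(0)
  rejected <- character(0)
  skipped_rows <- 0L
  counts <- list()
  for (f in files) {
    meta <- tryCatch(parse_sensor_filename(f), error = function(e) NULL)
    if (is.null(meta)) { unparsed <- c(unparsed, f); next }
    id <- meta$participant_id
    if (is.null(stores[[id]])) {
      if (unknown_participants == "reject") { rejected <- c(rejected, f); next }
      stores[[id]] <- participant_store(id)
    }
    if (f %in% stores[[id]]$provenance$file) next  # already ingested
    n_rec <- 0L
    if (meta$datatype %in% TABLE_TYPES) {
      rec <- read_sensor_file(file.path(folder, f), meta)
      rep <- attr(rec, "parse_report")
      skipped_rows <- skipped_rows + rep$n_skipped
      n_rec <- nrow(rec)
      stores[[id]] <- store_add_records(stores[[id]], meta$datatype, rec)
    }
    stores[[id]]$provenance <- rbind(
      stores[[id]]$provenance,
      data.frame(file = f, datatype = meta$datatype, date = meta$date,
                 n_records = n_rec)
    )
    key <- paste(id, meta$datatype)
    cur <- counts[[key]]
    if (is.null(cur)) cur <- c(files = 0L, records = 0L)
    counts[[key]] <- cur + c(files = 1L, records = n_rec)
  }
  tab <- if (length(counts)) {
    parts <- strsplit(names(counts), " ", fixed = TRUE)
    data.frame(
      participant_id = vapply(parts, `[`, "", 1L),
      datatype = vapply(parts, `[`, "", 2L),
      files = vapply(counts, `[[`, 0L, "files"),
      records = vapply(counts, `[[`, 0L, "records"),
      row.names = NULL
    )
  } else {
    data.frame(participant_id = character(0), datatype = character(0),
               files = integer(0), records = integer(0))
  }
  list(stores = stores,
       report = list(ingested = tab, unparsed = unparsed, rejected = rejected,
                     skipped_rows = skipped_rows))
}

#' Persist and reload a participant store
#'
#' One folder per participant, one delimited file per logical table, written
#' in the same schemas as the collector files (plus the provenance listing).
#'
#' @param store a `participant_store`.
#' @param dir parent directory.
#' @export
save_store <- function(store, dir) {
  d <- file.path(dir, store$participant_id)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  for (tb in names(store$tables)) {
    rec <- store$tables[[tb]]
    out <- rec[setdiff(names(rec), "participant_id")]
    tscol <- if (tb == "audio") "clip_start" else "timestamp"
    if (nrow(out)) out[[tscol]] <- format_timestamp(out[[tscol]])
    if (tb == "proximity" && nrow(out)) out$detected <- ifelse(out$detected, "true", "false")
    utils::write.csv(out, file.path(d, paste0(tb, ".csv")),
                     row.names = FALSE, quote = FALSE, na = "")
  }
  prov <- store$provenance
  utils::write.csv(prov, file.path(d, "provenance.csv"), row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(d)
}

#' @rdname save_store
#' @param participant_id participant code to load.
#' @export
load_store <- function(dir, participant_id) {
  d <- file.path(dir, participant_id)
  if (!dir.exists(d)) stop("no persisted store for ", participant_id, " under ", dir)
  store <- participant_store(participant_id)
  for (tb in names(store$tables)) {
    p <- file.path(d, paste0(tb, ".csv"))
    if (!file.exists(p)) next
    meta <- file_meta(participant_id, toupper(tb))
    rec <- read_sensor_file(p, meta)
    store <- store_add_records(store, toupper(tb), rec)
  }
  pp <- file.path(d, "provenance.csv")
  if (file.exists(pp)) {
    prov <- utils::read.csv(pp, colClasses = c("character", "character",
                                               "character", "integer"))
    prov$date <- as.Date(prov$date)
    store$provenance <- prov
  }
  store
}
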