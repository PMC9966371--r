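#' @name flight-dialect
#' @title The flight-record file dialect
#' @description
#' A flight is stored as one JSON sidecar plus one CSV per subject:
#' \itemize{
#'   \item sidecar (\code{<flight_id>.json}): \code{format_version},
#'     \code{flight_id}, \code{datetime} (ISO-8601), \code{protocol},
#'     \code{flight_type}, and a \code{subjects} array; each subject entry
#'     holds \code{subject_id}, optional \code{age}, \code{sex},
#'     \code{station}, and \code{data_file}, the CSV path relative to the
#'     sidecar.
#'   \item data CSV: columns \code{time_s, spo2_pct, hr_bpm, mask_on} and
#'     optionally \code{altitude_ft}. Empty cells are missing samples; the
#'     mask column must be complete. Timestamps are seconds from record
#'     start and strictly increasing.
#' }
#' Numbers are serialized at full double precision so records round-trip
#' exactly.
NULL

.FORMAT_VERSION <- "1.0"
.REQUIRED_COLS <- c("time_s", "spo2_pct", "hr_bpm", "mask_on")

# Format doubles so that read-back reproduces the value bit-exactly:
# 15 significant digits where that round-trips, 17 otherwise.
.fmtNum <- function(x) {
  out <- character(length(x))
  na <- is.na(x)
  xs <- x[!na]
  s17 <- sprintf("%.17g", xs)
  s15 <- sprintf("%.15g", xs)
  use15 <- as.numeric(s15) == xs
  s17[use15] <- s15[use15]
  out[!na] <- s17
  out
}

.parseNumCol <- function(raw, col, file) {
  x <- trimws(raw)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & nzchar(x) & is.na(out))
  if (length(bad))
    stop(sprintf("format error in %s: column '%s' has non-numeric value '%s' at row %d",
      basename(file), col, x[bad[1L]], bad[1L]))
  out[!nzchar(x)] <- NA_real_
  out
}

#' Write a flight record to disk
#'
#' Emits the JSON sidecar at \code{path} and one data CSV per subject next
#' to it, named \code{<flight_id>_<subject_id>.csv}. The emitted files
#' round-trip through [readFlightRecord()] exactly.
#'
#' @param record a [FlightRecord-class].
#' @param path destination sidecar path (\code{.json}).
#' @return \code{path}, invisibly
#' @seealso [flight-dialect] for the file layout
#' @export
writeFlightRecord <- function(record, path) {
  stopifnot(is(record, "FlightRecord"))
  validObject(record)
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  subj_meta <- vector("list", length(record@subjects))
  for (i in seq_along(record@subjects)) {
    s <- record@subjects[[i]]
    csv <- paste0(record@flight_id, "_", s@subject_id, ".csv")
    cols <- list(time_s = .fmtNum(tsTimes(s@spo2)),
      spo2_pct = .fmtNum(tsValues(s@spo2)),
      hr_bpm = .fmtNum(tsValues(s@hr)),
      mask_on = .fmtNum(tsValues(s@mask)))
    if (!is.null(s@altitude))
      cols$altitude_ft <- .fmtNum(tsValues(s@altitude))
    lines <- c(paste(names(cols), collapse = ","),
      do.call(paste, c(cols, sep = ",")))
    writeLines(lines, file.path(dir, csv))
    subj_meta[[i]] <- list(subject_id = s@subject_id,
      age = if (is.na(s@age)) NULL else s@age,
      sex = s@sex,
      station = if (is.na(s@station)) NULL else s@station,
      data_file = csv)
  }
  sidecar <- list(format_version = .FORMAT_VERSION,
    flight_id = record@flight_id, datetime = record@datetime,
    protocol = record@protocol, flight_type = record@flight_type,
    subjects = subj_meta)
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}

.readSubjectCSV <- function(file, subject_id, meta) {
  if (!file.exists(file)) stop("data file not found: ", file)
  df <- utils::read.csv(file, colClasses = "character",
    check.names = FALSE, na.strings = NULL)
  missing_cols <- setdiff(.REQUIRED_COLS, names(df))
  if (length(missing_cols))
    stop(sprintf("format error in %s: missing required column(s): %s",
      basename(file), paste(missing_cols, collapse = ", ")))
  time_s <- .parseNumCol(df$time_s, "time_s", file)
  if (anyNA(time_s))
    stop(sprintf("format error in %s: column 'time_s' has a missing value at row %d",
      basename(file), which(is.na(time_s))[1L]))
  if (length(time_s) > 1L && any(diff(time_s) <= 0)) {
    row <- which(diff(time_s) <= 0)[1L] + 1L
    stop(sprintf("format error in %s: non-monotone timestamp at row %d",
      basename(file), row))
  }
  spo2 <- .parseNumCol(df$spo2_pct, "spo2_pct", file)
  out_of_range <- which(spo2 < 0 | spo2 > 100)
  if (length(out_of_range))
    stop(sprintf("format error in %s: column 'spo2_pct' outside [0, 100] at row %d",
      basename(file), out_of_range[1L]))
  hr <- .parseNumCol(df$hr_bpm, "hr_bpm", file)
  mask <- .parseNumCol(df$mask_on, "mask_on", file)
  bad_mask <- which(is.na(mask) | !mask %in% c(0, 1))
  if (length(bad_mask))
    stop(sprintf("format error in %s: column 'mask_on' must be 0 or 1 at row %d",
      basename(file), bad_mask[1L]))
  altitude <- if ("altitude_ft" %in% names(df))
    timeSeries(time_s, .parseNumCol(df$altitude_ft, "altitude_ft", file),
      "altitude")
  else NULL
  age <- meta$age
  station <- meta$station
  sex <- meta$sex
  subjectRecord(subject_id,
    spo2 = timeSeries(time_s, spo2, "spo2"),
    hr = timeSeries(time_s, hr, "hr"),
    mask = timeSeries(time_s, mask, "mask"),
    altitude = altitude,
    age = if (is.null(age) || !length(age)) NA_real_
      else suppressWarnings(as.numeric(age)),
    sex = if (is.null(sex) || !sex %in% c("F", "M", "unspecified"))
      "unspecified" else sex,
    station = if (is.null(station) || !length(station)) NA_integer_
      else suppressWarnings(as.integer(station)))
}

#' Read a flight record from its JSON sidecar
#'
#' Required fields and data columns are validated strictly (missing columns,
#' non-monotone timestamps and SpO2 outside [0, 100] are format errors naming
#' the offending row); unparseable \emph{optional} metadata (age, sex,
#' station) degrades to missing rather than failing the load.
#'
#' @param path path to the sidecar JSON written by [writeFlightRecord()].
#' @return a [FlightRecord-class]
#' @export
readFlightRecord <- function(path) {
  if (!file.exists(path)) stop("flight sidecar not found: ", path)
  sc <- jsonlite::read_json(path)
  for (field in c("format_version", "flight_id", "subjects"))
    if (is.null(sc[[field]]))
      stop("format error in ", basename(path), ": missing field '", field, "'")
  dir <- dirname(path)
  subjects <- lapply(sc$subjects, function(m) {
    if (is.null(m$subject_id) || !nzchar(m$subject_id))
      stop("format error in ", basename(path),
        ": subject entry lacks subject_id")
    .readSubjectCSV(file.path(dir, m$data_file), m$subject_id, m)
  })
  flightRecord(flight_id = sc$flight_id,
    datetime = if (is.null(sc$datetime)) "" else sc$datetime,
    protocol = if (is.null(sc$protocol)) "" else sc$protocol,
    flight_type = if (is.null(sc$flight_type)) "total" else sc$flight_type,
    subjects = subjects)
}

#' Search a directory for stored flights
#'
#' Scans \code{directory} for flight sidecars and returns one descriptor row
#' per flight matching \code{query}, sorted by datetime. Only the sidecars
#' are read, not the data CSVs.
#'
#' @param directory path to scan (non-recursive).
#' @param query \code{NULL} (match everything) or a predicate function taking
#'   a one-row descriptor data.frame and returning \code{TRUE}/\code{FALSE}.
#' @return data.frame with columns \code{flight_id}, \code{datetime},
#'   \code{protocol}, \code{flight_type}, \code{n_subjects}, \code{path}
#' @examples
#' \dontrun{
#' searchFlights("flights/", query = function(d) d$flight_type == "decompression")
#' }
#' @export
searchFlights <- function(directory, query = NULL) {
  empty <- data.frame(flight_id = character(0), datetime = character(0),
    protocol = character(0), flight_type = character(0),
    n_subjects = integer(0), path = character(0))
  if (!dir.exists(directory)) return(empty)
  files <- list.files(directory, pattern = "\\.json$", full.names = TRUE)
  rows <- list()
  for (f in files) {
    sc <- tryCatch(jsonlite::read_json(f), error = function(e) NULL)
    if (is.null(sc) || is.null(sc$format_version) || is.null(sc$flight_id))
      next
    rows[[length(rows) + 1L]] <- data.frame(
      flight_id = sc$flight_id,
      datetime = if (is.null(sc$datetime)) "" else sc$datetime,
      protocol = if (is.null(sc$protocol)) "" else sc$protocol,
      flight_type = if (is.null(sc$flight_type)) "total" else sc$flight_type,
      n_subjects = length(sc$subjects), path = f)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$datetime, out$flight_id), , drop = FALSE]
  if (!is.null(query)) {
    keep <- vapply(seq_len(nrow(out)),
      function(i) isTRUE(query(out[i, , drop = FALSE])), logical(1))
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Remove flights from a sample
#'
#' @param sample a [FlightSample-class].
#' @param remove_ids character vector of flight ids to drop; ids not present
#'   raise a warning, not an error.
#' @return a new [FlightSample-class]; the input is unmodified
#' @export
editSample <- function(sample, remove_ids = character(0)) {
  stopifnot(is(sample, "FlightSample"))
  ids <- flightId(sample)
  absent <- setdiff(remove_ids, ids)
  if (length(absent))
    warning("flight id(s) not in sample: ", paste(absent, collapse = ", "))
  flightSample(sample@flights[!ids %in% remove_ids])
}

.phaseReportList <- function(phases) {
  setNames(lapply(.PHASE_NAMES, function(p) {
    st <- phases@status[[p]]
    list(value_s = if (st == "defined") phases@values[[p]] else NULL,
      status = st,
      note = switch(st, censored = "not reached", undefined = "never occurred",
        NULL),
      censor_time_s = if (st == "censored" && !is.na(phases@censor_time[[p]]))
        phases@censor_time[[p]] else NULL)
  }), .PHASE_NAMES)
}

#' Export a per-subject report
#'
#' Writes subject metadata, the six phase durations with censoring flags, and
#' min/max/mean/slope for SpO2 and heart rate. The JSON form is the machine
#' artifact (values re-parse exactly); the plain-text form is a human
#' summary.
#'
#' @param subject a [SubjectRecord-class].
#' @param phases the subject's [PhaseParameters-class].
#' @param stats data.frame of per-channel trace statistics, as produced by
#'   [summarizeTrace()] on the SpO2 and HR channels (rows bound together).
#' @param path destination path; \code{.json} writes JSON, \code{.txt}
#'   plain text.
#' @return \code{path}, invisibly
#' @export
exportReport <- function(subject, phases, stats, path) {
  stopifnot(is(subject, "SubjectRecord"), is(phases, "PhaseParameters"))
  as_text <- grepl("\\.txt$", path, ignore.case = TRUE)
  rep_stats <- lapply(seq_len(nrow(stats)), function(i) as.list(stats[i, ]))
  if (as_text) {
    ph <- as.data.frame(phases)
    lines <- c(
      sprintf("Subject report: %s", subject@subject_id),
      sprintf("  sex: %s   age: %s   station: %s", subject@sex,
        ifelse(is.na(subject@age), "unspecified", subject@age),
        ifelse(is.na(subject@station), "unspecified", subject@station)),
      "", "Phase parameters (s):",
      vapply(seq_len(nrow(ph)), function(i) {
        st <- ph$status[i]
        val <- switch(st, defined = sprintf("%g", ph$value_s[i]),
          censored = "not reached (censored)", undefined = "never occurred")
        sprintf("  %-4s %s", ph$parameter[i], val)
      }, character(1)),
      "", "Trace statistics:",
      vapply(seq_len(nrow(stats)), function(i) {
        sprintf("  %-5s min %g  max %g  mean %.2f  slope %.3f/min",
          stats$channel[i], stats$minimum[i], stats$maximum[i],
          stats$mean[i], stats$slope_per_min[i])
      }, character(1)))
    writeLines(lines, path)
  } else {
    out <- list(format_version = .FORMAT_VERSION, report = "subject",
      subject = list(subject_id = subject@subject_id,
        age = if (is.na(subject@age)) NULL else subject@age,
        sex = subject@sex,
        station = if (is.na(subject@station)) NULL else subject@station),
      thresholds = as.list(phases@thresholds),
      phases = .phaseReportList(phases),
      stats = rep_stats)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  invisible(path)
}
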