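#' @import methods
#' @importFrom stats approx median quantile sd setNames
NULL

#' TimeSeries: uniformly-sampled measurements of one physiological channel
#'
#' Holds one channel of a flight record: SpO2 (percent), heart rate (bpm),
#' altitude (feet) or oxygen-mask state (1 = connected, 0 = disconnected).
#' Times are seconds from record start and must be strictly increasing;
#' absolute wall-clock time lives in the flight metadata, never here.
#'
#' @slot times numeric, seconds from record start, non-negative, strictly
#'   increasing.
#' @slot values numeric, channel measurements; \code{NA} marks a missing
#'   sample (sensor dropout). SpO2 must lie in [0, 100]; mask in \{0, 1\}
#'   with no missing samples.
#' @slot channel character scalar, one of \code{"spo2"}, \code{"hr"},
#'   \code{"mask"}, \code{"altitude"}.
#' @export
setClass("TimeSeries",
  representation(times = "numeric", values = "numeric", channel = "character"))

setValidity("TimeSeries", function(object) {
  msgs <- character(0)
  if (length(object@channel) != 1L || is.na(object@channel) ||
      !nzchar(object@channel))
    msgs <- c(msgs, "channel must be a non-empty string")
  if (length(object@times) != length(object@values))
    msgs <- c(msgs, "times and values must have equal length")
  if (anyNA(object@times))
    msgs <- c(msgs, "times must not contain NA")
  if (length(object@times) && object@times[1L] < 0)
    msgs <- c(msgs, "times must be non-negative")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msgs <- c(msgs, "times must be strictly increasing")
  ch <- if (length(object@channel) == 1L) object@channel else ""
  v <- object@values
  if (identical(ch, "spo2") &&
      any(v < 0 | v > 100, na.rm = TRUE))
    msgs <- c(msgs, "SpO2 values must lie in [0, 100] or be NA")
  if (identical(ch, "mask")) {
    if (anyNA(v)) msgs <- c(msgs, "mask values must not be NA")
    else if (any(!v %in% c(0, 1)))
      msgs <- c(msgs, "mask values must be 0 or 1")
  }
  if (length(msgs)) msgs else TRUE
})

setClassUnion("TimeSeriesOrNULL", c("TimeSeries", "NULL"))

#' SubjectRecord: one crew member's channels and metadata for one flight
#'
#' SpO2, heart rate and mask-state channels share a single time grid (the
#' constructor [subjectRecord()] aligns them at ingestion); an altitude
#' profile is optional.
#'
#' @slot subject_id non-empty character scalar.
#' @slot age numeric scalar, years (\code{NA} when unknown).
#' @slot sex character scalar: \code{"F"}, \code{"M"} or
#'   \code{"unspecified"}.
#' @slot station integer seat number (\code{NA} when unknown).
#' @slot spo2,hr,mask [TimeSeries-class] channels on a common grid.
#' @slot altitude [TimeSeries-class] or \code{NULL}.
#' @export
setClass("SubjectRecord",
  representation(subject_id = "character", age = "numeric", sex = "character",
    station = "integer", spo2 = "TimeSeries", hr = "TimeSeries",
    mask = "TimeSeries", altitude = "TimeSeriesOrNULL"))

setValidity("SubjectRecord", function(object) {
  msgs <- character(0)
  if (length(object@subject_id) != 1L || is.na(object@subject_id) ||
      !nzchar(object@subject_id))
    msgs <- c(msgs, "subject_id must be a non-empty string")
  if (!object@sex %in% c("F", "M", "unspecified"))
    msgs <- c(msgs, "sex must be one of F, M, unspecified")
  t0 <- object@spo2@times
  if (!isTRUE(all.equal(t0, object@hr@times)) ||
      !isTRUE(all.equal(t0, object@mask@times)))
    msgs <- c(msgs, "spo2, hr and mask must share the same time grid")
  if (length(msgs)) msgs else TRUE
})

#' FlightRecord: one chamber flight with its crew
#'
#' @slot flight_id non-empty character scalar, unique within a sample.
#' @slot datetime ISO-8601 character scalar (wall-clock start of the flight).
#' @slot protocol free-text protocol label.
#' @slot flight_type free-text category, matched case-insensitively against
#'   the flight-type taxonomy by [applyFilters()].
#' @slot subjects list of [SubjectRecord-class], at least one.
#' @export
setClass("FlightRecord",
  representation(flight_id = "character", datetime = "character",
    protocol = "character", flight_type = "character", subjects = "list"))

setValidity("FlightRecord", function(object) {
  msgs <- character(0)
  if (length(object@flight_id) != 1L || !nzchar(object@flight_id))
    msgs <- c(msgs, "flight_id must be a non-empty string")
  if (length(object@subjects) < 1L)
    msgs <- c(msgs, "a flight must contain at least one subject")
  if (!all(vapply(object@subjects, is, logical(1), "SubjectRecord")))
    msgs <- c(msgs, "subjects must all be SubjectRecord objects")
  ids <- vapply(object@subjects, function(s) s@subject_id, character(1))
  if (anyDuplicated(ids))
    msgs <- c(msgs, "subject_ids must be distinct within a flight")
  if (length(msgs)) msgs else TRUE
})

#' FlightSample: an ordered collection of flights under joint analysis
#'
#' @slot flights list of [FlightRecord-class] with pairwise distinct
#'   flight ids.
#' @export
setClass("FlightSample", representation(flights = "list"))

setValidity("FlightSample", function(object) {
  msgs <- character(0)
  if (!all(vapply(object@flights, is, logical(1), "FlightRecord")))
    msgs <- c(msgs, "flights must all be FlightRecord objects")
  else {
    ids <- vapply(object@flights, function(f) f@flight_id, character(1))
    if (anyDuplicated(ids))
      msgs <- c(msgs, "flight_ids must be pairwise distinct")
  }
  if (length(msgs)) msgs else TRUE
})

#' MaskEvents: disconnection/reconnection intervals of the oxygen mask
#'
#' One row per maximal disconnected run of the mask channel. \code{DM} is the
#' disconnection time, \code{RM} the reconnection time; \code{RM} is \code{NA}
#' when the record ends disconnected (right-censored), which may only happen
#' for the last interval.
#'
#' @slot DM numeric, disconnection times (s).
#' @slot RM numeric, reconnection times (s); \code{NA} = censored.
#' @export
setClass("MaskEvents", representation(DM = "numeric", RM = "numeric"))

setValidity("MaskEvents", function(object) {
  msgs <- character(0)
  if (length(object@DM) != length(object@RM))
    msgs <- c(msgs, "DM and RM must have equal length")
  else if (length(object@DM)) {
    if (anyNA(object@DM)) msgs <- c(msgs, "DM must not be NA")
    cens <- which(is.na(object@RM))
    if (length(cens) > 1L || (length(cens) == 1L &&
        cens != length(object@RM)))
      msgs <- c(msgs, "only the last interval may have a censored RM")
    ok <- !is.na(object@RM)
    if (any(object@DM[ok] >= object@RM[ok]))
      msgs <- c(msgs, "DM must precede RM")
    if (length(object@DM) > 1L) {
      ends <- ifelse(is.na(object@RM), Inf, object@RM)
      if (any(diff(object@DM) <= 0) ||
          any(utils::head(ends, -1L) > object@DM[-1L]))
        msgs <- c(msgs, "intervals must be ordered and non-overlapping")
    }
  }
  if (length(msgs)) msgs else TRUE
})

.PHASE_NAMES <- c("DT", "DeD", "HD", "DeT", "HT", "RT")

#' PhaseParameters: the six phase durations of the desaturation curve
#'
#' All durations are in seconds. \code{DT} is the mask disconnection time
#' (RM - DM); \code{DeD}/\code{HD} the delays from disconnection until SpO2
#' first falls below the desaturation (default 97\%) and hypoxia (default
#' 90\%) thresholds; \code{DeT}/\code{HT} the total dwell time below those
#' thresholds over the whole test; \code{RT} the time from reconnection until
#' SpO2 reaches the recovery threshold (default 97\%) again.
#'
#' Each parameter carries a status: \code{"defined"} (value present),
#' \code{"undefined"} (the event can never occur, e.g. SpO2 never fell below
#' the threshold) or \code{"censored"} (the record ended before the event;
#' \code{censor_time} holds the duration observed up to the record end).
#'
#' @slot values named numeric of length 6 (\code{DT, DeD, HD, DeT, HT, RT});
#'   \code{NA} unless status is \code{"defined"}.
#' @slot status named character, per-parameter status.
#' @slot censor_time named numeric, observed partial duration for censored
#'   parameters, \code{NA} otherwise.
#' @slot thresholds named numeric: \code{desat}, \code{hypoxia},
#'   \code{recovery}, in percent SpO2.
#' @slot debounce integer, consecutive-sample debounce used for crossings.
#' @export
setClass("PhaseParameters",
  representation(values = "numeric", status = "character",
    censor_time = "numeric", thresholds = "numeric", debounce = "integer"))

setValidity("PhaseParameters", function(object) {
  msgs <- character(0)
  if (!identical(names(object@values), .PHASE_NAMES) ||
      !identical(names(object@status), .PHASE_NAMES) ||
      !identical(names(object@censor_time), .PHASE_NAMES))
    msgs <- c(msgs, "values, status, censor_time must be named DT, DeD, HD, DeT, HT, RT")
  else {
    if (!all(object@status %in% c("defined", "undefined", "censored")))
      msgs <- c(msgs, "status must be defined, undefined or censored")
    def <- object@status == "defined"
    if (anyNA(object@values[def]))
      msgs <- c(msgs, "defined parameters must carry a value")
    if (any(object@values[def] < 0))
      msgs <- c(msgs, "defined durations must be non-negative")
    v <- object@values
    if (def[["DeD"]] && def[["HD"]] && v[["DeD"]] > v[["HD"]] + 1e-9)
      msgs <- c(msgs, "DeD must not exceed HD")
    if (def[["HT"]] && def[["DeT"]] && v[["HT"]] > v[["DeT"]] + 1e-9)
      msgs <- c(msgs, "HT must not exceed DeT")
  }
  if (!all(c("desat", "hypoxia", "recovery") %in% names(object@thresholds)))
    msgs <- c(msgs, "thresholds must name desat, hypoxia, recovery")
  if (length(msgs)) msgs else TRUE
})

#' SegmentSlope: a fitted linear trend over one window of one channel
#'
#' Ordinary least squares over the samples inside the closed window
#' [t0, t1]; the slope is reported per minute (\%/min for SpO2, bpm/min for
#' heart rate) following the physiological convention for desaturation rates.
#'
#' @slot t0,t1 numeric window bounds, seconds, \code{t0 < t1}.
#' @slot channel \code{"spo2"} or \code{"hr"}.
#' @slot slope numeric, channel units per minute.
#' @slot intercept numeric, fitted value at \code{t0}, channel units.
#' @slot r_squared numeric in [0, 1]; defined as 1 whenever residuals are all
#'   zero, including a constant trace.
#' @slot n integer, number of non-missing samples used (>= 2).
#' @slot source \code{"automatic"} or \code{"manual"}.
#' @slot label character, segment label (\code{"baseline"},
#'   \code{"desaturation"}, \code{"recovery"} or \code{""}).
#' @export
setClass("SegmentSlope",
  representation(t0 = "numeric", t1 = "numeric", channel = "character",
    slope = "numeric", intercept = "numeric", r_squared = "numeric",
    n = "integer", source = "character", label = "character"))

setValidity("SegmentSlope", function(object) {
  msgs <- character(0)
  if (object@t0 >= object@t1) msgs <- c(msgs, "t0 must be < t1")
  if (object@n < 2L) msgs <- c(msgs, "a slope needs >= 2 samples")
  if (!object@source %in% c("automatic", "manual"))
    msgs <- c(msgs, "source must be automatic or manual")
  if (!is.na(object@r_squared) &&
      (object@r_squared < -1e-9 || object@r_squared > 1 + 1e-9))
    msgs <- c(msgs, "r_squared must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' FilterSpec: declarative cohort-selection criteria
#'
#' All criteria combine by conjunction (AND); an omitted criterion imposes no
#' constraint. Censored phase values fail a range check unless
#' \code{include_censored}.
#'
#' @slot identity character vector of subject ids to keep
#'   (length 0 = no constraint).
#' @slot age_range numeric length 2, (min, max) years; \code{NA} = open end.
#' @slot sex \code{NA} or one of \code{"F"}, \code{"M"},
#'   \code{"unspecified"}.
#' @slot mask_state \code{NA}, \code{"disconnected"} (subject has at least
#'   one mask disconnection) or \code{"connected"} (none).
#' @slot phase_ranges named list of numeric length-2 (min, max) ranges over
#'   \code{DT, DeD, HD, DeT, HT, RT}, seconds.
#' @slot flight_type one of \code{"total"}, \code{"valid"},
#'   \code{"day_and_night"}, \code{"day_only"}, \code{"decompression"},
#'   \code{"medical"}.
#' @slot include_censored logical; if \code{TRUE}, a censored phase value
#'   passes its range check instead of failing it.
#' @export
setClass("FilterSpec",
  representation(identity = "character", age_range = "numeric",
    sex = "character", mask_state = "character", phase_ranges = "list",
    flight_type = "character", include_censored = "logical"))

.FLIGHT_TYPES <- c("total", "valid", "day_and_night", "day_only",
  "decompression", "medical")

setValidity("FilterSpec", function(object) {
  msgs <- character(0)
  if (length(object@age_range) != 2L)
    msgs <- c(msgs, "age_range must have length 2")
  else if (!anyNA(object@age_range) &&
           object@age_range[1L] > object@age_range[2L])
    msgs <- c(msgs, "age_range min must be <= max")
  if (!is.na(object@sex) && !object@sex %in% c("F", "M", "unspecified"))
    msgs <- c(msgs, "sex must be F, M or unspecified")
  if (!is.na(object@mask_state) &&
      !object@mask_state %in% c("connected", "disconnected"))
    msgs <- c(msgs, "mask_state must be connected or disconnected")
  if (!object@flight_type %in% .FLIGHT_TYPES)
    msgs <- c(msgs, paste("flight_type must be one of:",
      paste(.FLIGHT_TYPES, collapse = ", ")))
  bad <- setdiff(names(object@phase_ranges), .PHASE_NAMES)
  if (length(bad))
    msgs <- c(msgs, paste0("unknown phase parameter in phase_ranges: ",
      paste(bad, collapse = ", ")))
  for (nm in names(object@phase_ranges)) {
    r <- object@phase_ranges[[nm]]
    if (length(r) != 2L || !is.numeric(r))
      msgs <- c(msgs, paste0("phase range ", nm, " must be numeric (min, max)"))
    else if (!anyNA(r) && r[1L] > r[2L])
      msgs <- c(msgs, paste0("phase range ", nm, ": min must be <= max"))
  }
  if (length(msgs)) msgs else TRUE
})
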