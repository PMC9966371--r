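#' Construct a TimeSeries
#'
#' @param times numeric, seconds from record start, strictly increasing.
#' @param values numeric channel measurements; \code{NA} = missing sample.
#' @param channel channel label: \code{"spo2"}, \code{"hr"}, \code{"mask"} or
#'   \code{"altitude"}.
#' @return a [TimeSeries-class]
#' @examples
#' ts <- timeSeries(0:9, rep(98, 10), "spo2")
#' samplingInterval(ts)
#' @export
timeSeries <- function(times, values, channel) {
  new("TimeSeries", times = as.numeric(times), values = as.numeric(values),
    channel = as.character(channel))
}

#' @rdname TimeSeries-class
#' @export
setMethod("tsTimes", "TimeSeries", function(x) x@times)

#' @rdname TimeSeries-class
#' @export
setMethod("tsValues", "TimeSeries", function(x) x@values)

#' @rdname TimeSeries-class
#' @export
setMethod("tsChannel", "TimeSeries", function(x) x@channel)

#' @describeIn TimeSeries-class nominal sampling interval: the median of
#'   successive time differences (s).
#' @export
setMethod("samplingInterval", "TimeSeries", function(x) {
  if (length(x@times) < 2L) return(NA_real_)
  stats::median(diff(x@times))
})

setMethod("length", "TimeSeries", function(x) length(x@times))

setMethod("show", "TimeSeries", function(object) {
  n <- length(object@times)
  cat(sprintf("TimeSeries <%s>: %d samples", object@channel, n))
  if (n) cat(sprintf(", t = [%g, %g] s, dt ~ %g s, %d missing",
    object@times[1L], object@times[n], samplingInterval(object),
    sum(is.na(object@values))))
  cat("\n")
})

# Restrict a TimeSeries to the closed window [t0, t1].
.tsWindow <- function(ts, t0, t1) {
  keep <- ts@times >= t0 & ts@times <= t1
  timeSeries(ts@times[keep], ts@values[keep], ts@channel)
}

# Resample a channel onto a target grid: previous-value hold for the step-like
# mask signal, linear interpolation for continuous vitals.
.resampleOnto <- function(ts, grid) {
  if (isTRUE(all.equal(ts@times, grid))) return(ts)
  ok <- !is.na(ts@values)
  if (sum(ok) < 2L)
    stop("cannot resample channel '", ts@channel,
      "': fewer than 2 non-missing samples")
  method <- if (identical(ts@channel, "mask")) "constant" else "linear"
  v <- stats::approx(ts@times[ok], ts@values[ok], xout = grid,
    method = method, rule = 2)$y
  if (identical(ts@channel, "mask")) v <- round(v)
  timeSeries(grid, v, ts@channel)
}

#' Construct a SubjectRecord, aligning channels onto the SpO2 grid
#'
#' If the heart-rate, mask or altitude channels arrive on a different time
#' grid than SpO2 they are resampled onto the SpO2 grid at ingestion:
#' previous-value hold for the mask (a step signal), linear interpolation for
#' the continuous vitals.
#'
#' @param subject_id non-empty string.
#' @param spo2,hr,mask [TimeSeries-class] channels.
#' @param altitude optional [TimeSeries-class] altitude profile, or
#'   \code{NULL}.
#' @param age years, \code{NA} if unknown.
#' @param sex \code{"F"}, \code{"M"} or \code{"unspecified"}.
#' @param station integer seat number, \code{NA} if unknown.
#' @return a [SubjectRecord-class]
#' @export
subjectRecord <- function(subject_id, spo2, hr, mask, altitude = NULL,
                          age = NA_real_, sex = "unspecified",
                          station = NA_integer_) {
  grid <- spo2@times
  hr <- .resampleOnto(hr, grid)
  mask <- .resampleOnto(mask, grid)
  if (!is.null(altitude)) altitude <- .resampleOnto(altitude, grid)
  new("SubjectRecord", subject_id = subject_id, age = as.numeric(age),
    sex = sex, station = as.integer(station), spo2 = spo2, hr = hr,
    mask = mask, altitude = altitude)
}

#' @rdname SubjectRecord-class
#' @export
setMethod("subjectId", "SubjectRecord", function(x) x@subject_id)

#' @rdname SubjectRecord-class
#' @export
setMethod("channel", "SubjectRecord", function(x, name) {
  switch(name,
    spo2 = x@spo2, hr = x@hr, mask = x@mask, altitude = x@altitude,
    stop("unknown channel: ", name))
})

setMethod("show", "SubjectRecord", function(object) {
  cat(sprintf("SubjectRecord '%s' (sex %s, age %s): %d samples over %g s\n",
    object@subject_id, object@sex,
    ifelse(is.na(object@age), "?", object@age), length(object@spo2@times),
    if (length(object@spo2@times)) max(object@spo2@times) else 0))
})

#' Construct a FlightRecord
#'
#' @param flight_id unique flight identifier.
#' @param subjects list of [SubjectRecord-class].
#' @param datetime ISO-8601 wall-clock start, e.g. \code{"2023-05-04T09:30:00"}.
#' @param protocol free-text protocol label.
#' @param flight_type free-text category (e.g. \code{"day_only"},
#'   \code{"decompression"}).
#' @return a [FlightRecord-class]
#' @export
flightRecord <- function(flight_id, subjects, datetime = "",
                         protocol = "", flight_type = "total") {
  new("FlightRecord", flight_id = flight_id, datetime = datetime,
    protocol = protocol, flight_type = flight_type, subjects = subjects)
}

#' @rdname FlightRecord-class
#' @export
setMethod("flightId", "FlightRecord", function(x) x@flight_id)

#' @rdname FlightRecord-class
#' @export
setMethod("subjects", "FlightRecord", function(x) x@subjects)

setMethod("show", "FlightRecord", function(object) {
  cat(sprintf("FlightRecord '%s' (%s, type %s): %d subject(s)\n",
    object@flight_id, object@datetime, object@flight_type,
    length(object@subjects)))
})

#' Construct a FlightSample
#'
#' @param flights list of [FlightRecord-class] with distinct ids.
#' @return a [FlightSample-class]
#' @export
flightSample <- function(flights = list()) {
  new("FlightSample", flights = flights)
}

#' @rdname FlightSample-class
#' @export
setMethod("flights", "FlightSample", function(x) x@flights)

#' @rdname FlightSample-class
#' @export
setMethod("flightId", "FlightSample", function(x)
  vapply(x@flights, flightId, character(1)))

setMethod("length", "FlightSample", function(x) length(x@flights))

setMethod("show", "FlightSample", function(object) {
  ns <- sum(vapply(object@flights, function(f) length(f@subjects), integer(1)))
  cat(sprintf("FlightSample: %d flight(s), %d subject(s)\n",
    length(object@flights), ns))
})
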