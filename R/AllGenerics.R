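#' @rdname TimeSeries-class
#' @param x a \code{TimeSeries}
#' @export
setGeneric("tsTimes", function(x) standardGeneric("tsTimes"))

#' @rdname TimeSeries-class
#' @export
setGeneric("tsValues", function(x) standardGeneric("tsValues"))

#' @rdname TimeSeries-class
#' @export
setGeneric("tsChannel", function(x) standardGeneric("tsChannel"))

#' @rdname TimeSeries-class
#' @export
setGeneric("samplingInterval", function(x) standardGeneric("samplingInterval"))

#' @rdname SubjectRecord-class
#' @param x an object with a subject identifier
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname SubjectRecord-class
#' @param x an object holding channels
#' @param name channel name: \code{"spo2"}, \code{"hr"}, \code{"mask"} or
#'   \code{"altitude"}
#' @export
setGeneric("channel", function(x, name) standardGeneric("channel"))

#' @rdname FlightRecord-class
#' @param x a \code{FlightRecord} or \code{FlightSample}
#' @export
setGeneric("flightId", function(x) standardGeneric("flightId"))

#' @rdname FlightRecord-class
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))

#' @rdname FlightSample-class
#' @param x a \code{FlightSample}
#' @export
setGeneric("flights", function(x) standardGeneric("flights"))

#' @rdname MaskEvents-class
#' @param x a \code{MaskEvents}
#' @export
setGeneric("nIntervals", function(x) standardGeneric("nIntervals"))

#' @rdname PhaseParameters-class
#' @param x a \code{PhaseParameters}
#' @export
setGeneric("phaseValues", function(x) standardGeneric("phaseValues"))

#' @rdname PhaseParameters-class
#' @export
setGeneric("phaseStatus", function(x) standardGeneric("phaseStatus"))

#' @rdname PhaseParameters-class
#' @export
setGeneric("censorTimes", function(x) standardGeneric("censorTimes"))
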