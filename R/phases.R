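#' Analysis configuration with the procedure's default thresholds
#'
#' The shipped defaults are the thresholds that define the phase parameters:
#' 97\% SpO2 for the desaturation-related phases (DeD, DeT, RT) and 90\% for
#' the hypoxia-related phases (HD, HT). Phase crossings use strictly
#' \code{< threshold}; recovery uses \code{>= threshold}.
#'
#' @param desat_threshold percent SpO2 below which a subject counts as
#'   desaturated (default 97).
#' @param hypoxia_threshold percent SpO2 below which a subject counts as
#'   hypoxic (default 90).
#' @param recovery_threshold percent SpO2 that must be re-reached after mask
#'   reconnection (default 97).
#' @param debounce minimum number of consecutive samples satisfying a
#'   threshold condition before a crossing is declared (default 1 = none).
#' @param max_gap maximum tolerated inter-sample interval, s, before a record
#'   is flagged discontinuous (default 5).
#' @param response_drop minimum SpO2 fall, percent, expected after mask
#'   disconnection (default 2).
#' @param response_window window after disconnection, s, within which the
#'   fall must occur (default 120).
#' @return a named list of class \code{oxiflight_config}
#' @seealso [readPhaseConfig()] to load a configuration from YAML or JSON.
#' @export
phaseConfig <- function(desat_threshold = 97, hypoxia_threshold = 90,
                        recovery_threshold = 97, debounce = 1L,
                        max_gap = 5, response_drop = 2,
                        response_window = 120) {
  stopifnot(debounce >= 1L, max_gap > 0, response_drop >= 0,
    response_window > 0)
  structure(list(desat_threshold = desat_threshold,
    hypoxia_threshold = hypoxia_threshold,
    recovery_threshold = recovery_threshold, debounce = as.integer(debounce),
    max_gap = max_gap, response_drop = response_drop,
    response_window = response_window), class = "oxiflight_config")
}

#' Read an analysis configuration from a YAML or JSON file
#'
#' Recognised keys are the arguments of [phaseConfig()]; unknown keys are an
#' error, omitted keys take the defaults.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return a configuration list as from [phaseConfig()]
#' @export
readPhaseConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(phaseConfig))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(phaseConfig, raw)
}

#' Detect oxygen-mask disconnection intervals
#'
#' Scans the binary mask channel for maximal runs of \code{mask == 0}
#' (disconnected). For each run, \code{DM} is the time of its first sample
#' and \code{RM} the time of the first reconnected sample after it; \code{RM}
#' is censored (\code{NA}) when the record ends disconnected.
#'
#' @param mask a [TimeSeries-class] with values in \{0, 1\}.
#' @return a [MaskEvents-class]
#' @examples
#' m <- timeSeries(0:5, c(1, 1, 0, 0, 0, 1), "mask")
#' detectMaskIntervals(m)  # DM = 2 s, RM = 5 s
#' @export
detectMaskIntervals <- function(mask) {
  v <- tsValues(mask)
  if (!length(v)) stop("mask series is empty")
  if (anyNA(v) || !all(v %in% c(0, 1)))
    stop("mask values must be 0 or 1")
  t <- tsTimes(mask)
  r <- rle(v == 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  off <- which(r$values)
  DM <- t[starts[off]]
  RM <- ifelse(ends[off] < length(v), t[pmin(ends[off] + 1L, length(v))],
    NA_real_)
  new("MaskEvents", DM = as.numeric(DM), RM = as.numeric(RM))
}

#' @rdname MaskEvents-class
#' @export
setMethod("nIntervals", "MaskEvents", function(x) length(x@DM))

#' @describeIn MaskEvents-class intervals as a data.frame with columns
#'   \code{DM}, \code{RM}, \code{censored}.
#' @param x a \code{MaskEvents}
#' @param ... unused
#' @export
setMethod("as.data.frame", "MaskEvents",
  function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(DM = x@DM, RM = x@RM, censored = is.na(x@RM))
})

setMethod("show", "MaskEvents", function(object) {
  cat(sprintf("MaskEvents: %d disconnection interval(s)\n", length(object@DM)))
  if (length(object@DM)) print(as.data.frame(object))
})

#' First threshold crossing of a trace
#'
#' The primitive behind the phase delays: returns the time of the first
#' sample at or after \code{anchor} that begins a run of at least
#' \code{debounce} consecutive samples satisfying the condition — strictly
#' \code{value < threshold} for \code{direction = "below"},
#' \code{value >= threshold} for \code{"at_or_above"}. Missing samples never
#' satisfy the condition and break a run.
#'
#' @param trace a [TimeSeries-class].
#' @param threshold percent SpO2 (or channel units).
#' @param direction \code{"below"} or \code{"at_or_above"}.
#' @param anchor earliest time, s, at which the crossing may start.
#' @param debounce minimum run length in samples (>= 1).
#' @return crossing time in seconds, or \code{NA_real_} if no qualifying run
#'   exists
#' @examples
#' tr <- timeSeries(0:10, 98 - 0.5 * (0:10), "spo2")
#' thresholdCrossingTime(tr, 97, "below", anchor = 0)  # 3: s(2) = 97 is not < 97
#' @export
thresholdCrossingTime <- function(trace, threshold,
                                  direction = c("below", "at_or_above"),
                                  anchor = 0, debounce = 1L) {
  direction <- match.arg(direction)
  stopifnot(debounce >= 1L)
  t <- tsTimes(trace)
  v <- tsValues(trace)
  keep <- t >= anchor
  t <- t[keep]; v <- v[keep]
  if (!length(t)) return(NA_real_)
  cond <- if (direction == "below") v < threshold else v >= threshold
  cond[is.na(cond)] <- FALSE
  if (debounce == 1L) {
    i <- which(cond)[1L]
    return(if (is.na(i)) NA_real_ else t[i])
  }
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= debounce)[1L]
  if (is.na(hit)) return(NA_real_)
  t[ends[hit] - r$lengths[hit] + 1L]
}

# Dwell time below a threshold: each sample strictly below contributes its
# local inter-sample interval; the last sample contributes the nominal dt.
.dwellTimeBelow <- function(trace, threshold) {
  t <- tsTimes(trace)
  v <- tsValues(trace)
  if (!length(t)) return(0)
  dt_nom <- samplingInterval(trace)
  if (is.na(dt_nom)) dt_nom <- 0
  w <- c(diff(t), dt_nom)
  below <- !is.na(v) & v < threshold
  sum(w[below])
}

.phase <- function(value, status = "defined", censor = NA_real_) {
  list(value = value, status = status, censor = censor)
}

#' Compute the six phase parameters of the desaturation curve
#'
#' Uses the first mask disconnection interval (DM, RM). With thresholds from
#' \code{config}:
#' \itemize{
#'   \item \code{DT} = RM - DM (censored at the record end if the mask is
#'     never reconnected);
#'   \item \code{DeD}/\code{HD} = delay from DM until SpO2 first falls below
#'     the desaturation/hypoxia threshold (undefined if it never does);
#'   \item \code{DeT}/\code{HT} = total dwell time below the
#'     desaturation/hypoxia threshold over the whole record, each sample
#'     below threshold contributing its local inter-sample interval;
#'   \item \code{RT} = delay from RM until SpO2 reaches the recovery
#'     threshold again (censored if never re-reached before the record ends,
#'     or if RM itself is censored).
#' }
#' With no disconnection interval, DT/DeD/HD/RT are undefined while DeT/HT
#' are still the whole-record dwell times.
#'
#' @param subject a [SubjectRecord-class].
#' @param config analysis configuration from [phaseConfig()].
#' @return a [PhaseParameters-class]
#' @export
computePhaseParameters <- function(subject, config = phaseConfig()) {
  stopifnot(is(subject, "SubjectRecord"))
  spo2 <- subject@spo2
  t <- tsTimes(spo2)
  ev <- detectMaskIntervals(subject@mask)
  deb <- config$debounce
  end_t <- t[length(t)]

  DeT <- .phase(.dwellTimeBelow(spo2, config$desat_threshold))
  HT <- .phase(.dwellTimeBelow(spo2, config$hypoxia_threshold))

  if (nIntervals(ev) == 0L) {
    DT <- DeD <- HD <- RT <- .phase(NA_real_, "undefined")
  } else {
    DM <- ev@DM[1L]
    RM <- ev@RM[1L]
    DT <- if (is.na(RM)) .phase(NA_real_, "censored", end_t - DM)
      else .phase(RM - DM)
    cr <- function(th) thresholdCrossingTime(spo2, th, "below",
      anchor = DM, debounce = deb)
    ded_t <- cr(config$desat_threshold)
    DeD <- if (is.na(ded_t)) .phase(NA_real_, "undefined")
      else .phase(ded_t - DM)
    hd_t <- cr(config$hypoxia_threshold)
    HD <- if (is.na(hd_t)) .phase(NA_real_, "undefined")
      else .phase(hd_t - DM)
    if (is.na(RM)) {
      RT <- .phase(NA_real_, "censored", NA_real_)
    } else {
      rt_t <- thresholdCrossingTime(spo2, config$recovery_threshold,
        "at_or_above", anchor = RM, debounce = deb)
      RT <- if (is.na(rt_t)) .phase(NA_real_, "censored", end_t - RM)
        else .phase(rt_t - RM)
    }
  }

  ph <- list(DT = DT, DeD = DeD, HD = HD, DeT = DeT, HT = HT, RT = RT)
  new("PhaseParameters",
    values = vapply(ph, `[[`, numeric(1), "value"),
    status = vapply(ph, `[[`, character(1), "status"),
    censor_time = vapply(ph, `[[`, numeric(1), "censor"),
    thresholds = c(desat = config$desat_threshold,
      hypoxia = config$hypoxia_threshold,
      recovery = config$recovery_threshold),
    debounce = deb)
}

#' @rdname PhaseParameters-class
#' @export
setMethod("phaseValues", "PhaseParameters", function(x) x@values)

#' @rdname PhaseParameters-class
#' @export
setMethod("phaseStatus", "PhaseParameters", function(x) x@status)

#' @rdname PhaseParameters-class
#' @export
setMethod("censorTimes", "PhaseParameters", function(x) x@censor_time)

#' @describeIn PhaseParameters-class one row per parameter with value, status
#'   and censoring time.
#' @param x a \code{PhaseParameters}
#' @param ... unused
#' @export
setMethod("as.data.frame", "PhaseParameters",
  function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(parameter = .PHASE_NAMES, value_s = unname(x@values),
    status = unname(x@status), censor_time_s = unname(x@censor_time))
})

setMethod("show", "PhaseParameters", function(object) {
  cat(sprintf(
    "PhaseParameters (thresholds: desat %g%%, hypoxia %g%%, recovery %g%%)\n",
    object@thresholds[["desat"]], object@thresholds[["hypoxia"]],
    object@thresholds[["recovery"]]))
  print(as.data.frame(object))
})
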