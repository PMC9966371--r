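#' Fit an ordinary-least-squares slope over a window of one channel
#'
#' Fits a straight line to the non-missing samples inside the closed window
#' \code{[t0, t1]}. The slope is reported per minute (\%/min or bpm/min);
#' the intercept is the fitted value at \code{t0}. The coefficient of
#' determination is defined as 1 whenever residuals are all zero, which
#' covers the constant-trace case where the total sum of squares is 0.
#'
#' @param trace a [TimeSeries-class].
#' @param t0,t1 window bounds, s (closed interval).
#' @param source \code{"automatic"} or \code{"manual"}.
#' @param label optional segment label.
#' @return a [SegmentSlope-class]
#' @examples
#' tr <- timeSeries(0:10, 98 - 0.5 * (0:10), "spo2")
#' fitSegmentSlope(tr, 0, 10)  # slope -30 %/min, r^2 = 1
#' @export
fitSegmentSlope <- function(trace, t0, t1, source = "automatic", label = "") {
  stopifnot(t0 < t1)
  w <- .tsWindow(trace, t0, t1)
  ok <- !is.na(w@values)
  if (sum(ok) < 2L)
    stop("insufficient data: window [", t0, ", ", t1,
      "] holds fewer than 2 non-missing samples")
  x <- w@times[ok]
  y <- w@values[ok]
  xm <- mean(x); ym <- mean(y)
  sxx <- sum((x - xm)^2)
  b <- sum((x - xm) * (y - ym)) / sxx
  a <- ym - b * xm
  res <- y - (a + b * x)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - ym)^2)
  r2 <- if (ss_res <= 1e-12 * max(1, ss_tot)) 1 else 1 - ss_res / ss_tot
  new("SegmentSlope", t0 = t0, t1 = t1, channel = w@channel,
    slope = b * 60, intercept = a + b * t0, r_squared = r2,
    n = sum(ok), source = source, label = label)
}

#' @describeIn SegmentSlope-class one-row data.frame of the fit.
#' @param x a \code{SegmentSlope}
#' @param ... unused
#' @export
setMethod("as.data.frame", "SegmentSlope",
  function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(label = x@label, channel = x@channel, t0 = x@t0, t1 = x@t1,
    slope_per_min = x@slope, intercept = x@intercept,
    r_squared = x@r_squared, n = x@n, source = x@source)
})

setMethod("show", "SegmentSlope", function(object) {
  cat(sprintf(
    "SegmentSlope [%s/%s] (%g, %g) s: %.4g %s/min (r^2 = %.4f, n = %d, %s)\n",
    object@label, object@channel, object@t0, object@t1, object@slope,
    if (object@channel == "spo2") "%" else "bpm", object@r_squared,
    object@n, object@source))
})

#' Automatic phase-anchored segment slopes
#'
#' Fits slopes for SpO2 and heart rate over three windows anchored at the
#' phase landmarks of the first disconnection interval: \emph{baseline}
#' (record start to DM), \emph{desaturation} (DM to the time of the SpO2
#' minimum inside the disconnection interval) and \emph{recovery} (RM to
#' RM + RT). Windows with an undefined endpoint, or holding fewer than two
#' samples, are skipped. A manual refit of any window via
#' [fitSegmentSlope()] with \code{source = "manual"} carries the same window
#' semantics and replaces the automatic segment.
#'
#' @param subject a [SubjectRecord-class].
#' @param phases the subject's [PhaseParameters-class].
#' @return list of [SegmentSlope-class] (possibly empty); see
#'   [segmentTable()] for a tabular view
#' @export
autoSegment <- function(subject, phases) {
  stopifnot(is(subject, "SubjectRecord"), is(phases, "PhaseParameters"))
  ev <- detectMaskIntervals(subject@mask)
  t <- tsTimes(subject@spo2)
  windows <- list()
  t_start <- t[1L]
  t_end <- t[length(t)]
  if (nIntervals(ev) == 0L) {
    windows$baseline <- c(t_start, t_end)
  } else {
    DM <- ev@DM[1L]
    RM <- ev@RM[1L]
    if (DM > t_start) windows$baseline <- c(t_start, DM)
    iv_end <- if (is.na(RM)) t_end else RM
    in_iv <- t >= DM & t <= iv_end
    v_iv <- tsValues(subject@spo2)[in_iv]
    if (any(!is.na(v_iv))) {
      t_min <- t[in_iv][which.min(v_iv)]
      if (t_min > DM) windows$desaturation <- c(DM, t_min)
    }
    rt <- phaseValues(phases)[["RT"]]
    if (!is.na(RM) && phaseStatus(phases)[["RT"]] == "defined" && rt > 0)
      windows$recovery <- c(RM, RM + rt)
  }
  out <- list()
  for (nm in names(windows)) {
    w <- windows[[nm]]
    for (ch in c("spo2", "hr")) {
      fit <- tryCatch(
        fitSegmentSlope(channel(subject, ch), w[1L], w[2L],
          source = "automatic", label = nm),
        error = function(e) NULL)
      if (!is.null(fit)) out[[length(out) + 1L]] <- fit
    }
  }
  out
}

#' Tabulate a list of segment slopes
#'
#' @param segments list of [SegmentSlope-class], as from [autoSegment()].
#' @return data.frame with one row per segment
#' @export
segmentTable <- function(segments) {
  if (!length(segments))
    return(data.frame(label = character(0), channel = character(0),
      t0 = numeric(0), t1 = numeric(0), slope_per_min = numeric(0),
      intercept = numeric(0), r_squared = numeric(0), n = integer(0),
      source = character(0)))
  do.call(rbind, lapply(segments, as.data.frame))
}

#' Minimum, maximum, mean and slope of a trace window
#'
#' Statistics over the non-missing samples of the closed window (the whole
#' record when \code{t0}/\code{t1} are omitted). The slope comes from
#' [fitSegmentSlope()] and is \code{NA} when fewer than two samples are
#' available.
#'
#' @param trace a [TimeSeries-class].
#' @param t0,t1 optional window bounds, s; default the whole record.
#' @return one-row data.frame with columns \code{channel}, \code{t0},
#'   \code{t1}, \code{minimum}, \code{maximum}, \code{mean},
#'   \code{slope_per_min}, \code{n}
#' @export
summarizeTrace <- function(trace, t0 = NULL, t1 = NULL) {
  tt <- tsTimes(trace)
  if (!length(tt)) stop("empty trace")
  if (is.null(t0)) t0 <- tt[1L]
  if (is.null(t1)) t1 <- tt[length(tt)]
  w <- .tsWindow(trace, t0, t1)
  v <- w@values[!is.na(w@values)]
  if (!length(v)) stop("window [", t0, ", ", t1, "] holds no non-missing samples")
  slope <- if (length(v) >= 2L)
    fitSegmentSlope(trace, t0, t1)@slope else NA_real_
  data.frame(channel = w@channel, t0 = t0, t1 = t1, minimum = min(v),
    maximum = max(v), mean = mean(v), slope_per_min = slope,
    n = length(v))
}
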