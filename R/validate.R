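#' Check a record's suitability for phase analysis
#'
#' Automates the visual-inspection step preceding inclusion in a group
#' analysis: the recording must be continuous, and the SpO2 response must
#' coincide with the mask disconnection. Four defects are flagged:
#' \describe{
#'   \item{gap_too_long}{some inter-sample interval exceeds \code{max_gap}.}
#'   \item{mask_events_missing}{no mask disconnection interval was found.}
#'   \item{no_desaturation_response}{SpO2 fails to fall by at least
#'     \code{response_drop} percent, relative to its value at disconnection,
#'     within \code{response_window} seconds after DM.}
#'   \item{out_of_range_values}{some SpO2 sample lies outside [0, 100].}
#' }
#'
#' @param subject a [SubjectRecord-class].
#' @param config analysis configuration from [phaseConfig()] supplying
#'   \code{max_gap}, \code{response_drop} and \code{response_window}.
#' @return list with elements \code{valid} (logical) and \code{reasons}
#'   (character vector, empty iff valid)
#' @export
validateRecord <- function(subject, config = phaseConfig()) {
  stopifnot(is(subject, "SubjectRecord"))
  reasons <- character(0)
  spo2 <- subject@spo2
  t <- tsTimes(spo2)
  v <- tsValues(spo2)
  if (length(t) > 1L && any(diff(t) > config$max_gap))
    reasons <- c(reasons, "gap_too_long")
  ev <- detectMaskIntervals(subject@mask)
  if (nIntervals(ev) == 0L) {
    reasons <- c(reasons, "mask_events_missing")
  } else {
    DM <- ev@DM[1L]
    # reference level: last non-missing sample at or before disconnection,
    # falling back to the first non-missing one after it
    pre <- v[t <= DM & !is.na(v)]
    post <- v[t > DM & !is.na(v)]
    ref <- if (length(pre)) pre[length(pre)] else post[1L]
    win <- v[t >= DM & t <= DM + config$response_window]
    win <- win[!is.na(win)]
    if (is.na(ref) || !length(win) ||
        (ref - min(win)) < config$response_drop)
      reasons <- c(reasons, "no_desaturation_response")
  }
  if (any(v < 0 | v > 100, na.rm = TRUE))
    reasons <- c(reasons, "out_of_range_values")
  list(valid = length(reasons) == 0L, reasons = reasons)
}
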