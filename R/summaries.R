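#' Align subjects onto a common time grid
#'
#' Shifts each subject's channel so that the chosen anchor maps to t = 0
#' (the first mask disconnection by default, since the phenomenon of interest
#' is the post-disconnection response) and linearly interpolates it onto a
#' common uniform grid. Timepoints outside a subject's recording span are
#' missing; per-timepoint availability is therefore auditable downstream via
#' the non-missing counts.
#'
#' @param subjects list of [SubjectRecord-class], or a
#'   [FlightSample-class] (all its subjects, in flight order).
#' @param channel \code{"spo2"} or \code{"hr"}.
#' @param anchor \code{"disconnection"} (t = 0 at the first DM; every
#'   subject must have one) or \code{"record_start"}.
#' @param dt_out output grid step, s; default the median native sampling
#'   interval across subjects.
#' @return a \linkS4class{SummarizedExperiment}: rows = subjects (rowData
#'   \code{subject_id}, \code{flight_id}), columns = grid timepoints
#'   (colData \code{time_s}), one assay named after the channel
#' @export
alignAndResample <- function(subjects, channel = c("spo2", "hr"),
                             anchor = c("disconnection", "record_start"),
                             dt_out = NULL) {
  channel <- match.arg(channel)
  anchor <- match.arg(anchor)
  if (is(subjects, "FlightSample")) {
    fl_ids <- rep(flightId(subjects),
      vapply(subjects@flights, function(f) length(f@subjects), integer(1)))
    subjects <- unlist(lapply(subjects@flights, slot, "subjects"),
      recursive = FALSE)
  } else {
    fl_ids <- rep(NA_character_, length(subjects))
  }
  if (!length(subjects)) stop("no subjects to align")
  ids <- vapply(subjects, subjectId, character(1))
  row_ids <- if (anyDuplicated(ids) && !anyNA(fl_ids))
    paste(fl_ids, ids, sep = "/") else ids

  shifted <- lapply(subjects, function(s) {
    ts <- channel(s, channel)
    off <- if (anchor == "disconnection") {
      ev <- detectMaskIntervals(s@mask)
      if (nIntervals(ev) == 0L)
        stop("subject '", s@subject_id,
          "' has no mask disconnection to anchor on")
      ev@DM[1L]
    } else tsTimes(ts)[1L]
    list(t = tsTimes(ts) - off, v = tsValues(ts))
  })
  if (is.null(dt_out))
    dt_out <- stats::median(vapply(subjects,
      function(s) samplingInterval(channel(s, channel)), numeric(1)))
  t_lo <- min(vapply(shifted, function(x) x$t[1L], numeric(1)))
  t_hi <- max(vapply(shifted, function(x) x$t[length(x$t)], numeric(1)))
  grid <- seq(t_lo, t_hi, by = dt_out)
  m <- t(vapply(shifted, function(x) {
    ok <- !is.na(x$v)
    if (sum(ok) < 2L) return(rep(NA_real_, length(grid)))
    stats::approx(x$t[ok], x$v[ok], xout = grid, method = "linear",
      rule = 1)$y
  }, numeric(length(grid))))
  dimnames(m) <- list(row_ids, NULL)
  SummarizedExperiment::SummarizedExperiment(
    assays = stats::setNames(list(m), channel),
    rowData = S4Vectors::DataFrame(subject_id = ids, flight_id = fl_ids,
      row.names = row_ids),
    colData = S4Vectors::DataFrame(time_s = grid),
    metadata = list(channel = channel, anchor = anchor, dt_out = dt_out))
}

#' Per-timepoint group curve (mean±SD or median±IQR)
#'
#' Statistics are computed per timepoint over the subjects with a
#' non-missing value there (pairwise-available, no listwise deletion);
#' \code{n} records how many contributed. The SD is the sample standard
#' deviation (n − 1 denominator), taken as 0 when a single subject
#' contributes; quartiles use linear interpolation (R type 7).
#'
#' @param aligned a \linkS4class{SummarizedExperiment} from
#'   [alignAndResample()].
#' @param method \code{"mean_sd"} or \code{"median_iqr"}.
#' @return data.frame with columns \code{time_s}, \code{center},
#'   \code{dispersion_low}, \code{dispersion_high}, \code{n}; the method is
#'   attached as attribute \code{"method"}
#' @export
groupCurve <- function(aligned, method = c("mean_sd", "median_iqr")) {
  method <- match.arg(method)
  m <- SummarizedExperiment::assay(aligned, 1L)
  if (!nrow(m)) stop("aligned matrix has no subjects")
  grid <- SummarizedExperiment::colData(aligned)$time_s
  n <- colSums(!is.na(m))
  if (method == "mean_sd") {
    center <- colMeans(m, na.rm = TRUE)
    disp <- apply(m, 2L, function(col) {
      col <- col[!is.na(col)]
      if (length(col) <= 1L) 0 else stats::sd(col)
    })
    lo <- center - disp
    hi <- center + disp
  } else {
    center <- apply(m, 2L, stats::median, na.rm = TRUE)
    lo <- apply(m, 2L, stats::quantile, probs = 0.25, na.rm = TRUE,
      names = FALSE, type = 7)
    hi <- apply(m, 2L, stats::quantile, probs = 0.75, na.rm = TRUE,
      names = FALSE, type = 7)
  }
  center[n == 0L] <- NA_real_
  lo[n == 0L] <- NA_real_
  hi[n == 0L] <- NA_real_
  out <- data.frame(time_s = grid, center = unname(center),
    dispersion_low = unname(lo), dispersion_high = unname(hi),
    n = unname(n))
  attr(out, "method") <- method
  out
}

#' Heat-map matrix of an aligned cohort
#'
#' Returns the numeric subjects-by-timepoints matrix together with the
#' colour-scale bounds: SpO2 defaults to [60, 100] (baseline down to the
#' expected nadir at 25,000 ft); heart rate defaults to the data range.
#' Rendering (see [plotHeatmap()]) is a thin optional layer and never
#' mutates the matrix.
#'
#' @param aligned a \linkS4class{SummarizedExperiment} from
#'   [alignAndResample()].
#' @param value_range optional numeric \code{c(low, high)} colour bounds.
#' @return list with \code{matrix}, \code{time_s}, \code{subject_ids},
#'   \code{value_range}, \code{channel}
#' @export
heatmapMatrix <- function(aligned, value_range = NULL) {
  m <- SummarizedExperiment::assay(aligned, 1L)
  if (!nrow(m)) stop("aligned matrix has no subjects")
  ch <- S4Vectors::metadata(aligned)$channel
  if (is.null(value_range)) {
    value_range <- if (identical(ch, "spo2")) c(60, 100)
      else range(m, na.rm = TRUE)
  }
  list(matrix = m,
    time_s = SummarizedExperiment::colData(aligned)$time_s,
    subject_ids = rownames(m), value_range = value_range, channel = ch)
}

#' Render a heat map to a PNG file
#'
#' @param hm list from [heatmapMatrix()].
#' @param file destination PNG path.
#' @param ... further arguments to \code{pheatmap::pheatmap}.
#' @return \code{file}, invisibly
#' @export
plotHeatmap <- function(hm, file, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("heat-map rendering needs the 'pheatmap' package")
  breaks <- seq(hm$value_range[1L], hm$value_range[2L], length.out = 101)
  m <- hm$matrix
  m[m < hm$value_range[1L]] <- hm$value_range[1L]
  m[m > hm$value_range[2L]] <- hm$value_range[2L]
  pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
    breaks = breaks, show_colnames = FALSE, filename = file, ...)
  invisible(file)
}

#' Descriptive statistical summary of a cohort table
#'
#' Per-variable n, mean, SD, median, quartiles and range over the defined,
#' non-censored values of each phase parameter and over the non-missing
#' values of each trace statistic; censored counts are reported separately
#' and censored values never enter the statistics. With a single value the
#' SD is \code{NA} (undefined). Quartiles use linear interpolation (type 7).
#'
#' @param phase_table per-subject table from [phaseTable()] (or any
#'   data.frame with the same column conventions: a numeric column per
#'   variable, and optionally a matching \code{<var>_status} column with
#'   values defined/undefined/censored).
#' @param variables character vector of columns to summarize; default all
#'   six phase parameters plus any trace-stat columns present.
#' @return data.frame with one row per variable: \code{variable}, \code{n},
#'   \code{mean}, \code{sd}, \code{median}, \code{q1}, \code{q3},
#'   \code{min}, \code{max}, \code{censored_count}
#' @export
descriptiveSummary <- function(phase_table, variables = NULL) {
  if (!nrow(phase_table)) stop("empty cohort")
  if (is.null(variables)) {
    stat_cols <- grep("^(spo2|hr)_(min|max|mean|slope)$",
      names(phase_table), value = TRUE)
    variables <- c(intersect(.PHASE_NAMES, names(phase_table)), stat_cols)
  }
  rows <- lapply(variables, function(v) {
    if (!v %in% names(phase_table)) stop("unknown variable: ", v)
    x <- phase_table[[v]]
    st_col <- paste0(v, "_status")
    if (st_col %in% names(phase_table)) {
      st <- phase_table[[st_col]]
      cens <- sum(st == "censored", na.rm = TRUE)
      x <- x[st == "defined"]
    } else {
      cens <- 0L
      x <- x[!is.na(x)]
    }
    x <- x[!is.na(x)]
    n <- length(x)
    q <- if (n) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE,
      type = 7) else rep(NA_real_, 3L)
    data.frame(variable = v, n = n,
      mean = if (n) mean(x) else NA_real_,
      sd = if (n >= 2L) stats::sd(x) else NA_real_,
      median = q[2L], q1 = q[1L], q3 = q[3L],
      min = if (n) min(x) else NA_real_,
      max = if (n) max(x) else NA_real_,
      censored_count = cens)
  })
  do.call(rbind, rows)
}
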