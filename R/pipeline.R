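#' Per-subject analysis table for a sample
#'
#' Runs mask-event detection, phase computation, whole-record trace
#' statistics and the validity check for every subject of every flight, and
#' assembles the results into one flat table — the working currency of the
#' cohort filters and group summaries.
#'
#' @param sample a [FlightSample-class] (or a single
#'   [FlightRecord-class]).
#' @param config analysis configuration from [phaseConfig()].
#' @return data.frame with one row per subject: identifiers and metadata,
#'   \code{n_mask_intervals}, \code{DM}, \code{RM}, the six phase parameters
#'   (\code{<p>} value and \code{<p>_status}), whole-record
#'   \code{spo2_min/max/mean/slope} and \code{hr_*}, \code{valid} and
#'   \code{invalid_reasons}
#' @export
phaseTable <- function(sample, config = phaseConfig()) {
  if (is(sample, "FlightRecord")) sample <- flightSample(list(sample))
  stopifnot(is(sample, "FlightSample"))
  rows <- list()
  for (fl in sample@flights) {
    for (s in fl@subjects) {
      ev <- detectMaskIntervals(s@mask)
      ph <- computePhaseParameters(s, config)
      vr <- validateRecord(s, config)
      st_s <- summarizeTrace(s@spo2)
      st_h <- summarizeTrace(s@hr)
      v <- phaseValues(ph)
      st <- phaseStatus(ph)
      row <- data.frame(flight_id = fl@flight_id,
        flight_type = fl@flight_type, subject_id = s@subject_id,
        age = s@age, sex = s@sex,
        n_mask_intervals = nIntervals(ev),
        DM = if (nIntervals(ev)) ev@DM[1L] else NA_real_,
        RM = if (nIntervals(ev)) ev@RM[1L] else NA_real_)
      for (p in .PHASE_NAMES) {
        row[[p]] <- v[[p]]
        row[[paste0(p, "_status")]] <- st[[p]]
      }
      row$spo2_min <- st_s$minimum; row$spo2_max <- st_s$maximum
      row$spo2_mean <- st_s$mean; row$spo2_slope <- st_s$slope_per_min
      row$hr_min <- st_h$minimum; row$hr_max <- st_h$maximum
      row$hr_mean <- st_h$mean; row$hr_slope <- st_h$slope_per_min
      row$valid <- vr$valid
      row$invalid_reasons <- paste(vr$reasons, collapse = ";")
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) stop("sample contains no subjects")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.readSampleFiles <- function(paths) {
  if (!length(paths)) stop("no input flight files given")
  flightSample(lapply(paths, readFlightRecord))
}

#' Analyze flights end to end and export per-subject reports
#'
#' For every subject of every input flight: validity check, phase
#' parameters, automatic segment slopes, trace statistics, and a JSON +
#' plain-text report. A combined per-subject table and a segment-slope table
#' are written as CSV. Subjects whose record fails analysis are reported
#' with a warning and flagged in the table, not fatal.
#'
#' @param flight_paths character vector of sidecar JSON paths.
#' @param out_dir output directory (created if needed); writes
#'   \code{phase_table.csv}, \code{segments.csv} and
#'   \code{reports/<flight>_<subject>.json/.txt}.
#' @param config analysis configuration from [phaseConfig()].
#' @return the phase table, invisibly
#' @export
cmdAnalyze <- function(flight_paths, out_dir, config = phaseConfig()) {
  sample <- .readSampleFiles(flight_paths)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rep_dir <- file.path(out_dir, "reports")
  if (!dir.exists(rep_dir)) dir.create(rep_dir)
  tab <- phaseTable(sample, config)
  segs <- list()
  for (fl in sample@flights) {
    for (s in fl@subjects) {
      res <- tryCatch({
        ph <- computePhaseParameters(s, config)
        seg <- segmentTable(autoSegment(s, ph))
        stats <- rbind(summarizeTrace(s@spo2), summarizeTrace(s@hr))
        base <- file.path(rep_dir,
          paste0(fl@flight_id, "_", s@subject_id))
        exportReport(s, ph, stats, paste0(base, ".json"))
        exportReport(s, ph, stats, paste0(base, ".txt"))
        seg
      }, error = function(e) {
        warning("subject '", s@subject_id, "' of flight '", fl@flight_id,
          "' failed: ", conditionMessage(e))
        NULL
      })
      if (!is.null(res) && nrow(res)) {
        res <- cbind(flight_id = fl@flight_id, subject_id = s@subject_id,
          res)
        segs[[length(segs) + 1L]] <- res
      }
    }
  }
  utils::write.csv(tab, file.path(out_dir, "phase_table.csv"),
    row.names = FALSE)
  seg_tab <- if (length(segs)) do.call(rbind, segs) else
    data.frame(flight_id = character(0), subject_id = character(0))
  utils::write.csv(seg_tab, file.path(out_dir, "segments.csv"),
    row.names = FALSE)
  invisible(tab)
}

.writeAligned <- function(aligned, file) {
  m <- SummarizedExperiment::assay(aligned, 1L)
  df <- data.frame(subject_id = rownames(m), m, check.names = FALSE)
  names(df)[-1L] <- as.character(
    SummarizedExperiment::colData(aligned)$time_s)
  utils::write.csv(df, file, row.names = FALSE)
}

#' Filter a cohort and write its group summaries
#'
#' Applies the filter specification, aligns the retained subjects on the
#' chosen anchor, and writes group curves, heat-map matrices and the
#' descriptive summary as CSV (deterministic given inputs and
#' configuration). Heat maps are rendered to PNG when \code{render = TRUE}
#' and the \code{pheatmap} package is available.
#'
#' @param flight_paths character vector of sidecar JSON paths.
#' @param out_dir output directory; writes
#'   \code{group_curve_<channel>.csv}, \code{heatmap_<channel>.csv},
#'   \code{descriptive_summary.csv} and \code{cohort_subjects.csv}.
#' @param filters \code{NULL}, a [FilterSpec-class], or the path to a JSON
#'   spec from [saveFilters()].
#' @param config analysis configuration from [phaseConfig()].
#' @param method \code{"mean_sd"} or \code{"median_iqr"}.
#' @param anchor \code{"disconnection"} or \code{"record_start"}.
#' @param dt_out output grid step, s.
#' @param render render heat maps to PNG (default \code{FALSE}).
#' @return list with \code{phase_table}, \code{summary}, \code{curves},
#'   invisibly
#' @export
cmdSummarize <- function(flight_paths, out_dir, filters = NULL,
                         config = phaseConfig(), method = "mean_sd",
                         anchor = "disconnection", dt_out = 1,
                         render = FALSE) {
  sample <- .readSampleFiles(flight_paths)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tab <- phaseTable(sample, config)
  spec <- if (is.null(filters)) filterSpec()
    else if (is(filters, "FilterSpec")) filters
    else loadFilters(filters)
  flt <- applyFilters(sample, tab, spec)
  if (!length(flt$sample@flights))
    stop("empty cohort: the filter specification removed every subject")
  keep <- paste(tab$flight_id, tab$subject_id) %in%
    paste(flt$subjects$flight_id, flt$subjects$subject_id)
  tab_kept <- tab[keep, , drop = FALSE]
  utils::write.csv(flt$subjects, file.path(out_dir, "cohort_subjects.csv"),
    row.names = FALSE)
  curves <- list()
  for (ch in c("spo2", "hr")) {
    aligned <- alignAndResample(flt$sample, channel = ch, anchor = anchor,
      dt_out = dt_out)
    gc <- groupCurve(aligned, method)
    curves[[ch]] <- gc
    utils::write.csv(gc, file.path(out_dir,
      paste0("group_curve_", ch, ".csv")), row.names = FALSE)
    .writeAligned(aligned, file.path(out_dir,
      paste0("heatmap_", ch, ".csv")))
    if (render && requireNamespace("pheatmap", quietly = TRUE))
      plotHeatmap(heatmapMatrix(aligned),
        file.path(out_dir, paste0("heatmap_", ch, ".png")))
  }
  summ <- descriptiveSummary(tab_kept)
  utils::write.csv(summ, file.path(out_dir, "descriptive_summary.csv"),
    row.names = FALSE)
  invisible(list(phase_table = tab_kept, summary = summ, curves = curves))
}

#' Generate and store a synthetic flight
#'
#' Writes the flight-record files plus the ground-truth table
#' (\code{ground_truth.csv}) to \code{out_dir}.
#'
#' @param out_dir output directory.
#' @param n_subjects number of subjects.
#' @param seed master seed.
#' @param base_params a [syntheticParams()] list.
#' @param between_subject_sd named list of jitter SDs (see
#'   [generateFlight()]).
#' @param flight_id flight identifier.
#' @param ... further metadata passed to [generateFlight()].
#' @return path of the written sidecar, invisibly
#' @export
cmdSynth <- function(out_dir, n_subjects = 8L, seed = 1L,
                     base_params = syntheticParams(),
                     between_subject_sd = list(), flight_id = "FL001",
                     ...) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  g <- generateFlight(n_subjects, base_params = base_params,
    between_subject_sd = between_subject_sd, seed = seed,
    flight_id = flight_id, ...)
  path <- file.path(out_dir, paste0(flight_id, ".json"))
  writeFlightRecord(g$flight, path)
  utils::write.csv(g$truth, file.path(out_dir, "ground_truth.csv"),
    row.names = FALSE)
  invisible(path)
}
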