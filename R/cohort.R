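#' Construct a cohort filter specification
#'
#' All criteria combine by conjunction; an omitted criterion imposes no
#' constraint, so the default spec keeps every subject.
#'
#' @param identity character vector of subject ids to keep (empty = no
#'   constraint).
#' @param age_range numeric \code{c(min, max)} in years; \code{NA} leaves an
#'   end open.
#' @param sex \code{NA} or \code{"F"}/\code{"M"}/\code{"unspecified"}.
#' @param mask_state \code{NA}, \code{"disconnected"} (subject must have a
#'   mask disconnection interval) or \code{"connected"} (must have none).
#' @param phase_ranges named list of \code{c(min, max)} ranges in seconds
#'   over \code{DT, DeD, HD, DeT, HT, RT}.
#' @param flight_type \code{"total"} (no validity constraint),
#'   \code{"valid"} (keep only subjects whose validity check passes), or one
#'   of the flight categories \code{"day_and_night"}, \code{"day_only"},
#'   \code{"decompression"}, \code{"medical"} matched case-insensitively
#'   against the flight metadata.
#' @param include_censored if \code{TRUE}, censored phase values pass range
#'   checks instead of failing them.
#' @return a [FilterSpec-class]
#' @export
filterSpec <- function(identity = character(0),
                       age_range = c(NA_real_, NA_real_),
                       sex = NA_character_, mask_state = NA_character_,
                       phase_ranges = list(), flight_type = "total",
                       include_censored = FALSE) {
  new("FilterSpec", identity = as.character(identity),
    age_range = as.numeric(age_range), sex = as.character(sex),
    mask_state = as.character(mask_state),
    phase_ranges = lapply(phase_ranges, as.numeric),
    flight_type = flight_type, include_censored = include_censored)
}

setMethod("show", "FilterSpec", function(object) {
  cat("FilterSpec (criteria AND-combined):\n")
  if (length(object@identity))
    cat("  identity in {", paste(object@identity, collapse = ", "), "}\n")
  if (!anyNA(object@age_range) || !all(is.na(object@age_range)))
    cat(sprintf("  age in [%s, %s] years\n", object@age_range[1L],
      object@age_range[2L]))
  if (!is.na(object@sex)) cat("  sex ==", object@sex, "\n")
  if (!is.na(object@mask_state)) cat("  mask_state ==", object@mask_state, "\n")
  for (nm in names(object@phase_ranges))
    cat(sprintf("  %s in [%s, %s] s\n", nm, object@phase_ranges[[nm]][1L],
      object@phase_ranges[[nm]][2L]))
  cat("  flight_type:", object@flight_type, "\n")
  cat("  include_censored:", object@include_censored, "\n")
})

.inRange <- function(x, r) {
  (is.na(r[1L]) | x >= r[1L]) & (is.na(r[2L]) | x <= r[2L])
}

#' Filter a sample down to the subjects matching a specification
#'
#' Evaluates every subject of every flight against the conjunction of the
#' criteria in \code{spec}, using the per-subject phase table for phase-range
#' and validity criteria. Censored phase values fail their range check unless
#' \code{spec@include_censored}; undefined values always fail a range check
#' on that parameter.
#'
#' @param sample a [FlightSample-class].
#' @param phase_table per-subject analysis table from [phaseTable()] (must
#'   cover every subject in \code{sample}).
#' @param spec a [FilterSpec-class].
#' @return list with \code{sample} (a [FlightSample-class] containing only
#'   the matching subjects; flights left with no subjects are dropped) and
#'   \code{subjects} (data.frame with \code{flight_id}, \code{subject_id})
#' @export
applyFilters <- function(sample, phase_table, spec) {
  stopifnot(is(sample, "FlightSample"), is(spec, "FilterSpec"))
  validObject(spec)
  keep_flights <- list()
  kept <- data.frame(flight_id = character(0), subject_id = character(0))
  for (fl in sample@flights) {
    ft_ok <- TRUE
    if (!spec@flight_type %in% c("total", "valid"))
      ft_ok <- identical(tolower(fl@flight_type),
        tolower(spec@flight_type))
    if (!ft_ok) next
    sel <- vapply(fl@subjects, function(s) {
      row <- phase_table[phase_table$flight_id == fl@flight_id &
                         phase_table$subject_id == s@subject_id, , drop = FALSE]
      if (nrow(row) != 1L)
        stop("phase_table lacks a row for subject '", s@subject_id,
          "' of flight '", fl@flight_id, "'")
      .subjectMatches(s, row, spec)
    }, logical(1))
    if (any(sel)) {
      fl2 <- fl
      fl2@subjects <- fl@subjects[sel]
      keep_flights[[length(keep_flights) + 1L]] <- fl2
      kept <- rbind(kept, data.frame(flight_id = fl@flight_id,
        subject_id = vapply(fl@subjects[sel], subjectId, character(1))))
    }
  }
  list(sample = flightSample(keep_flights), subjects = kept)
}

.subjectMatches <- function(s, row, spec) {
  if (length(spec@identity) && !s@subject_id %in% spec@identity)
    return(FALSE)
  if (!all(is.na(spec@age_range))) {
    if (is.na(s@age) || !.inRange(s@age, spec@age_range)) return(FALSE)
  }
  if (!is.na(spec@sex) && !identical(s@sex, spec@sex)) return(FALSE)
  if (!is.na(spec@mask_state)) {
    has_disc <- isTRUE(row$n_mask_intervals > 0L)
    want <- identical(spec@mask_state, "disconnected")
    if (has_disc != want) return(FALSE)
  }
  if (identical(spec@flight_type, "valid") && !isTRUE(row$valid))
    return(FALSE)
  for (nm in names(spec@phase_ranges)) {
    st <- row[[paste0(nm, "_status")]]
    if (identical(st, "censored")) {
      if (!spec@include_censored) return(FALSE)
    } else if (!identical(st, "defined")) {
      return(FALSE)
    } else if (!.inRange(row[[nm]], spec@phase_ranges[[nm]])) {
      return(FALSE)
    }
  }
  TRUE
}

.specToList <- function(spec) {
  list(format_version = .FORMAT_VERSION, kind = "filter_spec",
    identity = as.list(spec@identity),
    age_range = spec@age_range,
    sex = spec@sex, mask_state = spec@mask_state,
    phase_ranges = spec@phase_ranges,
    flight_type = spec@flight_type,
    include_censored = spec@include_censored)
}

#' Save a filter specification for later analysis
#'
#' @param spec a [FilterSpec-class].
#' @param path destination JSON path.
#' @return \code{path}, invisibly; \code{loadFilters(saveFilters(spec, p))}
#'   reproduces \code{spec}
#' @export
saveFilters <- function(spec, path) {
  stopifnot(is(spec, "FilterSpec"))
  validObject(spec)
  jsonlite::write_json(.specToList(spec), path, auto_unbox = TRUE,
    digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Load a stored filter specification
#'
#' Rejects files violating the spec invariants (unknown fields, min > max).
#'
#' @param path JSON path written by [saveFilters()].
#' @return a [FilterSpec-class]
#' @export
loadFilters <- function(path) {
  if (!file.exists(path)) stop("filter file not found: ", path)
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) stop("malformed filter file: ", conditionMessage(e)))
  if (!length(raw)) stop("malformed filter file: empty")
  known <- c("format_version", "kind", "identity", "age_range", "sex",
    "mask_state", "phase_ranges", "flight_type", "include_censored")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown field(s) in filter file: ", paste(bad, collapse = ", "))
  nullNA <- function(x, d) if (is.null(x) || !length(x)) d else x
  pr <- raw$phase_ranges
  if (is.null(pr) || (is.list(pr) && !length(pr))) pr <- list()
  if (!is.list(pr)) pr <- as.list(as.data.frame(pr))
  spec <- filterSpec(
    identity = unlist(nullNA(raw$identity, character(0))),
    age_range = nullNA(raw$age_range, c(NA_real_, NA_real_)),
    sex = nullNA(raw$sex, NA_character_),
    mask_state = nullNA(raw$mask_state, NA_character_),
    phase_ranges = lapply(pr, as.numeric),
    flight_type = nullNA(raw$flight_type, "total"),
    include_censored = isTRUE(raw$include_censored))
  validObject(spec)
  spec
}
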