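# Independent brute-force oracles, deliberately naive: index-by-index loops
# with no shared code with the package implementation.

# First sample at or after `anchor` starting a run of >= debounce consecutive
# samples satisfying the condition; NA if none.
oracle_crossing <- function(times, values, threshold, direction, anchor,
                            debounce = 1L) {
  keep <- times >= anchor
  t <- times[keep]
  v <- values[keep]
  n <- length(t)
  cond <- logical(n)
  for (i in seq_len(n)) {
    cond[i] <- if (is.na(v[i])) FALSE
      else if (direction == "below") v[i] < threshold
      else v[i] >= threshold
  }
  for (i in seq_len(n)) {
    if (i + debounce - 1L > n) break
    if (all(cond[i:(i + debounce - 1L)])) return(t[i])
  }
  NA_real_
}

# Dwell-time sum: each sample strictly below threshold contributes its local
# inter-sample interval; the last sample contributes the nominal dt.
oracle_dwell <- function(times, values, threshold) {
  n <- length(times)
  if (!n) return(0)
  dt_nom <- if (n > 1L) median(diff(times)) else 0
  total <- 0
  for (i in seq_len(n)) {
    if (!is.na(values[i]) && values[i] < threshold) {
      w <- if (i < n) times[i + 1L] - times[i] else dt_nom
      total <- total + w
    }
  }
  total
}

# Naive mask scan: first 0 of each maximal disconnected run, and the first 1
# after it (NA if the record ends disconnected).
oracle_mask_intervals <- function(times, mask) {
  DM <- numeric(0); RM <- numeric(0)
  in_run <- FALSE
  for (i in seq_along(mask)) {
    if (!in_run && mask[i] == 0) {
      DM <- c(DM, times[i]); in_run <- TRUE
    } else if (in_run && mask[i] == 1) {
      RM <- c(RM, times[i]); in_run <- FALSE
    }
  }
  if (in_run) RM <- c(RM, NA_real_)
  list(DM = DM, RM = RM)
}

# Random piecewise-linear SpO2 trace on a 1 Hz grid.
random_pw_trace <- function(duration = 400, n_knots = 6, lo = 55, hi = 100) {
  grid <- 0:duration
  kt <- sort(c(0, duration, runif(n_knots - 2, 0, duration)))
  kv <- runif(n_knots, lo, hi)
  approx(kt, kv, xout = grid)$y
}

# Subject with explicit channels on a shared 1 Hz grid.
make_subject <- function(spo2, mask = NULL, hr = NULL, id = "S01", ...) {
  n <- length(spo2)
  grid <- seq_len(n) - 1
  if (is.null(mask)) mask <- rep(1, n)
  if (is.null(hr)) hr <- rep(70, n)
  subjectRecord(id,
    spo2 = timeSeries(grid, spo2, "spo2"),
    hr = timeSeries(grid, hr, "hr"),
    mask = timeSeries(grid, mask, "mask"), ...)
}

# Subject with one disconnection and a piecewise-linear desaturation of known
# decline rate (percent per second).
make_linear_subject <- function(id = "S01", DM = 50, RM = 250,
                                duration = 400, baseline = 98,
                                rate = 0.2, recover_rate = 0.5, ...) {
  grid <- 0:duration
  s <- rep(baseline, length(grid))
  fall <- grid >= DM & grid < RM
  s[fall] <- baseline - rate * (grid[fall] - DM)
  s_rm <- baseline - rate * (RM - DM)
  rec <- grid >= RM
  s[rec] <- pmin(baseline, s_rm + recover_rate * (grid[rec] - RM))
  s <- pmax(s, 40)
  mask <- as.numeric(!(grid >= DM & grid < RM))
  make_subject(s, mask = mask, id = id, ...)
}

# A random flight sample with known ages for cohort tests.
make_cohort <- function(ages, flight_id = "FLC", flight_type = "day_only",
                        sexes = NULL) {
  subj <- lapply(seq_along(ages), function(i)
    make_linear_subject(id = sprintf("C%02d", i), age = ages[i],
      sex = if (is.null(sexes)) "unspecified" else sexes[i]))
  flightSample(list(flightRecord(flight_id, subj,
    datetime = "2023-02-01T10:00:00", flight_type = flight_type)))
}
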