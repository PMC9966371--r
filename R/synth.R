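#' Parameters of the synthetic flight-record generator
#'
#' The defaults emulate the standard hypoxia-awareness exposure at 25,000 ft:
#' SpO2 baseline near 98\%, a 5-minute mask-off exposure during which
#' saturation decays exponentially toward a nadir near 60\%, exponential
#' recovery after reconnection, and a sympathetic heart-rate rise mirroring
#' the desaturation depth. SpO2 and heart rate are quantized to integers on
#' output, as pulse oximeters report.
#'
#' @param duration record length, s.
#' @param dt sampling interval, s (pulse-oximeter nominal 1 Hz).
#' @param DM,RM mask disconnection/reconnection times, s; \code{RM = NA}
#'   leaves the record disconnected at the end (censored).
#' @param baseline_spo2 pre-exposure SpO2, percent.
#' @param nadir_spo2 asymptotic SpO2 under sustained exposure, percent.
#' @param desat_delay lag after DM before the decline starts, s (lung and
#'   circulatory oxygen stores).
#' @param desat_tau time constant of the exponential decline, s.
#' @param recovery_tau time constant of the post-reconnection recovery, s.
#' @param baseline_hr resting heart rate, bpm.
#' @param hr_rise heart-rate increment at full desaturation depth, bpm.
#' @param noise_sd_spo2,noise_sd_hr additive Gaussian sensor noise SD.
#' @param dropout_prob per-sample probability of a missing SpO2/HR sample.
#' @param quantize round SpO2/HR to integers on output (default TRUE).
#' @param seed integer RNG seed; identical seeds give bit-identical records.
#' @return named list of class \code{oxiflight_synth_params}
#' @export
syntheticParams <- function(duration = 600, dt = 1, DM = 60, RM = 360,
                            baseline_spo2 = 98, nadir_spo2 = 60,
                            desat_delay = 10, desat_tau = 80,
                            recovery_tau = 25, baseline_hr = 70,
                            hr_rise = 25, noise_sd_spo2 = 0,
                            noise_sd_hr = 0, dropout_prob = 0,
                            quantize = TRUE, seed = 1L) {
  p <- list(duration = duration, dt = dt, DM = DM, RM = RM,
    baseline_spo2 = baseline_spo2, nadir_spo2 = nadir_spo2,
    desat_delay = desat_delay, desat_tau = desat_tau,
    recovery_tau = recovery_tau, baseline_hr = baseline_hr,
    hr_rise = hr_rise, noise_sd_spo2 = noise_sd_spo2,
    noise_sd_hr = noise_sd_hr, dropout_prob = dropout_prob,
    quantize = quantize, seed = as.integer(seed))
  .checkSynthParams(p)
  structure(p, class = "oxiflight_synth_params")
}

.checkSynthParams <- function(p) {
  if (p$dt <= 0) stop("invalid params: dt must be > 0")
  if (p$duration <= p$dt) stop("invalid params: duration must exceed dt")
  if (!(p$nadir_spo2 > 0 && p$nadir_spo2 < p$baseline_spo2 &&
        p$baseline_spo2 <= 100))
    stop("invalid params: need 0 < nadir_spo2 < baseline_spo2 <= 100")
  if (!is.na(p$RM) && p$DM >= p$RM)
    stop("invalid params: DM must precede RM")
  if (p$DM < 0 || p$DM > p$duration)
    stop("invalid params: DM must lie inside the record")
  if (p$desat_delay < 0 || p$desat_tau <= 0 || p$recovery_tau <= 0)
    stop("invalid params: delays/taus must be positive")
  if (p$noise_sd_spo2 < 0 || p$noise_sd_hr < 0 ||
      p$dropout_prob < 0 || p$dropout_prob >= 1)
    stop("invalid params: noise/dropout out of range")
  invisible(p)
}

# Run expr with a private RNG state seeded at `seed`, restoring the caller's.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# Noiseless SpO2 model: baseline until DM + delay, exponential decay toward
# the nadir until RM, exponential return toward baseline afterwards.
.spo2Model <- function(t, p) {
  s <- rep(p$baseline_spo2, length(t))
  t_fall <- p$DM + p$desat_delay
  rm_eff <- if (is.na(p$RM)) Inf else p$RM
  falling <- t >= t_fall & t < rm_eff
  s[falling] <- p$nadir_spo2 + (p$baseline_spo2 - p$nadir_spo2) *
    exp(-(t[falling] - t_fall) / p$desat_tau)
  if (is.finite(rm_eff) && any(t >= rm_eff)) {
    s_rm <- if (rm_eff >= t_fall)
      p$nadir_spo2 + (p$baseline_spo2 - p$nadir_spo2) *
        exp(-(rm_eff - t_fall) / p$desat_tau)
    else p$baseline_spo2
    rec <- t >= rm_eff
    s[rec] <- p$baseline_spo2 - (p$baseline_spo2 - s_rm) *
      exp(-(t[rec] - rm_eff) / p$recovery_tau)
  }
  s
}

# Closed-form inversions of the model used for analytic ground truth.
# Quantization to integer percent moves the observable crossing boundary to
# threshold - 0.5 (a reading below threshold first appears when the underlying
# signal crosses the rounding boundary), so the effective threshold is shifted
# before inverting; the continuous crossing time is then snapped forward to
# the sample grid the pipeline sees.
.snapToGrid <- function(t_star, grid) {
  i <- which(grid >= t_star - 1e-9)[1L]
  if (is.na(i)) NA_real_ else grid[i]
}

.analyticTruth <- function(p, grid) {
  q <- if (p$quantize) 0.5 else 0
  t_fall <- p$DM + p$desat_delay
  rm_eff <- if (is.na(p$RM)) Inf else p$RM
  DM_g <- .snapToGrid(p$DM, grid)
  RM_g <- if (is.finite(rm_eff)) .snapToGrid(p$RM, grid) else NA_real_

  fall_cross <- function(th) {
    th_eff <- th - q
    if (p$baseline_spo2 < th_eff) return(DM_g)  # already below at anchor
    if (th_eff <= p$nadir_spo2) return(NA_real_)
    t_star <- t_fall + p$desat_tau *
      log((p$baseline_spo2 - p$nadir_spo2) / (th_eff - p$nadir_spo2))
    if (t_star >= rm_eff) return(NA_real_)  # reconnected before crossing
    .snapToGrid(t_star, grid)
  }
  ded_t <- fall_cross(97)
  hd_t <- fall_cross(90)

  rt_t <- NA_real_
  if (is.finite(rm_eff)) {
    th_eff <- 97 - q
    s_rm <- .spo2Model(rm_eff, p)
    if (s_rm >= th_eff) rt_t <- RM_g
    else if (th_eff < p$baseline_spo2) {
      t_star <- rm_eff + p$recovery_tau *
        log((p$baseline_spo2 - s_rm) / (p$baseline_spo2 - th_eff))
      rt_t <- .snapToGrid(t_star, grid)
    }
  }

  list(DM = DM_g, RM = RM_g,
    DT = if (is.na(RM_g)) NA_real_ else RM_g - DM_g,
    DeD = if (is.na(ded_t)) NA_real_ else ded_t - DM_g,
    HD = if (is.na(hd_t)) NA_real_ else hd_t - DM_g,
    RT = if (is.na(rt_t)) NA_real_ else rt_t - RM_g)
}

#' Generate one synthetic subject with analytic ground truth
#'
#' The noiseless SpO2 curve is baseline until \code{DM + desat_delay}, decays
#' exponentially toward \code{nadir_spo2} until \code{RM}, then recovers
#' exponentially toward baseline; heart rate rises proportionally to the
#' desaturation depth. Ground-truth crossing times (DeD, HD, RT at the
#' default 97/90/97 thresholds) are inverted from the exponentials in closed
#' form and snapped to the sample grid \emph{before} noise, dropouts and
#' integer quantization are applied; DeT/HT ground truth is the per-sample
#' dwell sum on the noiseless quantized trace.
#'
#' @param params a [syntheticParams()] list.
#' @param subject_id,age,sex,station subject metadata.
#' @return list with \code{subject} (a [SubjectRecord-class]) and
#'   \code{truth} (one-row data.frame: grid-snapped \code{DM}, \code{RM} and
#'   the six phase durations, \code{NA} where censored/undefined)
#' @examples
#' g <- generateSubject(syntheticParams(seed = 42))
#' g$truth
#' @export
generateSubject <- function(params = syntheticParams(), subject_id = "S01",
                            age = NA_real_, sex = "unspecified",
                            station = NA_integer_) {
  .checkSynthParams(params)
  p <- params
  grid <- seq(0, p$duration, by = p$dt)
  s_clean <- .spo2Model(grid, p)
  depth <- (p$baseline_spo2 - s_clean) / (p$baseline_spo2 - p$nadir_spo2)
  hr_clean <- p$baseline_hr + p$hr_rise * depth
  rm_eff <- if (is.na(p$RM)) Inf else p$RM
  mask <- as.numeric(!(grid >= p$DM & grid < rm_eff))

  truth <- .analyticTruth(p, grid)
  s_q <- if (p$quantize) round(s_clean) else s_clean
  w <- p$dt
  truth$DeT <- sum(s_q < 97) * w
  truth$HT <- sum(s_q < 90) * w

  obs <- .withSeed(p$seed, {
    spo2 <- s_clean + stats::rnorm(length(grid), 0, p$noise_sd_spo2)
    hr <- hr_clean + stats::rnorm(length(grid), 0, p$noise_sd_hr)
    drop_s <- stats::runif(length(grid)) < p$dropout_prob
    drop_h <- stats::runif(length(grid)) < p$dropout_prob
    list(spo2 = spo2, hr = hr, drop_s = drop_s, drop_h = drop_h)
  })
  spo2 <- pmin(pmax(obs$spo2, 0), 100)
  hr <- pmax(obs$hr, 0)
  if (p$quantize) {
    spo2 <- round(spo2)
    hr <- round(hr)
  }
  spo2[obs$drop_s] <- NA_real_
  hr[obs$drop_h] <- NA_real_

  subject <- subjectRecord(subject_id,
    spo2 = timeSeries(grid, spo2, "spo2"),
    hr = timeSeries(grid, hr, "hr"),
    mask = timeSeries(grid, mask, "mask"),
    age = age, sex = sex, station = station)
  truth_df <- data.frame(subject_id = subject_id, DM = truth$DM,
    RM = truth$RM, DT = truth$DT, DeD = truth$DeD, HD = truth$HD,
    DeT = truth$DeT, HT = truth$HT, RT = truth$RT)
  list(subject = subject, truth = truth_df, params = p)
}

#' Generate a synthetic multi-subject flight
#'
#' Per-subject parameters are jittered around \code{base_params} with
#' independent Gaussian spreads; each subject draws from its own RNG stream
#' derived deterministically from \code{seed}, so adding subjects never
#' perturbs earlier ones.
#'
#' @param n_subjects number of crew members (>= 1).
#' @param base_params a [syntheticParams()] list.
#' @param between_subject_sd named list of Gaussian SDs for the numeric
#'   fields of \code{base_params} to jitter (e.g.
#'   \code{list(desat_tau = 10, baseline_spo2 = 0.5)}).
#' @param seed integer master seed.
#' @param flight_id,datetime,protocol,flight_type flight metadata.
#' @param ages,sexes optional per-subject metadata vectors (length
#'   \code{n_subjects}).
#' @return list with \code{flight} (a [FlightRecord-class]) and
#'   \code{truth} (data.frame, one row per subject)
#' @export
generateFlight <- function(n_subjects, base_params = syntheticParams(),
                           between_subject_sd = list(), seed = 1L,
                           flight_id = "FL001",
                           datetime = "2023-01-10T09:00:00",
                           protocol = "type_iv_25000ft",
                           flight_type = "day_only",
                           ages = NULL, sexes = NULL) {
  stopifnot(n_subjects >= 1L)
  bad <- setdiff(names(between_subject_sd), names(base_params))
  if (length(bad))
    stop("invalid spread(s): not a generator parameter: ",
      paste(bad, collapse = ", "))
  if (any(unlist(between_subject_sd) < 0))
    stop("invalid spread(s): SDs must be non-negative")
  subj <- vector("list", n_subjects)
  truth <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    # independent per-subject stream: a fixed-prime stride keeps streams
    # decoupled and below .Machine$integer.max
    seed_i <- as.integer((as.numeric(seed) + 104729 * i) %% 2147483647)
    p <- base_params
    if (length(between_subject_sd)) {
      jit <- .withSeed(seed_i + 1L,
        stats::rnorm(length(between_subject_sd), 0,
          unlist(between_subject_sd)))
      for (k in seq_along(between_subject_sd)) {
        nm <- names(between_subject_sd)[k]
        p[[nm]] <- p[[nm]] + jit[k]
      }
      # keep the jittered parameters physiologically and formally valid
      p$nadir_spo2 <- min(max(p$nadir_spo2, 1), p$baseline_spo2 - 1)
      p$baseline_spo2 <- min(p$baseline_spo2, 100)
      p$DM <- max(p$DM, 0)
      if (!is.na(p$RM)) p$RM <- max(p$RM, p$DM + 2 * p$dt)
      p$desat_delay <- max(p$desat_delay, 0)
      p$desat_tau <- max(p$desat_tau, 1)
      p$recovery_tau <- max(p$recovery_tau, 1)
      p$noise_sd_spo2 <- max(p$noise_sd_spo2, 0)
      p$noise_sd_hr <- max(p$noise_sd_hr, 0)
      p$dropout_prob <- min(max(p$dropout_prob, 0), 0.99)
    }
    p$seed <- seed_i
    id <- sprintf("S%02d", i)
    g <- generateSubject(p, subject_id = id,
      age = if (is.null(ages)) NA_real_ else ages[i],
      sex = if (is.null(sexes)) "unspecified" else sexes[i])
    subj[[i]] <- g$subject
    truth[[i]] <- g$truth
  }
  list(flight = flightRecord(flight_id, subj, datetime = datetime,
      protocol = protocol, flight_type = flight_type),
    truth = do.call(rbind, truth))
}
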