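test_that("identical seeds give bit-identical records, also after file I/O", {
  p <- syntheticParams(noise_sd_spo2 = 1, noise_sd_hr = 2,
    dropout_prob = 0.01, seed = 33)
  a <- generateSubject(p)
  b <- generateSubject(p)
  expect_identical(tsValues(channel(a$subject, "spo2")),
    tsValues(channel(b$subject, "spo2")))
  expect_identical(a$truth, b$truth)

  da <- withr::local_tempdir(); db <- withr::local_tempdir()
  fa <- generateFlight(3, base_params = p, seed = 17,
    between_subject_sd = list(desat_tau = 8))
  fb <- generateFlight(3, base_params = p, seed = 17,
    between_subject_sd = list(desat_tau = 8))
  writeFlightRecord(fa$flight, file.path(da, "f.json"))
  writeFlightRecord(fb$flight, file.path(db, "f.json"))
  for (f in c("f.json", "FL001_S01.csv", "FL001_S02.csv", "FL001_S03.csv"))
    expect_identical(readLines(file.path(da, f)), readLines(file.path(db, f)))

  # write -> read -> write reproduces the bytes
  dc <- withr::local_tempdir()
  writeFlightRecord(readFlightRecord(file.path(da, "f.json")),
    file.path(dc, "f.json"))
  expect_identical(readLines(file.path(dc, "FL001_S02.csv")),
    readLines(file.path(da, "FL001_S02.csv")))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generateSubject(syntheticParams(noise_sd_spo2 = 1, seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("noiseless pipeline phases match analytic ground truth within one dt", {
  set.seed(41)
  n_ok <- 0L
  n_tot <- 0L
  for (i in 1:30) {
    dt <- sample(c(0.5, 1, 2), 1)
    p <- syntheticParams(duration = 600, dt = dt,
      DM = runif(1, 30, 90), RM = runif(1, 240, 420),
      baseline_spo2 = runif(1, 97.5, 99.5), nadir_spo2 = runif(1, 55, 70),
      desat_delay = runif(1, 0, 20), desat_tau = runif(1, 40, 120),
      recovery_tau = runif(1, 15, 40), seed = 1000 + i)
    g <- generateSubject(p)
    ph <- computePhaseParameters(g$subject)
    val <- phaseValues(ph)
    for (nm in c("DT", "DeD", "HD", "DeT", "HT", "RT")) {
      truth <- g$truth[[nm]]
      if (is.na(truth)) next
      n_tot <- n_tot + 1L
      if (abs(val[[nm]] - truth) <= dt + 1e-9) n_ok <- n_ok + 1L
    }
  }
  expect_equal(n_ok, n_tot)
})

test_that("defaults approach the expected nadir near 60% for long exposures", {
  g <- generateSubject(syntheticParams(duration = 1200, DM = 60, RM = 900,
    seed = 2))
  v <- tsValues(channel(g$subject, "spo2"))
  expect_gte(min(v), syntheticParams()$nadir_spo2 - 1)
  expect_lte(min(v), syntheticParams()$nadir_spo2 + 2)
  expect_lte(max(v), syntheticParams()$baseline_spo2)
  # heart rate rises under hypoxia
  hr <- tsValues(channel(g$subject, "hr"))
  expect_gt(max(hr), syntheticParams()$baseline_hr + 20)
})

test_that("generateFlight reduces to generateSubject and keeps ids distinct", {
  base <- syntheticParams(seed = 123)
  fl <- generateFlight(1, base_params = base, seed = 123)
  solo <- generateSubject(`$<-`(base, "seed",
    as.integer((123 + 104729) %% 2147483647)))
  expect_identical(
    tsValues(channel(subjects(fl$flight)[[1]], "spo2")),
    tsValues(channel(solo$subject, "spo2")))

  fl8 <- generateFlight(8, seed = 5)
  ids <- vapply(subjects(fl8$flight), subjectId, character(1))
  expect_length(unique(ids), 8L)
  expect_equal(nrow(fl8$truth), 8L)

  # adding subjects never perturbs earlier ones
  fl3 <- generateFlight(3, seed = 5)
  expect_identical(
    tsValues(channel(subjects(fl8$flight)[[2]], "spo2")),
    tsValues(channel(subjects(fl3$flight)[[2]], "spo2")))

  expect_error(generateFlight(2, between_subject_sd = list(bogus = 1)),
    "not a generator parameter")
  expect_error(generateFlight(2, between_subject_sd = list(DM = -1)),
    "non-negative")
})

test_that("cohort ground-truth means are recovered by the group summary", {
  fl <- generateFlight(60, seed = 7,
    between_subject_sd = list(desat_tau = 10, desat_delay = 3))
  tab <- phaseTable(flightSample(list(fl$flight)))
  ds <- descriptiveSummary(tab, "DeD")
  truth_mean <- mean(fl$truth$DeD)
  # pipeline and analytic truth may differ by up to one sample per subject
  expect_lt(abs(ds$mean - truth_mean), 1.5)
})

test_that("noisy estimation with debounce keeps DeD error within 3 samples", {
  set.seed(2024)
  cfg <- phaseConfig(debounce = 3L)
  errs <- numeric(0)
  for (i in 1:200) {
    p <- syntheticParams(noise_sd_spo2 = 1, seed = 5000 + i)
    g <- generateSubject(p)
    ph <- computePhaseParameters(g$subject, cfg)
    if (phaseStatus(ph)[["DeD"]] != "defined" || is.na(g$truth$DeD)) next
    errs <- c(errs, phaseValues(ph)[["DeD"]] - g$truth$DeD)
  }
  expect_gte(length(errs), 190L)
  expect_gte(mean(abs(errs) <= 3 * 1), 0.95)
})
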