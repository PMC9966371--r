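test_that("mask interval detection matches the run-length scan oracle", {
  m <- timeSeries(0:5, c(1, 1, 0, 0, 0, 1), "mask")
  ev <- detectMaskIntervals(m)
  expect_equal(ev@DM, 2)
  expect_equal(ev@RM, 5)

  expect_equal(nIntervals(detectMaskIntervals(
    timeSeries(0:5, rep(1, 6), "mask"))), 0L)

  ev2 <- detectMaskIntervals(timeSeries(0:2, c(1, 0, 0), "mask"))
  expect_equal(ev2@DM, 1)
  expect_true(is.na(ev2@RM))

  expect_error(detectMaskIntervals(timeSeries(numeric(0), numeric(0), "mask")),
    "empty")

  set.seed(21)
  for (i in 1:20) {
    n <- sample(20:100, 1)
    mk <- as.numeric(runif(n) > 0.4)
    t <- cumsum(runif(n, 0.5, 2))
    got <- detectMaskIntervals(timeSeries(t, mk, "mask"))
    ora <- oracle_mask_intervals(t, mk)
    expect_equal(got@DM, ora$DM)
    expect_equal(got@RM, ora$RM)
  }
})

test_that("threshold crossings follow strict-below / at-or-above semantics", {
  expect_true(is.na(thresholdCrossingTime(
    timeSeries(0:20, rep(98, 21), "spo2"), 97, "below")))

  # s(t) = 98 - 0.5 t: s(2) = 97.0 is not < 97, s(3) = 96.5 is
  tr <- timeSeries(0:10, 98 - 0.5 * (0:10), "spo2")
  expect_equal(thresholdCrossingTime(tr, 97, "below", anchor = 0), 3)

  tr2 <- timeSeries(0:5, c(98, 96, 98, 96, 96, 96), "spo2")
  expect_equal(thresholdCrossingTime(tr2, 97, "below", debounce = 3), 3)
  expect_equal(thresholdCrossingTime(tr2, 97, "below", debounce = 1), 1)

  # missing samples break a debounce run
  tr3 <- timeSeries(0:5, c(98, 96, NA, 96, 96, 96), "spo2")
  expect_equal(thresholdCrossingTime(tr3, 97, "below", debounce = 3), 3)

  # anchor excludes earlier crossings
  expect_equal(thresholdCrossingTime(tr2, 97, "below", anchor = 2), 3)

  # recovery direction is inclusive
  tr4 <- timeSeries(0:4, c(90, 95, 97, 98, 98), "spo2")
  expect_equal(thresholdCrossingTime(tr4, 97, "at_or_above"), 2)
})

test_that("crossing times match the per-sample scan oracle on random traces", {
  set.seed(31)
  for (i in 1:40) {
    v <- random_pw_trace(duration = 200)
    v[sample(length(v), 5)] <- NA
    tr <- timeSeries(0:200, v, "spo2")
    th <- runif(1, 60, 99)
    dir <- sample(c("below", "at_or_above"), 1)
    anc <- runif(1, 0, 100)
    deb <- sample(1:4, 1)
    expect_equal(
      thresholdCrossingTime(tr, th, dir, anchor = anc, debounce = deb),
      oracle_crossing(0:200, v, th, dir, anc, deb))
  }
})

test_that("phase parameters agree with brute-force oracles on random records", {
  set.seed(47)
  cfg <- phaseConfig()
  for (i in 1:40) {
    dur <- 300
    v <- random_pw_trace(duration = dur, lo = 50)
    grid <- 0:dur
    DM <- runif(1, 40, 80)
    RM <- runif(1, 180, 260)
    mk <- as.numeric(!(grid >= DM & grid < RM))
    s <- make_subject(v, mask = mk)
    ph <- computePhaseParameters(s, cfg)
    val <- phaseValues(ph)
    st <- phaseStatus(ph)

    ora_ev <- oracle_mask_intervals(grid, mk)
    dm <- ora_ev$DM[1]; rm <- ora_ev$RM[1]
    expect_equal(val[["DT"]], rm - dm)

    ded <- oracle_crossing(grid, v, 97, "below", dm)
    if (is.na(ded)) expect_identical(st[["DeD"]], "undefined")
    else expect_equal(val[["DeD"]], ded - dm)
    hd <- oracle_crossing(grid, v, 90, "below", dm)
    if (is.na(hd)) expect_identical(st[["HD"]], "undefined")
    else expect_equal(val[["HD"]], hd - dm)
    rt <- oracle_crossing(grid, v, 97, "at_or_above", rm)
    if (is.na(rt)) expect_identical(st[["RT"]], "censored")
    else expect_equal(val[["RT"]], rt - rm)

    expect_equal(val[["DeT"]], oracle_dwell(grid, v, 97))
    expect_equal(val[["HT"]], oracle_dwell(grid, v, 90))

    # ordering invariants
    if (st[["DeD"]] == "defined" && st[["HD"]] == "defined")
      expect_lte(val[["DeD"]], val[["HD"]])
    expect_lte(val[["HT"]], val[["DeT"]])
  }
})

test_that("a trace never below 97% yields zero dwell and undefined delays", {
  s <- make_subject(rep(98, 120),
    mask = c(rep(1, 30), rep(0, 60), rep(1, 30)))
  ph <- computePhaseParameters(s)
  expect_equal(phaseValues(ph)[["DeT"]], 0)
  expect_equal(phaseValues(ph)[["HT"]], 0)
  expect_identical(phaseStatus(ph)[["DeD"]], "undefined")
  expect_identical(phaseStatus(ph)[["HD"]], "undefined")
  expect_equal(phaseValues(ph)[["DT"]], 60)  # RM - DM = 90 - 30
})

test_that("DT is censored when the record ends disconnected", {
  s <- make_subject(c(rep(98, 20), seq(98, 60, length.out = 40)),
    mask = c(rep(1, 20), rep(0, 40)))
  ph <- computePhaseParameters(s)
  expect_identical(phaseStatus(ph)[["DT"]], "censored")
  expect_identical(phaseStatus(ph)[["RT"]], "censored")
  expect_equal(censorTimes(ph)[["DT"]], 59 - 20)  # observed up to record end
})

test_that("no disconnection leaves anchored phases undefined but dwell defined", {
  s <- make_subject(c(rep(98, 10), rep(92, 10)))
  ph <- computePhaseParameters(s)
  expect_identical(unname(phaseStatus(ph)[c("DT", "DeD", "HD", "RT")]),
    rep("undefined", 4))
  expect_equal(phaseValues(ph)[["DeT"]], 10)
})

test_that("dwell times are monotone in their thresholds", {
  set.seed(53)
  for (i in 1:10) {
    v <- random_pw_trace(duration = 200, lo = 50)
    grid <- 0:200
    mk <- as.numeric(!(grid >= 50 & grid < 150))
    s <- make_subject(v, mask = mk)
    ths <- sort(runif(2, 60, 99))
    lo_cfg <- phaseConfig(desat_threshold = ths[1],
      hypoxia_threshold = min(ths[1], 90))
    hi_cfg <- phaseConfig(desat_threshold = ths[2],
      hypoxia_threshold = min(ths[2], 90))
    expect_lte(phaseValues(computePhaseParameters(s, lo_cfg))[["DeT"]],
      phaseValues(computePhaseParameters(s, hi_cfg))[["DeT"]])
  }
})

test_that("configuration files round-trip and reject unknown fields", {
  d <- withr::local_tempdir()
  yml <- file.path(d, "cfg.yaml")
  writeLines(c("desat_threshold: 96", "debounce: 3"), yml)
  cfg <- readPhaseConfig(yml)
  expect_equal(cfg$desat_threshold, 96)
  expect_equal(cfg$debounce, 3L)
  expect_equal(cfg$hypoxia_threshold, 90)  # default preserved

  js <- file.path(d, "cfg.json")
  jsonlite::write_json(list(max_gap = 10), js, auto_unbox = TRUE)
  expect_equal(readPhaseConfig(js)$max_gap, 10)

  writeLines("not_a_field: 1", yml)
  expect_error(readPhaseConfig(yml), "unknown config field.*not_a_field")
})
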