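assay <- SummarizedExperiment::assay
colData <- SummarizedExperiment::colData

test_that("alignment at native dt from record start is the identity", {
  v <- random_pw_trace(duration = 100)
  s <- make_subject(v)
  al <- alignAndResample(list(s), "spo2", anchor = "record_start")
  expect_equal(dim(al), c(1L, 101L))
  expect_equal(unname(assay(al)[1, ]), v)
  expect_equal(colData(al)$time_s, 0:100)
})

test_that("disconnection anchoring makes time-shifted copies identical", {
  shape <- function(offset, total = 400) {
    grid <- 0:total
    rel <- grid - offset
    v <- ifelse(rel < 0, 98, pmax(98 - 0.3 * rel, 65))
    mk <- as.numeric(!(rel >= 0 & rel < 200))
    make_subject(v, mask = mk, id = paste0("S", offset))
  }
  a <- shape(50)
  b <- shape(70)
  al <- alignAndResample(list(a, b), "spo2", anchor = "disconnection")
  m <- assay(al)
  both <- !is.na(m[1, ]) & !is.na(m[2, ])
  expect_gt(sum(both), 300)
  expect_equal(m[1, both], m[2, both], ignore_attr = TRUE)
})

test_that("subjects shorter than the grid yield missing cells, tracked in n", {
  long <- make_subject(rep(90, 200), id = "L")
  short <- make_subject(rep(94, 100), id = "S")
  al <- alignAndResample(list(long, short), "spo2", anchor = "record_start")
  m <- assay(al)
  expect_true(all(is.na(m["S", 101:200])))
  gc <- groupCurve(al, "mean_sd")
  expect_equal(gc$n[1:100], rep(2L, 100))
  expect_equal(gc$n[101:200], rep(1L, 100))
  # mean 92 / SD 2*sqrt(2)... here sd of {90, 94} = 2*sqrt(2)? no: sd = 2.828
  expect_equal(gc$center[1], 92)
  expect_equal(gc$dispersion_high[1] - gc$center[1], sd(c(90, 94)))
  # single contributor: SD taken as 0
  expect_equal(gc$dispersion_low[150], gc$center[150])
})

test_that("group curves reproduce closed-form statistics", {
  rows <- lapply(1:4, function(i) make_subject(rep(95, 50), id = paste0("R", i)))
  al <- alignAndResample(rows, "spo2", anchor = "record_start")
  gc <- groupCurve(al, "mean_sd")
  expect_true(all(gc$center == 95))
  expect_true(all(gc$dispersion_high - gc$dispersion_low == 0))

  two <- alignAndResample(list(make_subject(rep(90, 30), id = "A"),
    make_subject(rep(94, 30), id = "B")), "spo2", "record_start")
  gc2 <- groupCurve(two, "mean_sd")
  expect_equal(unique(gc2$center), 92)
  expect_equal(unique(gc2$dispersion_high), 92 + 2 * sqrt(2))

  five <- alignAndResample(lapply(1:5, function(i)
    make_subject(rep(i, 20), id = paste0("Q", i))), "spo2", "record_start")
  gc3 <- groupCurve(five, "median_iqr")
  expect_equal(unique(gc3$center), 3)
  # linear-interpolation (type 7) quartiles of 1..5
  expect_equal(unique(gc3$dispersion_low), unname(quantile(1:5, 0.25)))
  expect_equal(unique(gc3$dispersion_high), unname(quantile(1:5, 0.75)))

  # median curve shrugs off one extreme row at n = 5
  robust <- alignAndResample(c(lapply(1:4, function(i)
    make_subject(rep(i, 20), id = paste0("Q", i))),
    list(make_subject(rep(100, 20), id = "Q5"))), "spo2", "record_start")
  gc4 <- groupCurve(robust, "median_iqr")
  expect_equal(unique(gc4$center), 3)
})

test_that("mean curves shift with a constant and ignore row permutation", {
  set.seed(83)
  traces <- lapply(1:4, function(i)
    make_subject(random_pw_trace(80), id = paste0("P", i)))
  al <- alignAndResample(traces, "spo2", "record_start")
  gc <- groupCurve(al, "mean_sd")
  al_perm <- alignAndResample(traces[c(3, 1, 4, 2)], "spo2", "record_start")
  expect_equal(groupCurve(al_perm, "mean_sd")$center, gc$center)

  shifted <- lapply(traces, function(s) {
    v <- tsValues(channel(s, "spo2")) - 5
    make_subject(v, id = subjectId(s))
  })
  gc_s <- groupCurve(alignAndResample(shifted, "spo2", "record_start"),
    "mean_sd")
  expect_equal(gc_s$center, gc$center - 5)
  expect_equal(gc_s$dispersion_high - gc_s$center,
    gc$dispersion_high - gc$center)
})

test_that("heat-map matrices are the aligned data, untouched", {
  subj <- lapply(1:3, function(i) make_subject(rep(92, 100), id = paste0("H", i)))
  al <- alignAndResample(subj, "spo2", "record_start")
  hm <- heatmapMatrix(al)
  expect_equal(dim(hm$matrix), c(3L, 100L))
  expect_true(all(hm$matrix == 92))
  expect_equal(hm$value_range, c(60, 100))  # SpO2 default scale
  expect_identical(hm$matrix, assay(al))

  hr_al <- alignAndResample(subj, "hr", "record_start")
  expect_equal(heatmapMatrix(hr_al)$value_range, c(70, 70))
})

test_that("descriptive summaries match direct arithmetic", {
  tab <- data.frame(DT = c(100, 200, 300),
    DT_status = rep("defined", 3))
  ds <- descriptiveSummary(tab, "DT")
  expect_equal(ds$n, 3L)
  expect_equal(ds$mean, 200)
  expect_equal(ds$sd, 100)
  expect_equal(ds$median, 200)
  expect_equal(ds$min, 100)
  expect_equal(ds$max, 300)

  # 2 of 5 RT censored: n = 3, censored_count = 2
  tab2 <- data.frame(RT = c(80, 90, 100, NA, NA),
    RT_status = c(rep("defined", 3), rep("censored", 2)))
  ds2 <- descriptiveSummary(tab2, "RT")
  expect_equal(ds2$n, 3L)
  expect_equal(ds2$censored_count, 2L)
  expect_equal(ds2$mean, 90)

  # singleton: mean == median == min == max, SD undefined (NA)
  ds3 <- descriptiveSummary(data.frame(HD = 42, HD_status = "defined"), "HD")
  expect_equal(ds3$mean, 42)
  expect_equal(ds3$median, 42)
  expect_true(is.na(ds3$sd))

  # identical subjects: zero spread everywhere
  sample <- flightSample(list(flightRecord("FD",
    lapply(1:4, function(i) make_linear_subject(id = paste0("E", i))))))
  ds4 <- descriptiveSummary(phaseTable(sample))
  expect_true(all(ds4$sd == 0, na.rm = TRUE))
  expect_true(all(ds4$q3 - ds4$q1 == 0, na.rm = TRUE))
})
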