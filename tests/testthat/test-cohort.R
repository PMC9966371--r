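cohort_fixture <- function() {
  sample <- make_cohort(ages = 20:29,
    sexes = rep(c("F", "M"), 5))
  list(sample = sample, tab = phaseTable(sample))
}

test_that("the empty specification is the identity filter", {
  fx <- cohort_fixture()
  res <- applyFilters(fx$sample, fx$tab, filterSpec())
  expect_equal(nrow(res$subjects), 10L)
  expect_identical(res$subjects$subject_id,
    vapply(subjects(flights(fx$sample)[[1]]), subjectId, character(1)))
})

test_that("attribute filters match a brute-force scan", {
  fx <- cohort_fixture()
  # impossible age range
  res0 <- applyFilters(fx$sample, fx$tab,
    filterSpec(age_range = c(200, 300)))
  expect_equal(nrow(res0$subjects), 0L)
  expect_length(flights(res0$sample), 0L)

  # ages 20..29, range [25, 29] -> 5 subjects
  res <- applyFilters(fx$sample, fx$tab, filterSpec(age_range = c(25, 29)))
  brute <- vapply(subjects(flights(fx$sample)[[1]]),
    function(s) !is.na(s@age) && s@age >= 25 && s@age <= 29, logical(1))
  expect_equal(nrow(res$subjects), 5L)
  expect_identical(res$subjects$subject_id,
    vapply(subjects(flights(fx$sample)[[1]])[brute], subjectId, character(1)))

  resF <- applyFilters(fx$sample, fx$tab, filterSpec(sex = "F"))
  expect_equal(nrow(resF$subjects), 5L)

  resI <- applyFilters(fx$sample, fx$tab,
    filterSpec(identity = c("C01", "C07")))
  expect_identical(resI$subjects$subject_id, c("C01", "C07"))
})

test_that("filters compose by conjunction and ignore subject order", {
  fx <- cohort_fixture()
  specA <- filterSpec(age_range = c(22, 28))
  specB <- filterSpec(sex = "M")
  specAB <- filterSpec(age_range = c(22, 28), sex = "M")
  resA <- applyFilters(fx$sample, fx$tab, specA)
  resAB1 <- applyFilters(resA$sample, fx$tab, specB)
  resAB2 <- applyFilters(fx$sample, fx$tab, specAB)
  expect_identical(resAB1$subjects$subject_id, resAB2$subjects$subject_id)

  # reversing subject order selects the same set
  fl <- flights(fx$sample)[[1]]
  fl_rev <- flightRecord(flightId(fl), rev(subjects(fl)),
    flight_type = fl@flight_type)
  res_rev <- applyFilters(flightSample(list(fl_rev)), fx$tab, specAB)
  expect_setequal(res_rev$subjects$subject_id, resAB2$subjects$subject_id)
})

test_that("phase ranges honor censoring semantics", {
  # two subjects: one fully defined, one ending disconnected (RT censored)
  s1 <- make_linear_subject(id = "D1")
  grid <- 0:99
  s2 <- make_subject(c(rep(98, 20), seq(97, 60, length.out = 80)),
    mask = c(rep(1, 20), rep(0, 80)), id = "D2")
  sample <- flightSample(list(flightRecord("FF", list(s1, s2))))
  tab <- phaseTable(sample)
  expect_identical(tab$RT_status, c("defined", "censored"))

  spec <- filterSpec(phase_ranges = list(RT = c(0, 1e6)))
  res <- applyFilters(sample, tab, spec)
  expect_identical(res$subjects$subject_id, "D1")

  spec2 <- filterSpec(phase_ranges = list(RT = c(0, 1e6)),
    include_censored = TRUE)
  res2 <- applyFilters(sample, tab, spec2)
  expect_setequal(res2$subjects$subject_id, c("D1", "D2"))

  # an out-of-range defined value still fails
  rt1 <- tab$RT[1]
  spec3 <- filterSpec(phase_ranges = list(RT = c(rt1 + 1, rt1 + 2)))
  expect_equal(nrow(applyFilters(sample, tab, spec3)$subjects), 0L)
})

test_that("flight_type 'valid' keeps only subjects passing validation", {
  good <- make_linear_subject(id = "V1")
  flat <- make_subject(rep(98, 200),
    mask = c(rep(1, 40), rep(0, 120), rep(1, 40)), id = "V2")
  sample <- flightSample(list(flightRecord("FV", list(good, flat))))
  tab <- phaseTable(sample)
  res <- applyFilters(sample, tab, filterSpec(flight_type = "valid"))
  expect_identical(res$subjects$subject_id, "V1")
  # 'total' imposes no validity constraint
  res_t <- applyFilters(sample, tab, filterSpec(flight_type = "total"))
  expect_equal(nrow(res_t$subjects), 2L)
})

test_that("flight-type categories match flight metadata case-insensitively", {
  a <- make_cohort(ages = c(30, 31), flight_id = "FA",
    flight_type = "Decompression")
  b <- make_cohort(ages = c(40, 41), flight_id = "FB",
    flight_type = "day_only")
  sample <- flightSample(c(flights(a), flights(b)))
  tab <- phaseTable(sample)
  res <- applyFilters(sample, tab, filterSpec(flight_type = "decompression"))
  expect_identical(unique(res$subjects$flight_id), "FA")
})

test_that("filter specifications round-trip through JSON", {
  d <- withr::local_tempdir()
  specs <- list(
    filterSpec(),
    filterSpec(identity = c("A", "B"), age_range = c(25, 40), sex = "F",
      mask_state = "disconnected",
      phase_ranges = list(DT = c(100, 400), HT = c(0, 200),
        RT = c(NA, 120)),
      flight_type = "decompression", include_censored = TRUE))
  for (k in seq_along(specs)) {
    p <- file.path(d, sprintf("f%d.json", k))
    saveFilters(specs[[k]], p)
    back <- loadFilters(p)
    for (sl in slotNames("FilterSpec"))
      expect_equal(slot(back, sl), slot(specs[[k]], sl), info = sl)
  }
  # the stored file lists exactly the ranges that were set
  stored <- jsonlite::read_json(file.path(d, "f2.json"))
  expect_length(stored$phase_ranges, 3L)
})

test_that("invalid or malformed filter files are rejected", {
  d <- withr::local_tempdir()
  p <- file.path(d, "bad.json")
  jsonlite::write_json(list(format_version = "1.0",
    phase_ranges = list(DT = c(400, 100))), p, auto_unbox = TRUE)
  expect_error(loadFilters(p), "min must be <= max")

  jsonlite::write_json(list(format_version = "1.0", no_such_field = 1), p,
    auto_unbox = TRUE)
  expect_error(loadFilters(p), "unknown field.*no_such_field")

  writeLines("", p)
  expect_error(loadFilters(p), "malformed|empty")

  expect_error(filterSpec(phase_ranges = list(XX = c(0, 1))),
    "unknown phase parameter")
})
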