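test_that("maturity follows age when age is informative", {
  expect_equal(classify_maturity("known", 5), "juvenile")
  expect_equal(classify_maturity("known", 8), "mature")
  expect_equal(classify_maturity("minimum", 23), "mature")
  # minimum age below threshold defers to length
  expect_equal(classify_maturity("minimum", 3, 9.18, 0.32), "juvenile")
})

test_that("maturity falls back to the length posterior", {
  # P(N(12.4, 0.2^2) > 11.7) = pnorm(3.5) > 0.5
  expect_equal(classify_maturity("unknown", NA, 12.4, 0.2), "mature")
  expect_equal(classify_maturity("unknown", NA, 10.0, 0.5), "juvenile")
  # boundary: exactly half the mass above the threshold is juvenile
  expect_equal(classify_maturity("unknown", NA, 11.7, 0.3), "juvenile")
  expect_error(classify_maturity("unknown", NA), "indeterminate")
  expect_error(classify_maturity("minimum", 4), "indeterminate")
})

test_that("maturity is monotone in sighting-history length", {
  for (at in c("known", "minimum")) {
    m <- classify_maturity(rep(at, 30), 1:30, 10.0, 0.3)
    expect_false(any(m[-1] == "juvenile" & m[-30] == "mature"))
    expect_true(all(m[8:30] == "mature"))
  }
})

test_that("reproductive classes partition the whale-years", {
  expect_equal(assign_repro_class("mature", 2019, list(2020)), "PF")
  expect_equal(assign_repro_class("mature", 2018, list(2018)), "LF")
  expect_equal(assign_repro_class("mature", 2017, list(integer())), "MF")
  expect_equal(assign_repro_class("juvenile", 2017, list(integer())), "JF")
  # calf the year after makes even a juvenile-aged female PF
  expect_equal(assign_repro_class("juvenile", 2019, list(2020)), "PF")
  expect_error(assign_repro_class("mature", 2018, list(c(2018, 2019))),
               "calf")
})

test_that("build_dataset joins, classifies and drops empty records", {
  sightings <- tibble::tibble(
    whale_id = c("a", "b", "c"),
    first_year = c(2010L, 2017L, 2012L),
    first_seen_as_calf = c(FALSE, TRUE, FALSE),
    calf_years = list(2021L, integer(), integer())
  )
  h <- tibble::tibble(whale_id = c("a", "b", "c"),
                      year = c(2020L, 2020L, 2020L),
                      log_fp4m = c(4.5, NA, 3.2))
  m <- tibble::tibble(whale_id = c("a", "b"), year = c(2020L, 2020L),
                      w50 = c(0.18, 0.15), w50_sd = c(NA, NA),
                      tl_mean = c(12.5, 10.1), tl_sd = c(0.2, 0.2))
  out <- build_dataset(sightings, h, m)
  expect_equal(nrow(out), 3)
  expect_equal(as.character(out$group[out$whale_id == "a"]), "PF")
  expect_equal(as.character(out$group[out$whale_id == "b"]), "JF")
  # c: minimum age 8 -> mature, no calf -> MF
  expect_equal(as.character(out$group[out$whale_id == "c"]), "MF")

  # record with neither measurement is dropped with a count
  h2 <- dplyr::bind_rows(h, tibble::tibble(whale_id = "c", year = 2021L,
                                           log_fp4m = NA_real_))
  expect_message(out2 <- build_dataset(sightings, h2, m), "lacking both")
  expect_equal(nrow(out2), 3)

  # conflicting duplicate keys error
  hdup <- dplyr::bind_rows(h, h[1, ])
  expect_error(build_dataset(sightings, hdup, m), "duplicate")
})

test_that("per-whale lengths fill records without a same-year measurement", {
  sightings <- tibble::tibble(
    whale_id = "a", first_year = 2018L, first_seen_as_calf = FALSE,
    calf_years = list(integer()))
  h <- tibble::tibble(whale_id = "a", year = 2020L, log_fp4m = 4.0)
  lengths <- tibble::tibble(whale_id = "a", tl_mean = 12.4, tl_sd = 0.2)
  # minimum age 2: indeterminate without the length table
  expect_error(build_dataset(sightings, h), "indeterminate")
  out <- build_dataset(sightings, h, lengths = lengths)
  expect_equal(as.character(out$group), "MF")
})

test_that("packaged dataset reproduces the published class partition", {
  recs <- gray_whale_records()
  expect_equal(nrow(recs), 111)
  fp <- table(recs$group[!is.na(recs$fp4m)])
  expect_equal(as.integer(fp[c("PF", "LF", "JF", "MF")]), c(5, 4, 19, 48))
  wv <- table(recs$group[!is.na(recs$w50)])
  expect_equal(as.integer(wv[c("PF", "LF", "JF", "MF")]), c(5, 3, 17, 52))
  joint <- !is.na(recs$fp4m) & !is.na(recs$w50)
  expect_equal(sum(joint), 42)
})

test_that("sightings CSV round-trips with calf-year validation", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("whale_id,first_year,first_seen_as_calf,calf_years",
               "a,2010,TRUE,2015;2018", "b,2012,FALSE,"), path)
  s <- read_sightings(path)
  expect_equal(s$calf_years[[1]], c(2015L, 2018L))
  expect_equal(s$calf_years[[2]], integer())
  writeLines(c("whale_id,first_year,first_seen_as_calf,calf_years",
               "a,2016,TRUE,2015"), path)
  expect_error(read_sightings(path), "line")
})
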