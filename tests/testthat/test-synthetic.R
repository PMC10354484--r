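test_that("a fixed seed gives byte-identical datasets", {
  s1 <- simulate_dataset(seed = 10)
  s2 <- simulate_dataset(seed = 10)
  expect_identical(s1$assays, s2$assays)
  expect_identical(s1$morph, s2$morph)
  expect_identical(s1$sightings, s2$sightings)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_dataset(seed = 11)
  expect_false(identical(s1$truth$true_w50, s3$truth$true_w50))
})

test_that("ground truth respects the configuration", {
  all_mf_preg <- simulate_dataset(
    sim_config(n_per_class = c(PF = 4, LF = 0, JF = 0, MF = 20),
               mf_pregnant_fraction = 1), seed = 1)
  expect_true(all(truth_table(all_mf_preg)$pregnant))
  none <- simulate_dataset(
    sim_config(mf_pregnant_fraction = 0), seed = 2)
  tt <- truth_table(none)
  expect_false(any(tt$pregnant[tt$group == "MF"]))
  expect_true(all(tt$pregnant[tt$group == "PF"]))
  expect_false(any(tt$pregnant[tt$group %in% c("LF", "JF")]))
})

test_that("label marginals match the configured fraction", {
  # exact binomial bounds on the number of pregnant MF
  cfg <- sim_config(n_per_class = c(PF = 5, LF = 4, JF = 19, MF = 400),
                    mf_pregnant_fraction = 0.15)
  tt <- truth_table(simulate_dataset(cfg, seed = 3))
  n_preg <- sum(tt$pregnant[tt$group == "MF"])
  bounds <- qbinom(c(0.0005, 0.9995), 400, 0.15)
  expect_gte(n_preg, bounds[1])
  expect_lte(n_preg, bounds[2])
})

test_that("class-conditional moments match the configuration within 3 SE", {
  cfg <- sim_config(n_per_class = c(PF = 150, LF = 0, JF = 150, MF = 0))
  sim <- simulate_dataset(cfg, seed = 4)
  tr <- sim$truth
  for (cls in c("PF", "JF")) {
    par_f <- if (cls == "PF") cfg$fp4m_pregnant else cfg$fp4m_nonpregnant
    par_w <- if (cls == "PF") cfg$w50_pregnant else cfg$w50_nonpregnant
    x <- tr$true_fp4m[tr$group == cls]
    expect_lt(abs(mean(x) - par_f["mean"]), 3 * par_f["sd"] / sqrt(150))
    w <- tr$true_w50[tr$group == cls]
    expect_lt(abs(mean(w) - par_w["mean"]), 3 * par_w["sd"] / sqrt(150))
  }
})

test_that("the generated raw tables rebuild into the true classes", {
  sim <- simulate_dataset(seed = 5)
  h <- suppressMessages(prep_hormones(sim$assays))
  m <- suppressMessages(prep_morphometrics(sim$morph))
  recs <- suppressMessages(
    build_dataset(sim$sightings, h, m, lengths = whale_lengths(sim$morph)))
  tt <- truth_table(sim)
  joined <- dplyr::inner_join(recs, tt, by = "record_id")
  expect_equal(as.character(joined$group.x), as.character(joined$group.y))
  # every whale-year with assays survives into the record table
  expect_equal(sort(unique(recs$whale_id[!is.na(recs$fp4m)])),
               sort(unique(sim$assays$whale_id)))
})

test_that("zero component overlap makes the width model perfect", {
  cfg <- sim_config(n_per_class = c(PF = 6, LF = 2, JF = 12, MF = 0),
                    w50_pregnant = c(mean = 0.26, sd = 0.004),
                    w50_nonpregnant = c(mean = 0.14, sd = 0.004),
                    w50_measurement_sd = 0.002,
                    p_early_measurement = 0)
  sim <- simulate_dataset(cfg, seed = 6)
  m <- suppressMessages(prep_morphometrics(sim$morph))
  recs <- suppressMessages(
    build_dataset(sim$sightings, morph_annual = m,
                  lengths = whale_lengths(sim$morph)))
  bb <- boot_pregnancy(recs, model = "w50", n_boot = 100, seed = 7)
  cm <- confusion_metrics(classify_pregnant(bb$summary$point),
                          bb$summary$group)
  expect_equal(cm$metrics$value_pct[cm$metrics$metric == "accuracy"], 100)
})

test_that("with study-like overlap the width model beats the hormone
           model on known-status whales", {
  cfg <- sim_config(n_per_class = c(PF = 12, LF = 8, JF = 40, MF = 0))
  sim <- simulate_dataset(cfg, seed = 8)
  h <- suppressMessages(prep_hormones(sim$assays))
  m <- suppressMessages(prep_morphometrics(sim$morph))
  recs <- suppressMessages(
    build_dataset(sim$sightings, h, m, lengths = whale_lengths(sim$morph)))
  acc <- function(model) {
    bb <- boot_pregnancy(recs, model = model, n_boot = 150, seed = 9)
    cm <- confusion_metrics(classify_pregnant(bb$summary$point),
                            bb$summary$group)
    cm$metrics$value_pct[cm$metrics$metric == "accuracy"]
  }
  expect_gt(acc("w50"), acc("fp4m"))
})

test_that("CSV export round-trips through the readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(seed = 12)
  write_sim_dataset(sim, dir)
  expect_true(all(file.exists(file.path(
    dir, c("assays.csv", "morph.csv", "sightings.csv", "truth.csv")))))
  a <- read_assays(file.path(dir, "assays.csv"))
  expect_equal(nrow(a), nrow(sim$assays))
  s <- read_sightings(file.path(dir, "sightings.csv"))
  expect_identical(s$calf_years, sim$sightings$calf_years)
})
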