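test_that("forced records appear in every bootstrap sample", {
  withr::local_seed(1)
  recs <- toy_records()
  forced <- recs$record_id[recs$group == "PF"]
  for (i in 1:100) {
    s <- draw_bootstrap_sample(recs, forced)
    expect_equal(nrow(s), nrow(recs))
    expect_true(all(forced %in% s$record_id))
    # forced records appear exactly once under the hold_forced scheme
    expect_equal(sum(s$record_id %in% forced), length(forced))
  }
  # forcing everything reproduces the dataset exactly
  all_forced <- draw_bootstrap_sample(recs, recs$record_id)
  expect_equal(dplyr::arrange(all_forced, record_id),
               dplyr::arrange(recs, record_id))
  # no forcing is a plain bootstrap of the right size
  plain <- draw_bootstrap_sample(recs[1:3, ], character())
  expect_equal(nrow(plain), 3)
  expect_true(all(plain$record_id %in% recs$record_id[1:3]))
  expect_error(draw_bootstrap_sample(recs, "absent:1999"), "not present")
})

test_that("resample_all scheme appends missed forced records", {
  withr::local_seed(2)
  recs <- toy_records()
  forced <- recs$record_id[recs$group == "PF"]
  for (i in 1:50) {
    s <- draw_bootstrap_sample(recs, forced, scheme = "resample_all")
    expect_gte(nrow(s), nrow(recs))
    expect_true(all(forced %in% s$record_id))
  }
})

test_that("perfect separation gives certain, zero-width intervals", {
  withr::local_seed(3)
  recs <- toy_records()
  # under the best-of-restarts protocol every replicate finds the global
  # two-cluster optimum, so the bootstrap distribution collapses
  bb <- boot_pregnancy(recs, model = "joint", n_boot = 50, seed = 4,
                       init = "best")
  s <- bb$summary
  expect_equal(bb$retention, 1)
  expect_true(all(s$ci_high - s$ci_low < 1e-6))
  expect_true(all(s$point[s$group == "PF"] > 0.999))
  expect_true(all(s$point[s$group == "JF"] < 0.001))
  # the single-start protocol still classifies every record correctly
  bp <- boot_pregnancy(recs, model = "joint", n_boot = 50, seed = 4)
  expect_true(all(bp$summary$point[bp$summary$group == "PF"] >= 0.75))
  expect_true(all(bp$summary$point[bp$summary$group == "JF"] < 0.75))
})

test_that("summaries are ordered and bounded probabilities", {
  recs <- gray_whale_records()
  bb <- boot_pregnancy(recs, model = "joint", n_boot = 150, seed = 5)
  s <- bb$summary
  expect_true(all(s$point >= 0 & s$point <= 1))
  expect_true(all(s$ci_low <= s$lq + 1e-12))
  expect_true(all(s$lq <= s$uq + 1e-12))
  expect_true(all(s$uq <= s$ci_high + 1e-12))
  expect_true(all(s$ci_low <= s$point_median & s$point_median <= s$ci_high))
  expect_equal(nrow(s), 42)
  expect_equal(bb$n_retained, round(bb$retention * 150))
})

test_that("identical seed and config reproduce bit-identical summaries", {
  recs <- gray_whale_records()
  b1 <- boot_pregnancy(recs, model = "w50", n_boot = 60, seed = 99)
  b2 <- boot_pregnancy(recs, model = "w50", n_boot = 60, seed = 99)
  expect_identical(b1$summary, b2$summary)
  b3 <- boot_pregnancy(recs, model = "w50", n_boot = 60, seed = 100)
  expect_false(identical(b1$summary$point, b3$summary$point))
})

test_that("point estimates are Monte-Carlo stable in n_boot", {
  recs <- gray_whale_records()
  b1 <- boot_pregnancy(recs, model = "fp4m", n_boot = 1000, seed = 7)
  b2 <- boot_pregnancy(recs, model = "fp4m", n_boot = 10000, seed = 8)
  d <- abs(b1$summary$point - b2$summary$point)
  # typical record moves well under 0.02; borderline records (medians
  # near 0.5) carry bootstrap noise of a few hundredths at 1000 replicates
  expect_lt(mean(d), 0.02)
  expect_lt(max(d), 0.08)
})

test_that("the point rule defaults to mean for the bivariate model and
           median for the univariate ones", {
  recs <- gray_whale_records()
  bj <- boot_pregnancy(recs, model = "joint", n_boot = 40, seed = 1)
  expect_equal(bj$point_rule, "mean")
  expect_identical(bj$summary$point, bj$summary$point_mean)
  bw <- boot_pregnancy(recs, model = 3, n_boot = 40, seed = 1)
  expect_equal(bw$model, "w50")
  expect_equal(bw$point_rule, "median")
  expect_identical(bw$summary$point, bw$summary$point_median)
})

test_that("degenerate inputs raise a hard retention error", {
  recs <- toy_records()
  recs$w50 <- 0.15   # all identical: every fit collapses
  expect_error(boot_pregnancy(recs, model = "w50", n_boot = 5, seed = 1),
               "no bootstrap replicate was retained")
})
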