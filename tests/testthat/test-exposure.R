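test_that("time credits follow the gap-capped span to the next record", {
  # regular 30-s spacing: every record carries 0.5 min
  expect_equal(time_credits(seq(0, 150, 30)), rep(0.5, 6))
  # a 60-s gap credits 1 min; a 10-min gap is capped at 2 min
  expect_equal(time_credits(c(0, 60, 660)), c(1, 2, 0.5))
  expect_equal(time_credits(numeric(0)), numeric(0))
})

test_that("threshold resolution handles absolute and relative forms", {
  expect_equal(resolve_threshold("absolute", 70), 70)
  expect_equal(resolve_threshold("relative", 30, baseline = 100), 70)
  # a 30% drop from the published median baseline of 96 mm Hg
  expect_equal(resolve_threshold("relative", 30, baseline = 96), 67.2)
  expect_error(resolve_threshold("relative", 30), "missing baseline")
})

test_that("minutes below uses strict inequality and time credits", {
  cr30 <- rep(0.5, 30)
  expect_equal(minutes_below(rep(65, 30), cr30, 70), 15)
  expect_equal(minutes_below(rep(75, 30), cr30, 70), 0)
  # a reading exactly at the threshold does not count ("MAP < 70")
  expect_equal(minutes_below(c(70, 69.99), c(0.5, 0.5), 70), 0.5)
})

test_that("area and TWA below threshold follow the rectangle rule", {
  # MAP 65 for 10 minutes below 70: deficit 5 x 10 min
  expect_equal(auc_below(rep(65, 20), rep(0.5, 20), 70), 50)
  expect_equal(auc_below(rep(75, 20), rep(0.5, 20), 70), 0)
  # two records (60, 68), each half a minute
  expect_equal(auc_below(c(60, 68), c(0.5, 0.5), 70), 6)
  # TWA = area / monitored duration
  expect_equal(twa_below(rep(65, 20), rep(10, 20), 70), 5)
  # an AUC of 50 min x mm Hg over a 200-minute case averages to 0.25 mm Hg
  expect_equal(auc_below(rep(69.75, 20), rep(10, 20), 70) / 200, 0.25)
  expect_error(twa_below(numeric(0), numeric(0), 70), "zero monitored")
})

test_that("exposure summaries equal brute-force per-sample summation", {
  set.seed(42)
  for (i in 1:200) {
    tr <- random_trace(n = sample(20:80, 1), seed = 5000 + i,
                       map_mean = 75, map_sd = 10)
    v <- data.frame(patient_id = 1L, phase = "intraop", t = tr$t,
                    sbp = tr$map + 30, dbp = tr$map - 15, map = tr$map,
                    source = "invasive")
    es <- exposure_summary(v, c(60, 65, 70, 75))
    for (th in c(60, 65, 70, 75)) {
      o <- oracle_exposure(tr$map, tr$t, th)
      row <- es[es$threshold == th, ]
      expect_equal(row$minutes_below, o$minutes, tolerance = 1e-12)
      expect_equal(row$auc_below, o$auc, tolerance = 1e-12)
      expect_equal(row$twa_below, o$twa, tolerance = 1e-12)
      expect_equal(row$monitored_min, o$monitored, tolerance = 1e-12)
    }
  }
})

test_that("exposure metrics are nondecreasing in the threshold", {
  for (i in 1:30) {
    tr <- random_trace(n = 50, seed = 7000 + i, map_mean = 72)
    v <- data.frame(patient_id = 1L, phase = "intraop", t = tr$t,
                    sbp = tr$map + 30, dbp = tr$map - 15, map = tr$map,
                    source = "invasive")
    es <- exposure_summary(v, seq(50, 90, 5))
    es <- es[order(es$threshold), ]
    expect_true(all(diff(es$minutes_below) >= 0))
    expect_true(all(diff(es$auc_below) >= 0))
    expect_true(all(diff(es$twa_below) >= 0))
  }
})

test_that("doubling time credits doubles duration and area but not TWA", {
  tr <- random_trace(n = 40, seed = 11, gap_prob = 0, map_mean = 72)
  v1 <- data.frame(patient_id = 1L, phase = "intraop", t = tr$t,
                   sbp = tr$map + 30, dbp = tr$map - 15, map = tr$map,
                   source = "invasive")
  v2 <- v1; v2$t <- v1$t * 2  # 60-s spacing
  e1 <- exposure_summary(v1, 70, interval = 30)
  e2 <- exposure_summary(v2, 70, interval = 60)
  expect_equal(e2$minutes_below, 2 * e1$minutes_below)
  expect_equal(e2$auc_below, 2 * e1$auc_below)
  expect_equal(e2$monitored_min, 2 * e1$monitored_min)
  expect_equal(e2$twa_below, e1$twa_below, tolerance = 1e-12)
})

test_that("relative thresholds resolve per patient from the baseline", {
  v <- tiny_vitals(2)  # baselines 96 and 97
  bl <- baseline_table_map(v)
  es <- exposure_summary(v, 30, kind = "relative", baselines = bl)
  expect_equal(sort(unique(round(es$threshold_value, 1))), c(67.2, 67.9))
  expect_error(exposure_summary(v, 30, kind = "relative"),
               "baselines")
})

test_that("duration bins and quartiles encode exposure as published", {
  mk <- function(minutes) {
    data.frame(patient_id = seq_along(minutes), threshold = 70,
               threshold_type = "absolute", threshold_value = 70,
               minutes_below = minutes, auc_below = minutes * 3,
               twa_below = minutes * 3 / 200, monitored_min = 200)
  }
  e <- categorize_exposure(mk(c(0, 0.4, 0.5, 5, 5.01, 10, 12, 15, 16, 40)))
  expect_equal(as.character(e$duration_bin),
               c("none", "none", "0.5-5", "0.5-5", "5-10", "5-10", "10-15",
                 "10-15", ">15", ">15"))
  # every patient falls in exactly one bin
  expect_false(anyNA(e$duration_bin))
  # quartiles partition the exposed patients into equal quarters,
  # unexposed patients form the reference level
  expect_equal(as.character(e$auc_quartile[1:2]), c("none", "none"))
  expect_equal(unname(table(e$auc_quartile)[paste0("Q", 1:4)]),
               rep(2L, 4), ignore_attr = TRUE)
  # quartile assignment is monotone in the underlying value
  ex <- e[e$minutes_below >= 0.5, ]
  expect_true(all(diff(as.integer(ex$auc_quartile[order(ex$auc_below)]))
                  >= 0))
  expect_error(categorize_exposure(mk(c(0, 1, 2, 0.2))),
               "fewer than 4 exposed")
})
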