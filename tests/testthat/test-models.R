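test_that("a balanced 2x2 with equal outcome rates gives OR 1", {
  d <- expand_2x2(30, 270, 30, 270)
  ft <- fit_logistic(y ~ x, d)
  x_row <- ft$terms[ft$terms$term == "x", ]
  expect_equal(x_row$or, 1, tolerance = 1e-6)
  expect_lt(x_row$ci_low, 1)
  expect_gt(x_row$ci_high, 1)
})

test_that("2x2 logistic fits equal the closed-form cross-product ratio", {
  set.seed(12)
  for (i in 1:10) {
    cts <- sample(20:400, 4)
    d <- expand_2x2(cts[1], cts[2], cts[3], cts[4])
    ft <- fit_logistic(y ~ x, d)
    expect_equal(ft$terms$or[ft$terms$term == "x"],
                 (cts[1] * cts[4]) / (cts[2] * cts[3]), tolerance = 1e-6)
  }
  # published hypertension counts: 472/874 MACE vs 15,243/34,388 non-MACE
  d <- expand_2x2(472, 15243, 874 - 472, 34388 - 15243)
  ft <- fit_logistic(y ~ x, d)
  expect_equal(ft$terms$or[ft$terms$term == "x"],
               (472 * 19145) / (402 * 15243), tolerance = 1e-6)
})

test_that("Wald intervals bracket the odds ratio", {
  d <- expand_2x2(40, 160, 25, 175)
  ft <- fit_logistic(y ~ x, d)
  tt <- ft$terms[ft$terms$term == "x", ]
  expect_lt(tt$ci_low, tt$or)
  expect_gt(tt$ci_high, tt$or)
  expect_equal(tt$or, exp(tt$estimate), tolerance = 1e-12)
})

test_that("perfect separation raises an explicit error", {
  d <- data.frame(y = c(rep(0, 20), rep(1, 20)),
                  x = c(rep(0, 20), rep(1, 20)))
  expect_error(fit_logistic(y ~ x, d), "separation")
})

test_that("null-effect Wald CIs cover OR = 1 at close to nominal rate", {
  set.seed(31)
  covered <- logical(200)
  for (i in 1:200) {
    x <- rbinom(300, 1, 0.4)
    y <- rbinom(300, 1, 0.2)           # independent of x
    ft <- tryCatch(fit_logistic(y ~ x, data.frame(x = x, y = y)),
                   error = function(e) NULL)
    tt <- ft$terms[ft$terms$term == "x", ]
    covered[i] <- tt$ci_low <= 1 && tt$ci_high >= 1
  }
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("standardized mean differences match published values", {
  # binary SMD from the printed hypertension and age>=80 proportions;
  # the hypertension value (0.1950) sits on a print-rounding boundary, so
  # agreement is asserted to half a unit of the printed precision
  expect_lt(abs(smd_from_props(0.54, 0.443) - 0.20), 0.006)
  expect_equal(round(smd_from_props(0.151, 0.07), 2), 0.26)
  # identical groups give zero, as does a constant variable
  g <- rep(c(TRUE, FALSE), each = 50)
  expect_equal(smd(rep(c(0, 1), 50), g), 0)
  expect_equal(smd(rep(1, 100), g), 0)
  # continuous SMD against a hand computation
  x <- c(rnorm(50, 10, 2), rnorm(50, 12, 2))
  m1 <- mean(x[!g]); m2 <- mean(x[g])
  s1 <- sd(x[!g]); s2 <- sd(x[g])
  expect_equal(smd(x, g), abs(m1 - m2) / sqrt((s1^2 + s2^2) / 2),
               tolerance = 1e-12)
  # symmetry under swapping group labels
  expect_equal(smd(x, g), smd(x, !g), tolerance = 1e-12)
})

test_that("baseline comparison reports counts, chi-square and SMD", {
  set.seed(5)
  d <- data.frame(mace = rbinom(500, 1, 0.3),
                  htn = rbinom(500, 1, 0.4),
                  age = rnorm(500, 72, 5),
                  asa = factor(sample(c("I", "II", "III"), 500, TRUE)))
  bt <- baseline_comparison(d, c("htn", "age", "asa"))
  expect_true(all(bt$smd >= 0))
  # chi-square agrees with the standard test without continuity correction
  ct <- suppressWarnings(chisq.test(table(d$htn, d$mace), correct = FALSE))
  expect_equal(bt$stat[bt$variable == "htn"], unname(ct$statistic),
               tolerance = 1e-9)
  expect_equal(bt$p[bt$variable == "htn"], ct$p.value, tolerance = 1e-9)
  # SMD agrees with the direct computation
  expect_equal(bt$smd[bt$variable == "htn"],
               smd(d$htn, d$mace), tolerance = 1e-12)
  # identical groups: zero SMD
  d2 <- d; d2$htn <- 1 - d2$mace * 0  # constant
  bt2 <- baseline_comparison(d2, "htn")
  expect_equal(bt2$smd, 0)
})

test_that("incidence summaries reproduce the published percentages", {
  expect_equal(incidence_summary(35262, 874)$incidence_pct, 2.48)
  expect_equal(incidence_summary(100, 0)$incidence_pct, 0)
  expect_equal(incidence_summary(13418, 296, digits = 1)$incidence_pct, 2.2)
  s <- incidence_summary(35262, 874,
                         c(mi = 101, hf = 139, arrhythmia = 391,
                           angina = 215, arrest_death = 65), digits = 3)
  expect_equal(s$subtypes$pct,
               c(0.286, 0.394, 1.109, 0.610, 0.184), tolerance = 0.0015)
})

test_that("stratified models keep the first exposed bin as reference", {
  set.seed(77)
  n <- 6000
  bins <- c("none", "0.5-5", "5-10", "10-15", ">15")
  d <- data.frame(
    age = sample(c(70, 85), n, TRUE, prob = c(0.8, 0.2)),
    duration_bin = factor(sample(bins, n, TRUE), levels = bins))
  # effect of the >15 bin only below age 80
  lp <- -3 + 1.1 * (d$duration_bin == ">15") * (d$age < 80)
  d$mace <- rbinom(n, 1, plogis(lp))
  sm <- stratified_models(d, age_cut = 80)
  expect_setequal(unique(sm$stratum), c("age<80", "age>=80"))
  # the reference bin never appears as an estimated term
  expect_false(any(grepl("0.5-5", sm$term)))
  lo <- sm[sm$stratum == "age<80" & sm$term == ">15", ]
  hi <- sm[sm$stratum == "age>=80" & sm$term == ">15", ]
  expect_gt(lo$ci_low, 1)                  # effect detected under 80
  expect_true(hi$ci_low <= 1 && hi$ci_high >= 1)  # null at >= 80
  # age cut below the cohort minimum yields a single stratum
  one <- stratified_models(d, age_cut = 60)
  expect_equal(unique(one$stratum), "age>=60")
})

test_that("exposure models return unadjusted and adjusted fits per form", {
  set.seed(9)
  n <- 4000
  bins <- c("none", "0.5-5", "5-10", "10-15", ">15")
  qs <- c("none", paste0("Q", 1:4))
  d <- data.frame(
    duration_bin = factor(sample(bins, n, TRUE), levels = bins),
    auc_quartile = factor(sample(qs, n, TRUE), levels = qs),
    twa_quartile = factor(sample(qs, n, TRUE), levels = qs),
    age = rnorm(n, 72, 5))
  d$mace <- rbinom(n, 1, 0.05)
  m <- run_exposure_models(d, confounders = "age")
  expect_setequal(unique(m$exposure), c("duration", "auc", "twa"))
  expect_setequal(unique(m$model), c("unadjusted", "adjusted"))
  # one term per non-reference level, for each of the two models
  expect_equal(nrow(m[m$exposure == "duration", ]), 8L)
  # under a null outcome the CIs cover 1 for most terms
  expect_gt(mean(m$ci_low <= 1 & m$ci_high >= 1), 0.8)
})
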