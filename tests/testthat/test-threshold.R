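make_curves <- function(grid, probs_by_stratum) {
  data.table::rbindlist(lapply(names(probs_by_stratum), function(s) {
    data.table::data.table(map = grid, stratum = s,
                           prob = probs_by_stratum[[s]])
  }))
}

test_that("cumulative exposure grid counts strictly-below time", {
  # one patient, constant 30-s sampling, MAP stepping down
  v <- data.frame(patient_id = 1L, phase = "intraop",
                  t = seq(0, by = 30, length.out = 8),
                  map = c(80, 75, 70, 65, 65, 60, 60, 60),
                  sbp = 110, dbp = 70, source = "invasive")
  M <- cumulative_exposure_grid(v, grid = c(60, 65, 70, 75, 80))
  expect_equal(unname(M[1, ]), c(0, 1.5, 2.5, 3, 3.5))
  # readings exactly at a grid value do not count below it
  expect_equal(M[1, "70"], minutes_below(v$map, rep(0.5, 8), 70))
})

test_that("risk curves report empty cells as missing, not zero", {
  expos <- matrix(c(0, 0, 0, 20, 25, 30), nrow = 3,
                  dimnames = list(1:3, c("60", "70")))
  cu <- univariate_risk_curve(expos, mace = c(0, 1, 0), strata = c(1, 10),
                              smooth_width = 1)
  # nobody has >= 1 min below 60
  expect_true(all(is.na(cu$prob[cu$map == 60])))
  expect_false(any(is.na(cu$prob[cu$map == 70])))
  # single-patient cohort: no crash, probabilities 0/1/NA only
  one <- univariate_risk_curve(expos[1, , drop = FALSE], mace = 0,
                               strata = c(1, 10), smooth_width = 1)
  expect_true(all(is.na(one$prob) | one$prob %in% c(0, 1)))
})

test_that("risk curves are flat when the outcome is independent", {
  set.seed(21)
  n <- 20000
  expos <- matrix(pmax(0, rnorm(n * 3, 8, 6)), ncol = 3,
                  dimnames = list(1:n, c("60", "70", "80")))
  expos <- t(apply(expos, 1, sort))  # nondecreasing in the grid
  colnames(expos) <- c("60", "70", "80")
  p0 <- 0.05
  mace <- rbinom(n, 1, p0)
  cu <- univariate_risk_curve(expos, mace, strata = c(1, 5),
                              smooth_width = 1)
  z <- (cu$prob_raw - p0) / sqrt(p0 * (1 - p0) / cu$n_at_risk)
  expect_lt(max(abs(z), na.rm = TRUE), 4)
})

test_that("convergence detection finds the declared changepoint", {
  grid <- 40:100
  sep_curve <- function(cut) ifelse(grid < cut, 0.03, 0)
  cu <- make_curves(grid, list(a = 0.025 + sep_curve(70),
                               b = rep(0.025, length(grid))))
  det <- detect_convergence(cu, tol = 0.01)
  expect_true(det$converged)
  expect_equal(det$threshold, 70)
  # identical curves: no separation anywhere -> no threshold
  same <- make_curves(grid, list(a = rep(0.03, 61), b = rep(0.03, 61)))
  det0 <- detect_convergence(same, tol = 0.01)
  expect_false(det0$converged)
  expect_true(is.na(det0$threshold))
  # separation persisting to the top of the grid -> not converged
  allsep <- make_curves(grid, list(a = rep(0.06, 61), b = rep(0.02, 61)))
  expect_false(detect_convergence(allsep, tol = 0.01)$converged)
})

test_that("the convergence detector is translation-equivariant", {
  grid <- 40:100
  probs <- list(a = 0.02 + 0.03 * plogis((65 - grid) / 3),
                b = 0.02 + 0.01 * plogis((65 - grid) / 3))
  cu <- make_curves(grid, probs)
  cu5 <- data.table::copy(cu)
  cu5$map <- cu5$map + 5
  d0 <- detect_convergence(cu, tol = 0.01)
  d5 <- detect_convergence(cu5, tol = 0.01)
  expect_equal(d5$threshold, d0$threshold + 5)
})

test_that("mismatched grids are rejected", {
  cu <- rbind(
    data.frame(map = 40:60, stratum = "a", prob = 0.02),
    data.frame(map = 41:61, stratum = "b", prob = 0.03))
  expect_error(detect_convergence(cu), "mismatched grids")
  expect_error(
    detect_convergence(data.frame(map = 40:60, stratum = "a", prob = 0.02)),
    "at least two strata")
})

test_that("spline-adjusted risk curve predicts sane probabilities", {
  set.seed(33)
  n <- 5000
  d <- data.frame(lowest_1min = runif(n, 45, 95),
                  age = rnorm(n, 72, 5),
                  asa = factor(sample(c("II", "III"), n, TRUE)))
  # risk rises below 65
  lp <- -3.6 + 0.08 * pmax(0, 65 - d$lowest_1min)
  d$mace <- rbinom(n, 1, plogis(lp))
  cv <- adjusted_risk_curve(d, lowest = "lowest_1min",
                            confounders = c("age", "asa"), grid = 40:100)
  expect_true(all(cv$prob >= 0 & cv$prob <= 1))
  # predicted risk at MAP 50 clearly exceeds risk at 85
  expect_gt(cv$prob[cv$map == 50], 2 * cv$prob[cv$map == 85])
  # a null cohort yields an essentially flat curve
  d0 <- d; d0$mace <- rbinom(n, 1, 0.03)
  cv0 <- adjusted_risk_curve(d0, lowest = "lowest_1min",
                             confounders = c("age", "asa"), grid = 40:100)
  expect_lt(diff(range(cv0$prob[cv0$map >= 50 & cv0$map <= 95])), 0.05)
})

test_that("standardization-adjusted strata curves handle confounding", {
  set.seed(55)
  n <- 20000
  old <- rbinom(n, 1, 0.3)
  # exposure driven by age; outcome driven by age only (no exposure effect)
  expos <- matrix(pmax(0, rnorm(n, 5 + 6 * old, 4)), ncol = 1,
                  dimnames = list(1:n, "70"))
  mace <- rbinom(n, 1, plogis(-4 + 1.2 * old))
  d <- data.frame(age = 70 + 12 * old + rnorm(n), mace = mace)
  raw <- univariate_risk_curve(expos, mace, strata = c(1, 8),
                               smooth_width = 1)
  adj <- adjusted_risk_curve_strata(expos, d, confounders = "age",
                                    strata = c(1, 8), smooth_width = 1)
  raw_sep <- abs(diff(raw$prob_raw[raw$map == 70]))
  adj_sep <- abs(diff(adj$prob_raw[adj$map == 70]))
  # adjustment removes most of the spurious separation
  expect_lt(adj_sep, 0.4 * raw_sep)
})
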