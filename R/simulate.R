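# Synthetic perioperative cohort generator.

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

rlnorm_iqr <- function(n, med, q1, q3) {
  sdlog <- (log(q3) - log(q1)) / (2 * qnorm(0.75))
  exp(rnorm(n, log(med), sdlog))
}

simulate_covariates <- function(cfg) {
  n <- cfg$n_patients
  pv <- cfg$covariate_prevalences
  samp <- function(p) sample(names(p), n, replace = TRUE, prob = p)
  dt <- data.table(
    patient_id = seq_len(n),
    age = rtrunc_norm(n, 70.5, 5.5, lower = 65),
    sex = ifelse(runif(n) < pv$sex_male, "male", "female"),
    bmi = rlnorm_iqr(n, 24.4, 22.2, 26.8),
    smoking = samp(pv$smoking), drinking = samp(pv$drinking),
    hypertension = runif(n) < pv$hypertension,
    diabetes = runif(n) < pv$diabetes,
    arrhythmia = runif(n) < pv$arrhythmia,
    chf = runif(n) < pv$chf, chd = runif(n) < pv$chd,
    valvular = runif(n) < pv$valvular, pad = runif(n) < pv$pad,
    cvd = runif(n) < pv$cvd, renal = runif(n) < pv$renal,
    hgb = rlnorm_iqr(n, 130, 119, 141),
    scr = rlnorm_iqr(n, 70.5, 60, 82.5),
    fb = rlnorm_iqr(n, 3.4, 2.9, 4.0),
    statin = runif(n) < pv$statin,
    antiplatelet = runif(n) < pv$antiplatelet,
    beta_blocker = runif(n) < pv$beta_blocker,
    acei = runif(n) < pv$acei, arb = runif(n) < pv$arb,
    diuretic = runif(n) < pv$diuretic,
    asa = factor(samp(pv$asa), levels = c("I", "II", "III", "IV")),
    surgery_type = samp(pv$surgery_type),
    emergency = runif(n) < pv$emergency,
    blood_loss = rlnorm_iqr(n, 100, 50, 200),
    urine_volume = rlnorm_iqr(n, 300, 100, 550),
    crystalloid_rate = rtrunc_norm(n, 0.05, 0.01, lower = 0.01))
  br <- cfg$duration_breaks
  bin <- sample.int(length(cfg$duration_probs), n, replace = TRUE,
                    prob = cfg$duration_probs)
  dt[, surgery_duration := runif(n, br[bin], br[bin + 1L])]
  dt
}

# MAP matrix: one row per patient, one 30-s (sampling_interval) step per
# column; NA beyond each patient's surgery duration.
simulate_map_matrix <- function(cfg, baseline, age, steps) {
  tp <- cfg$trace_params
  n <- length(steps)
  max_steps <- max(steps)
  step_min <- cfg$sampling_interval / 60
  mu <- baseline - tp$intraop_drop + tp$age_slope * (age - 71) +
    rnorm(n, 0, tp$level_sd)
  phi <- tp$mean_reversion
  sd_stat <- tp$volatility / sqrt(1 - phi^2)
  M <- matrix(NA_real_, n, max_steps)
  prev <- rnorm(n, 0, sd_stat)
  for (j in seq_len(max_steps)) {
    prev <- phi * prev + rnorm(n, 0, tp$volatility)
    M[, j] <- prev
  }
  # induction dip over the first minutes, linearly recovering
  ind_steps <- max(1L, round(tp$induction_duration / step_min))
  ind_depth <- pmax(0, rnorm(n, tp$induction_depth_mean,
                             tp$induction_depth_sd))
  for (j in seq_len(min(ind_steps, max_steps)))
    M[, j] <- M[, j] - ind_depth * (1 - (j - 1) / ind_steps)
  # Poisson-placed triangular hypotensive dips
  n_dips <- rpois(n, tp$dip_rate_per_hr * steps * step_min / 60)
  tot <- sum(n_dips)
  if (tot > 0) {
    pid <- rep.int(seq_len(n), n_dips)
    depth <- tp$dip_depth_min + rexp(tot, 1 / (tp$dip_depth_mean -
                                                 tp$dip_depth_min))
    dur <- pmax(1, rexp(tot, 1 / tp$dip_duration_mean)) / step_min
    start <- runif(tot, 1, steps[pid])
    a <- pmax(1L, as.integer(start))
    b <- pmin(steps[pid], as.integer(start + dur))
    keep <- b >= a
    if (any(keep)) {
      a <- a[keep]; b <- b[keep]
      dpth <- depth[keep]; dpid <- pid[keep]
      len <- b - a + 1L
      cols <- sequence(len, from = a)
      rows <- rep.int(dpid, len)
      rel <- (sequence(len) - 1) / pmax(rep.int(len, len) - 1L, 1L)
      prof <- rep.int(dpth, len) * (1 - abs(2 * rel - 1))
      prof[rep.int(len, len) == 1L] <- dpth[len == 1L]
      ij <- cbind(rows, cols)
      M[ij] <- M[ij] - prof
    }
  }
  M <- M + mu
  M <- pmin(pmax(M, 26), 154)
  mask <- col(M) > steps
  M[mask] <- NA_real_
  M
}

# logit P(MACE) linear predictor, without intercept
outcome_linear_predictor <- function(cfg, cov, minutes_below_true) {
  g <- cfg$covariate_log_or
  gv <- function(nm) if (nm %in% names(g)) g[[nm]] else 0
  lp <- gv("age_per_yr") * (cov$age - 71) +
    gv("arrhythmia") * cov$arrhythmia + gv("chf") * cov$chf +
    gv("chd") * cov$chd + gv("valvular") * cov$valvular +
    gv("hypertension") * cov$hypertension + gv("pad") * cov$pad +
    gv("cvd") * cov$cvd + gv("renal") * cov$renal +
    gv("asa_III") * (cov$asa == "III") + gv("asa_IV") * (cov$asa == "IV") +
    gv("emergency") * cov$emergency +
    gv("beta_blocker") * cov$beta_blocker + gv("statin") * cov$statin +
    gv("antiplatelet") * cov$antiplatelet + gv("diuretic") * cov$diuretic +
    gv("hgb_per_gl") * (cov$hgb - 130) + gv("scr_per_umoll") * (cov$scr - 70) +
    gv("fb_per_gl") * (cov$fb - 3.4) +
    gv("duration_per_min") * (cov$surgery_duration - 180) +
    gv("blood_loss_per_ml") * (cov$blood_loss - 100) +
    gv("thoracic") * (cov$surgery_type == "thoracic") +
    gv("vascular") * (cov$surgery_type == "vascular") +
    gv("ear_nose") * (cov$surgery_type == "ear_nose")
  lp + log(cfg$true_or_gt15min) * (minutes_below_true > 15) +
    cfg$beta_lin * pmin(minutes_below_true, cfg$cap_min)
}

# intercept such that the realized marginal incidence matches the target
calibrate_alpha <- function(lp, target) {
  f <- function(a) mean(plogis(a + lp)) - target
  uniroot(f, c(-30, 10), tol = 1e-10)$root
}

#' Simulate a synthetic perioperative cohort
#'
#' Generates covariates, pre- and intraoperative blood-pressure traces and
#' 30-day MACE outcomes under the configured dose-response model, then
#' corrupts a fraction of records with artifacts that each violate exactly
#' one of the four validity rules. Deterministic given the config seed.
#'
#' The MAP trajectory is a discrete-time mean-reverting (AR(1)) process
#' around an age-adjusted intraoperative level below the patient's
#' preoperative baseline, plus an induction dip in the first minutes and
#' Poisson-placed triangular hypotensive dips. Systolic/diastolic pressures
#' derive from MAP through a per-patient pulse pressure with
#' `dbp = map - pp/3`, `sbp = dbp + pp`, so the MAP identity is exact on
#' clean records. The outcome follows
#' `logit P(MACE) = alpha + log(OR_>15) 1[T > 15] + beta_lin min(T, cap) +
#' gamma' Z` with `T` the minutes below the true threshold, `alpha`
#' calibrated so the marginal incidence matches the target.
#'
#' @param config an [sim_config()] object.
#' @return list of class `ioh_cohort`: `patients` (one row per patient,
#'   covariates, outcome and subtype flags), `vitals` (long format:
#'   `patient_id`, `phase`, `t`, `sbp`, `dbp`, `map`, `source`, plus the
#'   internal truth column `.artifact_rule`), `config`, and `truth`
#'   (per-patient minutes below the true threshold, the calibrated
#'   intercept, and per-patient event probabilities).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "ioh_sim_config"))
  cfg <- config
  with_seed(stage_seed(cfg$seed, 1L), {
    cov <- simulate_covariates(cfg)
    n <- cfg$n_patients
    step_min <- cfg$sampling_interval / 60
    steps <- pmax(2L, as.integer(floor(cov$surgery_duration / step_min)))
    baseline_true <- rtrunc_norm(n, cfg$trace_params$baseline_mean,
                                 cfg$trace_params$baseline_sd, 70, 130)
    M <- simulate_map_matrix(cfg, baseline_true, cov$age, steps)
    minutes_below_true <- rowSums(M < cfg$true_threshold, na.rm = TRUE) *
      step_min
    lp <- outcome_linear_predictor(cfg, cov, minutes_below_true)
    alpha <- calibrate_alpha(lp, cfg$baseline_incidence)
    p_event <- plogis(alpha + lp)
    mace <- runif(n) < p_event
    # overlapping MACE subtypes, weights from published subtype counts
    sub_w <- c(mi = 101, hf = 139, arrhythmia = 391, angina = 215,
               arrest_death = 65)
    subs <- matrix(FALSE, n, length(sub_w),
                   dimnames = list(NULL, names(sub_w)))
    idx <- which(mace)
    if (length(idx)) {
      primary <- sample(names(sub_w), length(idx), replace = TRUE,
                        prob = sub_w)
      subs[cbind(idx, match(primary, colnames(subs)))] <- TRUE
      second <- runif(length(idx)) < 0.042
      if (any(second)) {
        alt <- vapply(primary[second], function(pr)
          sample(setdiff(names(sub_w), pr), 1L), character(1))
        subs[cbind(idx[second], match(alt, colnames(subs)))] <- TRUE
      }
    }
    cov[, mace := mace]
    for (s in colnames(subs)) cov[[paste0("mace_", s)]] <- subs[, s]

    # long-format vitals
    pid <- rep.int(seq_len(n), steps)
    step_within <- sequence(steps)
    map_v <- M[cbind(pid, step_within)]
    pp_pat <- rtrunc_norm(n, cfg$trace_params$pulse_pressure_mean,
                          cfg$trace_params$pulse_pressure_sd, 25, 65)
    pp <- pmin(pp_pat[pid], 3 * (map_v - 6))
    dbp_v <- map_v - pp / 3
    invasive <- runif(n) < cfg$invasive_prob
    intraop <- setDT(list(
      patient_id = pid, phase = rep("intraop", length(pid)),
      t = (step_within - 1) * cfg$sampling_interval,
      sbp = dbp_v + pp, dbp = dbp_v, map = map_v,
      source = c("noninvasive", "invasive")[invasive[pid] + 1L]))
    # preoperative readings, 5 minutes apart, ending before anesthesia start
    n_pre <- sample(cfg$preop_readings[1]:cfg$preop_readings[2], n,
                    replace = TRUE)
    ppid <- rep.int(seq_len(n), n_pre)
    pseq <- sequence(n_pre)
    pmap <- pmin(pmax(baseline_true[ppid] +
                        rnorm(length(ppid), 0,
                              cfg$trace_params$preop_noise_sd), 40), 150)
    ppp <- pmin(pp_pat[ppid], 3 * (pmap - 6))
    preop <- setDT(list(
      patient_id = ppid, phase = rep("preop", length(ppid)),
      t = -300 * (rep.int(n_pre, n_pre) - pseq + 1L),
      sbp = pmap - ppp / 3 + ppp, dbp = pmap - ppp / 3, map = pmap,
      source = rep("noninvasive", length(ppid))))
    # redundant noninvasive records for a few invasive patients
    mixed <- which(invasive & runif(n) < cfg$mixed_source_frac)
    extra <- NULL
    if (length(mixed)) {
      k <- 3L
      base <- as.integer(runif(length(mixed), 1, pmax(steps[mixed] - k, 2)))
      epid <- rep(mixed, each = k)
      estep <- rep(base, each = k) + rep(seq_len(k) - 1L, length(mixed))
      et <- (estep - 1L) * cfg$sampling_interval + 7
      level <- (baseline_true - cfg$trace_params$intraop_drop)[epid]
      emap <- pmin(pmax(rnorm(length(epid), level, 6), 30), 150)
      epp <- pmin(pp_pat[epid], 3 * (emap - 6))
      extra <- data.table(
        patient_id = epid, phase = "intraop", t = et,
        sbp = emap - epp / 3 + epp, dbp = emap - epp / 3, map = emap,
        source = "noninvasive")
    }
    vitals <- rbindlist(list(preop, intraop, extra), use.names = TRUE)
    setorder(vitals, patient_id, t)
    vitals[, .artifact_rule := 0L]
  })
  vitals <- inject_artifacts(vitals, cfg$artifact_rate,
                             seed = stage_seed(cfg$seed, 2L))
  structure(list(patients = cov[], vitals = vitals, config = cfg,
                 truth = list(minutes_below_true = minutes_below_true,
                              alpha = alpha, p_event = p_event,
                              baseline_map = baseline_true)),
            class = "ioh_cohort")
}

#' @export
print.ioh_cohort <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic perioperative cohort: %d patients, %d BP records\n",
    "  MACE: %d (%.2f%%); seed %d\n"),
    nrow(x$patients), nrow(x$vitals), sum(x$patients$mace),
    100 * mean(x$patients$mace), x$config$seed))
  invisible(x)
}

#' Corrupt records with single-rule artifacts
#'
#' Modifies exactly `ceiling(rate * N)` records so that each violates
#' exactly one randomly chosen validity rule among the four (and no other):
#' rule 1 sets SBP >= 300; rule 2 sets SBP <= DBP + 5; rule 3 sets
#' DBP <= 5; rule 4 pushes MAP above 155 or below 25. The violated rule is
#' recorded in the internal column `.artifact_rule` so tests can compare
#' the cleaned set against the injected truth.
#'
#' @param vitals vitals table (clean records).
#' @param rate fraction of records to corrupt, in `[0, 0.5)`.
#' @param seed integer seed for the corruption draw.
#' @return the vitals table with corrupted rows and `.artifact_rule` set
#'   (0 = untouched).
#' @export
inject_artifacts <- function(vitals, rate, seed = 1L) {
  if (rate < 0 || rate >= 0.5)
    stop("artifact rate must be in [0, 0.5)", call. = FALSE)
  vitals <- as.data.table(vitals)
  if (!".artifact_rule" %in% names(vitals)) vitals[, .artifact_rule := 0L]
  if (rate == 0 || nrow(vitals) == 0L) return(vitals[])
  n_mod <- ceiling(rate * nrow(vitals))
  with_seed(seed, {
    rows <- sample.int(nrow(vitals), n_mod)
    rules <- sample.int(4L, n_mod, replace = TRUE)
    r1 <- rows[rules == 1L]
    vitals[r1, `:=`(sbp = runif(length(r1), 300, 340), .artifact_rule = 1L)]
    r2 <- rows[rules == 2L]
    if (length(r2)) {
      low <- vitals$dbp[r2] < 20
      if (any(low)) vitals[r2[low], dbp := runif(sum(low), 40, 90)]
      vitals[r2, `:=`(sbp = dbp + runif(length(r2), 0, 5),
                      .artifact_rule = 2L)]
    }
    r3 <- rows[rules == 3L]
    vitals[r3, `:=`(dbp = runif(length(r3), 0.5, 5), .artifact_rule = 3L)]
    r4 <- rows[rules == 4L]
    if (length(r4)) {
      high <- runif(length(r4)) < 0.5
      vitals[r4, `:=`(map = ifelse(high, runif(length(r4), 156, 200),
                                   runif(length(r4), 5, 24)),
                      .artifact_rule = 4L)]
    }
  })
  vitals[]
}
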