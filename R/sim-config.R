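# Simulation configuration for the synthetic perioperative cohort.

# deterministic per-stage seed fan-out from the single config seed
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + stage) %% 2147483629)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

default_covariate_prevalences <- function() {
  list(
    sex_male = 0.519,
    smoking = c(non = 0.938, current = 0.031, former = 0.031),
    drinking = c(non = 0.806, current = 0.132, former = 0.061),
    hypertension = 0.443, diabetes = 0.228, arrhythmia = 0.094,
    chf = 0.002, chd = 0.111, valvular = 0.004, pad = 0.022,
    cvd = 0.077, renal = 0.012,
    statin = 0.054, antiplatelet = 0.084, beta_blocker = 0.086,
    acei = 0.038, arb = 0.091, diuretic = 0.072,
    asa = c(I = 0.017, II = 0.784, III = 0.192, IV = 0.007),
    emergency = 0.024,
    surgery_type = c(ear_nose = 0.049, hepatobiliary = 0.171,
                     orthopedics = 0.278, urology = 0.095, general = 0.175,
                     neurosurgery = 0.046, thoracic = 0.075,
                     vascular = 0.027, others = 0.084)
  )
}

default_covariate_log_or <- function() {
  c(age_per_yr = 0.04, arrhythmia = log(2.2), chf = log(3.0),
    chd = log(1.8), valvular = log(2.0), hypertension = log(1.2),
    pad = log(1.5), cvd = log(1.3), renal = log(1.8),
    asa_III = log(1.6), asa_IV = log(3.0), emergency = log(1.8),
    beta_blocker = log(1.5), statin = log(1.2), antiplatelet = log(1.2),
    diuretic = log(1.3),
    hgb_per_gl = -0.008, scr_per_umoll = 0.003, fb_per_gl = 0.15,
    duration_per_min = 0.0015, blood_loss_per_ml = 0.0008,
    thoracic = log(1.8), vascular = log(2.0), ear_nose = log(0.5))
}

default_trace_params <- function() {
  list(
    mean_reversion = 0.90,     # AR(1) coefficient per 30-s step
    volatility = 3,            # innovation SD, mm Hg per step
    intraop_drop = 10,         # mean MAP drop from baseline under anesthesia
    level_sd = 4,              # between-patient SD of the intraop level shift
    age_slope = -0.15,         # intraop level change per year of age over 71
    induction_depth_mean = 12, # induction dip, mm Hg
    induction_depth_sd = 4,
    induction_duration = 10,   # minutes
    dip_rate_per_hr = 1.2,     # Poisson-placed hypotensive dips
    dip_depth_min = 4,         # mm Hg; depth = min + Exp(mean - min)
    dip_depth_mean = 14,
    dip_duration_mean = 6,     # minutes, exponential, floor 1
    baseline_mean = 96,        # preoperative MAP, mm Hg
    baseline_sd = 10.4,
    preop_noise_sd = 4,
    pulse_pressure_mean = 45,
    pulse_pressure_sd = 8
  )
}

#' Synthetic cohort configuration
#'
#' Bundles every tunable of the synthetic perioperative cohort generator.
#' The defaults emulate the structure of a large retrospective cohort of
#' older noncardiac-surgery patients: ~2.5% MACE incidence, 30-second
#' blood-pressure sampling, covariate prevalences matching the published
#' non-MACE baseline column, a dose-dependent true effect of time with MAP
#' below 70 mm Hg (odds ratio 1.5 for more than 15 minutes, plus a small
#' linear per-minute term), and a 0.5% artifact contamination rate.
#'
#' @param n_patients cohort size (>= 1).
#' @param seed integer seed; every stage's randomness is derived from it.
#' @param true_threshold harmful MAP threshold in mm Hg (default 70).
#' @param true_or_gt15min odds ratio for > 15 minutes below the threshold
#'   (default 1.5).
#' @param beta_lin log-odds per minute below the threshold (capped at
#'   `cap_min`); the small default adds the graded dose-response seen in
#'   area/TWA quartiles.
#' @param baseline_incidence target marginal MACE incidence (default 0.025);
#'   the model intercept is calibrated against it on the realized cohort.
#' @param sampling_interval seconds between intraoperative records
#'   (default 30).
#' @param artifact_rate fraction of records corrupted (in `[0, 0.5)`).
#' @param trace_params list of trace-model settings; see
#'   `default_trace_params()` in the package source for the full set.
#' @param covariate_prevalences list of covariate distributions.
#' @param covariate_log_or named vector of covariate log-odds effects on
#'   the outcome.
#' @param duration_probs,duration_breaks surgery-duration mixture: bin
#'   probabilities over `length(duration_probs)` uniform bins with the given
#'   break points (minutes).
#' @param cap_min cap (minutes) for the linear exposure term (default 60).
#' @param invasive_prob probability a patient is monitored invasively.
#' @param mixed_source_frac fraction of invasively monitored patients who
#'   additionally carry a few redundant noninvasive records (exercises
#'   source selection).
#' @param preop_readings range (min, max) of preoperative readings per
#'   patient.
#' @return validated list of class `ioh_sim_config`.
#' @export
sim_config <- function(n_patients, seed = 1L,
                       true_threshold = 70, true_or_gt15min = 1.5,
                       beta_lin = 0.002, baseline_incidence = 0.025,
                       sampling_interval = 30, artifact_rate = 0.005,
                       trace_params = list(),
                       covariate_prevalences = list(),
                       covariate_log_or = NULL,
                       duration_probs = c(0.026, 0.497, 0.225, 0.252),
                       duration_breaks = c(31, 60, 180, 240, 480),
                       cap_min = 60, invasive_prob = 0.6,
                       mixed_source_frac = 0.1,
                       preop_readings = c(3L, 6L)) {
  stopifnot(n_patients >= 1, length(seed) == 1)
  if (artifact_rate < 0 || artifact_rate >= 0.5)
    stop("artifact_rate must be in [0, 0.5)", call. = FALSE)
  if (true_threshold <= 25 || true_threshold >= 155)
    stop("true_threshold must be in (25, 155) mm Hg", call. = FALSE)
  if (baseline_incidence <= 0 || baseline_incidence >= 1)
    stop("baseline_incidence must be in (0, 1)", call. = FALSE)
  if (length(duration_probs) != length(duration_breaks) - 1L ||
      any(duration_probs < 0) || any(diff(duration_breaks) <= 0))
    stop("invalid surgery-duration distribution", call. = FALSE)
  tp <- modifyList(default_trace_params(), trace_params)
  if (tp$volatility <= 0 || tp$mean_reversion < 0 || tp$mean_reversion >= 1)
    stop("invalid trace parameters: need volatility > 0 and ",
         "mean_reversion in [0, 1)", call. = FALSE)
  cfg <- list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    true_threshold = true_threshold, true_or_gt15min = true_or_gt15min,
    beta_lin = beta_lin, baseline_incidence = baseline_incidence,
    sampling_interval = sampling_interval, artifact_rate = artifact_rate,
    trace_params = tp,
    covariate_prevalences = modifyList(default_covariate_prevalences(),
                                       covariate_prevalences),
    covariate_log_or = if (is.null(covariate_log_or))
      default_covariate_log_or() else covariate_log_or,
    duration_probs = duration_probs / sum(duration_probs),
    duration_breaks = duration_breaks,
    cap_min = cap_min, invasive_prob = invasive_prob,
    mixed_source_frac = mixed_source_frac,
    preop_readings = as.integer(preop_readings))
  class(cfg) <- "ioh_sim_config"
  cfg
}

#' Null-effect configuration
#'
#' A [sim_config()] in which the outcome is independent of both the
#' hypotension exposure and every covariate: the >15-minute odds ratio is
#' 1, the linear term is 0 and all covariate effects are 0. Used for
#' coverage and flat-curve checks.
#'
#' @inheritParams sim_config
#' @param ... passed to [sim_config()].
#' @export
null_config <- function(n_patients, seed = 1L, ...) {
  cfg <- sim_config(n_patients, seed, true_or_gt15min = 1, beta_lin = 0, ...)
  cfg$covariate_log_or[] <- 0
  cfg
}

#' @export
print.ioh_sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic cohort config: n = %d, seed = %d\n",
    "  true threshold %g mm Hg; OR(>15 min) = %g; linear %g /min\n",
    "  target incidence %.3f; sampling %g s; artifact rate %.3f\n"),
    x$n_patients, x$seed, x$true_threshold, x$true_or_gt15min,
    x$beta_lin, x$baseline_incidence, x$sampling_interval,
    x$artifact_rate))
  invisible(x)
}
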