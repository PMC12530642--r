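# Replicated end-to-end recovery study: does the pipeline find the
# generator's harm threshold and effect size back?

#' Null-effect coverage study
#'
#' Simulates replicates under [null_config()] (outcome independent of the
#' exposure and of every covariate), fits the three categorical exposure
#' encodings against MACE, and records whether each term's 95% CI covers
#' the true odds ratio of 1.
#'
#' @param n_patients cohort size per replicate.
#' @param n_replicates number of replicates.
#' @param seed master seed.
#' @param threshold exposure threshold (mm Hg).
#' @return data.table: `replicate`, `exposure`, `term`, `or`, `ci_low`,
#'   `ci_high`, `covered`.
#' @export
null_coverage_study <- function(n_patients = 4000, n_replicates = 20,
                                seed = 1, threshold = 70) {
  rows <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    cfg <- null_config(n_patients, seed = stage_seed(seed, 2000 + i))
    co <- simulate_cohort(cfg)
    cl <- clean_vitals(co$vitals)
    expo <- categorize_exposure(exposure_summary(cl$vitals, threshold))
    ap <- expo[as.data.table(co$patients), on = "patient_id"]
    mod <- run_exposure_models(ap)
    mod[, `:=`(replicate = i, covered = ci_low <= 1 & ci_high >= 1)]
    rows[[i]] <- mod[, .(replicate, exposure, model, term, or, ci_low,
                         ci_high, covered)]
    rm(co, cl, expo, ap)
  }
  rbindlist(rows)
}

#' Threshold- and effect-recovery study
#'
#' Simulates `n_replicates` independent cohorts, runs each through the full
#' analysis path (artifact cleaning, cumulative exposure over the MAP grid,
#' stratified risk curves, convergence detection, duration-bin logistic
#' model adjusted for the standard confounders) and collects the detected
#' threshold and the adjusted odds ratio for the ">15 min" duration bin.
#'
#' @param n_patients cohort size per replicate.
#' @param n_replicates number of replicates.
#' @param seed master seed; replicate seeds are fanned out from it.
#' @param config named list of [sim_config()] overrides (e.g.
#'   `true_threshold = 60`).
#' @param grid,strata,smooth_width,window see [pipeline_config()].
#' @param tol_factor convergence tolerance as a fraction of the marginal
#'   incidence (default 0.25).
#' @param threshold exposure threshold for the association model; defaults
#'   to the generator's true threshold.
#' @return data.table with one row per replicate: `replicate`, `seed`,
#'   `incidence`, `threshold_est`, `converged`, `or_gt15`, `ci_low`,
#'   `ci_high` (adjusted ">15 min" odds ratio and Wald CI).
#' @export
recovery_study <- function(n_patients = 20000, n_replicates = 10, seed = 1,
                           config = list(), grid = 40:100,
                           strata = c(1, 3, 5, 10), smooth_width = 5,
                           window = 5, tol_factor = 0.25,
                           threshold = NULL) {
  rows <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    cfg <- do.call(sim_config,
                   c(list(n_patients = n_patients,
                          seed = stage_seed(seed, 1000 + i)), config))
    th_expo <- if (is.null(threshold)) cfg$true_threshold else threshold
    co <- simulate_cohort(cfg)
    cl <- clean_vitals(co$vitals)
    M <- cumulative_exposure_grid(cl$vitals, grid)
    pt <- ensure_asa_score(co$patients)[match(as.integer(rownames(M)),
                                              patient_id)]
    curves <- univariate_risk_curve(M, pt$mace, strata, smooth_width)
    det <- detect_convergence(curves, tol = tol_factor * mean(pt$mace),
                              window = window)
    expo <- categorize_exposure(exposure_summary(cl$vitals, th_expo))
    ap <- expo[pt, on = "patient_id"]
    mod <- run_exposure_models(ap, exposures = c(duration = "duration_bin"),
                               confounders = default_confounders())
    gt15 <- mod[model == "adjusted" & term == ">15"]
    rows[[i]] <- data.table(
      replicate = i, seed = cfg$seed, incidence = mean(pt$mace),
      threshold_est = det$threshold, converged = det$converged,
      or_gt15 = gt15$or, ci_low = gt15$ci_low, ci_high = gt15$ci_high)
    rm(co, cl, M, curves, expo, ap)
    gc(verbose = FALSE)
  }
  rbindlist(rows)
}
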