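# End-to-end pipeline: generate/load -> clean -> expose -> discover ->
# associate -> report.

#' Default confounder set
#'
#' The confounding variables carried by the adjusted models: demographics,
#' cardiovascular history, renal function, preoperative labs and
#' medications, and surgical factors.
#'
#' @return character vector of column names in the patient table.
#' @export
default_confounders <- function() {
  c("age", "cvd", "chd", "valvular", "chf", "arrhythmia", "hypertension",
    "pad", "renal", "hgb", "scr", "fb", "antiplatelet", "beta_blocker",
    "acei", "arb", "diuretic", "asa_score", "surgery_type",
    "surgery_duration", "emergency", "blood_loss", "urine_volume",
    "crystalloid_rate")
}

# the models enter ASA as a numeric score (I-IV -> 1-4); derive it when the
# table carries only the factor
ensure_asa_score <- function(patients) {
  patients <- as.data.table(patients)
  if (!"asa_score" %in% names(patients) && "asa" %in% names(patients))
    patients[, asa_score := as.integer(factor(asa,
                                              levels = c("I", "II", "III",
                                                         "IV")))]
  patients
}

#' Pipeline configuration
#'
#' Every downstream module parameter is reachable from here. Either supply
#' `vitals_path`/`patients_path` to analyse existing files, or `generator`
#' settings (passed to [sim_config()]) to simulate a cohort. Unknown keys
#' passed through `...` are rejected.
#'
#' @param seed integer master seed.
#' @param generator named list of [sim_config()] arguments (used when no
#'   input paths are given); `n_patients` required.
#' @param vitals_path,patients_path optional input files.
#' @param threshold primary absolute MAP threshold (mm Hg) for the exposure
#'   encodings and association models.
#' @param grid MAP grid for threshold discovery.
#' @param strata cumulative-duration strata (minutes).
#' @param smooth_width risk-curve smoother width in grid points.
#' @param tol convergence tolerance (`NULL` = 0.25 x marginal incidence).
#' @param window convergence persistence window in grid points.
#' @param confounders confounder column names.
#' @param age_cut stratification age (years).
#' @param widths moving-average widths (minutes) for the lowest MAP.
#' @param interval,gap_cap sampling interval and gap cap in seconds.
#' @param out_dir output directory (created if needed); `NULL` = no files.
#' @param verbose log stage progress to standard error.
#' @param ... must be empty; unknown keys raise an error.
#' @return list of class `ioh_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, generator = NULL,
                            vitals_path = NULL, patients_path = NULL,
                            threshold = 70, grid = 40:100,
                            strata = c(1, 3, 5, 10), smooth_width = 5,
                            tol = NULL, window = 5,
                            confounders = default_confounders(),
                            age_cut = 80, widths = c(1, 3, 5),
                            interval = 30, gap_cap = 120,
                            out_dir = NULL, verbose = FALSE, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown pipeline config keys: ",
         paste(names(extra), collapse = ", "), call. = FALSE)
  if (is.null(generator) && (is.null(vitals_path) || is.null(patients_path)))
    stop("supply either generator settings or both input paths",
         call. = FALSE)
  structure(list(seed = as.integer(seed), generator = generator,
                 vitals_path = vitals_path, patients_path = patients_path,
                 threshold = threshold, grid = grid, strata = strata,
                 smooth_width = smooth_width, tol = tol, window = window,
                 confounders = confounders, age_cut = age_cut,
                 widths = widths, interval = interval, gap_cap = gap_cap,
                 out_dir = out_dir, verbose = verbose),
            class = "ioh_pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[iohmace] ", fmt), ...))
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate (or load) -> clean -> expose -> discover ->
#' associate -> report. Deterministic given the config seed. When
#' `out_dir` is set, writes the exposure table, risk curves, threshold
#' estimates, model tables, baseline table, cleaning report and a run
#' manifest (config echo + package version + seed) as delimited/JSON files.
#'
#' @param config an [pipeline_config()] object.
#' @return list of class `ioh_pipeline_result` with elements `patients`,
#'   `cleaning_report`, `baselines`, `lowest`, `exposure`, `curves`
#'   (univariate), `curves_adjusted`, `spline_curve`, `threshold_univariate`,
#'   `threshold_adjusted`, `models`, `stratified`, `baseline_table`,
#'   `summary`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ioh_pipeline_config"))
  cfg <- config
  if (!is.null(cfg$vitals_path)) {
    log_stage(cfg$verbose, "load: reading %s", cfg$vitals_path)
    vitals <- read_vitals(cfg$vitals_path)
    patients <- read_patients(cfg$patients_path)
    diags <- validate_inputs(vitals, patients)
    if (nrow(diags))
      stop("input validation failed (", nrow(diags), " diagnostics); ",
           "first: ", diags$detail[1], call. = FALSE)
  } else {
    gen <- cfg$generator
    gen$seed <- cfg$seed
    log_stage(cfg$verbose, "simulate: n = %s", gen$n_patients)
    cohort <- simulate_cohort(do.call(sim_config, gen))
    vitals <- cohort$vitals
    patients <- cohort$patients
  }
  log_stage(cfg$verbose, "clean: %d records", nrow(vitals))
  cl <- clean_vitals(vitals)
  baselines <- baseline_table_map(cl$vitals)
  lowest <- lowest_map_set(cl$vitals, cfg$widths, cfg$interval, cfg$gap_cap)

  log_stage(cfg$verbose, "expose: threshold %g mm Hg", cfg$threshold)
  expo <- exposure_summary(cl$vitals, cfg$threshold, "absolute",
                           interval = cfg$interval, gap_cap = cfg$gap_cap)
  expo <- categorize_exposure(expo)

  log_stage(cfg$verbose, "discover: grid %g-%g", min(cfg$grid), max(cfg$grid))
  M <- cumulative_exposure_grid(cl$vitals, cfg$grid, cfg$interval,
                                cfg$gap_cap)
  patients <- ensure_asa_score(patients)
  setkey(patients, NULL)
  pt <- patients[match(as.integer(rownames(M)), patient_id)]
  curves <- univariate_risk_curve(M, pt$mace, cfg$strata, cfg$smooth_width)
  th_uni <- detect_convergence(curves, cfg$tol, cfg$window)
  curves_adj <- adjusted_risk_curve_strata(M, pt, cfg$confounders,
                                           strata = cfg$strata,
                                           smooth_width = cfg$smooth_width)
  th_adj <- detect_convergence(curves_adj, cfg$tol, cfg$window)
  pt_low <- lowest[pt, on = "patient_id"]
  spline_curve <- adjusted_risk_curve(pt_low,
                                      lowest = sprintf("lowest_%gmin",
                                                       cfg$widths[1]),
                                      confounders = cfg$confounders,
                                      grid = cfg$grid)

  log_stage(cfg$verbose, "associate")
  ap <- expo[pt, on = "patient_id"]
  models <- run_exposure_models(ap, confounders = cfg$confounders)
  strat <- stratified_models(ap, cfg$age_cut, confounders = cfg$confounders)
  bl_vars <- intersect(c("sex", "age", "bmi", "smoking", "drinking",
                         "hypertension", "diabetes", "arrhythmia", "chf",
                         "chd", "valvular", "pad", "cvd", "renal", "hgb",
                         "scr", "fb", "statin", "antiplatelet",
                         "beta_blocker", "acei", "arb", "diuretic", "asa",
                         "emergency", "surgery_type", "surgery_duration",
                         "blood_loss", "urine_volume", "crystalloid_rate"),
                       names(pt))
  bl <- baseline_comparison(pt, bl_vars)
  summ <- cohort_summary(pt)

  manifest <- list(
    package = "iohmace",
    version = as.character(utils::packageVersion("iohmace")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), c("verbose", "out_dir"))],
    n_patients = nrow(pt),
    n_records = nrow(vitals),
    incidence_pct = summ$incidence_pct,
    threshold_univariate = th_uni$threshold,
    threshold_adjusted = th_adj$threshold)

  res <- structure(list(
    patients = pt, cleaning_report = cl$report, baselines = baselines,
    lowest = lowest, exposure = expo, curves = curves,
    curves_adjusted = curves_adj, spline_curve = spline_curve,
    threshold_univariate = th_uni, threshold_adjusted = th_adj,
    models = models, stratified = strat, baseline_table = bl,
    summary = summ, manifest = manifest), class = "ioh_pipeline_result")
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(res, cfg$out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  fwrite(res$exposure, p("exposure.csv"))
  fwrite(res$curves, p("risk_curves_univariate.csv"))
  fwrite(res$curves_adjusted, p("risk_curves_adjusted.csv"))
  fwrite(res$spline_curve, p("risk_curve_spline.csv"))
  fwrite(res$models, p("association_models.csv"))
  fwrite(res$stratified, p("stratified_models.csv"))
  fwrite(res$baseline_table, p("baseline_table.csv"))
  fwrite(res$cleaning_report, p("cleaning_report.csv"))
  th <- data.table(
    analysis = c("univariate", "adjusted"),
    threshold = c(res$threshold_univariate$threshold,
                  res$threshold_adjusted$threshold),
    converged = c(res$threshold_univariate$converged,
                  res$threshold_adjusted$converged),
    tol = c(res$threshold_univariate$tol, res$threshold_adjusted$tol))
  fwrite(th, p("threshold_estimates.csv"))
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(out_dir)
}

#' @export
print.ioh_pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d patients, MACE %.2f%%\n",
              nrow(x$patients), x$summary$incidence_pct))
  cat("Univariate ", sep = "")
  print(x$threshold_univariate)
  cat("Adjusted ", sep = "")
  print(x$threshold_adjusted)
  invisible(x)
}
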