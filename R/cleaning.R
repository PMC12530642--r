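# Vitals cleaning: artifact rules, source selection, baseline MAP.

#' Identify invalid blood-pressure records
#'
#' Applies the four published invalidity rules to systolic (SBP), diastolic
#' (DBP) and mean arterial pressure (MAP) readings, all in mm Hg:
#'
#' 1. SBP \eqn{\ge} 300 or \eqn{\le} 20
#' 2. SBP \eqn{\le} DBP + 5
#' 3. DBP \eqn{\le} 5 or \eqn{\ge} 225
#' 4. MAP > 155 or < 25
#'
#' Rule boundaries are inclusive exactly as written. A record violating
#' several rules is attributed to the lowest-numbered one.
#'
#' @param sbp,dbp,map numeric vectors of equal length (mm Hg). Missing `map`
#'   values are reconstructed as `dbp + (sbp - dbp)/3` before the rules are
#'   checked; records still missing a pressure after reconstruction are
#'   flagged with code 5 ("missing").
#' @return integer vector: 0 for a valid record, 1-4 for the first violated
#'   rule, 5 for unusable missing fields.
#' @export
bp_rule_violation <- function(sbp, dbp, map) {
  n <- length(sbp)
  stopifnot(length(dbp) == n, length(map) == n)
  fix <- which(is.na(map) & !is.na(sbp) & !is.na(dbp))
  if (length(fix)) map[fix] <- dbp[fix] + (sbp[fix] - dbp[fix]) / 3
  code <- rep.int(0L, n)
  missing <- is.na(sbp) | is.na(dbp) | is.na(map)
  r1 <- !missing & (sbp >= 300 | sbp <= 20)
  r2 <- !missing & (sbp <= dbp + 5)
  r3 <- !missing & (dbp <= 5 | dbp >= 225)
  r4 <- !missing & (map > 155 | map < 25)
  # lowest-numbered rule wins
  code[r4] <- 4L
  code[r3] <- 3L
  code[r2] <- 2L
  code[r1] <- 1L
  code[missing] <- 5L
  code
}

#' Remove artifactual records from a vitals table
#'
#' Drops every record that violates at least one of the four validity rules
#' (see [bp_rule_violation()]), preserving record order, and reports how many
#' removals each rule accounted for (a record counts against the
#' lowest-numbered rule it violates). Records with missing pressures that
#' cannot be reconstructed are dropped under their own counter.
#'
#' @param vitals data.frame with columns `sbp`, `dbp`, `map` (and any others,
#'   which are carried through).
#' @return list with `records` (the clean table), `removed` (named integer
#'   vector: rules `"1"`-`"4"` and `"missing"`), and `n_removed`.
#' @export
filter_artifacts <- function(vitals) {
  vitals <- as.data.table(vitals)
  code <- bp_rule_violation(vitals$sbp, vitals$dbp, vitals$map)
  removed <- c(tabulate(code, nbins = 5L))
  names(removed) <- c("1", "2", "3", "4", "missing")
  # reconstructed MAP is kept so downstream metrics can use it
  recon <- is.na(vitals$map) & code == 0L
  if (any(recon)) {
    vitals <- copy(vitals)
    vitals[recon, map := dbp + (sbp - dbp) / 3]
  }
  list(records = vitals[code == 0L], removed = removed,
       n_removed = sum(removed))
}

#' Prefer invasive over noninvasive intraoperative records
#'
#' If a patient has any invasive intraoperative blood-pressure record, all of
#' that patient's noninvasive intraoperative records are dropped; otherwise
#' the noninvasive records are kept. Preoperative records are never touched.
#'
#' @param vitals data.frame with columns `patient_id`, `phase`
#'   (`"preop"`/`"intraop"`) and `source` (`"invasive"`/`"noninvasive"`).
#' @return the filtered table, original order preserved.
#' @export
select_source <- function(vitals) {
  vitals <- as.data.table(vitals)
  if (nrow(vitals) == 0L) return(vitals)
  intra <- vitals$phase == "intraop"
  inv_ids <- unique(vitals$patient_id[intra & vitals$source == "invasive"])
  drop <- intra & vitals$source == "noninvasive" &
    vitals$patient_id %in% inv_ids
  vitals[!drop]
}

#' Baseline mean arterial pressure
#'
#' The baseline MAP is the arithmetic mean of a patient's preoperative MAP
#' readings.
#'
#' @param preop_map numeric vector of preoperative MAP readings (mm Hg).
#' @return list with `value` (mm Hg) and `n_readings`.
#' @export
compute_baseline <- function(preop_map) {
  preop_map <- preop_map[!is.na(preop_map)]
  if (length(preop_map) == 0L)
    stop("missing baseline: no valid preoperative MAP readings",
         call. = FALSE)
  list(value = mean(preop_map), n_readings = length(preop_map))
}

#' Per-patient baseline MAP table
#'
#' @param vitals clean vitals table with `patient_id`, `phase`, `map`.
#' @return data.table with `patient_id`, `baseline_map`, `n_readings`;
#'   patients without preoperative readings get `NA` baseline (they are
#'   excluded from relative-threshold analyses only).
#' @export
baseline_table_map <- function(vitals) {
  vitals <- as.data.table(vitals)
  pre <- vitals[phase == "preop" & !is.na(map),
                .(baseline_map = mean(map), n_readings = .N),
                by = patient_id]
  ids <- unique(vitals[, .(patient_id)])
  out <- pre[ids, on = "patient_id"]
  out[is.na(n_readings), n_readings := 0L]
  out[]
}

#' Clean a cohort vitals table
#'
#' Runs source selection then artifact filtering per the four validity rules,
#' and returns the clean table plus a per-patient cleaning report.
#'
#' @param vitals long-format vitals table (`patient_id`, `phase`, `t`, `sbp`,
#'   `dbp`, `map`, `source`).
#' @return list with `vitals` (clean, ordered by patient and time) and
#'   `report` (data.table: `patient_id`, removals per rule, `n_removed`).
#' @export
clean_vitals <- function(vitals) {
  vitals <- as.data.table(vitals)
  req <- c("patient_id", "phase", "t", "sbp", "dbp", "map", "source")
  miss <- setdiff(req, names(vitals))
  if (length(miss))
    stop("vitals table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  # source selection and rule filtering in one pass over the table
  intra <- vitals$phase == "intraop"
  inv_ids <- unique(vitals$patient_id[intra & vitals$source == "invasive"])
  kept_src <- !(intra & vitals$source == "noninvasive" &
                  vitals$patient_id %in% inv_ids)
  code <- bp_rule_violation(vitals$sbp, vitals$dbp, vitals$map)
  recon <- which(is.na(vitals$map) & code == 0L)
  if (length(recon)) {
    vitals <- copy(vitals)  # don't touch the caller's table
    set(vitals, recon, "map",
        vitals$dbp[recon] + (vitals$sbp[recon] - vitals$dbp[recon]) / 3)
  }
  code_kept <- code[kept_src]
  rpt <- setDT(list(patient_id = vitals$patient_id[kept_src],
                    rule1 = as.integer(code_kept == 1L),
                    rule2 = as.integer(code_kept == 2L),
                    rule3 = as.integer(code_kept == 3L),
                    rule4 = as.integer(code_kept == 4L),
                    missing = as.integer(code_kept == 5L)))[
    , lapply(.SD, sum), by = patient_id]
  rpt[, n_removed := rule1 + rule2 + rule3 + rule4 + missing]
  clean <- vitals[kept_src & code == 0L]
  setorder(clean, patient_id, t)  # preop times are negative, so t orders phases too
  list(vitals = clean, report = rpt[])
}
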