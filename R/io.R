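# Delimited-file input/output and input validation.

VITALS_COLS <- c("patient_id", "phase", "t", "sbp", "dbp", "map", "source")

#' Write / read a long-format vitals table
#'
#' Comma-separated, one row per blood-pressure record with columns
#' `patient_id`, `phase` (`preop`/`intraop`), `t` (seconds relative to
#' anesthesia start, negative preoperatively), `sbp`, `dbp`, `map` (mm Hg)
#' and `source` (`invasive`/`noninvasive`). Internal columns (names starting
#' with a dot) are never written.
#'
#' @param vitals vitals table.
#' @param path file path.
#' @export
write_vitals <- function(vitals, path) {
  vitals <- as.data.table(vitals)
  keep <- names(vitals)[!startsWith(names(vitals), ".")]
  fwrite(vitals[, ..keep], path)
  invisible(path)
}

#' @rdname write_vitals
#' @export
read_vitals <- function(path) {
  v <- fread(path)
  miss <- setdiff(VITALS_COLS, names(v))
  if (length(miss))
    stop("vitals file ", path, " is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  v
}

#' Write / read the one-row-per-patient table
#'
#' @param patients patient table.
#' @param path file path.
#' @export
write_patients <- function(patients, path) {
  fwrite(as.data.table(patients), path)
  invisible(path)
}

#' @rdname write_patients
#' @export
read_patients <- function(path) {
  p <- fread(path)
  if (!"patient_id" %in% names(p))
    stop("patients file ", path, " is missing column patient_id",
         call. = FALSE)
  if (!"mace" %in% names(p))
    stop("patients file ", path, " is missing column mace", call. = FALSE)
  p
}

#' Validate pipeline input tables
#'
#' Checks the vitals and patient tables for required columns and types,
#' per-patient monotone timestamps, valid phase/source labels, and
#' referential integrity across the two files. Problems are returned as a
#' diagnostics table, never silently dropped.
#'
#' @param vitals vitals table (or path to one).
#' @param patients patient table (or path to one).
#' @return data.table with columns `check`, `patient_id`, `detail`; zero
#'   rows when everything passes.
#' @export
validate_inputs <- function(vitals, patients) {
  if (is.character(vitals)) vitals <- fread(vitals)
  if (is.character(patients)) patients <- fread(patients)
  vitals <- as.data.table(vitals)
  patients <- as.data.table(patients)
  diags <- list()
  add <- function(check, pid, detail)
    diags[[length(diags) + 1L]] <<- data.table(
      check = check, patient_id = as.character(pid), detail = detail)
  for (col in setdiff(VITALS_COLS, names(vitals)))
    add("missing_column", NA, paste0("vitals lacks column '", col, "'"))
  if (!"patient_id" %in% names(patients))
    add("missing_column", NA, "patients lacks column 'patient_id'")
  if (length(diags)) return(rbindlist(diags))
  for (col in c("t", "sbp", "dbp", "map"))
    if (!is.numeric(vitals[[col]]))
      add("bad_type", NA, paste0("vitals column '", col, "' is not numeric"))
  bad_phase <- setdiff(unique(vitals$phase), c("preop", "intraop"))
  if (length(bad_phase))
    add("bad_label", NA, paste0("unknown phase value(s): ",
                                paste(bad_phase, collapse = ", ")))
  bad_src <- setdiff(unique(vitals$source), c("invasive", "noninvasive"))
  if (length(bad_src))
    add("bad_label", NA, paste0("unknown source value(s): ",
                                paste(bad_src, collapse = ", ")))
  nm <- vitals[, .(bad = anyDuplicated(t[phase == "intraop"]) > 0 ||
                     is.unsorted(t[phase == "intraop"])),
               by = patient_id][bad == TRUE]
  for (pid in nm$patient_id)
    add("non_monotone_time", pid,
        "intraoperative timestamps are not strictly increasing")
  orphan <- setdiff(unique(vitals$patient_id), patients$patient_id)
  for (pid in orphan)
    add("referential", pid, "patient present in vitals but not in patients")
  no_vitals <- setdiff(patients$patient_id, unique(vitals$patient_id))
  for (pid in no_vitals)
    add("referential", pid, "patient has no vitals records")
  if (length(diags)) rbindlist(diags)
  else data.table(check = character(), patient_id = character(),
                  detail = character())
}
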