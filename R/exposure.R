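# Hypotension exposure statistics: minutes below, area below, time-weighted
# average below a MAP threshold; categorical encodings.

#' Per-record time credits
#'
#' Each record represents the span until the next record, capped at
#' `gap_cap` seconds so that a reading never stands in for a long
#' unmonitored stretch; the final record carries the nominal interval.
#'
#' @param t record times in seconds (ordered, strictly increasing).
#' @param interval nominal sampling interval in seconds.
#' @param gap_cap maximum credited gap in seconds.
#' @return numeric vector of credits in minutes.
#' @export
time_credits <- function(t, interval = 30, gap_cap = 120) {
  n <- length(t)
  if (n == 0L) return(numeric(0))
  gaps <- c(diff(t), interval)
  pmin(gaps, gap_cap) / 60
}

# Vectorized per-record credits for a cohort table already ordered by
# patient_id, t. Same result as time_credits() applied per patient.
cohort_credits <- function(patient_id, t, interval, gap_cap) {
  n <- length(t)
  if (n == 0L) return(numeric(0))
  gap <- c(t[-1L] - t[-n], interval)
  last <- c(patient_id[-1L] != patient_id[-n], TRUE)
  gap[last] <- interval
  pmin(gap, gap_cap) / 60
}

#' Resolve a hypotension threshold
#'
#' Absolute thresholds pass through unchanged; a relative threshold of x%
#' below baseline resolves to `baseline * (1 - x/100)`.
#'
#' @param kind `"absolute"` or `"relative"`.
#' @param value mm Hg (absolute) or percent drop (relative).
#' @param baseline baseline MAP in mm Hg; required for relative thresholds.
#' @return resolved threshold in mm Hg.
#' @export
resolve_threshold <- function(kind = c("absolute", "relative"), value,
                              baseline = NULL) {
  kind <- match.arg(kind)
  if (kind == "absolute") return(value)
  if (is.null(baseline) || is.na(baseline))
    stop("missing baseline: relative threshold needs a baseline MAP",
         call. = FALSE)
  baseline * (1 - value / 100)
}

#' Minutes with MAP below a threshold
#'
#' Sums the time credits of records whose MAP is strictly below the
#' threshold ("MAP < threshold"; a reading exactly at the threshold does not
#' count).
#'
#' @param map MAP readings (mm Hg), time-ordered.
#' @param credits per-record time credits in minutes (see [time_credits()]).
#' @param threshold mm Hg.
#' @return minutes below the threshold.
#' @export
minutes_below <- function(map, credits, threshold) {
  stopifnot(length(map) == length(credits))
  sum(credits[map < threshold])
}

#' Area under the threshold-time plot
#'
#' Rectangle-rule integral of the MAP deficit below the threshold:
#' `sum(max(0, threshold - map) * credit)` in min x mm Hg.
#'
#' @inheritParams minutes_below
#' @return area in min x mm Hg.
#' @export
auc_below <- function(map, credits, threshold) {
  stopifnot(length(map) == length(credits))
  sum(pmax(0, threshold - map) * credits)
}

#' Time-weighted average MAP deficit below a threshold
#'
#' The area below the threshold divided by the monitored duration
#' (`sum(credits)`); mm Hg.
#'
#' @inheritParams minutes_below
#' @return TWA deficit in mm Hg.
#' @export
twa_below <- function(map, credits, threshold) {
  dur <- sum(credits)
  if (dur <= 0) stop("zero monitored duration", call. = FALSE)
  auc_below(map, credits, threshold) / dur
}

#' Per-patient exposure summaries at one or more thresholds
#'
#' Computes minutes-below, area-below and time-weighted-average deficit for
#' every patient in a clean intraoperative vitals table, at each requested
#' threshold. Relative thresholds (percent below baseline) resolve per
#' patient; patients without a baseline are dropped from relative analyses.
#'
#' @param vitals clean vitals table; only `phase == "intraop"` rows are used.
#' @param thresholds numeric vector: mm Hg for `kind = "absolute"`, percent
#'   drop for `kind = "relative"`.
#' @param kind `"absolute"` (default) or `"relative"`.
#' @param baselines data.table `patient_id`, `baseline_map`; required for
#'   relative thresholds.
#' @param interval,gap_cap see [time_credits()].
#' @return data.table keyed by `patient_id` x `threshold` with
#'   `threshold_type`, `threshold_value` (resolved mm Hg), `minutes_below`,
#'   `auc_below`, `twa_below`, `monitored_min`.
#' @export
exposure_summary <- function(vitals, thresholds, kind = c("absolute", "relative"),
                             baselines = NULL, interval = 30, gap_cap = 120) {
  kind <- match.arg(kind)
  vitals <- as.data.table(vitals)[phase == "intraop"]
  setorder(vitals, patient_id, t)
  vitals[, credit := cohort_credits(patient_id, t, interval, gap_cap)]
  if (kind == "relative") {
    if (is.null(baselines))
      stop("relative thresholds need per-patient baselines", call. = FALSE)
    baselines <- as.data.table(baselines)
    vitals <- baselines[!is.na(baseline_map)][vitals, on = "patient_id",
                                              nomatch = NULL]
  }
  monitored <- vitals[, .(monitored_min = sum(credit)), by = patient_id]
  out <- rbindlist(lapply(thresholds, function(th) {
    tv <- if (kind == "absolute") rep(th, nrow(vitals))
          else vitals$baseline_map * (1 - th / 100)
    s <- setDT(list(
      patient_id = vitals$patient_id,
      mb = vitals$credit * (vitals$map < tv),
      ab = pmax(0, tv - vitals$map) * vitals$credit))[
      , .(minutes_below = sum(mb), auc_below = sum(ab)), by = patient_id]
    s <- monitored[s, on = "patient_id"]
    if (kind == "absolute") s[, threshold_value := th]
    else s[as.data.table(baselines), on = "patient_id",
           threshold_value := baseline_map * (1 - th / 100)]
    s[, threshold := th]
    s
  }))
  out[, twa_below := auc_below / monitored_min]
  out[, threshold_type := kind]
  setcolorder(out, c("patient_id", "threshold_type", "threshold",
                     "threshold_value", "minutes_below", "auc_below",
                     "twa_below", "monitored_min"))
  out[]
}

#' Categorical exposure encodings
#'
#' Bins the duration exposure into the study's categories
#' (`none` for < 0.5 min, then `0.5-5`, `5-10`, `10-15`, `>15`; the first
#' bin is closed on the right, so 5.0 min falls in `0.5-5`), and assigns
#' area and TWA quartiles among exposed patients only
#' (`minutes_below >= 0.5`); unexposed patients form the reference category
#' `none`. Quartiles are equal-frequency rank quartiles with ties broken by
#' `patient_id` order, so the assignment is reproducible.
#'
#' @param expo exposure table from [exposure_summary()], one threshold.
#' @param duration_breaks inner break points in minutes
#'   (default `c(0.5, 5, 10, 15)`).
#' @return `expo` with added factors `duration_bin`, `auc_quartile`,
#'   `twa_quartile`.
#' @export
categorize_exposure <- function(expo, duration_breaks = c(0.5, 5, 10, 15)) {
  expo <- as.data.table(expo)
  if (length(unique(expo$threshold)) > 1L)
    stop("categorize_exposure() expects a single threshold", call. = FALSE)
  b <- duration_breaks
  labs <- c("none", paste0(b[1], "-", b[2]), paste0(b[2], "-", b[3]),
            paste0(b[3], "-", b[4]), paste0(">", b[4]))
  expo[, duration_bin := cut(minutes_below,
                             breaks = c(-Inf, b[1] - 1e-12, b[2], b[3], b[4], Inf),
                             labels = labs, right = TRUE)]
  exposed <- expo$minutes_below >= b[1]
  qlabs <- c("none", paste0("Q", 1:4))
  rank_quartile <- function(x, id, keep) {
    q <- rep(NA_integer_, length(x))
    idx <- which(keep)
    if (length(idx) < 4L)
      stop("fewer than 4 exposed patients: quartiles undefined",
           call. = FALSE)
    ord <- idx[order(x[idx], id[idx])]
    q[ord] <- ceiling(4 * seq_along(ord) / length(ord))
    q
  }
  expo[, `:=`(
    auc_quartile = factor(qlabs[1L + ifelse(exposed,
      rank_quartile(auc_below, patient_id, exposed), 0L)], levels = qlabs),
    twa_quartile = factor(qlabs[1L + ifelse(exposed,
      rank_quartile(twa_below, patient_id, exposed), 0L)], levels = qlabs)
  )]
  expo[]
}
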