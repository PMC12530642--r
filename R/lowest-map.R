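# Lowest moving-average MAP at 1/3/5-minute widths.

# Split record indices into segments at gaps larger than gap_cap seconds.
segment_ids <- function(t, gap_cap) {
  if (length(t) == 0L) return(integer(0))
  cumsum(c(1L, as.integer(diff(t) > gap_cap)))
}

#' Lowest moving-average MAP
#'
#' Minimum over all contiguous trailing windows of the window-mean MAP.
#' The window holds `width * 60 / interval` consecutive samples and advances
#' one record at a time. Windows never span gaps wider than `gap_cap`
#' seconds: the trace is cut into segments at such gaps and windows are
#' formed within segments only.
#'
#' @param map numeric MAP readings (mm Hg), time-ordered.
#' @param t record times in seconds (same length as `map`).
#' @param width window width in minutes (the study uses 1, 3 and 5).
#' @param interval nominal sampling interval in seconds (default 30).
#' @param gap_cap gap (seconds) above which windows are broken (default 120).
#' @return the lowest window-mean MAP in mm Hg.
#' @export
moving_average_min <- function(map, t, width, interval = 30, gap_cap = 120) {
  stopifnot(length(map) == length(t), width > 0, interval > 0)
  k <- as.integer(round(width * 60 / interval))
  if (k < 1L) k <- 1L
  seg <- segment_ids(t, gap_cap)
  best <- Inf
  for (s in unique(seg)) {
    x <- map[seg == s]
    if (length(x) < k) next
    mins <- data.table::frollmean(x, n = k, algo = "exact")
    m <- min(mins, na.rm = TRUE)
    if (m < best) best <- m
  }
  if (!is.finite(best))
    stop("trace too short: no segment holds a full ", width,
         "-minute window", call. = FALSE)
  best
}

#' Per-patient lowest moving-average MAP set
#'
#' Computes the lowest moving-average intraoperative MAP at the requested
#' widths for every patient in a clean vitals table. Patients whose trace is
#' shorter than a window get `NA` for that width.
#'
#' @param vitals clean vitals table (`patient_id`, `phase`, `t`, `map`).
#' @param widths window widths in minutes, default `c(1, 3, 5)`.
#' @inheritParams moving_average_min
#' @return data.table with `patient_id` and one `lowest_<w>min` column per
#'   width.
#' @export
lowest_map_set <- function(vitals, widths = c(1, 3, 5), interval = 30,
                           gap_cap = 120) {
  vitals <- as.data.table(vitals)[phase == "intraop"]
  setorder(vitals, patient_id, t)
  n <- nrow(vitals)
  # segment breaks at patient changes or gaps wider than gap_cap
  newseg <- c(TRUE, vitals$patient_id[-1L] != vitals$patient_id[-n] |
                vitals$t[-1L] - vitals$t[-n] > gap_cap)
  seg <- cumsum(newseg)
  pos <- seq_len(n) - cummax(seq_len(n) * newseg) + 1L  # index within segment
  out <- vitals[, .(patient_id = unique(patient_id))]
  setnames(out, "patient_id")
  for (w in widths) {
    k <- max(1L, as.integer(round(w * 60 / interval)))
    rm_ <- data.table::frollmean(vitals$map, n = k, algo = "exact")
    rm_[pos < k] <- Inf  # window would span a segment break
    col <- sprintf("lowest_%gmin", w)
    mins <- setDT(list(patient_id = vitals$patient_id, v = rm_))[
      , .(m = min(v)), by = patient_id]
    mins[!is.finite(m), m := NA_real_]
    out[mins, on = "patient_id", (col) := m]
  }
  out[]
}
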