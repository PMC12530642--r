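# Shared fixtures and independent brute-force oracles used across tests.

# random blood-pressure trace with optional irregular gaps
random_trace <- function(n = 40, seed = NULL, interval = 30,
                         gap_prob = 0.1, map_mean = 80, map_sd = 12) {
  if (!is.null(seed)) set.seed(seed)
  gaps <- rep(interval, n - 1)
  widen <- runif(n - 1) < gap_prob
  gaps[widen] <- gaps[widen] + sample(c(30, 90, 180), sum(widen),
                                      replace = TRUE)
  t <- cumsum(c(0, gaps))
  map <- pmin(pmax(rnorm(n, map_mean, map_sd), 30, na.rm = TRUE), 150)
  list(t = t, map = map)
}

# brute-force all-windows moving-average minimum (independent of the
# package's segment/frollmean implementation)
oracle_moving_min <- function(map, t, width, interval = 30, gap_cap = 120) {
  k <- round(width * 60 / interval)
  n <- length(map)
  best <- Inf
  if (n >= k) {
    for (s in 1:(n - k + 1)) {
      idx <- s:(s + k - 1)
      if (k > 1 && any(diff(t[idx]) > gap_cap)) next
      best <- min(best, sum(map[idx]) / k)
    }
  }
  if (!is.finite(best)) NA_real_ else best
}

# brute-force per-sample exposure sums: loop over records, accumulate
oracle_exposure <- function(map, t, threshold, interval = 30,
                            gap_cap = 120) {
  n <- length(map)
  mins <- 0; area <- 0; dur <- 0
  for (i in seq_len(n)) {
    gap <- if (i < n) t[i + 1] - t[i] else interval
    credit <- min(gap, gap_cap) / 60
    dur <- dur + credit
    if (map[i] < threshold) {
      mins <- mins + credit
      area <- area + (threshold - map[i]) * credit
    }
  }
  list(minutes = mins, auc = area, twa = area / dur, monitored = dur)
}

# direct evaluation of the restricted cubic term
oracle_rcs2 <- function(x, k) {
  pp <- function(u) ifelse(u > 0, u^3, 0)
  (pp(x - k[1]) - pp(x - k[2]) * (k[3] - k[1]) / (k[3] - k[2]) +
      pp(x - k[3]) * (k[2] - k[1]) / (k[3] - k[2])) / (k[3] - k[1])^2
}

# expand a 2x2 table (exposed/unexposed x event/no-event) to a data frame
expand_2x2 <- function(a, b, c_, d) {
  # a = exposed events, b = exposed non-events,
  # c_ = unexposed events, d = unexposed non-events
  data.frame(
    y = rep(c(1, 0, 1, 0), c(a, b, c_, d)),
    x = rep(c(1, 1, 0, 0), c(a, b, c_, d)))
}

# one small valid vitals table for IO/pipeline tests
tiny_vitals <- function(n_patients = 3, n_records = 20, seed = 99) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_patients), function(i) {
    pre <- data.frame(patient_id = i, phase = "preop",
                      t = c(-600, -300), sbp = 135, dbp = 75,
                      map = 95 + i, source = "noninvasive")
    map <- round(rnorm(n_records, 82, 8), 1)
    intra <- data.frame(patient_id = i, phase = "intraop",
                        t = seq(0, by = 30, length.out = n_records),
                        sbp = map + 30, dbp = map - 15, map = map,
                        source = "invasive")
    rbind(pre, intra)
  }))
}
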