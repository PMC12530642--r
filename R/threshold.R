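# Harm-threshold discovery: risk curves of MACE probability against MAP,
# stratified by cumulative hypotension duration, and convergence detection.

#' Cumulative exposure over a MAP grid
#'
#' For every patient and every grid value m, the minutes spent with MAP
#' strictly below m (using the same per-record time credits as
#' [exposure_summary()]). With `kind = "relative"` the grid is expressed
#' in percent of the patient's baseline MAP (e.g. 70 means "below 70% of
#' baseline", a 30% drop), so the same ascending-grid machinery serves the
#' relative-threshold analysis; patients without a baseline are dropped.
#'
#' @param vitals clean vitals table; intraoperative rows are used.
#' @param grid increasing grid: mm Hg for `kind = "absolute"` (default
#'   40-100 in 1 mm Hg steps), percent of baseline for `"relative"`.
#' @param kind `"absolute"` (default) or `"relative"`.
#' @param baselines data.table `patient_id`, `baseline_map` (required for
#'   `kind = "relative"`).
#' @param interval,gap_cap see [time_credits()].
#' @return numeric matrix, one row per patient (rownames = patient ids,
#'   sorted), one column per grid value.
#' @export
cumulative_exposure_grid <- function(vitals, grid = 40:100, interval = 30,
                                     gap_cap = 120,
                                     kind = c("absolute", "relative"),
                                     baselines = NULL) {
  stopifnot(all(diff(grid) > 0))
  kind <- match.arg(kind)
  vitals <- as.data.table(vitals)[phase == "intraop"]
  if (kind == "relative") {
    if (is.null(baselines))
      stop("relative grids need per-patient baselines", call. = FALSE)
    bl <- as.data.table(baselines)[!is.na(baseline_map)]
    vitals <- bl[, .(patient_id, baseline_map)][vitals, on = "patient_id",
                                                nomatch = NULL]
  }
  setorder(vitals, patient_id, t)
  vitals[, credit := cohort_credits(patient_id, t, interval, gap_cap)]
  ids <- sort(unique(vitals$patient_id))
  G <- length(grid)
  # record with value x counts toward grid values strictly above x
  if (kind == "relative")
    vitals[, bin := findInterval(100 * map / baseline_map, grid) + 1L]
  else
    vitals[, bin := findInterval(map, grid) + 1L]
  agg <- vitals[bin <= G, .(credit = sum(credit)), by = .(patient_id, bin)]
  M <- matrix(0, nrow = length(ids), ncol = G,
              dimnames = list(as.character(ids), as.character(grid)))
  M[cbind(match(agg$patient_id, ids), agg$bin)] <- agg$credit
  for (j in seq_len(G - 1L) + 1L) M[, j] <- M[, j] + M[, j - 1L]
  M
}

# centred moving-average smoother that ignores missing cells
smooth_ma <- function(y, width) {
  if (width <= 1L) return(y)
  n <- length(y)
  half <- (width - 1L) %/% 2L
  out <- y
  for (i in seq_len(n)) {
    w <- y[max(1L, i - half):min(n, i + half)]
    out[i] <- if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }
  out
}

risk_curves_impl <- function(expo_grid, mace, strata, grid, smooth_width,
                             expected = NULL, marginal = NULL) {
  stopifnot(nrow(expo_grid) == length(mace))
  out <- rbindlist(lapply(strata, function(k) {
    memb <- expo_grid >= k
    n <- colSums(memb)
    obs <- colSums(memb * mace) / n
    if (!is.null(expected)) {
      exp_rate <- colSums(memb * expected) / n
      prob <- marginal * obs / exp_rate
    } else prob <- obs
    prob[n == 0L] <- NA_real_
    data.table(map = grid, stratum = sprintf(">=%g min", k),
               prob = smooth_ma(prob, smooth_width),
               prob_raw = prob, n_at_risk = as.integer(n))
  }))
  out[, prob := pmin(pmax(prob, 0), 1)]
  setattr(out, "class", c("ioh_risk_curves", class(out)))
  out[]
}

#' Univariate moving-average risk curves
#'
#' For each grid MAP value m and each cumulative-duration stratum s, the
#' observed MACE rate among patients whose time with MAP below m is at least
#' s minutes, smoothed along the grid with a centred moving average. Empty
#' cells are reported as missing, never as zero.
#'
#' @param expo_grid matrix from [cumulative_exposure_grid()].
#' @param mace logical/0-1 outcome vector aligned with the matrix rows.
#' @param strata cumulative-duration cut-offs in minutes
#'   (default `c(1, 3, 5, 10)`).
#' @param smooth_width moving-average width in grid points (default 5).
#' @return data.table (`map`, `stratum`, `prob`, `prob_raw`, `n_at_risk`)
#'   of class `ioh_risk_curves`.
#' @export
univariate_risk_curve <- function(expo_grid, mace, strata = c(1, 3, 5, 10),
                                  smooth_width = 5) {
  grid <- as.numeric(colnames(expo_grid))
  risk_curves_impl(expo_grid, as.numeric(mace), strata, grid, smooth_width)
}

#' Confounder-adjusted risk curves
#'
#' Adjusted analogues of [univariate_risk_curve()] by indirect
#' standardization: a logistic model of the outcome on the confounders alone
#' supplies each patient's expected risk, and every (grid, stratum) cell's
#' observed rate is scaled by the ratio of the marginal incidence to the
#' cell's mean expected risk. Curves that still separate after this
#' adjustment indicate exposure effects not explained by the confounders.
#'
#' @param expo_grid matrix from [cumulative_exposure_grid()].
#' @param data patient table containing the outcome and confounders, rows
#'   aligned with the matrix.
#' @param outcome name of the binary outcome column (default `"mace"`).
#' @param confounders character vector of confounder column names.
#' @inheritParams univariate_risk_curve
#' @return data.table of class `ioh_risk_curves`.
#' @export
adjusted_risk_curve_strata <- function(expo_grid, data, confounders,
                                       outcome = "mace",
                                       strata = c(1, 3, 5, 10),
                                       smooth_width = 5) {
  data <- as.data.frame(data)
  y <- as.numeric(data[[outcome]])
  f <- as.formula(paste(outcome, "~",
                        paste(sprintf("`%s`", confounders), collapse = " + ")))
  fit <- glm(f, data = data, family = binomial())
  if (!fit$converged)
    stop("confounder model failed to converge", call. = FALSE)
  grid <- as.numeric(colnames(expo_grid))
  risk_curves_impl(expo_grid, y, strata, grid, smooth_width,
                   expected = fitted(fit), marginal = mean(y))
}

#' Spline-adjusted risk curve
#'
#' Multivariable logistic regression of the outcome on a restricted cubic
#' spline (3 knots at the 10th/50th/90th percentiles) of the lowest MAP plus
#' confounders; returns the predicted MACE probability along the MAP grid
#' with continuous confounders held at their means and categorical ones at
#' their modes.
#'
#' @param data patient table with the outcome, the lowest-MAP column and
#'   confounders.
#' @param lowest name of the lowest-MAP column.
#' @param confounders character vector of confounder column names (may be
#'   empty).
#' @param outcome binary outcome column name.
#' @param grid MAP grid for prediction.
#' @param knots optional spline knots; default percentiles of the data.
#' @return data.table (`map`, `prob`, `stratum = "spline"`); the fitted
#'   model is attached as attribute `"fit"`.
#' @export
adjusted_risk_curve <- function(data, lowest = "lowest_1min",
                                confounders = character(), outcome = "mace",
                                grid = 40:100, knots = NULL) {
  data <- as.data.frame(data)
  x <- data[[lowest]]
  keep <- !is.na(x)
  data <- data[keep, , drop = FALSE]
  x <- x[keep]
  if (is.null(knots)) knots <- rcs_knots(x)
  B <- rcs_basis(x, knots)
  data$.rcs1 <- B[, 1]; data$.rcs2 <- B[, 2]
  rhs <- c(".rcs1", ".rcs2", sprintf("`%s`", confounders))
  f <- as.formula(paste(outcome, "~", paste(rhs, collapse = " + ")))
  fit <- glm(f, data = data, family = binomial())
  if (!fit$converged)
    stop("spline-adjusted model failed to converge (",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         ")", call. = FALSE)
  Bg <- rcs_basis(grid, knots)
  nd <- data.frame(.rcs1 = Bg[, 1], .rcs2 = Bg[, 2])
  for (v in confounders) {
    col <- data[[v]]
    nd[[v]] <- if (is.numeric(col)) mean(col, na.rm = TRUE) else {
      tab <- table(col)
      md <- names(tab)[which.max(tab)]
      if (is.factor(col)) factor(md, levels = levels(col))
      else if (is.logical(col)) as.logical(md) else md
    }
  }
  out <- data.table(map = as.numeric(grid),
                    prob = predict(fit, newdata = nd, type = "response"),
                    stratum = "spline")
  setattr(out, "fit", fit)
  out[]
}

#' Detect the convergence threshold of stratified risk curves
#'
#' Operationalizes the visual reading of stratified risk curves: below the
#' harm threshold the curves separate, above it they collapse onto each
#' other. The detector computes the maximum pairwise separation at each
#' grid value and locates the knee of that profile — the breakpoint of a
#' two-segment fit (a flat plateau of separation followed by a linear
#' decay), searched from the separation peak upward. The grid value just
#' above the fitted breakpoint is reported as the threshold. The knee is
#' scale-free, so detection does not depend on the absolute height of the
#' separation profile.
#'
#' The `converged` flag additionally requires that the curves really do
#' collapse: the median separation over the last `window` grid points must
#' lie within `tol`, and the fitted plateau separation must exceed `tol/2`
#' (otherwise the curves never separated in the first place).
#'
#' @param curves `ioh_risk_curves` table (>= 2 strata on a common grid).
#' @param tol separation tolerance on the probability scale used for the
#'   convergence check; default 0.25 x the mean across strata of the
#'   curve-average probability (a proxy for the marginal incidence).
#' @param window tail window in grid points for the convergence check
#'   (default 5).
#' @param min_frac grid points whose smallest stratum holds fewer than
#'   this fraction of the largest cell are masked before knee fitting
#'   (default 0.1); the max-min spread of small noisy cells is biased
#'   upward and would otherwise distort the profile's left edge.
#' @return list of class `ioh_threshold`: `threshold` (mm Hg or `NA`),
#'   `converged`, `tol`, `window`, `separation` (per-grid table), `reason`.
#' @export
detect_convergence <- function(curves, tol = NULL, window = 5,
                               min_frac = 0.1) {
  curves <- as.data.table(curves)
  grids <- curves[, .(g = list(map)), by = stratum]
  if (nrow(grids) < 2L)
    stop("need at least two strata curves", call. = FALSE)
  g1 <- grids$g[[1]]
  for (g in grids$g) if (!identical(g, g1))
    stop("curves are on mismatched grids", call. = FALSE)
  wide <- dcast(curves, map ~ stratum, value.var = "prob")
  P <- as.matrix(wide[, -1])
  sep <- apply(P, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) < 2L) NA_real_ else max(r) - min(r)
  })
  # cells with tiny at-risk denominators carry mostly sampling noise
  # (the max-min spread of noisy rates is biased upward); mask grid points
  # whose smallest stratum is under min_frac of the largest cell
  wt <- rep(1, length(sep))
  if ("n_at_risk" %in% names(curves)) {
    nw <- dcast(curves, map ~ stratum, value.var = "n_at_risk")
    n_min <- apply(as.matrix(nw[, -1]), 1, min, na.rm = TRUE)
    cut_n <- max(30, min_frac * max(n_min, na.rm = TRUE))
    sep[n_min < cut_n] <- NA_real_
    wt <- pmax(n_min, 1)
  }
  if (is.null(tol))
    tol <- 0.25 * mean(colMeans(P, na.rm = TRUE), na.rm = TRUE)
  grid <- wide$map
  res <- function(th, conv, reason) {
    structure(list(threshold = th, converged = conv, tol = tol,
                   window = window, reason = reason,
                   separation = data.table(map = grid, separation = sep)),
              class = "ioh_threshold")
  }
  ok <- which(!is.na(sep))
  if (length(ok) < window + 3L)
    return(res(NA_real_, FALSE, "too few grid points with both strata"))
  tail_idx <- utils::tail(ok, window)
  tail_sep <- median(sep[tail_idx])
  # knee search from the separation peak upward: fit a continuous
  # plateau / linear-decay / floor shape and take the end of the plateau
  peak <- ok[which.max(sep[ok])]
  idx <- ok[ok >= peak]
  if (length(idx) < 5L)
    return(res(NA_real_, FALSE,
               "separation persists into the top of the grid"))
  x <- grid[idx]; y <- sep[idx]; wts <- wt[idx]
  n <- length(idx)
  best <- NULL
  for (k1 in seq(1L, n - 2L)) {
    for (k2 in seq(k1 + 1L, n - 1L)) {
      w <- pmin(pmax((x - x[k1]) / (x[k2] - x[k1]), 0), 1)
      fit <- stats::lm.wfit(cbind(1 - w, w), y, wts)
      sse <- sum(wts * fit$residuals^2)
      if (is.null(best) || sse < best$sse - 1e-12)
        best <- list(sse = sse, k1 = k1,
                     plateau = fit$coefficients[1],
                     floor = fit$coefficients[2])
    }
  }
  th <- x[best$k1] + (grid[2] - grid[1])
  plateau <- unname(best$plateau)
  if (tail_sep > tol)
    return(res(NA_real_, FALSE,
               "separation persists into the top of the grid"))
  if (plateau <= tol / 2)
    return(res(NA_real_, FALSE, "curves never separate beyond tolerance"))
  res(th, TRUE, "converged")
}

#' @export
print.ioh_threshold <- function(x, ...) {
  if (x$converged)
    cat(sprintf("Convergence threshold: %.1f mm Hg (tol %.4f, window %d)\n",
                x$threshold, x$tol, x$window))
  else
    cat(sprintf("No convergence threshold (%s); tol %.4f\n", x$reason, x$tol))
  invisible(x)
}
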