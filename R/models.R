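# Logistic association models, age stratification, baseline comparisons.

#' Fit a logistic regression and tidy the result
#'
#' Maximum-likelihood logistic regression (via `stats::glm`) returning
#' odds ratios with 95% Wald confidence intervals. Quasi-complete
#' separation (runaway coefficients) raises an explicit error.
#'
#' @param formula model formula with a binary outcome.
#' @param data data frame.
#' @param sep_limit absolute log-odds beyond which a coefficient is treated
#'   as evidence of separation (default 15).
#' @return object of class `ioh_fit`: list with `terms` (data.table: `term`,
#'   `estimate`, `se`, `or`, `ci_low`, `ci_high`, `p`), `n`, `converged`,
#'   and the underlying `glm` as `fit`.
#' @export
fit_logistic <- function(formula, data, sep_limit = 15) {
  data <- as.data.frame(data)
  fit <- suppressWarnings(glm(formula, data = data, family = binomial()))
  cf <- coef(fit)
  if (anyNA(cf))
    stop("design matrix not full rank: ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  if (!fit$converged || any(abs(cf[-1]) > sep_limit))
    stop("logistic fit did not converge (possible separation); ",
         "largest |log-odds| = ", signif(max(abs(cf[-1])), 3), call. = FALSE)
  se <- sqrt(diag(vcov(fit)))
  z <- cf / se
  terms <- data.table(
    term = names(cf), estimate = unname(cf), se = unname(se),
    or = exp(unname(cf)),
    ci_low = exp(unname(cf - 1.96 * se)),
    ci_high = exp(unname(cf + 1.96 * se)),
    p = unname(2 * pnorm(-abs(z))))
  structure(list(terms = terms, n = nrow(fit$model),
                 converged = fit$converged, fit = fit),
            class = "ioh_fit")
}

#' @export
print.ioh_fit <- function(x, ...) {
  cat(sprintf("Logistic fit, n = %d\n", x$n))
  tt <- copy(x$terms)
  tt[, `:=`(or = round(or, 3), ci_low = round(ci_low, 3),
            ci_high = round(ci_high, 3), p = signif(p, 2))]
  print(tt[, .(term, or, ci_low, ci_high, p)])
  invisible(x)
}

# tidy one exposure term set out of an ioh_fit
extract_terms <- function(fit, prefix) {
  tt <- fit$terms[startsWith(term, prefix)]
  tt[, term := sub(paste0("^", prefix), "", term)]
  tt
}

#' Unadjusted and adjusted exposure-outcome models
#'
#' Fits, for each categorical exposure encoding (duration bins, area
#' quartiles, TWA quartiles), a univariate logistic model and a
#' confounder-adjusted one, with the unexposed category as reference.
#' Returns one tidy table across all models.
#'
#' @param data patient table containing the outcome, the exposure factors
#'   and the confounders.
#' @param exposures named character vector of exposure factor columns;
#'   default the three encodings produced by [categorize_exposure()].
#' @param confounders character vector of confounder column names.
#' @param outcome binary outcome column name.
#' @return data.table: `exposure`, `model` (`"unadjusted"`/`"adjusted"`),
#'   `term`, `or`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
run_exposure_models <- function(data,
                                exposures = c(duration = "duration_bin",
                                              auc = "auc_quartile",
                                              twa = "twa_quartile"),
                                confounders = character(),
                                outcome = "mace") {
  data <- as.data.frame(data)
  out <- list()
  for (nm in names(exposures)) {
    xcol <- exposures[[nm]]
    x <- droplevels(as.factor(data[[xcol]]))
    empty <- setdiff(levels(as.factor(data[[xcol]])), levels(x))
    if (length(empty))
      warning("exposure '", nm, "': empty levels collapsed: ",
              paste(empty, collapse = ", "), call. = FALSE)
    data[[xcol]] <- x
    f0 <- as.formula(paste(outcome, "~", sprintf("`%s`", xcol)))
    fit0 <- fit_logistic(f0, data)
    t0 <- extract_terms(fit0, paste0("`", xcol, "`"))
    if (nrow(t0) == 0L) t0 <- extract_terms(fit0, xcol)
    t0[, `:=`(exposure = nm, model = "unadjusted", n = fit0$n)]
    res <- t0
    if (length(confounders)) {
      f1 <- as.formula(paste(outcome, "~", sprintf("`%s`", xcol), "+",
                             paste(sprintf("`%s`", confounders),
                                   collapse = " + ")))
      fit1 <- fit_logistic(f1, data)
      t1 <- extract_terms(fit1, paste0("`", xcol, "`"))
      if (nrow(t1) == 0L) t1 <- extract_terms(fit1, xcol)
      t1[, `:=`(exposure = nm, model = "adjusted", n = fit1$n)]
      res <- rbind(t0, t1)
    }
    out[[nm]] <- res
  }
  out <- rbindlist(out)
  setcolorder(out, c("exposure", "model", "term"))
  out[]
}

#' Age-stratified duration-bin models
#'
#' Fits the duration-bin model separately below and at/above an age cut
#' (default 80 years), with the first exposed bin ("0.5-5") as reference:
#' unexposed patients are excluded from these fits, matching the stratified
#' presentation where every estimate is relative to the shortest exposed
#' duration.
#'
#' @param data patient table with `age`, the duration-bin factor, outcome
#'   and confounders.
#' @param age_cut stratification age in years (default 80).
#' @param duration_col duration-bin factor column (default `"duration_bin"`).
#' @param confounders confounder column names.
#' @param outcome binary outcome column name.
#' @return data.table: `stratum` (`"age<cut"` / `"age>=cut"`), `term`, `or`,
#'   `ci_low`, `ci_high`, `p`, `n`, `estimable`.
#' @export
stratified_models <- function(data, age_cut = 80,
                              duration_col = "duration_bin",
                              confounders = character(),
                              outcome = "mace") {
  data <- as.data.frame(data)
  exposed <- data[[duration_col]] != "none" & !is.na(data[[duration_col]])
  data <- data[exposed, , drop = FALSE]
  data[[duration_col]] <- droplevels(factor(data[[duration_col]]))
  strata <- list()
  lo <- data$age < age_cut
  if (any(lo)) strata[[sprintf("age<%g", age_cut)]] <- data[lo, ]
  if (any(!lo)) strata[[sprintf("age>=%g", age_cut)]] <- data[!lo, ]
  rhs <- sprintf("`%s`", duration_col)
  if (length(confounders))
    rhs <- paste(c(rhs, sprintf("`%s`", confounders)), collapse = " + ")
  f <- as.formula(paste(outcome, "~", rhs))
  out <- rbindlist(lapply(names(strata), function(s) {
    d <- strata[[s]]
    ft <- tryCatch(fit_logistic(f, d), error = function(e) e)
    if (inherits(ft, "error"))
      return(data.table(stratum = s, term = NA_character_,
                        estimate = NA_real_, se = NA_real_, or = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                        n = nrow(d), estimable = FALSE))
    tt <- extract_terms(ft, paste0("`", duration_col, "`"))
    if (nrow(tt) == 0L) tt <- extract_terms(ft, duration_col)
    tt[, `:=`(stratum = s, n = ft$n, estimable = TRUE)]
    tt
  }), fill = TRUE)
  setcolorder(out, c("stratum", "term"))
  out[]
}

#' Standardized mean difference
#'
#' For binary variables `|p1 - p2| / sqrt((p1(1-p1) + p2(1-p2)) / 2)`;
#' for continuous variables `|m1 - m2| / sqrt((s1^2 + s2^2) / 2)`.
#' Reported as an absolute value. Zero-variance comparisons return 0.
#'
#' @param x numeric or logical variable.
#' @param group logical or two-level grouping.
#' @param binary force binary treatment (default: auto for logical/0-1).
#' @return nonnegative SMD.
#' @export
smd <- function(x, group, binary = NULL) {
  group <- as.logical(group)
  ok <- !is.na(x) & !is.na(group)
  x <- x[ok]; group <- group[ok]
  if (is.null(binary))
    binary <- is.logical(x) || all(x %in% c(0, 1))
  x <- as.numeric(x)
  if (binary) {
    p1 <- mean(x[group]); p2 <- mean(x[!group])
    denom <- sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2)
    if (denom == 0) return(0)
    abs(p1 - p2) / denom
  } else {
    m1 <- mean(x[group]); m2 <- mean(x[!group])
    v1 <- var(x[group]); v2 <- var(x[!group])
    denom <- sqrt((v1 + v2) / 2)
    if (is.na(denom) || denom == 0) return(0)
    abs(m1 - m2) / denom
  }
}

#' Standardized mean difference from summary proportions
#'
#' @param p1,p2 group proportions.
#' @return SMD for a binary variable.
#' @export
smd_from_props <- function(p1, p2) {
  denom <- sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2)
  if (denom == 0) return(0)
  abs(p1 - p2) / denom
}

# chi-square statistic/p without continuity correction
chisq_nocc <- function(x, group) {
  tab <- table(x, group)
  if (any(dim(tab) < 2L)) return(list(stat = NA_real_, p = NA_real_))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(stat = stat, p = pchisq(stat, df, lower.tail = FALSE))
}

#' Baseline characteristics table with SMDs
#'
#' Compares every requested variable between outcome groups: categorical
#' variables get per-level counts/percentages, a chi-square test (no
#' continuity correction) and a binary SMD (multi-level variables use the
#' largest per-level SMD); continuous variables get mean (SD), median (IQR)
#' and the continuous SMD.
#'
#' @param data patient table.
#' @param vars character vector of variable names to compare.
#' @param group binary grouping column name (default `"mace"`).
#' @return data.table: `variable`, `level`, `type`, `summary_g0`,
#'   `summary_g1`, `stat`, `p`, `smd`.
#' @export
baseline_comparison <- function(data, vars, group = "mace") {
  data <- as.data.frame(data)
  g <- as.logical(data[[group]])
  rows <- list()
  fmt_np <- function(n, N) sprintf("%d (%.1f)", n, 100 * n / N)
  for (v in vars) {
    x <- data[[v]]
    if (is.numeric(x) && !all(x %in% c(0, 1), na.rm = TRUE)) {
      s <- function(keep) sprintf("%.1f (%.1f) | %.1f (%.1f-%.1f)",
        mean(x[keep], na.rm = TRUE), sd(x[keep], na.rm = TRUE),
        median(x[keep], na.rm = TRUE),
        quantile(x[keep], 0.25, na.rm = TRUE),
        quantile(x[keep], 0.75, na.rm = TRUE))
      rows[[length(rows) + 1L]] <- data.table(
        variable = v, level = NA_character_, type = "continuous",
        summary_g0 = s(!g), summary_g1 = s(g),
        stat = NA_real_, p = NA_real_, smd = smd(x, g, binary = FALSE))
    } else {
      xf <- if (is.logical(x) || all(x %in% c(0, 1), na.rm = TRUE))
        factor(as.numeric(x), levels = c(0, 1), labels = c("no", "yes"))
      else as.factor(x)
      cs <- chisq_nocc(xf, g)
      lv_smd <- vapply(levels(xf),
                       function(l) smd(xf == l, g, binary = TRUE), numeric(1))
      overall <- max(lv_smd, na.rm = TRUE)
      binary <- nlevels(xf) == 2L && all(levels(xf) == c("no", "yes"))
      lvls <- if (binary) "yes" else levels(xf)
      for (l in lvls) {
        rows[[length(rows) + 1L]] <- data.table(
          variable = v, level = l, type = "categorical",
          summary_g0 = fmt_np(sum(xf[!g] == l, na.rm = TRUE), sum(!g)),
          summary_g1 = fmt_np(sum(xf[g] == l, na.rm = TRUE), sum(g)),
          stat = cs$stat, p = cs$p, smd = overall)
      }
    }
  }
  rbindlist(rows)
}

#' Cohort MACE incidence summary
#'
#' Overall and per-subtype incidence percentages.
#'
#' @param n_patients cohort size.
#' @param n_mace number of patients with the composite outcome.
#' @param subtype_counts optional named integer vector of subtype counts
#'   (subtypes can overlap, so they need not sum to `n_mace`).
#' @param digits decimals for the overall percentage (default 2).
#' @return list with `n`, `n_mace`, `incidence_pct`, and `subtypes`
#'   (data.table `subtype`, `n`, `pct`).
#' @export
incidence_summary <- function(n_patients, n_mace, subtype_counts = NULL,
                              digits = 2) {
  out <- list(n = n_patients, n_mace = n_mace,
              incidence_pct = round(100 * n_mace / n_patients, digits))
  if (!is.null(subtype_counts))
    out$subtypes <- data.table(
      subtype = names(subtype_counts), n = as.integer(subtype_counts),
      pct = round(100 * subtype_counts / n_patients, digits))
  out
}

#' Cohort summary from a patient table
#'
#' @param patients patient table with `mace` and logical `mace_<subtype>`
#'   columns.
#' @param digits decimals for percentages.
#' @return see [incidence_summary()].
#' @export
cohort_summary <- function(patients, digits = 2) {
  patients <- as.data.frame(patients)
  sub_cols <- grep("^mace_", names(patients), value = TRUE)
  counts <- if (length(sub_cols))
    vapply(patients[sub_cols],
           function(z) as.integer(sum(z, na.rm = TRUE)), integer(1))
  else NULL
  if (!is.null(counts)) names(counts) <- sub("^mace_", "", sub_cols)
  incidence_summary(nrow(patients), sum(patients$mace, na.rm = TRUE),
                    counts, digits)
}
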