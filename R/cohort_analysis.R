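# Cohort-level analysis: per-eye derived quantities (inter-modality deltas,
# axis-class and irregularity-group labels, ORA), summary tables comparing
# subgroups, and the log-linear regressions.

#' Per-eye discrepancy between ray-traced and automated keratometry
#'
#' `delta_tcrpX_ak` is the power-vector difference magnitude between the
#' TCRP (3 mm or 4 mm zone) astigmatism and the automated-keratometry (AK)
#' astigmatism.
#'
#' @param cohort Cohort data frame in the [cohort_columns()] schema.
#' @param as_cylinder Double the difference to cylinder scale; default
#'   `FALSE`.
#' @return Data frame with `eye_id`, `delta_tcrp3_ak`, `delta_tcrp4_ak`.
#' @export
compute_deltas <- function(cohort, as_cylinder = FALSE) {
  needed <- c("ak_cyl_d", "ak_axis_deg", "tcrp3_cyl_d", "tcrp3_axis_deg",
              "tcrp4_cyl_d", "tcrp4_axis_deg")
  check_fields(cohort, needed)
  ak <- cyl_to_pv(cyl_astig(cohort$ak_cyl_d, cohort$ak_axis_deg))
  t3 <- cyl_to_pv(cyl_astig(cohort$tcrp3_cyl_d, cohort$tcrp3_axis_deg))
  t4 <- cyl_to_pv(cyl_astig(cohort$tcrp4_cyl_d, cohort$tcrp4_axis_deg))
  scale <- if (as_cylinder) 2 else 1
  data.frame(eye_id = cohort$eye_id,
             delta_tcrp3_ak = scale * pv_difference_magnitude(t3, ak),
             delta_tcrp4_ak = scale * pv_difference_magnitude(t4, ak),
             stringsAsFactors = FALSE)
}

#' Split eyes into low/high corneal-irregularity groups
#'
#' Grouping method 1 thresholds at the cohort median of the irregularity
#' index IR; method 2 at mean + 2 SD. A fixed threshold (e.g. 0.036 or
#' 0.077 mm, the values of a published 207-eye cohort) can be supplied
#' instead. An eye is `"high"` when its IR is greater than or equal to the
#' threshold.
#'
#' @param ir Numeric vector of irregularity indices (mm), one per eye.
#' @param method `1` (median) or `2` (mean + 2 SD); ignored when
#'   `threshold` is given.
#' @param threshold Optional fixed threshold in mm.
#' @return Character vector of `"low"` / `"high"` labels with the threshold
#'   used attached as attribute `"threshold"`.
#' @export
group_by_ir <- function(ir, method = 1, threshold = NULL) {
  if (length(ir) == 0) {
    stop("empty cohort: no IR values to group", call. = FALSE)
  }
  if (anyNA(ir) || any(!is.finite(ir))) {
    stop("IR values must be finite", call. = FALSE)
  }
  thr <- if (!is.null(threshold)) {
    as.numeric(threshold)
  } else if (method == 1) {
    stats::median(ir)
  } else if (method == 2) {
    mean(ir) + 2 * stats::sd(ir)
  } else {
    stop("`method` must be 1 or 2", call. = FALSE)
  }
  structure(ifelse(ir >= thr, "high", "low"), threshold = thr)
}

ols_fit <- function(resp, predictors, min_n) {
  stopifnot(is.data.frame(predictors))
  if (nrow(predictors) != length(resp)) {
    stop("response and predictors have different lengths", call. = FALSE)
  }
  if (length(resp) < min_n) {
    stop("need more observations than predictors", call. = FALSE)
  }
  d <- data.frame(.y = resp, predictors, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = d)
  if (anyNA(stats::coef(fit))) {
    stop("singular design: predictors are collinear", call. = FALSE)
  }
  s <- summary(fit)
  tss <- sum((resp - mean(resp))^2)
  r2 <- if (tss < 1e-20) 0 else s$r.squared
  structure(list(coefficients = stats::coef(fit),
                 standard_errors = s$coefficients[, "Std. Error"],
                 r_squared = r2,
                 n = length(resp),
                 model = fit),
            class = "regression_result")
}

#' Log-linear least-squares fit
#'
#' Ordinary least squares of `ln(y)` on an intercept plus the given
#' predictors (kept on their raw scale). Coefficients and standard errors
#' are therefore on the log scale of the response.
#'
#' @param y Positive response values.
#' @param predictors Data frame of predictor columns.
#' @return A `"regression_result"`: `coefficients`, `standard_errors`,
#'   `r_squared`, `n`, and the underlying `model`.
#' @export
fit_log_linear <- function(y, predictors) {
  if (anyNA(y) || any(!is.finite(y))) {
    stop("`y` must be finite", call. = FALSE)
  }
  if (any(y <= 0)) {
    stop("`y` must be strictly positive for the log transformation",
         call. = FALSE)
  }
  ols_fit(log(y), predictors, min_n = ncol(predictors) + 2)
}

#' Raw-scale least-squares fit
#'
#' Companion to [fit_log_linear()]: the same OLS without the log transform,
#' so both readings of a "logarithmic transformation" analysis can be
#' reported side by side.
#'
#' @inheritParams fit_log_linear
#' @return A `"regression_result"`.
#' @export
fit_linear <- function(y, predictors) {
  if (anyNA(y) || any(!is.finite(y))) {
    stop("`y` must be finite", call. = FALSE)
  }
  ols_fit(y, predictors, min_n = ncol(predictors) + 2)
}

#' Correlation with a two-sided p-value
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `rho`, `p_value`, `method`, `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  if (length(x) < 3) {
    stop("need at least 3 paired observations", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       method = method, n = length(x))
}

#' Two-sided comparison of two samples
#'
#' `"t"` is the equal-variance Student t test, `"mann_whitney"` the Wilcoxon
#' rank-sum test (normal approximation), `"paired_t"` the paired t test on
#' within-pair differences. A degenerate paired test with all differences
#' zero reports statistic 0 and p = 1 with a warning.
#'
#' @param values_a,values_b Numeric samples; equal lengths required for the
#'   paired test.
#' @param test One of `"t"`, `"mann_whitney"`, `"paired_t"`.
#' @return List with `statistic`, `p_value`, `test`, `n`, and `degenerate`
#'   (`TRUE` for the all-zero-difference paired case).
#' @export
compare_groups <- function(values_a, values_b,
                           test = c("t", "mann_whitney", "paired_t")) {
  test <- match.arg(test)
  degenerate <- FALSE
  if (test == "paired_t") {
    if (length(values_a) != length(values_b)) {
      stop("paired test requires equal-length samples", call. = FALSE)
    }
    d <- values_a - values_b
    if (stats::sd(d) == 0) {
      degenerate <- TRUE
      if (all(d == 0)) {
        warning("all paired differences are zero; reporting p = 1")
        statistic <- 0
        p <- 1
      } else {
        warning("constant nonzero paired differences; reporting p = 0")
        statistic <- sign(mean(d)) * Inf
        p <- 0
      }
    } else {
      ht <- stats::t.test(values_a, values_b, paired = TRUE)
      statistic <- unname(ht$statistic)
      p <- ht$p.value
    }
  } else if (test == "t") {
    ht <- stats::t.test(values_a, values_b, var.equal = TRUE)
    statistic <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    ht <- stats::wilcox.test(values_a, values_b, exact = FALSE)
    statistic <- unname(ht$statistic)
    p <- ht$p.value
  }
  list(statistic = statistic, p_value = p, test = test,
       n = c(length(values_a), length(values_b)), degenerate = degenerate)
}

# mean/sd/test summary of `vars` between the two levels of `labels`
# (NA labels dropped). Returns one row per variable.
group_summary_table <- function(data, vars, labels, level_a, level_b) {
  rows <- lapply(vars, function(v) {
    x <- data[[v]]
    a <- x[!is.na(labels) & labels == level_a & !is.na(x)]
    b <- x[!is.na(labels) & labels == level_b & !is.na(x)]
    p_t <- p_mw <- NA_real_
    if (length(a) >= 2 && length(b) >= 2 &&
        (stats::sd(a) > 0 || stats::sd(b) > 0)) {
      p_t <- tryCatch(compare_groups(a, b, "t")$p_value,
                      error = function(e) NA_real_)
      p_mw <- tryCatch(compare_groups(a, b, "mann_whitney")$p_value,
                       error = function(e) NA_real_)
    }
    data.frame(variable = v,
               n_a = length(a), mean_a = mean(a), sd_a = stats::sd(a),
               n_b = length(b), mean_b = mean(b), sd_b = stats::sd(b),
               p_t = p_t, p_mann_whitney = p_mw,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

safe_fit <- function(expr) {
  tryCatch(expr, error = function(e) {
    structure(list(error = conditionMessage(e)), class = "regression_skipped")
  })
}

#' Full cohort analysis
#'
#' Computes every per-eye derived quantity (deltas, WTR/ATR label, both
#' irregularity groupings, the ORA set) and the cohort summaries: a WTR vs
#' ATR comparison, low vs high irregularity comparisons under both grouping
#' methods, ORA by irregularity group, paired ORA comparisons (AK vs TCRP)
#' within the high-irregularity subgroup, and the log-linear regressions of
#' IR on age + irregular astigmatism and of each delta on age + IR + AK
#' magnitude (each also fitted on the raw scale).
#'
#' Eyes with zero AK cylinder have no astigmatic axis; they are excluded
#' from the WTR/ATR classification (label `NA`, count reported via
#' `message()` and in the result) but retained everywhere else.
#'
#' @param cohort Cohort data frame in the [cohort_columns()] schema.
#' @param sia_magnitudes,vertex_distance,incision_axis,sia_sign,as_cylinder
#'   Passed to [compute_ora_set()].
#' @param ir_grouping `"cohort"` (default) recomputes the thresholds from
#'   this cohort; `"fixed"` uses `ir_fixed_thresholds`.
#' @param ir_fixed_thresholds Length-2 numeric: the method-1 and method-2
#'   thresholds in mm used when `ir_grouping = "fixed"`.
#' @return A list of class `"cohort_report"`: `per_eye`, the four summary
#'   tables (`table1_wtr_atr`, `table3_ir_groups`, `table4_ora`,
#'   `table5_paired_ora`), `regressions`, `thresholds`,
#'   `excluded_zero_cyl`, and the configuration used.
#' @export
analyze_cohort <- function(cohort,
                           sia_magnitudes = c(0, 0.20, 0.40),
                           vertex_distance = 0.012,
                           incision_axis = 0,
                           sia_sign = 1,
                           as_cylinder = FALSE,
                           ir_grouping = c("cohort", "fixed"),
                           ir_fixed_thresholds = c(0.036, 0.077)) {
  ir_grouping <- match.arg(ir_grouping)
  problems <- validate_cohort(cohort)
  if (length(problems)) {
    stop("invalid cohort:\n", paste(problems, collapse = "\n"), call. = FALSE)
  }
  n <- nrow(cohort)
  if (n == 0) stop("empty cohort", call. = FALSE)

  deltas <- compute_deltas(cohort, as_cylinder = as_cylinder)

  zero_cyl <- cohort$ak_cyl_d == 0
  axis_class <- rep(NA_character_, n)
  if (any(!zero_cyl)) {
    axis_class[!zero_cyl] <- classify_wtr_atr(
      cyl_astig(cohort$ak_cyl_d[!zero_cyl], cohort$ak_axis_deg[!zero_cyl]))
  }
  if (any(zero_cyl)) {
    message(sum(zero_cyl),
            " eye(s) with zero AK cylinder excluded from WTR/ATR tables")
  }

  g1 <- group_by_ir(cohort$ir_mm, method = 1,
                    threshold = if (ir_grouping == "fixed") ir_fixed_thresholds[1])
  g2 <- group_by_ir(cohort$ir_mm, method = 2,
                    threshold = if (ir_grouping == "fixed") ir_fixed_thresholds[2])

  ora <- compute_ora_set(cohort, sia_magnitudes = sia_magnitudes,
                         vertex_distance = vertex_distance,
                         incision_axis = incision_axis,
                         sia_sign = sia_sign, as_cylinder = as_cylinder)

  sc <- sphero_cylinder(cohort$ra_sphere_d, cohort$ra_cyl_d,
                        cohort$ra_axis_deg, cohort$ra_notation)
  ra_corneal <- refraction_to_corneal_plane(sc, vertex_distance)
  ak_pv <- cyl_to_pv(cyl_astig(cohort$ak_cyl_d, cohort$ak_axis_deg))

  per_eye <- cbind(cohort,
                   deltas[, c("delta_tcrp3_ak", "delta_tcrp4_ak")],
                   data.frame(ak_j0 = ak_pv$j0, ak_j45 = ak_pv$j45,
                              ra_cyl_corneal_d = abs(ra_corneal$cylinder),
                              ap_ratio = cohort$ant_radius_mm /
                                cohort$post_radius_mm,
                              axis_class = axis_class,
                              ir_group1 = as.character(g1),
                              ir_group2 = as.character(g2),
                              stringsAsFactors = FALSE),
                   ora[, -1, drop = FALSE])

  vars1 <- c("age_years", "ak_cyl_d", "tcrp3_cyl_d", "tcrp4_cyl_d",
             "ak_j0", "ak_j45", "ra_cyl_corneal_d", "ir_mm", "sa_um",
             "delta_tcrp3_ak", "delta_tcrp4_ak")
  table1 <- group_summary_table(per_eye, vars1, per_eye$axis_class,
                                "WTR", "ATR")
  names(table1) <- sub("_a$", "_wtr", sub("_b$", "_atr", names(table1)))

  vars3 <- c("age_years", "irregular_astig_um", "ak_cyl_d", "tcrp3_cyl_d",
             "tcrp4_cyl_d", "ra_cyl_corneal_d", "ap_ratio",
             "delta_tcrp3_ak", "delta_tcrp4_ak")
  table3 <- do.call(rbind, lapply(1:2, function(m) {
    lab <- if (m == 1) per_eye$ir_group1 else per_eye$ir_group2
    thr <- attr(if (m == 1) g1 else g2, "threshold")
    tab <- group_summary_table(per_eye, vars3, lab, "low", "high")
    names(tab) <- sub("_a$", "_low", sub("_b$", "_high", names(tab)))
    cbind(grouping_method = m, threshold_mm = thr, tab)
  }))

  ora_cols <- setdiff(names(ora), "eye_id")
  table4 <- do.call(rbind, lapply(1:2, function(m) {
    lab <- if (m == 1) per_eye$ir_group1 else per_eye$ir_group2
    tab <- group_summary_table(per_eye, ora_cols, lab, "low", "high")
    names(tab) <- sub("_a$", "_low", sub("_b$", "_high", names(tab)))
    cbind(grouping_method = m, tab)
  }))

  variants <- ora_variant_names(length(sia_magnitudes))
  high2 <- per_eye$ir_group2 == "high"
  table5 <- do.call(rbind, lapply(c("tcrp3", "tcrp4"), function(src) {
    do.call(rbind, lapply(variants, function(v) {
      a <- per_eye[[paste0("ora_ak_", v)]][high2]
      b <- per_eye[[paste0("ora_", src, "_", v)]][high2]
      row <- data.frame(keratometry = src, variant = v, n = sum(high2),
                        mean_ora_ak = mean(a), mean_ora_tcrp = mean(b),
                        mean_diff = mean(a - b),
                        t_statistic = NA_real_, p_paired_t = NA_real_,
                        pearson_rho = NA_real_, pearson_p = NA_real_,
                        stringsAsFactors = FALSE)
      if (sum(high2) >= 3) {
        pt <- tryCatch(
          suppressWarnings(compare_groups(a, b, "paired_t")),
          error = function(e) NULL)
        if (!is.null(pt)) {
          row$t_statistic <- pt$statistic
          row$p_paired_t <- pt$p_value
        }
        pc <- tryCatch(correlate(a, b, "pearson"), error = function(e) NULL)
        if (!is.null(pc)) {
          row$pearson_rho <- pc$rho
          row$pearson_p <- pc$p_value
        }
      }
      row
    }))
  }))

  pos3 <- deltas$delta_tcrp3_ak > 0
  pos4 <- deltas$delta_tcrp4_ak > 0
  regressions <- list(
    ir_log = safe_fit(fit_log_linear(
      cohort$ir_mm,
      data.frame(age = cohort$age_years,
                 irregular_astig = cohort$irregular_astig_um))),
    ir_raw = safe_fit(fit_linear(
      cohort$ir_mm,
      data.frame(age = cohort$age_years,
                 irregular_astig = cohort$irregular_astig_um))),
    delta_tcrp3_log = safe_fit(fit_log_linear(
      deltas$delta_tcrp3_ak[pos3],
      data.frame(age = cohort$age_years, ir = cohort$ir_mm,
                 ak = cohort$ak_cyl_d)[pos3, ])),
    delta_tcrp3_raw = safe_fit(fit_linear(
      deltas$delta_tcrp3_ak,
      data.frame(age = cohort$age_years, ir = cohort$ir_mm,
                 ak = cohort$ak_cyl_d))),
    delta_tcrp4_log = safe_fit(fit_log_linear(
      deltas$delta_tcrp4_ak[pos4],
      data.frame(age = cohort$age_years, ir = cohort$ir_mm,
                 ak = cohort$ak_cyl_d)[pos4, ])),
    delta_tcrp4_raw = safe_fit(fit_linear(
      deltas$delta_tcrp4_ak,
      data.frame(age = cohort$age_years, ir = cohort$ir_mm,
                 ak = cohort$ak_cyl_d)))
  )

  structure(list(
    per_eye = per_eye,
    table1_wtr_atr = table1,
    table3_ir_groups = table3,
    table4_ora = table4,
    table5_paired_ora = table5,
    regressions = regressions,
    thresholds = c(method1 = attr(g1, "threshold"),
                   method2 = attr(g2, "threshold")),
    excluded_zero_cyl = sum(zero_cyl),
    config = list(sia_magnitudes = sia_magnitudes,
                  vertex_distance = vertex_distance,
                  incision_axis = incision_axis, sia_sign = sia_sign,
                  as_cylinder = as_cylinder, ir_grouping = ir_grouping)
  ), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort analysis report:", nrow(x$per_eye), "eyes\n")
  cat("  WTR:", sum(x$per_eye$axis_class == "WTR", na.rm = TRUE),
      " ATR:", sum(x$per_eye$axis_class == "ATR", na.rm = TRUE),
      " excluded (zero cylinder):", x$excluded_zero_cyl, "\n")
  cat(sprintf("  IR thresholds: median %.4f mm, mean+2SD %.4f mm\n",
              x$thresholds[["method1"]], x$thresholds[["method2"]]))
  cat(sprintf("  mean delta TCRP3-AK %.3f D, TCRP4-AK %.3f D\n",
              mean(x$per_eye$delta_tcrp3_ak),
              mean(x$per_eye$delta_tcrp4_ak)))
  invisible(x)
}

regression_json <- function(r) {
  if (inherits(r, "regression_skipped")) {
    return(list(skipped = r$error))
  }
  list(coefficients = as.list(r$coefficients),
       standard_errors = as.list(r$standard_errors),
       r_squared = r$r_squared, n = r$n)
}

#' Write a cohort report to a directory of CSV tables
#'
#' Writes `per_eye.csv`, `table1_wtr_atr.csv`, `table3_ir_groups.csv`,
#' `table4_ora.csv`, `table5_paired_ora.csv` and a `summary.json` holding
#' counts, thresholds, the configuration and the regression fits.
#'
#' @param report A `"cohort_report"` from [analyze_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("per_eye", "table1_wtr_atr", "table3_ir_groups",
              "table4_ora", "table5_paired_ora")
  for (tb in tables) {
    utils::write.csv(report[[tb]], file.path(dir, paste0(tb, ".csv")),
                     row.names = FALSE)
  }
  summary <- list(
    n = nrow(report$per_eye),
    excluded_zero_cyl = report$excluded_zero_cyl,
    ir_thresholds_mm = as.list(report$thresholds),
    config = report$config,
    regressions = lapply(report$regressions, regression_json)
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
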