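test_that("per-eye deltas match hand evaluations", {
  ch <- toy_cohort(3,
                   ak_cyl = c(1, 1, 1), ak_axis = c(0, 0, 0),
                   tcrp3_cyl = c(1, 1, 1), tcrp3_axis = c(0, 90, 0),
                   tcrp4_cyl = c(1, 0, 1), tcrp4_axis = c(0, 0, 0))
  d <- compute_deltas(ch)
  expect_equal(d$delta_tcrp3_ak, c(0, 1.0, 0))   # opposite double-angle vecs
  expect_equal(d$delta_tcrp4_ak, c(0, 0.5, 0))   # half-magnitude difference
  d2 <- compute_deltas(ch, as_cylinder = TRUE)
  expect_equal(d2$delta_tcrp3_ak, 2 * d$delta_tcrp3_ak)
  ch$ak_cyl_d[1] <- NA
  expect_error(compute_deltas(ch), "ak_cyl_d")
})

test_that("delta grows monotonically with TCRP3 axis rotation from AK", {
  rots <- seq(0, 90, by = 15)
  means <- vapply(rots, function(r) {
    ch <- toy_cohort(5, ak_cyl = rep(1, 5), ak_axis = rep(10, 5),
                     tcrp3_cyl = rep(1, 5),
                     tcrp3_axis = rep(normalize_axis(10 + r), 5))
    mean(compute_deltas(ch)$delta_tcrp3_ak)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("IR grouping honours fixed and cohort-derived thresholds", {
  # fixed thresholds with boundary membership in the high group
  g2 <- group_by_ir(c(0.077, 0.0769), threshold = 0.077)
  expect_equal(as.character(g2), c("high", "low"))
  g1 <- group_by_ir(c(0.035, 0.036), threshold = 0.036)
  expect_equal(as.character(g1), c("low", "high"))
  # cohort-derived: median and mean + 2 SD
  ir <- c(0.02, 0.03, 0.04, 0.05, 0.30)
  m1 <- group_by_ir(ir, method = 1)
  expect_equal(attr(m1, "threshold"), stats::median(ir))
  m2 <- group_by_ir(ir, method = 2)
  expect_equal(attr(m2, "threshold"), mean(ir) + 2 * stats::sd(ir))
  # identical IRs under method 1: everything >= the median
  same <- group_by_ir(rep(0.04, 4), method = 1)
  expect_equal(as.character(same), rep("high", 4))
  expect_error(group_by_ir(numeric(0)), "empty")
})

test_that("log-linear fit recovers exact and degenerate cases", {
  # noise-free log-linear data: exact interpolation
  x <- c(1, 1, 2, 2, 3, 3)
  y <- exp(0.7 - 0.4 * x)
  fit <- suppressWarnings(fit_log_linear(y, data.frame(x = x)))
  expect_equal(unname(fit$coefficients), c(0.7, -0.4), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_setequal(names(fit$coefficients), names(fit$standard_errors))
  # constant response: zero slope, zero R squared
  cfit <- suppressWarnings(fit_log_linear(rep(2.5, 6), data.frame(x = x)))
  expect_equal(unname(cfit$coefficients[["x"]]), 0, tolerance = 1e-12)
  expect_equal(cfit$r_squared, 0)
  expect_error(fit_log_linear(c(1, -1, 2, 3), data.frame(x = 1:4)),
               "positive")
  expect_error(fit_log_linear(exp(1:6),
                              data.frame(x = 1:6, x2 = 2 * (1:6))),
               "singular")
})

test_that("log-linear fit equals brute-force normal equations", {
  set.seed(77)
  n <- 40
  pred <- data.frame(a = stats::rnorm(n), b = stats::runif(n))
  y <- exp(0.3 + 0.5 * pred$a - 1.2 * pred$b + stats::rnorm(n, 0, 0.2))
  fit <- fit_log_linear(y, pred)
  X <- cbind(1, pred$a, pred$b)
  beta <- solve(t(X) %*% X, t(X) %*% log(y))
  expect_equal(unname(fit$coefficients), as.vector(beta), tolerance = 1e-8)
})

test_that("correlation wrapper covers both methods and degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate(x, x)$rho, 1)
  expect_equal(correlate(x, -x)$rho, -1)
  expect_equal(correlate(x, rev(x), method = "spearman")$rho, -1)
  expect_error(correlate(x, rep(1, 5)), "zero variance")
  expect_error(correlate(x, 1:4), "equal length")
  # independence null: small |rho| at n = 1000
  set.seed(55)
  r <- correlate(stats::rnorm(1000), stats::rnorm(1000))
  expect_lt(abs(r$rho), 0.1)
})

test_that("group comparisons match a hand-computed t statistic", {
  a <- c(1.1, 2.3, 3.1, 4.2, 5.0)
  b <- c(2.0, 2.9, 3.8, 4.9, 6.1)
  res <- compare_groups(a, b, test = "t")
  # pooled-variance Student t computed from first principles
  sp2 <- (4 * stats::var(a) + 4 * stats::var(b)) / 8
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  expect_equal(res$statistic, t_hand, tolerance = 1e-10)
  expect_equal(res$p_value, 2 * stats::pt(-abs(t_hand), df = 8),
               tolerance = 1e-10)
})

test_that("shifted distributions are detected and degenerate pairs guarded", {
  set.seed(66)
  a <- stats::rnorm(100, 0, 1)
  b <- stats::rnorm(100, 1, 1)   # shift of 1 SD
  expect_lt(compare_groups(a, b, "t")$p_value, 0.05)
  expect_lt(compare_groups(a, b, "mann_whitney")$p_value, 0.05)
  same <- c(1, 2, 3)
  expect_warning(compare_groups(same, same, "paired_t"), "zero")
  res <- suppressWarnings(compare_groups(same, same, "paired_t"))
  expect_equal(res$p_value, 1)
  expect_equal(res$statistic, 0)
  expect_true(res$degenerate)
  expect_error(compare_groups(1:4, 1:3, "paired_t"), "equal-length")
})

test_that("analyze_cohort produces a complete, row-conserving report", {
  ch <- generate_cohort(sim_params(n = 120, seed = 13))
  rep <- analyze_cohort(ch)
  expect_s3_class(rep, "cohort_report")
  expect_equal(nrow(rep$per_eye), 120)
  for (tb in c("table1_wtr_atr", "table3_ir_groups", "table4_ora",
               "table5_paired_ora")) {
    expect_s3_class(rep[[tb]], "data.frame")
    expect_gt(nrow(rep[[tb]]), 0)
  }
  # labels partition the cohort
  expect_true(all(rep$per_eye$ir_group1 %in% c("low", "high")))
  expect_true(all(rep$per_eye$ir_group2 %in% c("low", "high")))
  n_wtr <- sum(rep$per_eye$axis_class == "WTR", na.rm = TRUE)
  n_atr <- sum(rep$per_eye$axis_class == "ATR", na.rm = TRUE)
  expect_equal(n_wtr + n_atr + rep$excluded_zero_cyl, 120)
  # deterministic given cohort and config
  rep2 <- analyze_cohort(ch)
  expect_equal(rep$table4_ora, rep2$table4_ora)
  expect_equal(rep$regressions$delta_tcrp3_log$coefficients,
               rep2$regressions$delta_tcrp3_log$coefficients)
})

test_that("identical keratometry collapses deltas and paired ORA contrasts", {
  corneal <- sphero_cylinder(0, 1, 30, "pos")
  spec <- transpose_cyl(refraction_to_spectacle_plane(corneal))
  n <- 10
  ch <- toy_cohort(n, ak_cyl = rep(1, n), ak_axis = rep(30, n),
                   ir = seq(0.01, 0.40, length.out = n),
                   ra_sphere = rep(spec$sphere, n),
                   ra_cyl = rep(spec$cylinder, n),
                   ra_axis = rep(spec$axis, n))
  rep <- suppressWarnings(analyze_cohort(ch, ir_grouping = "fixed"))
  expect_equal(rep$per_eye$delta_tcrp3_ak, rep(0, n))
  expect_equal(rep$per_eye$delta_tcrp4_ak, rep(0, n))
  expect_equal(rep$table5_paired_ora$mean_diff,
               rep(0, nrow(rep$table5_paired_ora)))
  expect_equal(rep$table5_paired_ora$p_paired_t,
               rep(1, nrow(rep$table5_paired_ora)))
})

test_that("zero-cylinder eyes are excluded from axis tables with a count", {
  ch <- generate_cohort(sim_params(n = 30, seed = 17))
  ch$ak_cyl_d[1:3] <- 0
  ch$ak_axis_deg[1:3] <- 0
  expect_message(rep <- analyze_cohort(ch), "zero AK cylinder")
  expect_equal(rep$excluded_zero_cyl, 3)
  expect_equal(sum(is.na(rep$per_eye$axis_class)), 3)
})

test_that("report writes its CSV tables and JSON summary", {
  ch <- generate_cohort(sim_params(n = 60, seed = 19))
  rep <- analyze_cohort(ch)
  dir <- tempfile("report")
  write_report(rep, dir)
  for (f in c("per_eye.csv", "table1_wtr_atr.csv", "table3_ir_groups.csv",
              "table4_ora.csv", "table5_paired_ora.csv", "summary.json")) {
    expect_true(file.exists(file.path(dir, f)))
  }
  s <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(s$n, 60)
  expect_true(is.numeric(s$regressions$delta_tcrp3_log$r_squared))
  unlink(dir, recursive = TRUE)
})
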