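test_that("the Wilcoxon comparison matches exhaustive enumeration", {
  # smallest attainable two-sided p at n = (3, 3): complete separation
  expect_equal(wilcoxon_compare(c(1, 2, 3), c(10, 11, 12)), 0.1)
  # identical samples are not distinguishable
  expect_gt(wilcoxon_compare(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0.5)
  # null calibration: p approximately uniform under no shift
  set.seed(8)
  ps <- replicate(60, wilcoxon_compare(stats::rnorm(200), stats::rnorm(200)))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("residual diagnostics behave per their null contracts", {
  # Ljung-Box on iid noise rarely rejects
  lb <- vapply(1:50, function(s) {
    set.seed(s)
    ex <- signal_extraction("x", 1:500, rep(0, 500), stats::rnorm(500))
    residual_diagnostics(ex)$ljungbox_p
  }, numeric(1))
  expect_gte(mean(lb > 0.05), 0.9)

  # ADF on a random walk rarely rejects the unit root
  adf <- vapply(1:50, function(s) {
    set.seed(s + 100)
    ex <- signal_extraction("x", 1:300, rep(0, 300),
                            cumsum(stats::rnorm(300)))
    residual_diagnostics(ex)$adf_p
  }, numeric(1))
  expect_gte(mean(adf > 0.05), 0.9)

  short <- signal_extraction("x", 1:10, rep(0, 10), stats::rnorm(10))
  expect_error(residual_diagnostics(short), "at least 20")
})

test_that("signal-noise correlations capture the textbook cases", {
  # least-squares fit leaves Pearson-orthogonal residuals
  set.seed(12)
  x <- 1:50
  y <- 2 + 0.5 * x + stats::rnorm(50)
  fit <- stats::lm(y ~ x)
  ex <- signal_extraction("lm", x, stats::fitted(fit),
                          stats::residuals(fit))
  tab <- signal_noise_correlations(ex, methods = "pearson")
  expect_lt(abs(tab$correlation), 1e-10)

  same <- signal_extraction("dup", x, y, y)
  tab2 <- signal_noise_correlations(same)
  expect_equal(tab2$correlation, rep(1, 3))

  anti <- signal_extraction("rev", 1:10, 1:10, exp(-(1:10)))
  tab3 <- signal_noise_correlations(anti, methods = "spearman")
  expect_equal(tab3$correlation, -1)
  expect_equal(names(tab3), c("series_id", "model", "method", "correlation"))
})

test_that("studies are reproducible and mark degenerate noise", {
  spec <- simulation_spec(n_reps = 2, seed = 5)
  st1 <- run_simulation_study(spec, methods = c("ssa", "sdd_anterior_efold"))
  st2 <- run_simulation_study(spec, methods = c("ssa", "sdd_anterior_efold"))
  expect_identical(st1$rmse_matrix, st2$rmse_matrix)
  expect_identical(st1$summary, st2$summary)
  # the benchmark's relative RMSE against itself is exactly 1
  expect_equal(st1$summary$rrmse[st1$summary$model == "sdd_anterior_efold"], 1)
  # common random numbers: both methods saw the same replicates
  expect_equal(nrow(st1$rmse_matrix), 2L)

  spec0 <- simulation_spec(segments = list(noise_segment(0, 100, 0)),
                           n_reps = 2, seed = 5)
  expect_warning(
    st0 <- run_simulation_study(spec0,
                                methods = c("ssa", "sdd_anterior_efold")),
    "degenerate")
  expect_lt(max(st0$rmse_matrix), 1e-6)
  expect_true(all(is.na(st0$summary$rrmse)))
})

test_that("reports round-trip the study and keep the column contract", {
  spec <- simulation_spec(n_reps = 2, seed = 9)
  st <- run_simulation_study(spec, methods = c("ssa", "sdd_anterior_efold"))
  dir <- tempfile()
  r <- fixture_replicate()
  cors <- signal_noise_correlations(extract_signal_ssa(r$noisy),
                                    series_id = "rep0")
  render_report(st, dir, correlations = cors)
  smry <- utils::read.csv(file.path(dir, "summary.csv"))
  expect_equal(names(smry), c("model", "rmse", "mape", "mae", "rrmse",
                              "min_rmse", "max_rmse"))
  expect_equal(smry$rmse, st$summary$rmse, tolerance = 1e-12)
  expect_true(file.exists(file.path(dir, "correlations.csv")))

  # the manifest re-runs to the identical summary
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  spec2 <- simulation_spec(
    amplitude_A = man$spec$amplitude_A, lambda = man$spec$lambda,
    n_points = man$spec$n_points, x_start = man$spec$x_start,
    x_end = man$spec$x_end,
    segments = lapply(man$spec$segments, function(s)
      noise_segment(s$start, s$end, s$sigma)),
    n_reps = man$spec$n_reps, seed = man$spec$seed)
  st2 <- run_simulation_study(spec2, methods = man$methods)
  expect_equal(st2$summary, st$summary, tolerance = 1e-12)

  fake <- structure(list(rmse_matrix = matrix(numeric(0), 0, 1)),
                    class = "study_result")
  expect_error(render_report(fake, tempfile()), "empty")
})
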