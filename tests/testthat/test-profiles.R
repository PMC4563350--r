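test_that("two-column files parse, sort, and average duplicate positions", {
  p <- read_profile(write_lines_tmp(c("position,intensity",
                                      "10,100", "20,50", "30,25")))
  expect_s3_class(p, "expression_profile")
  expect_equal(p$positions, c(10, 20, 30))
  expect_equal(p$intensities, c(100, 50, 25))

  shuffled <- read_profile(write_lines_tmp(c("position,intensity",
                                             "30,25", "10,100", "20,50")))
  expect_equal(shuffled$positions, p$positions)
  expect_equal(shuffled$intensities, p$intensities)

  # ties at one position are averaged (per-nucleus scatter data)
  expect_warning(
    dup <- read_profile(write_lines_tmp(c("position,intensity", "10,100",
                                          "10,80", "20,50", "30,25"))),
    "duplicated positions")
  expect_equal(dup$positions, c(10, 20, 30))
  expect_equal(dup$intensities, c(90, 50, 25))
})

test_that("flyex-like whitespace files parse with configurable columns", {
  path <- write_lines_tmp(c("# comment", "1 10.5 0.2 100",
                            "2 20.5 0.3 51", "3 30.0 0.1 24"), ".txt")
  p <- read_profile(path, dialect = "flyex_like", position_col = 2,
                    intensity_col = 4)
  expect_equal(p$positions, c(10.5, 20.5, 30))
  expect_equal(p$intensities, c(100, 51, 24))
  expect_error(read_profile(path, dialect = "flyex_like",
                            intensity_col = 9), "columns")
})

test_that("non-finite rows are dropped with a log line, short files error", {
  path <- write_lines_tmp(c("position,intensity", "10,100", "15,NA",
                            "20,50", "30,25"))
  expect_message(p <- read_profile(path), "dropped 1")
  expect_equal(length(p), 3L)
  expect_error(
    suppressMessages(read_profile(write_lines_tmp(
      c("position,intensity", "10,100", "20,NA", "30,NA")))),
    "fewer than 3")
  expect_error(read_profile(tempfile()), "cannot read")
})

test_that("profile constructor enforces its invariants", {
  expect_error(expression_profile(c(1, 2), c(1, 2)), "at least 3")
  expect_error(expression_profile(1:3, c(1, NA, 3)), "non-finite")
  expect_error(expression_profile(c(1, 1, 2), c(1, 2, 3)), "duplicate")
  p <- expression_profile(c(3, 1, 2), c(30, 10, 20))
  expect_equal(p$positions, c(1, 2, 3))
  expect_equal(p$intensities, c(10, 20, 30))
})

test_that("AP-window cropping is inclusive, idempotent, and guards emptiness", {
  p <- expression_profile(seq(0, 100, by = 10), seq(100, 0, by = -10))
  cr <- crop_to_ap_window(p, 20, 80)
  expect_equal(range(cr$positions), c(20, 80))
  expect_equal(length(cr), 7L)  # boundaries inclusive
  expect_equal(crop_to_ap_window(cr, 20, 80), cr)
  expect_error(crop_to_ap_window(p, 90.5, 95.5), "no data points")
  expect_error(crop_to_ap_window(p, 80, 20), "lo < hi")
})

test_that("extraction files round-trip losslessly and encode the identity", {
  r <- fixture_replicate()
  ex <- extract_signal_ssa(r$noisy)
  path <- tempfile(fileext = ".csv")
  write_extraction(ex, path)
  back <- read_extraction(path, method = "ssa")
  expect_equal(back$signal, ex$signal, tolerance = 1e-12)
  expect_equal(back$residual, ex$residual, tolerance = 1e-12)
  expect_equal(back$positions, ex$positions, tolerance = 1e-12)
  df <- utils::read.csv(path)
  expect_equal(names(df), c("position", "observed", "signal", "residual"))
  expect_equal(df$residual, df$observed - df$signal, tolerance = 1e-9)

  empty <- signal_extraction("x", numeric(0), numeric(0), numeric(0))
  expect_error(write_extraction(empty, tempfile()), "empty")
})
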