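test_that("the SDD curve obeys its defining identities", {
  expect_equal(sdd_curve(10, 20, 0), 10)
  expect_equal(sdd_curve(10, 20, 20), 10 / exp(1))
  # element-wise oracle on a grid
  x <- seq(0, 80, by = 1)
  oracle <- vapply(x, function(xi) 100 * exp(1)^(-xi / 15), numeric(1))
  expect_equal(sdd_curve(100, 15, x), oracle, tolerance = 1e-12)
  # the 1/e drop at x = lambda, for arbitrary (A, lambda)
  for (i in 1:5) {
    A <- stats::runif(1, 1, 500); lam <- stats::runif(1, 5, 50)
    expect_equal(sdd_curve(A, lam, lam) / sdd_curve(A, lam, 0), 1 / exp(1))
  }
  expect_error(sdd_curve(0, 20, 1), "amplitude")
  expect_error(sdd_curve(10, -1, 1), "lambda")
})

test_that("steady-state length constant is sqrt(D * tau_p)", {
  expect_equal(steady_state_length_constant(4, 25), 10)
  expect_equal(steady_state_length_constant(0, 7), 0)
  expect_equal(steady_state_length_constant(1, 1), 1)
  expect_error(steady_state_length_constant(1, 0), "tau_p")
  expect_error(steady_state_length_constant(-1, 1), "D")
})

test_that("simulation specs validate segment coverage", {
  expect_error(simulation_spec(segments = list(noise_segment(0, 50, 5))),
               "cover")
  expect_error(simulation_spec(segments = list(noise_segment(0, 60, 5),
                                               noise_segment(70, 100, 5))),
               "gaps")
  expect_error(simulation_spec(segments = list(noise_segment(0, 60, 5),
                                               noise_segment(50, 100, 5))),
               "overlap")
  expect_error(noise_segment(10, 5, 1), "start < end")
  expect_error(noise_segment(0, 10, -1), "sigma")
})

test_that("replicates are deterministic in (seed, rep) and unbiased", {
  spec <- simulation_spec(n_reps = 20)
  r1 <- generate_replicate(spec, 3)
  r2 <- generate_replicate(spec, 3)
  expect_identical(r1$noisy$intensities, r2$noisy$intensities)
  expect_identical(r1$truth$provenance, "simulated_truth")
  expect_identical(r1$noisy$provenance, "simulated_noisy")

  # truth does not depend on the seed; noise does
  spec_b <- simulation_spec(n_reps = 20, seed = 99)
  r3 <- generate_replicate(spec_b, 3)
  expect_identical(r1$truth$intensities, r3$truth$intensities)
  expect_false(identical(r1$noisy$intensities, r3$noisy$intensities))

  # zero-mean noise across replicates
  resid_means <- vapply(0:19, function(i) {
    r <- generate_replicate(spec, i)
    mean(r$noisy$intensities - r$truth$intensities)
  }, numeric(1))
  expect_lt(abs(mean(resid_means)), 0.5)

  # zero noise reproduces the truth exactly
  spec0 <- simulation_spec(segments = list(noise_segment(0, 100, 0)),
                           n_reps = 1)
  r0 <- generate_replicate(spec0, 0)
  expect_identical(r0$noisy$intensities, r0$truth$intensities)
})

test_that("per-segment noise has the requested standard deviation", {
  spec <- simulation_spec(n_points = 10000,
                          segments = list(noise_segment(0, 100, 5)),
                          n_reps = 1)
  r <- generate_replicate(spec, 0)
  s <- stats::sd(r$noisy$intensities - r$truth$intensities)
  expect_gt(s, 4.9)
  expect_lt(s, 5.1)

  # distinct segments carry distinct amplitudes
  spec2 <- simulation_spec(n_points = 6000,
                           segments = list(noise_segment(0, 50, 2),
                                           noise_segment(50, 100, 20)),
                           n_reps = 1)
  r2 <- generate_replicate(spec2, 0)
  eps <- r2$noisy$intensities - r2$truth$intensities
  first <- r2$noisy$positions < 50
  expect_lt(stats::sd(eps[first]), 3)
  expect_gt(stats::sd(eps[!first]), 15)
})

test_that("simulation specs serialize to YAML and JSON and back", {
  spec <- simulation_spec(amplitude_A = 77, lambda = 18, n_points = 55,
                          segments = list(noise_segment(0, 30, 8),
                                          noise_segment(30, 60, 12),
                                          noise_segment(60, 100, 8)),
                          n_reps = 12, seed = 7)
  for (ext in c(".yaml", ".json")) {
    path <- tempfile(fileext = ext)
    write_simulation_spec(spec, path)
    back <- read_simulation_spec(path)
    expect_equal(back$amplitude_A, 77)
    expect_equal(back$lambda, 18)
    expect_equal(back$n_points, 55L)
    expect_equal(length(back$segments), 3L)
    expect_identical(generate_replicate(back, 0)$noisy$intensities,
                     generate_replicate(spec, 0)$noisy$intensities)
  }
})
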