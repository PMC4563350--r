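# Shared fixtures, all generated in code.

# Default-conditions replicate, cropped to the analysis window.
fixture_replicate <- function(rep_index = 0L, window = c(20, 80)) {
  spec <- simulation_spec(n_reps = max(1L, rep_index + 1L))
  r <- generate_replicate(spec, rep_index)
  if (!is.null(window)) {
    r$truth <- crop_to_ap_window(r$truth, window[1], window[2])
    r$noisy <- crop_to_ap_window(r$noisy, window[1], window[2])
  }
  r
}

# Noise-free exponential profile.
fixture_exponential <- function(A = 10, lambda = 20, x = seq(0, 80, by = 1),
                                provenance = "simulated_truth") {
  expression_profile(x, sdd_curve(A, lambda, x),
                     series_id = "exp_fixture", provenance = provenance)
}

write_lines_tmp <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
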