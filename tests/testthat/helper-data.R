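# shared fixtures and small constructors used across test files

make_effects <- function(y1, se1, y2, se2, n_patients = NULL) {
  eff <- data.frame(
    trial_id = sprintf("T%02d", seq_along(y1)),
    y1 = y1, se1 = se1, y2 = y2, se2 = se2,
    stringsAsFactors = FALSE
  )
  if (!is.null(n_patients)) eff$n_patients <- n_patients
  class(eff) <- c("effect_table", "data.frame")
  eff
}

# n points exactly on a line, constant SEs
line_effects <- function(n = 5, intercept = 0, slope = 0.5,
                         se1 = 1e-6, se2 = 1e-6,
                         x = seq(-0.8, -0.1, length.out = n)) {
  make_effects(x, rep(se1, n), intercept + slope * x, rep(se2, n))
}

# a moderately noisy toy with an interior correlation optimum
toy_effects <- function(n = 6, seed = 42, tau1 = 0.3, slope = 0.5,
                        resid_sd = 0.15, se_lo = 0.08, se_hi = 0.15) {
  p <- simulation_params(
    n_trials = n, tau1 = tau1, slope_true = slope, resid_sd = resid_sd,
    se1_range = c(se_lo, se_hi), se2_range = c(se_lo, se_hi), seed = seed
  )
  to_effects(simulate_trials(p))
}

fixture_effects <- function(set = "primary") {
  to_effects(build_analysis_set(mcrpc_trials(), set)$records)
}

# write a trial-table CSV and return its path
write_fixture_csv <- function(tab, dir = tempdir()) {
  path <- tempfile("trials", fileext = ".csv", tmpdir = dir)
  write_trial_table(tab, path)
  path
}
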