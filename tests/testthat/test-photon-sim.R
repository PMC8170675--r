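one_pop <- function(E = 0.5, width = 0, ...) {
  fret_populations(data.frame(mean_E = E, width = width, weight = 1), ...)
}

test_that("photon streams are deterministic given the seed and strictly ordered", {
  truth <- one_pop(0.5)
  a <- simulate_photon_stream(truth, sim_config(seed = 4, duration = 3))
  b <- simulate_photon_stream(truth, sim_config(seed = 4, duration = 3))
  c <- simulate_photon_stream(truth, sim_config(seed = 5, duration = 3))
  expect_identical(a$macrotime_s, b$macrotime_s)
  expect_false(identical(a$macrotime_s, c$macrotime_s))
  expect_true(all(diff(a$macrotime_s) > 0))
  # quantized to the 32 ps grid (up to double-precision roundoff on t/res)
  res <- 32e-12
  expect_true(all(abs(a$macrotime_s / res - round(a$macrotime_s / res)) < 1e-4))
})

test_that("generator rejects invalid mixtures and durations", {
  expect_error(fret_populations(data.frame(mean_E = 0.5, width = 0,
                                           weight = 0.7)), "sum to 1")
  expect_error(fret_populations(data.frame(mean_E = 1.5, width = 0,
                                           weight = 1)), "\\[0, 1\\]")
  expect_error(sim_config(duration = -1), "positive")
  expect_error(sim_config(donor_window = c(0, 20)), "partition")
})

test_that("donor-only molecules emit only in the donor-excitation window", {
  truth <- one_pop(0.5, donor_only_fraction = 1,
                   background_rates = c(0, 0))
  ps <- simulate_photon_stream(truth, sim_config(seed = 8, duration = 5))
  expect_gt(nrow(ps), 0)
  expect_true(all(ps$microtime_ns < 25))
  # essentially all photons in the donor channel (only leakage in ch 1)
  expect_gt(mean(ps$channel == 2L), 0.9)
})

test_that("symmetric-split component yields an E histogram peaked at 0.5", {
  truth <- one_pop(0.5, background_rates = c(50, 50))
  ps <- simulate_photon_stream(truth, sim_config(seed = 12, duration = 120))
  b <- analyze_stream(ps)
  expect_gt(sum(b$retained), 200)
  expect_equal(mean(b$E[b$retained]), 0.5, tolerance = 0.02)
})

test_that("two-component mixture weights are recovered by the histogram fit", {
  truth <- fret_populations(
    data.frame(mean_E = c(0.45, 0.75), width = 0.06, weight = c(0.4, 0.6)))
  ps <- simulate_photon_stream(truth, sim_config(seed = 13, duration = 400))
  b <- analyze_stream(ps)
  p1 <- calibrate_pure_peak(0.45, seed = 14)
  p2 <- calibrate_pure_peak(0.75, seed = 15)
  fit <- fit_fret_histogram(b$E[b$retained],
                            means = c(p1$mean, p2$mean),
                            widths = c(p1$width, p2$width))
  expect_lt(abs(fit$bound_fraction - 0.6), 0.03)
})
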