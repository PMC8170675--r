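test_that("kink energies have the closed-form limits", {
  expect_equal(kink_energy(10, 0, 14), 0)
  # long-distance asymptote 2 alpha^2 lp / xi for both parities
  a <- 24 * pi / 180
  asym <- 2 * a^2 * (40 / 0.34) / 14
  expect_equal(kink_energy(1e4, 24, 14), asym, tolerance = 1e-12)
  expect_equal(kink_energy(1e4, 24, 14, parity = "antisymmetric"), asym,
               tolerance = 1e-12)
  # frozen direct evaluation at the natural 31-bp spacer
  expect_equal(kink_energy(31, 24, 14, lp_bp = 117.6), 3.27, tolerance = 1e-3)
  expect_error(kink_energy(-3, 24, 14), "positive")
})

test_that("coupling energy is helically modulated and bounded by the parities", {
  em <- elastic_model(alpha_bend = 24, xi = 14)
  # frozen direct evaluation at ds = 8 with ds0 = 8, lambda = 10.5
  expect_equal(coupling_energy(8, em), 4.6, tolerance = 2e-3)
  # modulation argument repeats every lambda
  ds <- seq(5, 40, by = 0.5)
  e1 <- coupling_energy(ds, em)
  a <- 24 * pi / 180
  asym <- 2 * a^2 * em$lp_bp / em$xi
  mod <- (e1 - asym) * exp(ds / em$xi)
  expect_equal(mod[ds == 10], mod[ds == 10 + 10.5], tolerance = 1e-9)
  # symmetric/antisymmetric kink envelopes bound the curve
  upper <- kink_energy(ds, 24, em$xi, em$lp_bp, "symmetric")
  lower <- kink_energy(ds, 24, em$xi, em$lp_bp, "antisymmetric")
  expect_true(all(e1 >= lower - 1e-9 & e1 <= upper + 1e-9))
  expect_true(all(e1 >= 0))
  # cosine term vanishes at long distance, leaving the asymptote
  expect_equal(coupling_energy(1e4, em), asym, tolerance = 1e-12)
  # printed branch flips the modulation sign
  emp <- elastic_model(alpha_bend = 24, xi = 14, branch = "printed")
  expect_equal(coupling_energy(8, emp) - asym, -(coupling_energy(8, em) - asym),
               tolerance = 1e-9)
})

test_that("the Hill-exponent form plateaus at a*b", {
  em <- elastic_model(24, 14, a = 1.6, b = 1.9)
  expect_equal(hill_vs_spacer(1e4, em), 1.6 * 1.9, tolerance = 1e-12)
  em0 <- elastic_model(24, 1e-6, a = 1.6, b = 1.9)
  expect_equal(hill_vs_spacer(25, em0), 1.6 * 1.9, tolerance = 1e-9)
})

test_that("the bend angle is recovered from coupling-energy series", {
  # noise-free synthetic series: exact recovery
  em <- elastic_model(alpha_bend = 19, xi = 14)
  s0 <- simulate_spacer_series(em, c(8, 14, 18, 24, 31), 0, kind = "energy")
  f0 <- fit_elastic(s0, xi = 14)
  expect_equal(f0$alpha, 19, tolerance = 1e-6)
  # the three printed natural-promoter energies give the published angle
  s <- spacer_series(c(8, 18, 31), c(5.8, 4.5, 1.9), kind = "energy")
  fit <- fit_elastic(s, xi = 14)
  expect_equal(fit$alpha, 24, tolerance = 7 / 24)
  expect_error(fit_elastic(spacer_series(8, 5.8, kind = "energy"), xi = 14),
               "fewer points")
})

test_that("the decay length is recovered from Hill-exponent series", {
  em <- elastic_model(24, 14, a = 1.6, b = 1.9)
  hs <- simulate_spacer_series(em, c(8, 11, 14, 18, 21, 24, 28, 31, 35),
                               noise_sd = 0.05, seed = 71, kind = "hill")
  fit <- fit_elastic(hs, xi = 10, fix_xi = FALSE)
  expect_equal(fit$xi, 14, tolerance = fit$se_xi * 2 / 14)
  # sequential protocol: xi from the Hill series, then alpha with xi fixed
  es <- simulate_spacer_series(em, c(8, 18, 31), noise_sd = 0.1, seed = 72,
                               kind = "energy")
  sq <- fit_elastic_sequential(hs, es)
  expect_equal(sq$alpha, 24, tolerance = 0.15)
})

test_that("tension and mean bend follow from the decay length and angle", {
  em <- elastic_model(alpha_bend = 24, xi = 14)
  tb <- tension_and_bend(em, span_bp = 44)
  expect_equal(round(tb$tension_pN), 7)
  expect_equal(tb$tension_pN, 4.11 * 40 / (14 * 0.34)^2, tolerance = 1e-12)
  expect_equal(tb$mean_bend_deg_bp, 1.1, tolerance = 1e-2)
  expect_equal(tension_and_bend(elastic_model(0, 14))$mean_bend_deg_bp, 0)
  expect_error(tension_and_bend(em, span_bp = 0), "positive")
})

test_that("the gel periodicity fit recovers phase and period", {
  em <- elastic_model(24, 14, ds0 = 7.2)
  gel <- simulate_spacer_series(em, 5:40, noise_sd = 0.02, seed = 73,
                                kind = "gel_fraction")
  fit <- fit_periodicity(gel)
  expect_equal(fit$ds0, 7.2, tolerance = 0.5 / 7.2)
  fit_free <- fit_periodicity(gel, lambda_free = TRUE)
  expect_equal(fit_free$lambda, 10.5, tolerance = 0.03)
  # flat series: cosine amplitude collapses
  set.seed(74)
  flat <- spacer_series(5:40, rep(0.5, 36) + rnorm(36, 0, 1e-4),
                        kind = "gel_fraction")
  expect_lt(fit_periodicity(flat)$c1, 0.01)
  expect_error(fit_periodicity(spacer_series(1:4, 1:4, kind = "gel_fraction")),
               "at least 6")
})
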