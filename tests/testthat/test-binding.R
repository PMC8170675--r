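test_that("closed-form occupancy agrees with the state enumeration everywhere", {
  # 5 x 5 x 5 spot check here (the full 10^3 grid runs in the acceptance
  # suite); also the single-box form
  for (x in c(0.1, 1, 10, 100, 1000))
    for (dgs in c(1, 0, -2))
      for (dgj in c(1, 0, -3)) {
        m <- knf_model(dg_K = 2, dg_sigma = dgs, dg_J = dgj)
        st <- enumerate_states(x, m)
        expect_equal(knf_fraction(x, m), st$prob[st$state == "P1234"],
                     tolerance = 1e-12)
      }
  m1 <- knf_model(dg_K = 2, dg_sigma = -1, n_boxes = 1)
  st1 <- enumerate_states(5, m1)
  expect_equal(knf_fraction(5, m1), st1$prob[st1$state == "full"],
               tolerance = 1e-12)
})

test_that("reference points of the partition function hold", {
  # sigma = J = 1, s = 1: Q = 12, fully-bound fraction 1/12
  m <- knf_model(dg_K = 0, dg_sigma = 0, dg_J = 0)
  expect_equal(knf_fraction(1, m), 1 / 12)
  expect_equal(knf_fraction(0, m), 0)
  st <- enumerate_states(1, m)
  expect_equal(sum(st$weight), 12)
  expect_equal(nrow(st), 12L)   # 1 + 4 + 2 + 4 + 1 microstates
  # weights proportional to {1, 4s, 2s^2, 4s^3, s^4} by occupancy class
  s <- 2
  st2 <- enumerate_states(s, m)
  cls <- vapply(0:4, function(i) sum(st2$weight[st2$i == i]), numeric(1))
  expect_equal(cls, c(1, 4 * s, 2 * s^2, 4 * s^3, s^4))
  # single box, sigma = 1, s = 1: f = 1/(1 + 2 + 1)
  m1 <- knf_model(dg_K = 0, dg_sigma = 0, n_boxes = 1)
  expect_equal(knf_fraction(1, m1), 0.25)
  expect_error(knf_fraction(-1, m), "non-negative")
})

test_that("titration simulation respects the noise contract", {
  m <- knf_model(dg_K = 0, dg_sigma = 0, dg_J = 0)
  conc <- c(0.1, 1, 10)
  iso0 <- simulate_titration(m, conc, noise_sd = 0, seed = 1)
  expect_equal(iso0$f, knf_fraction(conc, m))
  expect_equal(simulate_titration(m, 1, 0)$f, 1 / 12)
  iso <- simulate_titration(m, conc, noise_sd = 0.05, n_rep = 4, seed = 2)
  expect_true(all(iso$f >= 0 & iso$f <= 1))
  expect_identical(iso, simulate_titration(m, conc, 0.05, n_rep = 4, seed = 2))
  # Hill midpoint
  expect_equal(simulate_titration(list(n = 2, K_Hill = 25), 25, 0)$f, 0.5)
  expect_error(simulate_titration(m, numeric(0), 0), "empty")
})

test_that("Hill fits recover generating parameters", {
  conc <- 10^seq(0, 3, length.out = 12)
  # noise-free: essentially exact
  iso0 <- simulate_titration(list(n = 2.5, K_Hill = 60), conc, 0)
  f0 <- fit_hill(iso0)
  expect_equal(f0$n, 2.5, tolerance = 1e-6)
  expect_equal(f0$K_Hill, 60, tolerance = 1e-4)
  # at realistic noise, on a grid spanning the transition with duplicate
  # titrations, the printed precision scale (~0.1-0.2) is reached
  grid_tr <- 10^seq(log10(18), log10(140), length.out = 12)
  iso <- simulate_titration(list(n = 3.6, K_Hill = 50), grid_tr, 0.02,
                            n_rep = 2, seed = 41)
  fit <- fit_hill(iso)
  expect_lt(abs(fit$n - 3.6), 0.15)
  expect_error(fit_hill(simulate_titration(list(n = 2, K_Hill = 1e6),
                                           conc, 0)), "transition")
})

test_that("two-box isotherms give Hill exponents in (2, 4], increasing with J", {
  conc <- 10^seq(-1, 3, length.out = 16)
  n_of_J <- vapply(c(2, 4, 6), function(cpl) {
    m <- knf_model(dg_K = 4, dg_sigma = -3, dg_J = -cpl)
    fit_hill(simulate_titration(m, conc, 0))$n
  }, numeric(1))
  expect_true(all(n_of_J > 2 & n_of_J <= 4))
  expect_true(all(diff(n_of_J) > 0))
})

test_that("the two-stage global fit recovers the coupling free energy", {
  conc <- 10^seq(-0.5, 3.2, length.out = 20)
  m1a <- knf_model(dg_K = 4, dg_sigma = -3, n_boxes = 1)
  m1b <- knf_model(dg_K = 4.7, dg_sigma = -3, n_boxes = 1)
  m2 <- knf_model(dg_K = 4, dg_sigma = -3, dg_J = -4.5)
  b1 <- simulate_titration(m1a, conc, 0.01, n_rep = 3, seed = 51)
  b2 <- simulate_titration(m1b, conc, 0.01, n_rep = 3, seed = 52)
  pr <- simulate_titration(m2, conc, 0.01, n_rep = 3, seed = 53)
  g <- fit_knf_global(list(b1, b2), list(pr))
  expect_equal(g$dg_sigma, -3, tolerance = 0.15)
  expect_equal(g$promoters[[1]]$coupling, 4.5, tolerance = 0.1)
  # J = 1 data: coupling comes out near zero
  m_nc <- knf_model(dg_K = 4, dg_sigma = -3, dg_J = 0)
  pr0 <- simulate_titration(m_nc, conc, 0.01, n_rep = 3, seed = 54)
  g0 <- fit_knf_global(list(b1, b2), list(pr0))
  expect_lt(abs(g0$promoters[[1]]$coupling), 0.3)
  expect_error(fit_knf_global(list()), "required")
})
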