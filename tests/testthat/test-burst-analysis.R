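# hand-built streams for exact burst-search checks
make_stream <- function(t, channel, microtime = 5) {
  structure(data.frame(macrotime_s = t, channel = channel,
                       microtime_ns = rep_len(microtime, length(t))),
            class = c("photon_stream", "data.frame"))
}

ident <- correction_set(gamma2 = 1, beta_DA = 0, beta_AD = 0,
                        alpha_direct = 0)

test_that("empty and sparse streams give no bursts", {
  expect_equal(nrow(find_bursts(make_stream(numeric(0), integer(0)))), 0L)
  sparse <- make_stream(seq(0, 10, by = 0.5), rep(c(1L, 2L), 11)[1:21])
  expect_equal(nrow(find_bursts(sparse)), 0L)
  shuffled <- make_stream(c(1, 0.5, 2), c(1L, 2L, 1L))
  expect_error(find_bursts(shuffled), "non-decreasing")
})

test_that("a single dense cluster is found as exactly one burst", {
  t <- c(0.01, 5 + (0:199) * 1e-6, 9.99)
  ch <- rep(c(1L, 2L), length.out = length(t))
  bs <- find_bursts(make_stream(t, ch), ident)
  expect_equal(nrow(bs), 1L)
  expect_equal(bs$n1 + bs$n2, 200L)
  expect_lte(attr(bs, "iterations"), 10L)
})

test_that("clusters at or below the corrected-count threshold are rejected", {
  t <- c(0.01, 5 + (0:79) * 1e-6, 9.99)   # 80 photons: needs > 80
  ch <- rep(c(1L, 2L), length.out = length(t))
  expect_equal(nrow(find_bursts(make_stream(t, ch), ident)), 0L)
  t2 <- c(0.01, 5 + (0:80) * 1e-6, 9.99)  # 81 photons passes
  ch2 <- rep(c(1L, 2L), length.out = length(t2))
  expect_equal(nrow(find_bursts(make_stream(t2, ch2), ident)), 1L)
})

test_that("burst count is monotone in the threshold and dt_max, and shift-invariant", {
  truth <- fret_populations(data.frame(mean_E = 0.5, width = 0.05, weight = 1),
                            background_rates = c(200, 400))
  ps <- simulate_photon_stream(truth, sim_config(seed = 21, duration = 40))
  n_at <- function(minp, dtm = 100e-6)
    nrow(find_bursts(ps, cfg = burst_search_config(dt_max = dtm,
                                                   min_corrected_photons = minp)))
  expect_true(n_at(40) >= n_at(80) && n_at(80) >= n_at(160))
  expect_true(n_at(80, 50e-6) <= n_at(80, 100e-6))
  # prepending/appending empty time does not change the result
  shifted <- ps
  shifted$macrotime_s <- shifted$macrotime_s + 100
  bs0 <- find_bursts(ps)
  bs1 <- find_bursts(shifted)
  expect_equal(nrow(bs1), nrow(bs0))
  expect_equal(bs1$n1, bs0$n1)
})

test_that("iterative background estimation converges quickly on synthetic data", {
  truth <- fret_populations(data.frame(mean_E = 0.5, width = 0.05, weight = 1),
                            background_rates = c(300, 700))
  ps <- simulate_photon_stream(truth, sim_config(seed = 22, duration = 60))
  bs <- find_bursts(ps)
  expect_lte(attr(bs, "iterations"), 10L)
  bg <- attr(bs, "background")
  # recovered background rates: donor-window share of each channel's rate
  expect_equal(unname(bg["b1"]), 150, tolerance = 0.2)
  expect_equal(unname(bg["b2"]), 350, tolerance = 0.2)
})

test_that("burst metrics match their closed forms", {
  # 25 donor + 25 acceptor photons spread over 1 ms, identity corrections
  t0 <- 5
  cluster <- rbind(
    data.frame(t = t0 + seq(0, 1000e-6, length.out = 25), ch = 2L),
    data.frame(t = t0 + seq(3e-6, 989e-6, length.out = 25), ch = 1L))
  cluster <- cluster[order(cluster$t), ]
  st <- make_stream(c(0.01, cluster$t, 9.99), c(1L, cluster$ch, 2L))
  cfg <- burst_search_config(min_corrected_photons = 40)
  bs <- burst_metrics(find_bursts(st, ident, cfg), st, ident)
  expect_equal(nrow(bs), 1L)
  expect_equal(c(bs$n1, bs$n2), c(25L, 25L))
  expect_equal(bs$E, 0.5, tolerance = 1e-3)
  # sigma_DA = T/(2 sqrt(3)) (1/nD' + 1/nA')^(1/2) with T = 1 ms
  expect_equal(bs$sigma_DA,
               bs$T / (2 * sqrt(3)) * sqrt(1 / bs$nD_corr + 1 / bs$nA_corr))
  expect_equal(bs$sigma_DA, 81.65e-6, tolerance = 1e-3)
  # no acceptor-excitation photons -> S = 1 (donor-only signature)
  expect_equal(bs$S, 1, tolerance = 1e-6)
  expect_equal(bs$n_AA, 0L)
})

test_that("stoichiometry filter drops S >= 0.8 and asymmetry keeps alpha = 0", {
  b <- data.frame(alpha_DA = c(0, 0, 5e-4), sigma_DA = c(1e-4, 1e-4, 1e-4),
                  S = c(0.5, 0.9, 0.5))
  f <- filter_bursts(b)
  expect_equal(f$retained, c(TRUE, FALSE, FALSE))
  expect_equal(f$pass_asymmetry, c(TRUE, TRUE, FALSE))
  expect_equal(f$pass_stoichiometry, c(TRUE, FALSE, TRUE))
})

test_that("shot-noise asymmetry filter retains about P(|Z| <= 1) of clean bursts", {
  truth <- fret_populations(data.frame(mean_E = 0.5, width = 0.02, weight = 1),
                            background_rates = c(100, 100))
  ps <- simulate_photon_stream(truth, sim_config(seed = 23, duration = 150))
  b <- burst_metrics(find_bursts(ps), ps)
  b <- filter_bursts(b)
  expect_equal(mean(b$pass_asymmetry), 0.683, tolerance = 0.1)
})

test_that("bleached bursts are flagged by positive asymmetry and removed", {
  truth <- fret_populations(data.frame(mean_E = 0.5, width = 0.02, weight = 1),
                            bleach_fraction = 0.5, background_rates = c(100, 100))
  ps <- simulate_photon_stream(truth, sim_config(seed = 24, duration = 150))
  b <- filter_bursts(burst_metrics(find_bursts(ps), ps))
  tb <- match_truth(b, ps)
  # rejection probability at the default burst brightness is ~0.95 (bursts
  # whose acceptor dies in the last few percent of the transit are
  # indistinguishable from shot noise)
  expect_gte(mean(!b$pass_asymmetry[tb$bleached]), 0.93)
  expect_gt(mean(b$alpha_DA[tb$bleached], na.rm = TRUE), 0)
})

test_that("donor-only molecules are removed by the stoichiometry filter", {
  truth <- fret_populations(data.frame(mean_E = 0.5, width = 0.02, weight = 1),
                            donor_only_fraction = 0.5,
                            background_rates = c(100, 100))
  ps <- simulate_photon_stream(truth, sim_config(seed = 25, duration = 100))
  b <- filter_bursts(burst_metrics(find_bursts(ps), ps))
  tb <- match_truth(b, ps)
  expect_gte(mean(!b$pass_stoichiometry[tb$donor_only]), 0.95)
  expect_gte(mean(b$pass_stoichiometry[!tb$donor_only]), 0.9)
})
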