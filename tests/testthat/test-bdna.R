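test_that("dye distances match the direct geometric evaluation", {
  # frozen oracle values from the cylindrical-helix expression with the
  # default geometry (L = 0.617, z = 0.338, rA = 1.177, rD = 1.247,
  # twist 36 deg/bp, offset 89.8 deg)
  expect_equal(dye_distance(0), 1.820, tolerance = 5e-4)
  expect_equal(dye_distance(10), 4.348, tolerance = 5e-4)
  # the axial term grows monotonically with separation
  g <- bdna_geometry()
  axial <- (g$L + (0:30) * g$z_bp)^2
  expect_true(all(diff(axial) > 0))
  # angular term repeats every 10 bp at 36 deg/bp: distances at d and d+10
  # differ only through the axial term
  d <- 0:5
  ang <- function(dd) dye_distance(dd)^2 - (g$L + dd * g$z_bp)^2
  expect_equal(ang(d), ang(d + 10), tolerance = 1e-9)
  expect_error(dye_distance(-1), "non-negative")
  expect_error(dye_distance(1.5), "integers")
})

test_that("the midpoint polynomial has the printed endpoints and a unique inverse", {
  expect_identical(mean_to_mp(0), 0.008)
  expect_equal(mean_to_mp(1), 1.016)
  # strictly increasing on [0, 1]
  x <- seq(0, 1, by = 0.01)
  expect_true(all(diff(mean_to_mp(x)) > 0))
  # round trip to 1e-9
  for (e in c(0.05, 0.3, 0.62, 0.97))
    expect_equal(mp_to_mean(mean_to_mp(e)), e, tolerance = 1e-8)
  expect_error(mp_to_mean(1.2), "no root")
})

test_that("the B-DNA efficiency profile chains the three relations", {
  prof <- bdna_profile(0:25)
  expect_true(all(prof$E_mean > 0 & prof$E_mean < 1))
  # decreases on average with separation despite helical modulation
  expect_lt(mean(prof$E_mean[21:26]), mean(prof$E_mean[1:6]))
  # at R_DA = R0 the midpoint efficiency is 1/2 by construction
  g <- bdna_geometry()
  r <- dye_distance(0:25)
  expect_equal(prof$E_mp, g$R0^6 / (g$R0^6 + r^6))
  # zero separation: E_mp ~ 0.9985 and E_mean solves the polynomial
  expect_equal(prof$E_mp[1], 0.9985, tolerance = 1e-4)
  expect_equal(mean_to_mp(prof$E_mean[1]), prof$E_mp[1], tolerance = 1e-8)
})

test_that("R0 is recovered from profiles generated at known values", {
  for (r0_true in c(5.4, 5.6)) {
    g <- bdna_geometry(R0 = r0_true)
    prof <- bdna_profile(seq(4, 24, by = 2), g)
    fit <- fit_r0(prof$delta_bp, prof$E_mean)
    expect_equal(fit$R0, r0_true, tolerance = 0.01)
  }
  expect_error(fit_r0(c(5, 10, 15), rep(0.5, 3)), "degenerate")
  expect_error(fit_r0(c(5, 10), c(0.9, 0.3)), "at least 3")
})
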