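test_that("the rotamer enumeration is exhaustive and Boltzmann-weighted", {
  cl <- enumerate_conformers(dye_attachment())
  expect_identical(attr(cl, "n_enumerated"), 2187L)   # 3^7
  expect_identical(attr(cl, "n_retained"), 2187L)     # no clash set
  expect_equal(sum(cl$weights), 1)
  # zero gauche penalty: uniform weights
  cl0 <- enumerate_conformers(dye_attachment(gauche_penalty = 0))
  expect_true(all(abs(cl0$weights - 1 / 2187) < 1e-12))
  # with a penalty, the all-anti chain (most extended) carries the top weight
  d <- sqrt(rowSums(cl$positions^2))
  expect_equal(which.max(cl$weights), which.max(d))
  expect_error(dye_attachment(n_bonds = 0), "at least 1")
})

test_that("clash filtering is monotone in the tolerated prefix", {
  att <- dye_attachment()
  clash <- data.frame(x = 0.3, y = 0.05, z = 0, radius = 0.12)
  kept <- vapply(c(0, 1, 4, 7), function(p)
    attr(enumerate_conformers(att, clash, p), "n_retained"), integer(1))
  expect_true(all(diff(kept) >= 0))
  expect_lt(kept[1], 2187L)
  # a clash atom engulfing everything leaves no conformers
  wall <- data.frame(x = 0.4, y = 0, z = 0, radius = 3)
  expect_error(enumerate_conformers(att, wall, 0), "clash")
})

test_that("anchor construction from base atoms has the prescribed geometry", {
  c8 <- c(1, 2, 3); n9 <- c8 + c(0.14, 0, 0); ref <- c8 + c(0.05, 0.12, 0)
  att <- dye_anchor_from_base(c8, n9, ref)
  expect_equal(sqrt(sum((att$anchor - c8)^2)), 0.132, tolerance = 1e-9)
  u <- (n9 - c8) / sqrt(sum((n9 - c8)^2))
  v <- (att$anchor - c8) / 0.132
  expect_equal(acos(sum(u * v)) * 180 / pi, 123, tolerance = 1e-6)
  # anchor lies in the base plane (z = 3 here)
  expect_equal(att$anchor[3], 3, tolerance = 1e-9)
})

test_that("cloud-averaged FRET has exact point-cloud limits", {
  expect_equal(predicted_fret(dye_cloud(c(0, 0, 0)), dye_cloud(c(0, 0, 0))), 1)
  expect_equal(predicted_fret(dye_cloud(c(0, 0, 0)),
                              dye_cloud(c(5.4, 0, 0))), 0.5)
  # monotone decreasing with separation
  E_sep <- vapply(c(3, 5, 7, 9), function(d)
    predicted_fret(dye_cloud(c(0, 0, 0)), dye_cloud(c(d, 0, 0))), numeric(1))
  expect_true(all(diff(E_sep) < 0))
  expect_error(predicted_fret(dye_cloud(c(0, 0, 0)), list()), "dye_cloud")
})

test_that("FRET between Gaussian clouds matches the distance-distribution oracle", {
  # independent oracle: quadrature over the closed-form pairwise-distance
  # density of two isotropic Gaussian clouds (noncentral chi form)
  set.seed(95)
  n <- 2000; sd_dye <- 0.54; mu <- 5.4; R0 <- 5.4
  A <- dye_cloud(matrix(rnorm(3 * n, 0, sd_dye), ncol = 3))
  B <- dye_cloud(sweep(matrix(rnorm(3 * n, 0, sd_dye), ncol = 3), 2,
                       c(mu, 0, 0), "+"))
  E_cloud <- predicted_fret(A, B, R0)
  sc <- sqrt(2) * sd_dye
  p_r <- function(r) r / (mu * sc * sqrt(2 * pi)) *
    (exp(-(r - mu)^2 / (2 * sc^2)) - exp(-(r + mu)^2 / (2 * sc^2)))
  E_oracle <- stats::integrate(function(r) R0^6 / (R0^6 + r^6) * p_r(r),
                               0, mu + 10 * sc, rel.tol = 1e-10)$value
  expect_equal(E_cloud, E_oracle, tolerance = 0.01)
})

test_that("FRET is invariant under joint rigid transformation of both clouds", {
  cl_d <- enumerate_conformers(dye_attachment())
  cl_a <- enumerate_conformers(dye_attachment(anchor = c(4, 1, 0),
                                              axis = c(-1, 0, 0)))
  E0 <- predicted_fret(cl_d, cl_a)
  set.seed(96)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  shift <- c(3, -2, 5)
  rot <- function(cl) dye_cloud(cl$positions %*% R +
                                  rep(shift, each = nrow(cl$positions)),
                                cl$weights)
  expect_equal(predicted_fret(rot(cl_d), rot(cl_a)), E0, tolerance = 1e-12)
  expect_true(E0 > 0 && E0 < 1)
})

test_that("clash atoms round-trip through the columnar reader", {
  tmp <- tempfile(fileext = ".csv")
  atoms <- data.frame(x = c(0.1, 0.5), y = c(0, 0.2), z = c(0, -0.1),
                      radius = c(0.17, 0.2))
  utils::write.csv(atoms, tmp, row.names = FALSE)
  back <- read_clash_atoms(tmp)
  expect_equal(back, atoms)
  # default radius is filled in when absent
  utils::write.csv(atoms[, 1:3], tmp, row.names = FALSE)
  expect_equal(read_clash_atoms(tmp, radius = 0.2)$radius, c(0.2, 0.2))
  unlink(tmp)
})
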