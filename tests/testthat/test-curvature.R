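test_that("straight centerlines have zero curvature everywhere", {
  st <- make_centerline("straight", 93)
  expect_equal(max(abs(segment_angles(st))), 0, tolerance = 1e-8)
})

test_that("a circular arc gives the geometric angle b/R per segment", {
  arc <- make_centerline("arc", 93, radius = 10)
  a <- segment_angles(arc)
  expected <- 180 / pi * 0.34 / 10   # 1.948 degrees
  expect_equal(mean(a), expected, tolerance = 0.01)
  expect_lt(stats::sd(a) / mean(a), 0.01)
  # total turning is conserved by the resampling
  expect_equal(sum(a), length(a) * expected, tolerance = 0.01)
})

test_that("angles are invariant under rigid motion and stable under refinement", {
  arc <- make_centerline("arc", 93, radius = 10)
  a <- segment_angles(arc)
  set.seed(81)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  a_rot <- segment_angles(arc$points %*% R + 7)
  expect_equal(a_rot, a, tolerance = 1e-9)
  # halving the segment length: total turning per arclength stays put
  a_half <- segment_angles(arc$points, b = 0.17)
  expect_equal(sum(a_half) / (length(a_half) * 0.17),
               sum(a) / (length(a) * 0.34), tolerance = 0.01)
})

test_that("a custom turning profile round-trips through segment_angles", {
  prof <- c(seq(0.2, 1.8, length.out = 45), seq(1.8, 0.4, length.out = 46))
  cl <- make_centerline("custom", 93, angles_deg = prof)
  a <- segment_angles(cl)
  expect_equal(a, prof[seq_along(a)], tolerance = 0.02)
})

test_that("degenerate point sets are rejected", {
  expect_error(segment_angles(rbind(c(0, 0, 0), c(1, 0, 0))), "at least 3")
  expect_error(segment_angles(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))),
               "repeated")
  expect_error(make_centerline("custom", 10, angles_deg = 1:3),
               "length_bp - 2")
})

test_that("group-averaged profiles report the free-bound curvature difference", {
  # per-bp curvatures chosen so the group difference is 0.6 deg/bp
  r_of <- function(k) 180 / pi * 0.34 / k
  free <- lapply(c(1.5, 1.6, 1.7), function(k)
    segment_angles(make_centerline("arc", 93, radius = r_of(k))))
  bound <- lapply(c(0.9, 1.0, 1.1), function(k)
    segment_angles(make_centerline("arc", 80, radius = r_of(k))))
  av <- average_profiles(free, bound)
  expect_equal(av$difference_deg_bp, 0.6, tolerance = 0.02)
  # identical groups: zero difference; single profile: mean is the profile
  same <- average_profiles(free, free)
  expect_equal(same$difference_deg_bp, 0)
  one <- average_profiles(free[1])
  expect_equal(one$mean_a, free[[1]])
  expect_error(average_profiles(list()), "empty")
})
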