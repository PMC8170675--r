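#' Build a synthetic DNA centerline
#'
#' Generates ordered 3D centerline coordinates with one point per base pair
#' (spacing `b` = 0.34 nm): a straight axis, a planar circular arc of given
#' radius (constant per-segment curvature `b/R`), or a planar chain with a
#' custom per-segment turning-angle profile.
#'
#' @param kind `"straight"`, `"arc"` or `"custom"`.
#' @param length_bp number of points (base pairs) along the centerline.
#' @param b segment length in nm.
#' @param radius arc radius in nm (for `kind = "arc"`).
#' @param angles_deg per-segment turning angles in degrees, length
#'   `length_bp - 2` (for `kind = "custom"`).
#' @param class_label optional class annotation.
#' @return A `centerline`: list with the `length_bp x 3` coordinate matrix
#'   `points`, the segment length `b`, and the label.
#' @export
#' @examples
#' arc <- make_centerline("arc", length_bp = 93, radius = 10)
#' summary(segment_angles(arc$points))
make_centerline <- function(kind = c("straight", "arc", "custom"),
                            length_bp, b = BP_NM, radius = NULL,
                            angles_deg = NULL, class_label = NULL) {
  kind <- match.arg(kind)
  stop_if_not(length_bp >= 3, "need at least 3 points")
  n <- as.integer(length_bp)
  pts <- switch(kind,
    straight = cbind((seq_len(n) - 1L) * b, 0, 0),
    arc = {
      stop_if_not(!is.null(radius) && radius > 0, "'radius' must be positive")
      phi <- (seq_len(n) - 1L) * b / radius
      cbind(radius * sin(phi), radius * (1 - cos(phi)), 0)
    },
    custom = {
      stop_if_not(length(angles_deg) == n - 2L,
                  "'angles_deg' must have length_bp - 2 entries")
      heading <- cumsum(c(0, deg2rad(angles_deg)))
      dx <- b * cos(heading); dy <- b * sin(heading)
      cbind(cumsum(c(0, dx)), cumsum(c(0, dy)), 0)
    })
  structure(list(points = unname(pts), b = b, class_label = class_label),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("DNA centerline: %d points, segment length %.3g nm",
              nrow(x$points), x$b))
  if (!is.null(x$class_label)) cat(sprintf(" [%s]", x$class_label))
  cat("\n")
  invisible(x)
}

# resample an ordered 3D point list to arclength-uniform spacing b,
# optionally smoothing each coordinate along the chord-length parameter
resample_centerline <- function(points, b, smoothing = 0, upsample = 10L) {
  n <- nrow(points)
  seg <- sqrt(rowSums(diff(points)^2))
  stop_if_not(all(seg > 0), "degenerate centerline: repeated points")
  t0 <- c(0, cumsum(seg))
  tt <- seq(0, t0[n], length.out = upsample * n)
  fine <- vapply(1:3, function(j) {
    if (smoothing > 0 && n >= 8) {
      sp <- stats::smooth.spline(t0, points[, j], spar = smoothing)
      stats::predict(sp, tt)$y
    } else {
      stats::spline(t0, points[, j], xout = tt, method = "natural")$y
    }
  }, numeric(length(tt)))
  arc <- c(0, cumsum(sqrt(rowSums(diff(fine)^2))))
  s_grid <- seq(0, max(arc), by = b)
  vapply(1:3, function(j) stats::approx(arc, fine[, j], xout = s_grid)$y,
         numeric(length(s_grid)))
}

#' Per-segment curvature angles of a DNA centerline
#'
#' Fits a smooth 3D parametric curve through the ordered points, resamples
#' it to arclength-uniform segments of length `b`, and returns the angle
#' between successive segment vectors,
#' `theta_i = acos(v_{i+1} . v_i / (|v_{i+1}| |v_i|))`, in degrees. A
#' straight line gives all zeros; a circular arc of radius `R` gives a
#' constant `b/R` per segment.
#'
#' @param points `n x 3` matrix of ordered coordinates (nm), or a
#'   `centerline`.
#' @param smoothing smoothing-spline parameter in `[0, 1]` (`0` =
#'   interpolating spline).
#' @param b segment length in nm.
#' @return numeric vector of `n_segments - 1` angles in degrees.
#' @export
segment_angles <- function(points, smoothing = 0, b = BP_NM) {
  if (inherits(points, "centerline")) points <- points$points
  points <- as.matrix(points)
  stop_if_not(nrow(points) >= 3L, "need at least 3 points")
  stop_if_not(smoothing >= 0, "'smoothing' must be non-negative")
  res <- resample_centerline(points, b, smoothing)
  v <- diff(res)
  dots <- rowSums(v[-nrow(v), , drop = FALSE] * v[-1, , drop = FALSE])
  norms <- sqrt(rowSums(v^2))
  cosang <- dots / (norms[-length(norms)] * norms[-1])
  rad2deg(acos(clamp(cosang, -1, 1)))
}

#' Average curvature profiles and group difference
#'
#' Center-aligns per-particle angle profiles (with respect to the middle of
#' the DNA), trims them to the common support, and averages within each
#' group. When two groups are given (e.g. free versus protein-bound
#' particles), also reports the mean per-bp curvature difference
#' `mean(mean_group1 - mean_group2)` over the common segments.
#'
#' @param profiles_a list of numeric angle profiles (degrees) for group A
#'   (e.g. free DNA classes).
#' @param profiles_b optional list for group B (e.g. bound classes).
#' @param alignment currently `"middle"`.
#' @return list with `mean_a`, `mean_b` (or NULL) and `difference_deg_bp`.
#' @export
average_profiles <- function(profiles_a, profiles_b = NULL,
                             alignment = "middle") {
  stop_if_not(alignment == "middle", "only middle alignment is implemented")
  stop_if_not(length(profiles_a) >= 1L, "empty group")
  if (!is.null(profiles_b)) stop_if_not(length(profiles_b) >= 1L, "empty group")
  center_trim <- function(profiles, len) {
    t(vapply(profiles, function(p) {
      n <- length(p)
      start <- floor((n - len) / 2) + 1L
      p[start:(start + len - 1L)]
    }, numeric(len)))
  }
  len_a <- min(lengths(profiles_a))
  len <- if (is.null(profiles_b)) len_a else min(len_a, min(lengths(profiles_b)))
  mean_a <- colMeans(center_trim(profiles_a, len))
  mean_b <- if (is.null(profiles_b)) NULL else colMeans(center_trim(profiles_b, len))
  diff <- if (is.null(mean_b)) NA_real_ else mean(mean_a - mean_b)
  list(mean_a = mean_a, mean_b = mean_b, difference_deg_bp = diff,
       n_segments = len)
}

#' Read or write a centerline as an XYZ text file
#'
#' Three whitespace-separated coordinate columns (nm), one point per line;
#' lines starting with `#` are ignored.
#'
#' @param centerline a `centerline` or an `n x 3` matrix.
#' @param path file path.
#' @param b segment length in nm (on read).
#' @return `read_xyz` returns a `centerline`.
#' @export
write_xyz <- function(centerline, path) {
  pts <- if (inherits(centerline, "centerline")) centerline$points else centerline
  utils::write.table(pts, path, sep = " ", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path, b = BP_NM) {
  pts <- as.matrix(utils::read.table(path, comment.char = "#"))
  stop_if_not(ncol(pts) == 3L, "XYZ file must have 3 columns")
  structure(list(points = unname(pts), b = b, class_label = NULL),
            class = "centerline")
}
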