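#' Geometric parameters for dye pairs on straight B-DNA
#'
#' Cylindrical-helix geometry for the mean donor-acceptor distance of a dye
#' pair attached at a given base-pair separation on B-form DNA: `L` is the
#' axial offset between the projections of the two dye centres for zero
#' separation, `z_bp` the helical rise per base pair, `r_A`/`r_D` the radial
#' offsets of acceptor/donor from the helix axis due to their linkers,
#' `beta_bp` the twist per base pair, and `alpha_offset` the azimuthal angle
#' between the dyes at zero separation. Defaults are the published
#' calibration for dyes of this size.
#'
#' @param L axial dye offset in nm.
#' @param z_bp helical rise in nm per bp.
#' @param r_A,r_D radial dye offsets in nm.
#' @param beta_bp helical twist in degrees per bp.
#' @param alpha_offset azimuthal dye-dye offset angle in degrees.
#' @param R0 Foerster distance in nm.
#' @return An object of class `bdna_geometry`.
#' @export
bdna_geometry <- function(L = 0.617, z_bp = 0.338, r_A = 1.177, r_D = 1.247,
                          beta_bp = 36, alpha_offset = 89.8, R0 = 5.4) {
  stop_if_not(L > 0 && z_bp > 0 && r_A > 0 && r_D > 0 && R0 > 0,
              "lengths must be positive")
  stop_if_not(is.finite(beta_bp) && is.finite(alpha_offset),
              "angles must be finite")
  structure(list(L = L, z_bp = z_bp, r_A = r_A, r_D = r_D,
                 beta_bp = beta_bp, alpha_offset = alpha_offset, R0 = R0),
            class = "bdna_geometry")
}

#' Mean donor-acceptor distance on straight B-DNA
#'
#' `R_DA = sqrt((L + d z_bp)^2 + r_A^2 + r_D^2
#'   - 2 r_A r_D cos(alpha + d beta_bp))` for a base-pair separation `d`:
#' an axial term growing with separation, modulated by the helical phase of
#' the two attachment points (period 10 bp at 36 degrees/bp).
#'
#' @param delta_bp non-negative integer base-pair separation(s).
#' @param geom a [bdna_geometry()].
#' @return distances in nm.
#' @export
#' @examples
#' dye_distance(0)    # 1.820 nm
#' dye_distance(10)   # 4.348 nm
dye_distance <- function(delta_bp, geom = bdna_geometry()) {
  stop_if_not(all(delta_bp >= 0) && all(delta_bp == round(delta_bp)),
              "'delta_bp' must be non-negative integers")
  ang <- deg2rad(geom$alpha_offset + delta_bp * geom$beta_bp)
  sqrt((geom$L + delta_bp * geom$z_bp)^2 + geom$r_A^2 + geom$r_D^2 -
         2 * geom$r_A * geom$r_D * cos(ang))
}

# empirical polynomial linking the linker-averaged mean efficiency to the
# midpoint efficiency of the mean dye positions
MP_COEF <- c(0.008, 0.679, 1.470, -1.141)

#' Convert between midpoint and linker-averaged transfer efficiency
#'
#' The transfer efficiency computed from the mean dye positions (`E_mp`) and
#' the efficiency averaged over the dye-linker positional distribution
#' (`<E>`) are related by the empirical polynomial
#' `E_mp = 0.008 + 0.679 <E> + 1.470 <E>^2 - 1.141 <E>^3`, strictly
#' increasing on `[0, 1]`. `mean_to_mp()` evaluates the polynomial;
#' `mp_to_mean()` inverts it by bracketed root finding (tolerance 1e-9).
#'
#' @param E_mean linker-averaged mean efficiency, in `[0, 1]`.
#' @param E_mp midpoint efficiency, in `[0.008, 1.016]` (the polynomial's
#'   range on the unit interval; values outside are flagged).
#' @return the converted efficiency (vectorized).
#' @export
#' @examples
#' mean_to_mp(0)          # 0.008
#' mean_to_mp(1)          # 1.016
#' mp_to_mean(mean_to_mp(0.3))
mean_to_mp <- function(E_mean) {
  stop_if_not(all(E_mean >= 0 & E_mean <= 1.02), "'E_mean' must lie in [0, 1.02]")
  MP_COEF[1] + MP_COEF[2] * E_mean + MP_COEF[3] * E_mean^2 + MP_COEF[4] * E_mean^3
}

#' @rdname mean_to_mp
#' @export
mp_to_mean <- function(E_mp) {
  lo_v <- mean_to_mp(0); hi_v <- mean_to_mp(1)
  vapply(E_mp, function(e) {
    if (e < lo_v - 1e-12 || e > hi_v + 1e-12)
      stop("no root in [0, 1] for E_mp = ", format(e), call. = FALSE)
    e <- clamp(e, lo_v, hi_v)
    stats::uniroot(function(x) mean_to_mp(x) - e, c(0, 1), tol = 1e-9)$root
  }, numeric(1))
}

#' Expected mean transfer efficiency profile of straight B-DNA
#'
#' Chains the geometric distance model, the Foerster relation
#' `E_mp = R0^6 / (R0^6 + R_DA^6)` and the inverse midpoint-to-mean
#' polynomial to predict the experimentally accessible `<E>` for each
#' base-pair separation.
#'
#' @param delta_bp non-negative integer separations.
#' @param geom a [bdna_geometry()].
#' @return data frame with `delta_bp`, `R_DA`, `E_mp` and `E_mean`.
#' @export
bdna_profile <- function(delta_bp, geom = bdna_geometry()) {
  R <- dye_distance(delta_bp, geom)
  E_mp <- fret_of_r(R, geom$R0)
  data.frame(delta_bp = delta_bp, R_DA = R, E_mp = E_mp,
             E_mean = mp_to_mean(E_mp))
}

#' Fit the Foerster distance to a measured B-DNA efficiency profile
#'
#' Least squares over `R0` only, with the helix geometry fixed: useful as a
#' consistency check that measured mean efficiencies on an (assumed straight)
#' B-DNA construct are compatible with the dye pair's literature Foerster
#' distance.
#'
#' @param delta_bp base-pair separations of the measurements.
#' @param E_mean measured mean transfer efficiencies.
#' @param geom a [bdna_geometry()]; its `R0` is the starting value.
#' @param interval search interval for `R0` in nm.
#' @return list with `R0`, approximate `se` and the residual sum of squares.
#' @export
fit_r0 <- function(delta_bp, E_mean, geom = bdna_geometry(),
                   interval = c(3, 9)) {
  stop_if_not(length(delta_bp) >= 3L, "need at least 3 separations")
  stop_if_not(length(delta_bp) == length(E_mean), "inputs must match")
  if (stats::sd(E_mean) < 1e-4)
    stop("degenerate profile: efficiencies carry no distance information",
         call. = FALSE)
  ssr <- function(R0) {
    g <- geom; g$R0 <- R0
    sum((bdna_profile(delta_bp, g)$E_mean - E_mean)^2)
  }
  opt <- stats::optimize(ssr, interval)
  h <- 0.01
  d2 <- (ssr(opt$minimum + h) - 2 * opt$objective + ssr(opt$minimum - h)) / h^2
  se <- if (is.finite(d2) && d2 > 0)
    sqrt(2 * opt$objective / max(length(E_mean) - 1, 1) / d2) else NA_real_
  list(R0 = opt$minimum, se = se, ssr = opt$objective)
}
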