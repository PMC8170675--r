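#' Two-state unfolding model on Stokes-radius data
#'
#' Denaturant-induced unfolding read out through the hydrodynamic (Stokes)
#' radius: the folded fraction follows a two-state equilibrium with a linear
#' free-energy relationship `dG(x) = m x + dG0`, the unfolded-state volume
#' grows linearly with denaturant, `v_u = m_u x + n_u`, and the observed
#' radius is the volume-weighted sphere-equivalent radius
#' `<R> = (3/(4 pi) (f v_f + (1 - f) v_u))^(1/3)`.
#'
#' The sign convention is such that `f` is the FOLDED fraction and `dG` the
#' folded-minus-unfolded free energy, so a stable protein has `dG0 < 0`.
#'
#' @param dG0 stability at zero denaturant in kJ/mol (negative = stable).
#' @param m denaturant dependence (m-value) in kJ/mol/M (> 0 destabilizing).
#' @param v_f folded-state volume in nm^3 (> 0).
#' @param m_u,n_u slope (nm^3/M) and intercept (nm^3, > 0) of the
#'   unfolded-state volume line.
#' @param RT thermal energy in kJ/mol (default 2.48 at 298 K).
#' @return An object of class `unfolding_model`.
#' @export
#' @examples
#' um <- unfolding_model(dG0 = -8.8, m = 3, v_f = 33.5, m_u = 10, n_u = 60)
#' folded_fraction(0, um)     # 0.972
#' predicted_radius(c(0, 3, 6), um)
unfolding_model <- function(dG0, m, v_f, m_u, n_u, RT = 2.48) {
  stop_if_not(v_f > 0 && n_u > 0, "'v_f' and 'n_u' must be positive")
  stop_if_not(RT > 0, "'RT' must be positive")
  structure(list(dG0 = dG0, m = m, v_f = v_f, m_u = m_u, n_u = n_u, RT = RT),
            class = "unfolding_model")
}

#' @export
print.unfolding_model <- function(x, ...) {
  cat("two-state unfolding model\n")
  cat(sprintf("  dG0 = %.2f kJ/mol, m = %.2f kJ/mol/M (midpoint %.2f M)\n",
              x$dG0, x$m, -x$dG0 / x$m))
  cat(sprintf("  v_f = %.1f nm^3, v_u = %.2f x + %.1f nm^3\n",
              x$v_f, x$m_u, x$n_u))
  invisible(x)
}

#' @rdname unfolding_model
#' @param x denaturant concentration in M (vectorized, >= 0).
#' @param model an [unfolding_model()].
#' @export
folded_fraction <- function(x, model) {
  stop_if_not(all(x >= 0), "denaturant concentrations must be non-negative")
  dG <- model$m * x + model$dG0
  stats::plogis(-dG / model$RT)
}

#' Predicted Stokes radius at a denaturant concentration
#'
#' @inheritParams folded_fraction
#' @return mean Stokes radii in nm.
#' @export
predicted_radius <- function(x, model) {
  f <- folded_fraction(x, model)
  v_u <- model$m_u * x + model$n_u
  if (any(v_u <= 0))
    stop("unfolded-state volume non-positive in the requested range",
         call. = FALSE)
  (3 / (4 * pi) * (f * model$v_f + (1 - f) * v_u))^(1 / 3)
}

#' Simulate a denaturation curve
#'
#' @param model an [unfolding_model()].
#' @param x_grid denaturant concentrations in M.
#' @param noise_sd SD of additive Gaussian noise on the radius, in nm.
#' @param seed RNG seed.
#' @return A `denaturation_curve` data frame with columns `x` and `R`.
#' @export
simulate_denaturation_curve <- function(model, x_grid, noise_sd = 0,
                                        seed = NULL) {
  stop_if_not(noise_sd >= 0, "'noise_sd' must be non-negative")
  R0 <- predicted_radius(x_grid, model)
  with_seed(seed, {
    R <- pmax(R0 + stats::rnorm(length(R0), 0, noise_sd), 1e-3)
    structure(data.frame(x = x_grid, R = R),
              class = c("denaturation_curve", "data.frame"))
  })
}

#' Fit the two-state unfolding model to a denaturation curve
#'
#' Nonlinear least squares over `(dG0, m, v_f, m_u, n_u)` with data-driven
#' starting values: the folded volume from the low-denaturant radii, the
#' unfolded-volume line from the high-denaturant third of the curve, and the
#' midpoint from the concentration at the half-radius.
#'
#' @param curve data frame with columns `x` (M) and `R` (nm), at least 6
#'   points spanning the transition.
#' @param RT thermal energy in kJ/mol.
#' @return An `unfolding_fit`: the fitted [unfolding_model()], coefficient
#'   table with standard errors, and the `nls` object.
#' @export
#' @examples
#' um <- unfolding_model(dG0 = -8.8, m = 3, v_f = 33.5, m_u = 10, n_u = 60)
#' curve <- simulate_denaturation_curve(um, seq(0, 6, by = 0.33),
#'                                      noise_sd = 0.02, seed = 1)
#' fit_unfolding(curve)
fit_unfolding <- function(curve, RT = 2.48) {
  stop_if_not(is.data.frame(curve) && all(c("x", "R") %in% names(curve)),
              "'curve' needs columns x and R")
  stop_if_not(nrow(curve) >= 6L, "need at least 6 points")
  curve <- curve[order(curve$x), ]
  if (diff(range(curve$R)) < 0.05 * stats::median(curve$R))
    stop("no unfolding transition detected in the radius range",
         call. = FALSE)
  vol <- 4 * pi / 3 * curve$R^3
  n <- nrow(curve)
  lo <- curve[seq_len(max(2L, floor(n / 4))), ]
  hi <- curve[seq.int(n - max(2L, floor(n / 3)) + 1L, n), ]
  v_f0 <- 4 * pi / 3 * mean(lo$R)^3
  line <- stats::lm(I(4 * pi / 3 * R^3) ~ x, data = hi)
  m_u0 <- max(stats::coef(line)[2], 1e-3)
  n_u0 <- max(stats::coef(line)[1], 1.5 * v_f0)
  Rmid <- (min(curve$R) + max(curve$R)) / 2
  x_mid0 <- curve$x[which.min(abs(curve$R - Rmid))]
  m0 <- 3
  fit <- minpack.lm::nlsLM(
    R ~ (3 / (4 * pi) * (stats::plogis(-(m * x + dG0) / RT) * v_f +
                           (1 - stats::plogis(-(m * x + dG0) / RT)) *
                             (m_u * x + n_u)))^(1 / 3),
    data = curve,
    start = list(dG0 = -m0 * x_mid0, m = m0, v_f = v_f0, m_u = m_u0, n_u = n_u0),
    lower = c(-100, 0.01, 1e-3, 0, 1e-3), upper = c(0, 100, Inf, Inf, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  model <- unfolding_model(dG0 = unname(est["dG0"]), m = unname(est["m"]),
                           v_f = unname(est["v_f"]), m_u = unname(est["m_u"]),
                           n_u = unname(est["n_u"]), RT = RT)
  structure(list(model = model, estimates = est, se = se,
                 ssr = sum(stats::resid(fit)^2), fit = fit),
            class = "unfolding_fit")
}

#' @export
print.unfolding_fit <- function(x, ...) {
  cat(sprintf("two-state unfolding fit: dG0 = %.2f +/- %.2f kJ/mol, m = %.2f kJ/mol/M\n",
              x$estimates["dG0"], x$se["dG0"], x$estimates["m"]))
  invisible(x)
}
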