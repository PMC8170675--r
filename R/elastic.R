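#' Elastic-coupling model of allosteric transmission through DNA
#'
#' Worm-like-chain description of how a local bend imposed at one
#' protein-binding box is transmitted along the double helix to a second box
#' a spacer of `ds` base pairs away. The transmitted tension decays over the
#' length `xi = sqrt(kBT lp / f)`, and the helical twist (period
#' `lambda_helix`) modulates whether the two boxes couple constructively or
#' destructively, giving the coupling free energy
#' `|dg_J|(ds) = 2 alpha^2 (lp/xi) (1 - cos(2 pi (ds + ds0)/lambda)
#' exp(-ds/xi))` under the default branch convention (see Details).
#'
#' @details
#' The kink solution of the WLC gives repulsive coupling for symmetric bends
#' and attractive coupling for antisymmetric ones. For a protein that
#' *reduces* intrinsic curvature the roles reverse, which is equivalent to a
#' switch in sign of the cosine term; with that switch, native promoters
#' whose boxes sit an integer number of helical turns apart lie on the
#' high-coupling branch and coupling decreases with spacer length. The
#' literal positive-cosine form is available via `branch = "printed"`.
#'
#' @param alpha_bend local bending angle per box in degrees, in `[0, 90)`.
#' @param xi tension decay length in bp (> 0).
#' @param lp_nm persistence length in nm (default 40).
#' @param lambda_helix helical periodicity in bp (default 10.5).
#' @param ds0 phase shift in bp (default 8; the direct gel-assay estimate is
#'   7.2 +/- 0.5 bp).
#' @param kBT thermal energy in pN nm (default 4.11, 23 C).
#' @param a,b dimensionless parameters of the Hill-exponent analogue
#'   [hill_vs_spacer()].
#' @param branch `"native_high"` (default; cosine subtracted) or
#'   `"printed"` (cosine added).
#' @return An object of class `elastic_model`.
#' @export
#' @examples
#' em <- elastic_model(alpha_bend = 24, xi = 14)
#' coupling_energy(c(8, 18, 31), em)
elastic_model <- function(alpha_bend, xi, lp_nm = 40, lambda_helix = 10.5,
                          ds0 = 8, kBT = 4.11, a = NULL, b = NULL,
                          branch = c("native_high", "printed")) {
  branch <- match.arg(branch)
  stop_if_not(xi > 0 && lp_nm > 0 && lambda_helix > 0,
              "'xi', 'lp_nm' and 'lambda_helix' must be positive")
  stop_if_not(alpha_bend >= 0 && alpha_bend < 90,
              "'alpha_bend' must lie in [0, 90) degrees")
  structure(list(alpha_bend = alpha_bend, xi = xi, lp_nm = lp_nm,
                 lp_bp = lp_nm / BP_NM, lambda_helix = lambda_helix,
                 ds0 = ds0, kBT = kBT, a = a, b = b, branch = branch),
            class = "elastic_model")
}

#' @export
print.elastic_model <- function(x, ...) {
  cat("elastic-coupling model\n")
  cat(sprintf("  bend alpha = %.2f deg/box, decay length xi = %.2f bp\n",
              x$alpha_bend, x$xi))
  cat(sprintf("  lp = %.1f nm, helix period = %.2f bp, phase ds0 = %.2f bp (%s branch)\n",
              x$lp_nm, x$lambda_helix, x$ds0, x$branch))
  tb <- tension_and_bend(x)
  cat(sprintf("  implied tension f = %.2f pN\n", tb$tension_pN))
  invisible(x)
}

cos_sign <- function(branch) if (branch == "printed") 1 else -1

#' Kink energy of two localized bends on a tensioned worm-like chain
#'
#' `dE = 2 alpha^2 (lp/xi) (1 +/- exp(-ds/xi))` in units of kB*T: the
#' enthalpic cost of two kinks of angle `alpha` separated by `ds` along a
#' WLC under tension, `+` for the symmetric (repulsive) arrangement, `-`
#' for the antisymmetric (attractive) one. Both parities share the non-zero
#' asymptote `2 alpha^2 lp / xi`, the cost of bending at each site
#' separately; the two parities bound the helically modulated
#' [coupling_energy()] curve.
#'
#' @param ds kink separation in bp (> 0).
#' @param alpha_deg kink angle in degrees.
#' @param xi decay length in bp.
#' @param lp_bp persistence length in bp (40 nm = 117.6 bp).
#' @param parity `"symmetric"` or `"antisymmetric"`.
#' @return energies in kB*T.
#' @export
#' @examples
#' kink_energy(31, alpha_deg = 24, xi = 14)   # ~3.27 kT
kink_energy <- function(ds, alpha_deg, xi, lp_bp = 40 / BP_NM,
                        parity = c("symmetric", "antisymmetric")) {
  parity <- match.arg(parity)
  stop_if_not(all(ds > 0) && xi > 0 && lp_bp > 0, "lengths must be positive")
  a <- deg2rad(alpha_deg)
  sgn <- if (parity == "symmetric") 1 else -1
  2 * a^2 * (lp_bp / xi) * (1 + sgn * exp(-ds / xi))
}

#' Inter-box coupling free energy versus spacer length
#'
#' Magnitude of the DNA-mediated coupling free energy between the two boxes,
#' `|dg_J| = 2 alpha^2 (lp/xi) (1 - cos(2 pi (ds + ds0)/lambda)
#' exp(-ds/xi))` (default branch; see [elastic_model()] for the sign
#' convention). The cosine modulation repeats with the helical period and
#' dies out with the tension decay length, leaving the single-site
#' asymptote.
#'
#' @param ds spacer length(s) in bp (> 0).
#' @param model an [elastic_model()].
#' @return coupling free energies in kB*T.
#' @export
coupling_energy <- function(ds, model) {
  stop_if_not(all(ds > 0), "'ds' must be positive")
  a <- deg2rad(model$alpha_bend)
  mod <- cos_sign(model$branch) *
    cos(2 * pi * (ds + model$ds0) / model$lambda_helix) * exp(-ds / model$xi)
  2 * a^2 * (model$lp_bp / model$xi) * (1 + mod)
}

#' Hill exponent versus spacer length (elastic-coupling form)
#'
#' `n = a (b - cos(2 pi (ds + ds0)/lambda) exp(-ds/xi))` under the default
#' branch convention: the same damped helical modulation as
#' [coupling_energy()] with empirical scale `a` and offset `b`; the
#' long-spacer plateau `a b` is the isolated-box limit.
#'
#' @param ds spacer length(s) in bp.
#' @param model an [elastic_model()] with `a` and `b` set.
#' @return Hill exponents.
#' @export
hill_vs_spacer <- function(ds, model) {
  stop_if_not(!is.null(model$a) && !is.null(model$b),
              "model needs 'a' and 'b' for the Hill-exponent form")
  mod <- cos_sign(model$branch) *
    cos(2 * pi * (ds + model$ds0) / model$lambda_helix) * exp(-ds / model$xi)
  model$a * (model$b + mod)
}

#' Spacer-length series
#'
#' Container for a measured or simulated quantity versus promoter spacer
#' length: inter-box coupling free energies (kB*T), Hill exponents, or
#' relative gel-assay bound fractions.
#'
#' @param ds spacer lengths in bp (> 0).
#' @param y observed values.
#' @param y_err optional standard errors.
#' @param kind `"energy"`, `"hill"` or `"gel_fraction"`.
#' @return A `spacer_series` data frame.
#' @export
spacer_series <- function(ds, y, y_err = NA_real_,
                          kind = c("energy", "hill", "gel_fraction")) {
  kind <- match.arg(kind)
  stop_if_not(all(ds > 0), "spacer lengths must be positive")
  stop_if_not(length(ds) == length(y), "'ds' and 'y' must match")
  structure(data.frame(ds = ds, y = y, y_err = y_err),
            kind = kind, class = c("spacer_series", "data.frame"))
}

#' Simulate a spacer-length series from the elastic model
#'
#' Evaluates [coupling_energy()], [hill_vs_spacer()] or the empirical
#' cosine-plus-exponential gel response on a spacer grid and adds Gaussian
#' noise.
#'
#' @param model an [elastic_model()].
#' @param spacers spacer lengths in bp.
#' @param noise_sd SD of additive Gaussian noise.
#' @param seed RNG seed.
#' @param kind which response to generate.
#' @param gel_coef coefficients `c(c0, c1, c2, decay)` of the gel response
#'   `y = c0 + c1 cos(2 pi (ds + ds0)/lambda) + c2 exp(-ds/decay)`.
#' @return a [spacer_series()].
#' @export
simulate_spacer_series <- function(model, spacers, noise_sd = 0, seed = NULL,
                                   kind = c("energy", "hill", "gel_fraction"),
                                   gel_coef = c(c0 = 0.45, c1 = 0.25,
                                                c2 = 0.2, decay = 15)) {
  kind <- match.arg(kind)
  y0 <- switch(kind,
               energy = coupling_energy(spacers, model),
               hill = hill_vs_spacer(spacers, model),
               gel_fraction = gel_coef[1] +
                 gel_coef[2] * cos(2 * pi * (spacers + model$ds0) / model$lambda_helix) +
                 gel_coef[3] * exp(-spacers / gel_coef[4]))
  with_seed(seed, {
    y <- y0 + stats::rnorm(length(y0), 0, noise_sd)
    spacer_series(spacers, y, y_err = if (noise_sd > 0) noise_sd else NA_real_,
                  kind = kind)
  })
}

#' Fit the elastic-coupling model to a spacer-length series
#'
#' For a Hill-exponent series, fits `(a, b, xi)` of [hill_vs_spacer()] with
#' the helical period and phase fixed; for a coupling-energy series, fits
#' the local bend angle `alpha` of [coupling_energy()] (and optionally `xi`
#' when `fix_xi = FALSE`). [fit_elastic_sequential()] chains the two, fixing
#' the decay length obtained from the Hill series in the energy fit, which
#' is the protocol used to extract the per-box bend angle from measured
#' coupling energies.
#'
#' @param series a [spacer_series()] of kind `"energy"` or `"hill"`.
#' @param xi decay length in bp (fixed value for energy fits; start value
#'   otherwise).
#' @param fix_xi keep `xi` fixed (default TRUE for energy series).
#' @param lambda_helix,ds0,lp_nm fixed geometry, as in [elastic_model()].
#' @param branch sign convention, see [elastic_model()].
#' @return An `elastic_fit` list: the fitted [elastic_model()], estimates
#'   with standard errors, and the residual sum of squares.
#' @export
#' @examples
#' s <- spacer_series(c(8, 18, 31), c(5.8, 4.5, 1.9), kind = "energy")
#' fit_elastic(s, xi = 14)    # alpha ~ 25 degrees
fit_elastic <- function(series, xi = 14, fix_xi = TRUE,
                        lambda_helix = 10.5, ds0 = 8, lp_nm = 40,
                        branch = "native_high") {
  kind <- attr(series, "kind") %||% "energy"
  ds <- series$ds; y <- series$y
  sgn <- cos_sign(branch)
  lp_bp <- lp_nm / BP_NM
  if (kind == "hill") {
    n_par <- if (fix_xi) 2L else 3L
    stop_if_not(length(ds) > n_par, "fewer points than free parameters")
    df <- data.frame(ds = ds, y = y)
    form <- if (fix_xi)
      y ~ a * (b + sgn * cos(2 * pi * (ds + ds0) / lambda_helix) * exp(-ds / xi))
    else
      y ~ a * (b + sgn * cos(2 * pi * (ds + ds0) / lambda_helix) * exp(-ds / xi_f))
    start <- if (fix_xi) list(a = 1.5, b = 1.5)
    else list(a = 1.5, b = 1.5, xi_f = xi)
    fit <- minpack.lm::nlsLM(form, data = df, start = start,
                             lower = if (fix_xi) c(1e-3, 1e-3) else c(1e-3, 1e-3, 1),
                             upper = if (fix_xi) c(Inf, Inf) else c(Inf, Inf, 200),
                             control = minpack.lm::nls.lm.control(maxiter = 500))
    est <- stats::coef(fit)
    se <- summary(fit)$coefficients[, "Std. Error"]
    xi_hat <- if (fix_xi) xi else unname(est["xi_f"])
    model <- elastic_model(alpha_bend = 0, xi = xi_hat, lp_nm = lp_nm,
                           lambda_helix = lambda_helix, ds0 = ds0,
                           a = unname(est["a"]), b = unname(est["b"]),
                           branch = branch)
    return(structure(list(model = model, kind = kind,
                          estimates = est, se = se,
                          xi = xi_hat, se_xi = if (fix_xi) NA_real_ else unname(se["xi_f"]),
                          ssr = sum(stats::resid(fit)^2), fit = fit),
                     class = "elastic_fit"))
  }
  if (kind == "energy") {
    n_par <- if (fix_xi) 1L else 2L
    stop_if_not(length(ds) > n_par, "fewer points than free parameters")
    if (fix_xi) {
      # linear in alpha^2: closed-form least squares
      h <- 2 * (lp_bp / xi) *
        (1 + sgn * cos(2 * pi * (ds + ds0) / lambda_helix) * exp(-ds / xi))
      a2 <- sum(h * y) / sum(h^2)
      stop_if_not(a2 > 0, "energy series incompatible with a real bend angle")
      alpha <- rad2deg(sqrt(a2))
      res <- y - a2 * h
      ssr <- sum(res^2)
      # delta-method standard error on alpha (degrees)
      var_a2 <- ssr / max(length(y) - 1, 1) / sum(h^2)
      se_alpha <- rad2deg(sqrt(var_a2) / (2 * sqrt(a2)))
      model <- elastic_model(alpha_bend = alpha, xi = xi, lp_nm = lp_nm,
                             lambda_helix = lambda_helix, ds0 = ds0,
                             branch = branch)
      return(structure(list(model = model, kind = kind,
                            estimates = c(alpha = alpha), se = c(alpha = se_alpha),
                            alpha = alpha, se_alpha = se_alpha,
                            xi = xi, se_xi = NA_real_, ssr = ssr),
                       class = "elastic_fit"))
    }
    df <- data.frame(ds = ds, y = y)
    fit <- minpack.lm::nlsLM(
      y ~ 2 * (pi * al / 180)^2 * (lp_bp / xi_f) *
        (1 + sgn * cos(2 * pi * (ds + ds0) / lambda_helix) * exp(-ds / xi_f)),
      data = df, start = list(al = 20, xi_f = xi),
      lower = c(0.1, 1), upper = c(89, 200),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    est <- stats::coef(fit)
    se <- summary(fit)$coefficients[, "Std. Error"]
    model <- elastic_model(alpha_bend = unname(est["al"]), xi = unname(est["xi_f"]),
                           lp_nm = lp_nm, lambda_helix = lambda_helix,
                           ds0 = ds0, branch = branch)
    return(structure(list(model = model, kind = kind, estimates = est, se = se,
                          alpha = unname(est["al"]), se_alpha = unname(se["al"]),
                          xi = unname(est["xi_f"]), se_xi = unname(se["xi_f"]),
                          ssr = sum(stats::resid(fit)^2), fit = fit),
                     class = "elastic_fit"))
  }
  stop("use fit_periodicity() for gel-fraction series", call. = FALSE)
}

#' @rdname fit_elastic
#' @param hill_series a Hill-exponent [spacer_series()].
#' @param energy_series a coupling-energy [spacer_series()].
#' @export
fit_elastic_sequential <- function(hill_series, energy_series, xi = 14,
                                   lambda_helix = 10.5, ds0 = 8, lp_nm = 40,
                                   branch = "native_high") {
  f1 <- fit_elastic(hill_series, xi = xi, fix_xi = FALSE,
                    lambda_helix = lambda_helix, ds0 = ds0, lp_nm = lp_nm,
                    branch = branch)
  f2 <- fit_elastic(energy_series, xi = f1$xi, fix_xi = TRUE,
                    lambda_helix = lambda_helix, ds0 = ds0, lp_nm = lp_nm,
                    branch = branch)
  model <- f2$model
  model$a <- f1$model$a
  model$b <- f1$model$b
  structure(list(model = model, hill_fit = f1, energy_fit = f2,
                 xi = f1$xi, se_xi = f1$se_xi,
                 alpha = f2$alpha, se_alpha = f2$se_alpha),
            class = "elastic_fit_sequential")
}

#' @export
print.elastic_fit <- function(x, ...) {
  cat(sprintf("elastic-coupling fit (%s series)\n", x$kind))
  if (!is.null(x$alpha))
    cat(sprintf("  alpha = %.2f +/- %.2f deg/box", x$alpha, x$se_alpha))
  if (!is.na(x$xi))
    cat(sprintf("  xi = %.2f%s bp",
                x$xi, if (is.na(x$se_xi)) " (fixed)" else sprintf(" +/- %.2f", x$se_xi)))
  cat(sprintf("  (SSR %.4g)\n", x$ssr))
  invisible(x)
}

#' @export
print.elastic_fit_sequential <- function(x, ...) {
  cat("sequential elastic-coupling fit\n")
  cat(sprintf("  stage 1 (Hill series): xi = %.2f +/- %.2f bp\n", x$xi, x$se_xi))
  cat(sprintf("  stage 2 (energy series, xi fixed): alpha = %.2f +/- %.2f deg/box\n",
              x$alpha, x$se_alpha))
  invisible(x)
}

#' Tension and mean bend implied by an elastic model
#'
#' The decay length corresponds to a tension `f = kBT lp / xi^2` (with `xi`
#' converted to nm at 0.34 nm/bp), and the mean bend per base pair over a
#' promoter span covering both boxes is `2 alpha / span`.
#'
#' @param model an [elastic_model()].
#' @param span_bp box-to-box promoter span in bp (default 44).
#' @return list with `tension_pN` and `mean_bend_deg_bp`.
#' @export
#' @examples
#' tension_and_bend(elastic_model(alpha_bend = 24, xi = 14))
tension_and_bend <- function(model, span_bp = 44) {
  stop_if_not(model$xi > 0, "'xi' must be positive")
  stop_if_not(span_bp > 0, "'span_bp' must be positive")
  xi_nm <- model$xi * BP_NM
  list(tension_pN = model$kBT * model$lp_nm / xi_nm^2,
       mean_bend_deg_bp = 2 * model$alpha_bend / span_bp)
}

#' Empirical periodicity fit of a gel-assay spacer series
#'
#' Fits `y = c0 + c1 cos(2 pi (ds + ds0)/lambda) + c2 exp(-ds/c3)` to the
#' relative bound-complex fraction versus spacer length, the empirical model
#' used to read the helical modulation period and phase off a gel retardation
#' screen. Multi-start over the phase avoids the periodic local minima.
#'
#' @param series a [spacer_series()] of kind `"gel_fraction"`.
#' @param lambda helical period in bp; fixed at 10.5 unless `lambda_free`.
#' @param lambda_free also fit the period.
#' @return list with `ds0`, `se_ds0`, `lambda`, the cosine amplitude `c1`
#'   and the full coefficient set with standard errors.
#' @export
fit_periodicity <- function(series, lambda = 10.5, lambda_free = FALSE) {
  stop_if_not(nrow(series) >= 6L, "need at least 6 spacer points")
  df <- data.frame(ds = series$ds, y = series$y)
  best <- NULL
  for (ds0_start in seq(0, lambda, length.out = 8)) {
    fit <- try(minpack.lm::nlsLM(
      if (lambda_free)
        y ~ c0 + c1 * cos(2 * pi * (ds + ds0) / lam) + c2 * exp(-ds / c3)
      else
        y ~ c0 + c1 * cos(2 * pi * (ds + ds0) / lambda) + c2 * exp(-ds / c3),
      data = df,
      start = c(list(c0 = mean(df$y), c1 = stats::sd(df$y), c2 = 0.1,
                     c3 = 15, ds0 = ds0_start),
                if (lambda_free) list(lam = lambda)),
      lower = c(-Inf, 0, -Inf, 1, -lambda, if (lambda_free) 5),
      upper = c(Inf, Inf, Inf, 500, 2 * lambda, if (lambda_free) 20),
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    ssr <- sum(stats::resid(fit)^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  stop_if_not(!is.null(best), "periodicity fit did not converge")
  est <- stats::coef(best$fit)
  se <- summary(best$fit)$coefficients[, "Std. Error"]
  lam_hat <- if (lambda_free) unname(est["lam"]) else lambda
  ds0_hat <- unname(est["ds0"]) %% lam_hat
  list(ds0 = ds0_hat, se_ds0 = unname(se["ds0"]),
       lambda = lam_hat,
       se_lambda = if (lambda_free) unname(se["lam"]) else NA_real_,
       c1 = unname(est["c1"]),
       coefficients = est, se = se, ssr = best$ssr, fit = best$fit)
}
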