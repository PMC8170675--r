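#' Sequential (KNF-type) cooperative binding model for boxed promoters
#'
#' A promoter carries one or two binding boxes with two transcription-factor
#' sites each. The first ligand binds any site with microscopic association
#' constant `K`; the second ligand binds only into a box that already holds
#' one, with `sigma`-fold enhanced affinity (intra-box cooperativity through
#' protein-protein contacts); once the first box is saturated, binding at
#' the second box is enhanced `J`-fold (inter-box cooperativity transmitted
#' through the DNA). Parameters are handled as free energies in units of
#' kB*T: `K = exp(-dg_K)` (per nM of free ligand), `sigma = exp(-dg_sigma)`,
#' `J = exp(-dg_J)`; `-dg_J` is the DNA-mediated coupling free energy
#' between the boxes.
#'
#' @param dg_K association free energy per site (kB*T, referenced to 1 nM).
#' @param dg_sigma intra-box cooperativity free energy (kB*T; negative =
#'   cooperative).
#' @param dg_J inter-box coupling free energy (kB*T; negative = cooperative).
#'   Unused for `n_boxes = 1`.
#' @param n_boxes 1 or 2.
#' @return An object of class `knf_model`.
#' @export
#' @examples
#' m <- knf_model(dg_K = 4, dg_sigma = -3, dg_J = -4.5)
#' knf_fraction(c(10, 50, 200), m)
knf_model <- function(dg_K, dg_sigma, dg_J = NULL, n_boxes = 2L) {
  stop_if_not(n_boxes %in% c(1L, 2L), "'n_boxes' must be 1 or 2")
  if (n_boxes == 2L)
    stop_if_not(!is.null(dg_J), "two-box model requires 'dg_J'")
  structure(list(dg_K = dg_K, dg_sigma = dg_sigma,
                 dg_J = if (n_boxes == 2L) dg_J else NULL,
                 n_boxes = as.integer(n_boxes)),
            class = "knf_model")
}

#' @export
print.knf_model <- function(x, ...) {
  cat(sprintf("KNF binding model (%d box%s)\n", x$n_boxes,
              if (x$n_boxes > 1) "es" else ""))
  cat(sprintf("  dg_K = %.3f kT (K = %.3g /nM)\n", x$dg_K, exp(-x$dg_K)))
  cat(sprintf("  dg_sigma = %.3f kT (sigma = %.3g)\n", x$dg_sigma,
              exp(-x$dg_sigma)))
  if (!is.null(x$dg_J))
    cat(sprintf("  dg_J = %.3f kT (J = %.3g, coupling -dg_J = %.3f kT)\n",
                x$dg_J, exp(-x$dg_J), -x$dg_J))
  invisible(x)
}

#' Fraction of fully bound promoter under the KNF model
#'
#' Two boxes: `f = J^2 sigma^2 s^4 / (1 + 4s + 2 sigma s^2 + 4 J sigma s^3 +
#' J^2 sigma^2 s^4)`; isolated box: `f = sigma s^2 / (1 + 2s + sigma s^2)`,
#' with `s = K x`. Valid in the limit of promoter concentration much below
#' `1/K` (no ligand depletion), the regime of picomolar promoter
#' concentrations used in single-molecule titrations.
#'
#' @param x free ligand concentration in nM (vectorized, >= 0).
#' @param model a [knf_model()].
#' @return fraction(s) of fully bound promoter in `[0, 1]`.
#' @export
knf_fraction <- function(x, model) {
  stop_if_not(all(x >= 0), "concentrations must be non-negative")
  s <- exp(-model$dg_K) * x
  sig <- exp(-model$dg_sigma)
  if (model$n_boxes == 1L)
    return(sig * s^2 / (1 + 2 * s + sig * s^2))
  J <- exp(-model$dg_J)
  top <- J^2 * sig^2 * s^4
  top / (1 + 4 * s + 2 * sig * s^2 + 4 * J * sig * s^3 + top)
}

#' Enumerate the microscopic binding states of the KNF model
#'
#' Lists every allowed configuration of the two-box, four-site promoter with
#' its statistical weight: one empty state (weight 1), four singly-bound
#' states (`s` each), two fully-occupied-box doubles (`sigma s^2` each;
#' cross-box doubles are forbidden by the sequential mechanism), four
#' triples (`J sigma s^3` each) and the saturated state
#' (`J^2 sigma^2 s^4`). The weights sum to the binding polynomial
#' `Q = 1 + 4s + 2 sigma s^2 + 4 J sigma s^3 + J^2 sigma^2 s^4`, and the
#' normalized saturated weight reproduces [knf_fraction()]; this enumeration
#' is the exhaustive oracle for the closed-form expressions and the sampling
#' distribution for occupancy statistics.
#'
#' @param x free ligand concentration in nM (scalar).
#' @param model a [knf_model()] (two-box models only for the full 12-state
#'   enumeration; single-box models give 4 states).
#' @return data frame with columns `state`, `i` (number of bound ligands),
#'   `weight` and `prob`.
#' @export
enumerate_states <- function(x, model) {
  stop_if_not(length(x) == 1L && x >= 0, "'x' must be a single non-negative value")
  s <- exp(-model$dg_K) * x
  sig <- exp(-model$dg_sigma)
  if (model$n_boxes == 1L) {
    st <- data.frame(
      state = c("empty", "site1", "site2", "full"),
      i = c(0L, 1L, 1L, 2L),
      weight = c(1, s, s, sig * s^2))
  } else {
    J <- exp(-model$dg_J)
    st <- data.frame(
      state = c("empty",
                "P1", "P2", "P3", "P4",
                "P12", "P34",
                "P123", "P124", "P134", "P234",
                "P1234"),
      i = c(0L, rep(1L, 4), rep(2L, 2), rep(3L, 4), 4L),
      weight = c(1, rep(s, 4), rep(sig * s^2, 2),
                 rep(J * sig * s^3, 4), J^2 * sig^2 * s^4))
  }
  st$prob <- st$weight / sum(st$weight)
  st
}

#' Hill binding isotherm
#'
#' `f = x^n / (K_Hill^n + x^n)`: the empirical cooperative isotherm whose
#' exponent `n` is a lower bound on the number of thermodynamically coupled
#' sites.
#'
#' @param x ligand concentration (nM, vectorized).
#' @param n Hill exponent (> 0).
#' @param K_Hill effective dissociation constant (nM, > 0).
#' @return bound fraction(s).
#' @export
hill_fraction <- function(x, n, K_Hill) {
  stop_if_not(n > 0 && K_Hill > 0, "'n' and 'K_Hill' must be positive")
  x^n / (K_Hill^n + x^n)
}

#' Fit the Hill equation to a binding isotherm
#'
#' Weighted nonlinear least squares of `f = x^n / (K_Hill^n + x^n)` on the
#' bound-fraction scale (weights `1/f_err^2` when errors are supplied). The
#' transition must be spanned by the concentration grid.
#'
#' @param isotherm data frame with columns `x` (nM), `f` and optionally
#'   `f_err`.
#' @return A `hill_fit`: `n`, `K_Hill`, standard errors, covariance matrix
#'   and the underlying `nls` object.
#' @export
#' @examples
#' iso <- simulate_titration(list(n = 3.6, K_Hill = 50),
#'                           concentrations = 10^seq(0, 3, length.out = 12),
#'                           noise_sd = 0.02, seed = 1)
#' fit_hill(iso)
fit_hill <- function(isotherm) {
  stop_if_not(is.data.frame(isotherm) && all(c("x", "f") %in% names(isotherm)),
              "'isotherm' needs columns x and f")
  stop_if_not(nrow(isotherm) >= 4L, "need at least 4 concentrations")
  if (max(isotherm$f) < 0.2 || min(isotherm$f) > 0.8)
    stop("no binding transition spanned by the concentration range",
         call. = FALSE)
  w <- if ("f_err" %in% names(isotherm) && isTRUE(all(isotherm$f_err > 0)))
    1 / isotherm$f_err^2 else rep(1, nrow(isotherm))
  K0 <- isotherm$x[which.min(abs(isotherm$f - 0.5))]
  fit <- minpack.lm::nlsLM(
    f ~ x^n / (K^n + x^n), data = isotherm,
    start = list(n = 1.5, K = max(K0, min(isotherm$x[isotherm$x > 0]))),
    weights = w, lower = c(1e-3, 1e-9), upper = c(20, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  structure(list(n = unname(est["n"]), K_Hill = unname(est["K"]),
                 se_n = unname(se["n"]), se_K = unname(se["K"]),
                 cov = stats::vcov(fit), fit = fit),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: n = %.3f +/- %.3f, K_Hill = %.3g +/- %.2g nM\n",
              x$n, x$se_n, x$K_Hill, x$se_K))
  invisible(x)
}

#' Global two-stage KNF fit of box and promoter isotherms
#'
#' Mirrors the calibration protocol for DNA-mediated coupling: first the
#' isolated-box isotherms are fit globally with the single-box model, with
#' the intra-box cooperativity `dg_sigma` shared across boxes and `dg_K`
#' local to each box; then, with `dg_sigma` fixed, each two-box promoter
#' isotherm (or replicate group) is fit with the two-box model, with a
#' global `dg_J` (and local `dg_K`) per promoter.
#'
#' @param boxes list of isolated-box isotherms (data frames with `x`, `f`,
#'   optional `f_err`).
#' @param promoters list of two-box promoter isotherms; each element may be
#'   one isotherm or a list of isotherms sharing `dg_J`.
#' @return A `knf_global_fit`: stage-1 `dg_sigma` (+/- se) and per-box
#'   `dg_K`; per-promoter `dg_J` (+/- se), the coupling free energy `-dg_J`,
#'   and local `dg_K` values.
#' @export
fit_knf_global <- function(boxes, promoters = list()) {
  stop_if_not(length(boxes) >= 1L,
              "isolated-box isotherms are required to calibrate dg_sigma")
  boxes <- lapply(boxes, as.data.frame)
  wts <- function(d) if ("f_err" %in% names(d) && isTRUE(all(d$f_err > 0)))
    1 / d$f_err^2 else rep(1, nrow(d))

  # ---- stage 1: shared dg_sigma, local dg_K over isolated boxes ----
  nb <- length(boxes)
  dgK0 <- vapply(boxes, function(d)
    -log(1 / max(d$x[which.min(abs(d$f - 0.5))], 1e-6)), numeric(1))
  obj1 <- function(th) {
    dg_sigma <- th[1]
    sum(vapply(seq_len(nb), function(i) {
      m <- knf_model(dg_K = th[1 + i], dg_sigma = dg_sigma, n_boxes = 1L)
      sum(wts(boxes[[i]]) * (knf_fraction(boxes[[i]]$x, m) - boxes[[i]]$f)^2)
    }, numeric(1)))
  }
  o1 <- stats::optim(c(-2, dgK0), obj1, method = "BFGS",
                     control = list(maxit = 1000, reltol = 1e-14))
  o1 <- stats::optim(o1$par, obj1, method = "BFGS", hessian = TRUE,
                     control = list(maxit = 1000, reltol = 1e-14))
  n_obs1 <- sum(vapply(boxes, nrow, integer(1)))
  se1 <- lsq_se_from_hessian(o1$hessian, o1$value, n_obs1, length(o1$par))
  dg_sigma <- o1$par[1]

  # ---- stage 2: dg_sigma fixed; global dg_J, local dg_K per promoter ----
  prom_fits <- lapply(promoters, function(p) {
    isos <- if (is.data.frame(p)) list(as.data.frame(p)) else lapply(p, as.data.frame)
    np <- length(isos)
    dgK0p <- vapply(isos, function(d)
      -log(1 / max(d$x[which.min(abs(d$f - 0.5))], 1e-6)), numeric(1))
    obj2 <- function(th) {
      dg_J <- th[1]
      sum(vapply(seq_len(np), function(i) {
        m <- knf_model(dg_K = th[1 + i], dg_sigma = dg_sigma, dg_J = dg_J)
        sum(wts(isos[[i]]) * (knf_fraction(isos[[i]]$x, m) - isos[[i]]$f)^2)
      }, numeric(1)))
    }
    # multi-start over the coupling, then a restart: the (dg_K, dg_J)
    # trade-off direction is nearly flat at strong coupling
    o2 <- NULL
    for (dgJ0 in c(0, -2, -4, -6)) {
      cand <- stats::optim(c(dgJ0, dgK0p), obj2, method = "BFGS",
                           control = list(maxit = 1000, reltol = 1e-14))
      if (is.null(o2) || cand$value < o2$value) o2 <- cand
    }
    o2 <- stats::optim(o2$par, obj2, method = "BFGS", hessian = TRUE,
                       control = list(maxit = 1000, reltol = 1e-14))
    n_obs <- sum(vapply(isos, nrow, integer(1)))
    se <- lsq_se_from_hessian(o2$hessian, o2$value, n_obs, length(o2$par))
    list(dg_J = o2$par[1], se_dg_J = se[1], coupling = -o2$par[1],
         dg_K = o2$par[-1], se_dg_K = se[-1], ssr = o2$value)
  })

  structure(list(dg_sigma = dg_sigma, se_dg_sigma = se1[1],
                 box_dg_K = o1$par[-1], se_box_dg_K = se1[-1],
                 promoters = prom_fits, ssr_boxes = o1$value),
            class = "knf_global_fit")
}

#' @export
print.knf_global_fit <- function(x, ...) {
  cat(sprintf("global KNF fit: dg_sigma = %.3f +/- %.3f kT\n",
              x$dg_sigma, x$se_dg_sigma))
  cat(sprintf("  box dg_K: %s\n",
              paste(sprintf("%.3f", x$box_dg_K), collapse = ", ")))
  for (i in seq_along(x$promoters)) {
    p <- x$promoters[[i]]
    cat(sprintf("  promoter %d: coupling -dg_J = %.3f +/- %.3f kT\n",
                i, p$coupling, p$se_dg_J))
  }
  invisible(x)
}

#' Simulate a binding titration
#'
#' Evaluates a binding model on a concentration grid and adds truncated
#' Gaussian noise, clipped to `[0, 1]`. The model may be a [knf_model()] or
#' a Hill parameter list `list(n =, K_Hill =)`.
#'
#' @param model binding model (KNF or Hill parameters).
#' @param concentrations ligand concentrations in nM (non-empty, >= 0).
#' @param noise_sd SD of the additive noise on the bound fraction.
#' @param n_rep independent replicates per concentration.
#' @param seed RNG seed.
#' @return a `binding_isotherm` data frame with columns `x`, `f`, `f_err`,
#'   `rep`.
#' @export
simulate_titration <- function(model, concentrations, noise_sd = 0,
                               n_rep = 1L, seed = NULL) {
  stop_if_not(length(concentrations) >= 1L, "empty concentration grid")
  stop_if_not(all(concentrations >= 0), "concentrations must be non-negative")
  stop_if_not(noise_sd >= 0, "'noise_sd' must be non-negative")
  f0 <- if (inherits(model, "knf_model")) knf_fraction(concentrations, model)
  else hill_fraction(concentrations, model$n, model$K_Hill)
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_rep), function(r) {
      f <- clamp(f0 + stats::rnorm(length(f0), 0, noise_sd), 0, 1)
      data.frame(x = concentrations, f = f,
                 f_err = if (noise_sd > 0) noise_sd else NA_real_, rep = r)
    }))
    structure(out, class = c("binding_isotherm", "data.frame"))
  })
}
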