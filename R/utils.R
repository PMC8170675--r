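# internal helpers shared across modules

BP_NM <- 0.34   # axial rise per base pair used for bp <-> nm conversions

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# clamp for acos arguments and probability-like quantities
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# trapezoidal integral on a uniform or non-uniform grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# run a block with a locally-seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stop_if_not(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
              "'seed' must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# approximate standard errors for a least-squares objective from a numerical
# Hessian: var(theta) ~ 2 * sigma2 * H^-1 with H = d2 SSR / d theta2
lsq_se_from_hessian <- function(hess, ssr, n_obs, n_par) {
  dof <- max(n_obs - n_par, 1L)
  sigma2 <- ssr / dof
  cov <- try(2 * sigma2 * solve(hess), silent = TRUE)
  if (inherits(cov, "try-error")) return(rep(NA_real_, n_par))
  se <- sqrt(pmax(diag(cov), 0))
  se
}
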