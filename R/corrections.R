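#' Detection-correction parameters for two-channel smFRET
#'
#' Bundles the five correction factors needed to convert raw two-channel
#' photon counts into corrected acceptor/donor counts, plus the PIE intensity
#' factor used for stoichiometry. Channel 1 is the acceptor channel, channel 2
#' the donor channel. The defaults are typical calibration values for a
#' green/red dye pair on a confocal PIE instrument: with `gamma1` fixed at 1,
#' `gamma2 = 1.12` accounts for the relative detection efficiency of donor
#' photons, `beta_DA = 0.050` is the leakage of donor emission into the
#' acceptor channel, `beta_AD = 0.0021` the (much smaller) reverse leakage,
#' `alpha_direct = 0.049` the probability of directly exciting the acceptor
#' with the donor laser, and `gamma_PIE = 2.5` compensates the different
#' donor/acceptor excitation intensities.
#'
#' @param gamma1,gamma2 detection-efficiency factors (> 0) for channels 1 and 2.
#' @param beta_DA leakage probability of donor photons into the acceptor
#'   channel, in `[0, 1)`.
#' @param beta_AD leakage probability of acceptor photons into the donor
#'   channel, in `[0, 1)`.
#' @param alpha_direct direct-acceptor-excitation probability, in `[0, 1)`.
#' @param gamma_PIE PIE excitation-intensity correction factor (> 0).
#' @return An object of class `correction_set`.
#' @export
#' @examples
#' correction_set()                      # calibrated defaults
#' correction_set(gamma2 = 1, beta_DA = 0, beta_AD = 0, alpha_direct = 0)
correction_set <- function(gamma1 = 1, gamma2 = 1.12,
                           beta_DA = 0.050, beta_AD = 0.0021,
                           alpha_direct = 0.049, gamma_PIE = 2.5) {
  stop_if_not(gamma1 > 0 && gamma2 > 0, "gamma factors must be positive")
  stop_if_not(beta_DA >= 0 && beta_DA < 1 && beta_AD >= 0 && beta_AD < 1,
              "leakage probabilities must lie in [0, 1)")
  stop_if_not(alpha_direct >= 0 && alpha_direct < 1,
              "'alpha_direct' must lie in [0, 1)")
  stop_if_not(gamma_PIE > 0, "'gamma_PIE' must be positive")
  structure(list(gamma1 = gamma1, gamma2 = gamma2,
                 beta_DA = beta_DA, beta_AD = beta_AD,
                 alpha_direct = alpha_direct, gamma_PIE = gamma_PIE),
            class = "correction_set")
}

#' @export
print.correction_set <- function(x, ...) {
  cat("smFRET correction set\n")
  cat(sprintf("  gamma1 = %.4g, gamma2 = %.4g\n", x$gamma1, x$gamma2))
  cat(sprintf("  leakage beta_DA = %.4g, beta_AD = %.4g\n", x$beta_DA, x$beta_AD))
  cat(sprintf("  direct excitation alpha = %.4g, gamma_PIE = %.4g\n",
              x$alpha_direct, x$gamma_PIE))
  invisible(x)
}

# linear map raw (n1, n2) -> corrected (nA', nD') for background-free counts;
# used both in analysis and (inverted) by the photon simulator
correction_matrix <- function(corr) {
  a <- corr$alpha_direct
  matrix(c((1 - a) * corr$gamma1 + a * corr$beta_AD,
           -(1 - a) * corr$beta_DA - a * corr$gamma2,
           -corr$beta_AD, corr$gamma2),
         nrow = 2, byrow = TRUE)
}

#' Correct raw two-channel photon counts
#'
#' Applies the detection-efficiency/leakage matrix to background-subtracted
#' counts and then removes the direct-acceptor-excitation contribution:
#' `(nA, nD') = M (n1 - b1 T, n2 - b2 T)` with
#' `M = (gamma1, -beta_DA; -beta_AD, gamma2)`, followed by
#' `nA' = nA - alpha (nD' + nA)`. Results may be slightly negative under
#' noise and are deliberately not clipped.
#'
#' @param n1,n2 raw photon counts in the acceptor (1) and donor (2) channel.
#' @param b1,b2 background rates (photons/s) in the two channels.
#' @param T_burst burst duration in seconds (scalar or vector).
#' @param corr a [correction_set()].
#' @return A data frame with columns `nA_corr` and `nD_corr`.
#' @export
#' @examples
#' ident <- correction_set(gamma2 = 1, beta_DA = 0, beta_AD = 0,
#'                         alpha_direct = 0)
#' correct_counts(100, 100, 0, 0, 1e-3, ident)   # identity
#' correct_counts(100, 100, 0, 0, 1e-3, correction_set())
correct_counts <- function(n1, n2, b1 = 0, b2 = 0, T_burst = 0,
                           corr = correction_set()) {
  stop_if_not(all(T_burst >= 0), "burst duration must be non-negative")
  stop_if_not(all(n1 >= 0) && all(n2 >= 0), "photon counts must be non-negative")
  s1 <- n1 - b1 * T_burst
  s2 <- n2 - b2 * T_burst
  nA <- corr$gamma1 * s1 - corr$beta_DA * s2
  nD <- -corr$beta_AD * s1 + corr$gamma2 * s2
  nA <- nA - corr$alpha_direct * (nD + nA)
  data.frame(nA_corr = nA, nD_corr = nD)
}
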