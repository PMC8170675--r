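#' Ground-truth description of smFRET subpopulations
#'
#' Describes the molecular species in a simulated diffusion smFRET
#' measurement: a mixture of FRET components (for example a free and a
#' ligand-bound promoter), a fraction of donor-only molecules, and a fraction
#' of bursts in which the acceptor photobleaches mid-transit.
#'
#' @param components data frame with columns `mean_E` (mean transfer
#'   efficiency in `[0, 1]`), `width` (between-burst SD of the true E) and
#'   `weight` (mixture weight, must sum to 1).
#' @param donor_only_fraction fraction of bursts from donor-only molecules.
#' @param bleach_fraction fraction of FRET bursts with mid-burst acceptor
#'   bleaching.
#' @param donor_lifetime donor-only fluorescence lifetime in ns.
#' @param acceptor_lifetime acceptor fluorescence lifetime in ns.
#' @param background_rates length-2 vector: background rates (photons/s) in
#'   the acceptor (1) and donor (2) channel.
#' @param burst_rate mean molecule transits per second.
#' @param brightness mean donor-excitation photons per burst.
#' @return An object of class `fret_populations`.
#' @export
#' @examples
#' fret_populations(data.frame(mean_E = c(0.45, 0.75), width = 0.06,
#'                             weight = c(0.5, 0.5)))
fret_populations <- function(components,
                             donor_only_fraction = 0,
                             bleach_fraction = 0,
                             donor_lifetime = 3.8,
                             acceptor_lifetime = 1.5,
                             background_rates = c(300, 700),
                             burst_rate = 5,
                             brightness = 180) {
  stop_if_not(is.data.frame(components) &&
                all(c("mean_E", "width", "weight") %in% names(components)),
              "'components' needs columns mean_E, width, weight")
  stop_if_not(abs(sum(components$weight) - 1) < 1e-8,
              "component weights must sum to 1")
  stop_if_not(all(components$mean_E >= 0 & components$mean_E <= 1),
              "component mean_E must lie in [0, 1]")
  stop_if_not(donor_only_fraction >= 0 && donor_only_fraction <= 1 &&
                bleach_fraction >= 0 && bleach_fraction <= 1,
              "fractions must lie in [0, 1]")
  stop_if_not(all(background_rates >= 0) && burst_rate >= 0 && brightness > 0,
              "rates must be non-negative and brightness positive")
  structure(list(components = components,
                 donor_only_fraction = donor_only_fraction,
                 bleach_fraction = bleach_fraction,
                 donor_lifetime = donor_lifetime,
                 acceptor_lifetime = acceptor_lifetime,
                 background_rates = background_rates,
                 burst_rate = burst_rate,
                 brightness = brightness),
            class = "fret_populations")
}

#' Simulation/measurement configuration for PIE photon streams
#'
#' Timing layout of the pulsed-interleaved-excitation scheme: a 50-ns period
#' containing one donor and one acceptor pulse, with excitation assigned
#' purely by microtime window (donor `[0, 25)` ns, acceptor `[25, 50)` ns),
#' and photon macrotimes quantized to the counting-electronics resolution.
#'
#' @param seed integer RNG seed.
#' @param duration measurement duration in seconds.
#' @param pie_period PIE period length in ns.
#' @param donor_window,acceptor_window half-open microtime windows in ns;
#'   together they must partition the period.
#' @param time_resolution_ps macrotime quantization in ps.
#' @param mean_interphoton_us mean intra-burst photon spacing in microseconds.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, duration = 60,
                       pie_period = 50,
                       donor_window = c(0, 25),
                       acceptor_window = c(25, 50),
                       time_resolution_ps = 32,
                       mean_interphoton_us = 10) {
  stop_if_not(duration > 0, "'duration' must be positive")
  stop_if_not(time_resolution_ps > 0, "'time_resolution_ps' must be positive")
  stop_if_not(isTRUE(all.equal(donor_window[2], acceptor_window[1])) &&
                isTRUE(all.equal(acceptor_window[2], pie_period)) &&
                donor_window[1] == 0,
              "donor and acceptor windows must partition the PIE period")
  structure(list(seed = as.integer(seed), duration = duration,
                 pie_period = pie_period,
                 donor_window = donor_window,
                 acceptor_window = acceptor_window,
                 time_resolution_ps = time_resolution_ps,
                 mean_interphoton_us = mean_interphoton_us),
            class = "sim_config")
}

# exponential microtimes truncated to a window of width `w` ns
rexp_trunc <- function(n, tau, w) {
  u <- stats::runif(n)
  -tau * log(1 - u * (1 - exp(-w / tau)))
}

#' Simulate a time-tagged two-channel PIE photon stream
#'
#' Generates the photon-level raw data that the burst analysis consumes:
#' Poisson-distributed molecule transits whose donor-excitation channel split
#' follows the component's transfer efficiency after applying the forward of
#' the detection-correction model (so that analysis with the same
#' [correction_set()] recovers E), direct acceptor-excitation photons for
#' stoichiometry, uniform background in both channels, donor-only molecules
#' emitting only in the donor-excitation window, and acceptor bleaching that
#' converts acceptor-channel photons to donor-channel photons after a
#' uniformly-distributed switch time within the burst (producing positive
#' burst asymmetry). Donor microtimes are drawn from an exponential with
#' lifetime `tau_D * (1 - E)`.
#'
#' @param truth a [fret_populations()] object.
#' @param cfg a [sim_config()] object.
#' @param corr the [correction_set()] assumed by the downstream analysis.
#' @return A `photon_stream`: data frame with columns `macrotime_s`,
#'   `channel` (1 = acceptor, 2 = donor) and `microtime_ns`, with the
#'   per-burst ground truth attached as attribute `"truth"`.
#' @export
#' @examples
#' truth <- fret_populations(data.frame(mean_E = 0.5, width = 0, weight = 1))
#' ps <- simulate_photon_stream(truth, sim_config(seed = 7, duration = 5))
#' head(ps)
simulate_photon_stream <- function(truth, cfg, corr = correction_set()) {
  stop_if_not(inherits(truth, "fret_populations"), "'truth' must be fret_populations")
  stop_if_not(inherits(cfg, "sim_config"), "'cfg' must be sim_config")
  with_seed(cfg$seed, {
    dw <- cfg$donor_window
    aw <- cfg$acceptor_window
    w_d <- dw[2] - dw[1]
    w_a <- aw[2] - aw[1]
    Cmat <- correction_matrix(corr)
    Cinv <- solve(Cmat)

    n_bursts <- stats::rpois(1, truth$burst_rate * cfg$duration)
    bursts <- NULL
    mt <- ch <- micro <- numeric(0)
    if (n_bursts > 0) {
      start <- sort(stats::runif(n_bursts, 0, cfg$duration))
      is_do <- stats::runif(n_bursts) < truth$donor_only_fraction
      comp <- sample.int(nrow(truth$components), n_bursts, replace = TRUE,
                         prob = truth$components$weight)
      E_true <- clamp(stats::rnorm(n_bursts, truth$components$mean_E[comp],
                                   truth$components$width[comp]), 1e-3, 1 - 1e-3)
      E_true[is_do] <- 0
      bleach <- !is_do & stats::runif(n_bursts) < truth$bleach_fraction
      u_bleach <- stats::runif(n_bursts)      # switch position within burst

      # raw channel-1 probability realizing E after the forward corrections;
      # donor-only molecules carry no acceptor, so the direct-excitation
      # term does not apply to them (leakage only)
      raw <- Cinv %*% rbind(E_true, 1 - E_true)
      raw <- pmax(raw, 0)
      p1 <- raw[1, ] / colSums(raw)
      if (any(is_do)) {
        Mmat <- matrix(c(corr$gamma1, -corr$beta_DA,
                         -corr$beta_AD, corr$gamma2), nrow = 2, byrow = TRUE)
        raw_do <- pmax(solve(Mmat, c(0, 1)), 0)
        p1[is_do] <- raw_do[1] / sum(raw_do)
      }

      n_dex <- stats::rpois(n_bursts, truth$brightness)
      n_aex <- ifelse(is_do, 0L,
                      stats::rpois(n_bursts, truth$brightness / corr$gamma_PIE))

      per <- vector("list", n_bursts)
      spacing <- cfg$mean_interphoton_us * 1e-6
      for (k in seq_len(n_bursts)) {
        nd <- n_dex[k]; na <- n_aex[k]
        n_tot <- nd + na
        if (n_tot == 0L) next
        t_rel <- cumsum(stats::rexp(n_tot, 1 / spacing))
        is_dex <- rep(c(TRUE, FALSE), c(nd, na))
        if (n_tot > 1L) is_dex <- is_dex[sample.int(n_tot)]
        T_k <- t_rel[n_tot]
        chan <- integer(n_tot)
        chan[is_dex] <- ifelse(stats::runif(nd) < p1[k], 1L, 2L)
        chan[!is_dex] <- 1L
        dex_E <- rep(E_true[k], n_tot)
        keep <- rep(TRUE, n_tot)
        if (bleach[k]) {
          t_sw <- u_bleach[k] * T_k
          late <- t_rel > t_sw
          # acceptor dead: FRET photons revert to donor channel, direct
          # acceptor excitation ceases
          flip <- late & is_dex & chan == 1L
          chan[flip] <- 2L
          dex_E[flip] <- 0          # donor no longer quenched
          keep[late & !is_dex] <- FALSE
        }
        mic <- numeric(n_tot)
        d2 <- is_dex & chan == 2L
        d1 <- is_dex & chan == 1L
        mic[d2] <- dw[1] + rexp_trunc(sum(d2), truth$donor_lifetime *
                                        pmax(1 - dex_E[d2], 1e-3), w_d)
        mic[d1] <- dw[1] + rexp_trunc(sum(d1), truth$acceptor_lifetime, w_d)
        mic[!is_dex] <- aw[1] + rexp_trunc(sum(!is_dex), truth$acceptor_lifetime, w_a)
        per[[k]] <- cbind(start[k] + t_rel[keep], chan[keep], mic[keep])
      }
      per <- do.call(rbind, per)
      if (!is.null(per)) {
        mt <- per[, 1]; ch <- per[, 2]; micro <- per[, 3]
      }
      bursts <- data.frame(start = start, component = comp, E_true = E_true,
                           donor_only = is_do, bleached = bleach,
                           n_dex = n_dex, n_aex = n_aex)
    }

    # uniform background, flat over the full PIE period
    nb <- stats::rpois(2, truth$background_rates * cfg$duration)
    if (sum(nb) > 0) {
      bg_t <- stats::runif(sum(nb), 0, cfg$duration)
      bg_ch <- rep(c(1L, 2L), nb)
      bg_mic <- stats::runif(sum(nb), 0, cfg$pie_period)
      mt <- c(mt, bg_t); ch <- c(ch, bg_ch); micro <- c(micro, bg_mic)
    }

    ord <- order(mt)
    mt <- mt[ord]; ch <- ch[ord]; micro <- micro[ord]
    # quantize to the counting resolution and enforce strictly increasing times
    res_s <- cfg$time_resolution_ps * 1e-12
    mt <- round(mt / res_s) * res_s
    dup <- c(FALSE, diff(mt) <= 0)
    stream <- data.frame(macrotime_s = mt[!dup], channel = ch[!dup],
                         microtime_ns = micro[!dup])
    structure(stream, truth = bursts, cfg = cfg,
              class = c("photon_stream", "data.frame"))
  })
}

#' @export
print.photon_stream <- function(x, ...) {
  cfg <- attr(x, "cfg")
  cat(sprintf("PIE photon stream: %d photons", nrow(x)))
  if (!is.null(cfg)) cat(sprintf(" over %.3g s", cfg$duration))
  cat(sprintf(" (%d acceptor-ch, %d donor-ch)\n",
              sum(x$channel == 1L), sum(x$channel == 2L)))
  invisible(x)
}

#' Read or write a photon stream as a columnar text table
#'
#' Plain-text exchange format: tab-separated columns `macrotime_s`,
#' `channel`, `microtime_ns` with a header line.
#'
#' @param stream a `photon_stream` (or compatible data frame).
#' @param path file path.
#' @return `read_photon_stream` returns a `photon_stream`.
#' @export
write_photon_stream <- function(stream, path) {
  utils::write.table(as.data.frame(stream)[c("macrotime_s", "channel", "microtime_ns")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_photon_stream
#' @export
read_photon_stream <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t")
  stop_if_not(all(c("macrotime_s", "channel", "microtime_ns") %in% names(x)),
              "photon stream file needs columns macrotime_s, channel, microtime_ns")
  structure(x, class = c("photon_stream", "data.frame"))
}
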