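#' Burst-search configuration
#'
#' @param dt_max maximum inter-photon time in seconds; a photon extends a
#'   burst if its inter-photon time satisfies
#'   `dt <= gamma_j * dt_max`, with `gamma_j` the detection-correction factor
#'   of its channel (ties at the threshold are retained).
#' @param min_corrected_photons a burst is identified if the corrected counts
#'   satisfy `nA' + nD' > min_corrected_photons`.
#' @param max_iterations cap on background re-estimation rounds.
#' @return An object of class `burst_search_config`.
#' @export
burst_search_config <- function(dt_max = 100e-6, min_corrected_photons = 80,
                                max_iterations = 10L) {
  stop_if_not(dt_max > 0, "'dt_max' must be positive")
  stop_if_not(min_corrected_photons > 0, "'min_corrected_photons' must be positive")
  structure(list(dt_max = dt_max,
                 min_corrected_photons = min_corrected_photons,
                 max_iterations = as.integer(max_iterations)),
            class = "burst_search_config")
}

# window masks for a photon stream given the PIE layout
pie_masks <- function(stream, donor_window = c(0, 25)) {
  dex <- stream$microtime_ns >= donor_window[1] &
    stream$microtime_ns < donor_window[2]
  list(dex = dex, aex = !dex)
}

# one pass of the sliding inter-photon-time burst search; returns candidate
# spans [i_start, i_end] over photon indices
burst_spans <- function(t, channel, corr, dt_max) {
  n <- length(t)
  if (n < 2L) return(data.frame(i_start = integer(0), i_end = integer(0)))
  gam <- ifelse(channel == 1L, corr$gamma1, corr$gamma2)
  keep <- c(FALSE, diff(t) <= gam[-1] * dt_max)
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values
  # a run of retained photons i..j is anchored by photon i-1
  data.frame(i_start = pmax(starts[ok] - 1L, 1L), i_end = ends[ok])
}

#' Identify fluorescence bursts with iterative background estimation
#'
#' Sliding-criterion burst search on a time-tagged photon stream: photon `i`
#' extends a burst iff its inter-photon time is at most
#' `gamma_j(i) * dt_max`, where `gamma_j` is the correction factor of the
#' photon's detection channel. Each candidate photon cluster is corrected via
#' [correct_counts()] (using the donor-excitation-window counts) with the
#' current background-rate estimates and retained iff
#' `nA' + nD' > min_corrected_photons`. Background rates are then
#' re-estimated from all photons outside retained bursts and the search is
#' repeated until the burst count is stable or `max_iterations` is reached;
#' the initial estimate uses all photons. Convergence is typically reached
#' within three iterations.
#'
#' @param stream a `photon_stream` (macrotimes must be non-decreasing).
#' @param corr a [correction_set()].
#' @param cfg a [burst_search_config()].
#' @param donor_window donor-excitation microtime window in ns.
#' @return A `burst_set`: data frame with one row per retained burst
#'   (photon index span, start time, duration `T`, raw counts `n1`/`n2`,
#'   PIE-resolved counts `n_DD`/`n_DA`/`n_AA`, corrected counts), with the
#'   final background rates and iteration count as attributes.
#' @export
#' @examples
#' truth <- fret_populations(data.frame(mean_E = 0.5, width = 0, weight = 1),
#'                           background_rates = c(50, 50))
#' ps <- simulate_photon_stream(truth, sim_config(seed = 3, duration = 5))
#' bs <- find_bursts(ps)
#' nrow(bs)
find_bursts <- function(stream, corr = correction_set(),
                        cfg = burst_search_config(),
                        donor_window = c(0, 25)) {
  empty <- structure(
    data.frame(i_start = integer(0), i_end = integer(0), t_start = numeric(0),
               T = numeric(0), n1 = integer(0), n2 = integer(0),
               n_DD = integer(0), n_DA = integer(0), n_AA = integer(0),
               nA_corr = numeric(0), nD_corr = numeric(0)),
    background = c(b1 = 0, b2 = 0), iterations = 0L,
    class = c("burst_set", "data.frame"))
  if (nrow(stream) == 0L) return(empty)
  t <- stream$macrotime_s
  stop_if_not(!is.unsorted(t), "photon macrotimes must be non-decreasing")
  channel <- stream$channel
  masks <- pie_masks(stream, donor_window)
  total_time <- max(t) - min(t)
  if (total_time <= 0) return(empty)

  # background rates refer to the donor-excitation window of each channel,
  # matching the counts entering the correction
  ch1_dex <- channel == 1L & masks$dex
  ch2_dex <- channel == 2L & masks$dex
  b1 <- sum(ch1_dex) / total_time
  b2 <- sum(ch2_dex) / total_time

  spans <- burst_spans(t, channel, corr, cfg$dt_max)
  if (nrow(spans) == 0L) return(empty)
  len <- spans$i_end - spans$i_start + 1L
  span_id <- rep.int(seq_len(nrow(spans)), len)
  idx <- sequence(len, from = spans$i_start)
  nspan <- nrow(spans)
  count_in <- function(mask) tabulate(span_id[mask[idx]], nbins = nspan)
  n1 <- count_in(ch1_dex)
  n2 <- count_in(ch2_dex)
  T_span <- t[spans$i_end] - t[spans$i_start]

  n_prev <- -1L
  iter <- 0L
  retained <- logical(nspan)
  while (iter < cfg$max_iterations) {
    iter <- iter + 1L
    cc <- correct_counts(n1, n2, b1, b2, T_span, corr)
    retained <- (cc$nA_corr + cc$nD_corr) > cfg$min_corrected_photons
    n_now <- sum(retained)
    # re-estimate background from photons outside retained bursts
    in_burst <- logical(length(t))
    in_burst[idx[retained[span_id]]] <- TRUE
    b1 <- sum(ch1_dex & !in_burst) / total_time
    b2 <- sum(ch2_dex & !in_burst) / total_time
    if (n_now == n_prev) break
    n_prev <- n_now
  }
  cc <- correct_counts(n1, n2, b1, b2, T_span, corr)
  retained <- (cc$nA_corr + cc$nD_corr) > cfg$min_corrected_photons

  keep <- which(retained)
  out <- data.frame(i_start = spans$i_start[keep], i_end = spans$i_end[keep],
                    t_start = t[spans$i_start[keep]], T = T_span[keep],
                    n1 = n1[keep], n2 = n2[keep],
                    n_DD = n2[keep],                       # donor ch, donor exc
                    n_DA = n1[keep],                       # acceptor ch, donor exc
                    n_AA = count_in(channel == 1L & masks$aex)[keep],
                    nA_corr = cc$nA_corr[keep], nD_corr = cc$nD_corr[keep])
  structure(out, background = c(b1 = b1, b2 = b2), iterations = iter,
            class = c("burst_set", "data.frame"))
}

#' @export
print.burst_set <- function(x, ...) {
  bg <- attr(x, "background")
  cat(sprintf("burst set: %d bursts", nrow(x)))
  if (!is.null(attr(x, "iterations")))
    cat(sprintf(" (background %.3g / %.3g photons/s, %d search iterations)",
                bg[1], bg[2], attr(x, "iterations")))
  cat("\n")
  if ("E" %in% names(x) && nrow(x) > 0)
    cat(sprintf("  mean E = %.3f", mean(x$E, na.rm = TRUE)),
        if ("retained" %in% names(x))
          sprintf(", %d retained after filtering", sum(x$retained)) else "",
        "\n", sep = "")
  invisible(x)
}

#' Per-burst transfer efficiency, stoichiometry and asymmetry
#'
#' Fills in the derived burst quantities: transfer efficiency
#' `E = nA' / (nA' + nD')`; PIE stoichiometry
#' `S = (n'_DD + n'_DA) / (n'_DD + n'_DA + gamma_PIE * n_AA)` (the corrected
#' donor-excitation signal over the total including direct acceptor
#' excitation); burst asymmetry `alpha_DA = <t_D> - <t_A>`, the difference of
#' the mean within-burst arrival times of donor-channel and acceptor-channel
#' donor-excitation photons (positive when the acceptor bleaches mid-burst);
#' and its shot-noise standard deviation
#' `sigma_DA = T / (2 sqrt(3)) * (1/nD' + 1/nA')^(1/2)`. Also records the
#' mean donor microtime (proportional to the donor lifetime in the presence
#' of acceptor).
#'
#' @param bursts a `burst_set` from [find_bursts()].
#' @param stream the `photon_stream` the bursts were found in.
#' @param corr a [correction_set()].
#' @param donor_window donor-excitation microtime window in ns.
#' @return The `burst_set` with columns `E`, `S`, `alpha_DA`, `sigma_DA`,
#'   `mean_donor_microtime` added. Bursts with non-positive total corrected
#'   counts get `E = NA`.
#' @export
burst_metrics <- function(bursts, stream, corr = correction_set(),
                          donor_window = c(0, 25)) {
  n <- nrow(bursts)
  if (n == 0L) {
    bursts$E <- bursts$S <- bursts$alpha_DA <- bursts$sigma_DA <-
      bursts$mean_donor_microtime <- numeric(0)
    return(bursts)
  }
  tot <- bursts$nA_corr + bursts$nD_corr
  E <- ifelse(tot > 0, bursts$nA_corr / tot, NA_real_)
  S <- tot / (tot + corr$gamma_PIE * bursts$n_AA)
  S[tot <= 0] <- NA_real_

  masks <- pie_masks(stream, donor_window)
  t <- stream$macrotime_s
  len <- bursts$i_end - bursts$i_start + 1L
  bid <- rep.int(seq_len(n), len)
  idx <- sequence(len, from = bursts$i_start)
  rel_t <- t[idx] - rep.int(bursts$t_start, len)
  ch <- stream$channel[idx]
  dex <- masks$dex[idx]
  sum_by <- function(w, v) {
    s <- rep(0, n)
    cnt <- tabulate(bid[w], nbins = n)
    if (any(w)) {
      tmp <- rowsum(v[w], bid[w])
      s[as.integer(rownames(tmp))] <- tmp[, 1]
    }
    list(sum = s, count = cnt)
  }
  dsum <- sum_by(ch == 2L & dex, rel_t)
  asum <- sum_by(ch == 1L & dex, rel_t)
  alpha_DA <- ifelse(dsum$count > 0 & asum$count > 0,
                     dsum$sum / pmax(dsum$count, 1L) -
                       asum$sum / pmax(asum$count, 1L), NA_real_)
  sigma_DA <- rep(NA_real_, n)
  ok <- bursts$nA_corr > 0 & bursts$nD_corr > 0
  sigma_DA[ok] <- bursts$T[ok] / (2 * sqrt(3)) *
    sqrt(1 / bursts$nD_corr[ok] + 1 / bursts$nA_corr[ok])
  msum <- sum_by(ch == 2L & dex, stream$microtime_ns[idx] - donor_window[1])
  mean_mic <- ifelse(msum$count > 0, msum$sum / pmax(msum$count, 1L), NA_real_)

  bursts$E <- E
  bursts$S <- S
  bursts$alpha_DA <- alpha_DA
  bursts$sigma_DA <- sigma_DA
  bursts$mean_donor_microtime <- mean_mic
  bursts
}

#' Filter bursts for acceptor bleaching and stoichiometry
#'
#' Applies the two burst-quality filters in order: the bleaching filter keeps
#' a burst iff `|alpha_DA| <= sigma_DA` (molecules whose acceptor bleached
#' mid-transit show a positive asymmetry well beyond shot noise), and the
#' stoichiometry filter keeps bursts with `S < s_max`, removing donor-only
#' molecules (which have `S` near 1). Retention flags are recorded per burst.
#'
#' @param bursts a `burst_set` with metrics from [burst_metrics()].
#' @param s_max stoichiometry cutoff (default 0.8).
#' @return The `burst_set` with logical columns `pass_asymmetry`,
#'   `pass_stoichiometry` and `retained` added.
#' @export
filter_bursts <- function(bursts, s_max = 0.8) {
  stop_if_not(all(c("alpha_DA", "S") %in% names(bursts)),
              "run burst_metrics() before filter_bursts()")
  pass_a <- !is.na(bursts$alpha_DA) & !is.na(bursts$sigma_DA) &
    abs(bursts$alpha_DA) <= bursts$sigma_DA
  pass_s <- !is.na(bursts$S) & bursts$S < s_max
  bursts$pass_asymmetry <- pass_a
  bursts$pass_stoichiometry <- pass_s
  bursts$retained <- pass_a & pass_s
  bursts
}
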