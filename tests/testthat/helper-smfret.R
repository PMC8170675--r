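# shared smFRET fixtures: simulate, analyze, and calibrate peaks in code

analyze_stream <- function(stream, corr = correction_set(),
                           cfg = burst_search_config()) {
  bursts <- find_bursts(stream, corr, cfg)
  bursts <- burst_metrics(bursts, stream, corr)
  filter_bursts(bursts)
}

# peak position/width calibrated from a pure single-population simulation,
# as done experimentally with ligand-free and saturating samples
calibrate_pure_peak <- function(mean_E, seed, duration = 120, width = 0.06) {
  truth <- fret_populations(data.frame(mean_E = mean_E, width = width,
                                       weight = 1))
  ps <- simulate_photon_stream(truth, sim_config(seed = seed,
                                                 duration = duration))
  b <- analyze_stream(ps)
  calibrate_fret_peak(b$E[b$retained])
}

# map analyzed bursts back onto the generator's ground-truth transit table
match_truth <- function(bursts, stream) {
  tb <- attr(stream, "truth")
  tb[findInterval(bursts$t_start + 1e-9, tb$start), ]
}
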