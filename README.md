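# dnacoop

Quantifying DNA-mediated allosteric cooperativity in transcription-factor
promoter binding from single-molecule FRET.

Some bacterial master regulators (the running example is a ComK-like
competence factor) bind their promoters at two *boxes* of two sites each,
separated by an 8–31 bp spacer. Binding at one box changes the curvature of
the DNA and is felt at the other box as a change in affinity — allostery
transmitted through the double helix itself. `dnacoop` implements the full
computational chain needed to measure and model that coupling:

- **Photon-level smFRET burst analysis** — corrected counts
  (γ₂ = 1.12, β_DA = 0.050, β_AD = 0.0021, α = 0.049 defaults), iterative
  burst search (Δt ≤ γ_j·100 µs, n′_A + n′_D > 80, background re-estimated
  to convergence), bleaching filter |α_DA| ≤ σ_DA with
  σ_DA = T/(2√3)·(1/n′_D + 1/n′_A)^½, PIE stoichiometry filter S < 0.8, and
  fixed-peak histogram fits for the bound fraction.
- **Binding thermodynamics** — the sequential (KNF-type) two-box partition
  function Q = 1 + 4s + 2σs² + 4Jσs³ + J²σ²s⁴ (s = Kx) with intra-box
  cooperativity σ and inter-box coupling J, an exhaustive 12-state
  enumeration oracle, the two-stage global fit for the coupling free energy
  −Δg_J = k_BT·ln J, Hill fits, and the occupancy-distribution Hill
  statistic n = var(i)/[⟨i⟩(1 − ⟨i⟩/N)].
- **Elastic coupling** — the tensioned worm-like-chain kink model
  |Δg_J|(Δs) = 2α²(l_p/ξ)(1 − cos[2π(Δs + Δs₀)/λ]·e^(−Δs/ξ)), its
  Hill-exponent analogue, the sequential ξ-then-α fitting protocol, tension
  f = k_BT·l_p/ξ², and the empirical cosine-plus-exponential gel-periodicity
  fit.
- **FRET geometry** — lifetime–efficiency analysis of Gaussian inter-dye
  distance distributions (σ_dye = σ/√2), the cylindrical-helix B-DNA
  reference profile with the empirical midpoint↔mean polynomial, and
  rotational-isomeric-state dye clouds (3⁷ = 2187 conformers, clash
  filtering, cloud-averaged E).
- **Supporting analyses** — DNA centerline curvature profiles (0.34 nm
  segments) and two-state unfolding fits on Stokes-radius denaturation
  curves.
- **Synthetic data for everything** — photon streams with two FRET
  subpopulations, donor-only molecules and acceptor bleaching; titrations;
  occupancy counts; spacer series; centerlines; denaturation curves. All
  generators are seeded and deterministic, so the entire pipeline is
  testable without instrument data.

## Worked example

Simulate a 50/50 mixture of free (E ≈ 0.45) and bound (E ≈ 0.75) promoter,
run the full burst pipeline, and extract the bound fraction:

```r
library(dnacoop)

truth <- fret_populations(
  data.frame(mean_E = c(0.45, 0.75), width = 0.06, weight = c(0.5, 0.5)),
  donor_only_fraction = 0.1, bleach_fraction = 0.1)
ps <- simulate_photon_stream(truth, sim_config(seed = 1001, duration = 1000))
ps
#> PIE photon stream: 2249061 photons over 1e+03 s (1139938 acceptor-ch, 1109123 donor-ch)

bursts <- find_bursts(ps)
bursts
#> burst set: 5095 bursts (background 149 / 347 photons/s, 2 search iterations)
bursts <- filter_bursts(burst_metrics(bursts, ps))
sum(bursts$retained)
#> [1] 2828

# peak positions/widths fixed from ligand-free and saturating runs
# (calibrate_fret_peak(); see the methods vignette)
fit <- fit_fret_histogram(bursts$E[bursts$retained],
                          means = c(0.457, 0.748), widths = c(0.067, 0.064))
fit$bound_fraction
#> [1] 0.4743931
```

The burst search converges in two background-estimation rounds, the
asymmetry and stoichiometry filters discard bleached and donor-only bursts,
and the fixed-peak fit recovers the simulated 50/50 mixture within the
±0.03 end-to-end tolerance.

Fit the elastic-coupling model to measured coupling free energies of the
three natural promoters (spacers 8, 18, 31 bp) with the decay length fixed
at ξ = 14 bp:

```r
s <- spacer_series(ds = c(8, 18, 31), y = c(5.8, 4.5, 1.9), kind = "energy")
fit_elastic(s, xi = 14)
#> elastic-coupling fit (energy series)
#>   alpha = 25.30 +/- 1.99 deg/box  xi = 14.00 (fixed) bp  (SSR 2.709)
tension_and_bend(elastic_model(alpha_bend = 24, xi = 14), span_bp = 44)
#> $tension_pN
#> [1] 7.255844
#> $mean_bend_deg_bp
#> [1] 1.090909
```

A ~25° local bend per box, a ~7 pN effective tension, and a mean bend of
1.1°/bp across the promoter — the mechanical picture of how the allosteric
signal travels between the boxes.

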