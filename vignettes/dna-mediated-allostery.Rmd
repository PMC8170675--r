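---
title: "Models and methods: DNA-mediated allosteric cooperativity from smFRET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: DNA-mediated allosteric cooperativity from smFRET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnacoop)
```

This vignette documents the models implemented in `dnacoop`, the assumptions
behind them, the tunable parameters with their defaults, and the design
choices made where more than one reasonable implementation existed. The
running example is a bacterial competence transcription factor (ComK-like)
that binds its promoters at two "boxes" of two sites each, separated by a
spacer of 8–31 bp; binding at one box bends or un-bends the DNA and thereby
changes the affinity of the other box. The package asks, quantitatively:
how large is that DNA-mediated coupling, how does it decay and oscillate
with spacer length, and what local bending does it imply?

## 1. Photon-level smFRET burst analysis

**Model.** Diffusion-based single-molecule FRET data are time-tagged photon
streams from two detection channels (1 = acceptor, 2 = donor) under pulsed
interleaved excitation (PIE): a 50 ns period holds one donor and one
acceptor pulse, and a photon's microtime assigns its excitation window
(donor `[0, 25)` ns, acceptor `[25, 50)` ns). Raw counts are distorted by
detection efficiencies, spectral leakage and direct acceptor excitation;
`correct_counts()` applies the standard linear correction
$$\binom{n_A}{n'_D} = \begin{pmatrix}\gamma_1 & -\beta_{DA}\\
-\beta_{AD} & \gamma_2\end{pmatrix}\binom{n_1 - b_1 T}{n_2 - b_2 T},
\qquad n'_A = n_A - \alpha\,(n'_D + n_A),$$
with defaults $\gamma_1 = 1$, $\gamma_2 = 1.12$, $\beta_{DA} = 0.050$,
$\beta_{AD} = 0.0021$, $\alpha = 0.049$ — typical long-term calibration
values for a green/red dye pair. Corrected counts are deliberately not
clipped at zero, so histograms can extend slightly outside `[0, 1]`.

**Burst search.** `find_bursts()` uses the inter-photon-time criterion: a
photon extends a burst iff $\Delta t_i \le \gamma_{j(i)}\,\Delta t_{\max}$
with $\Delta t_{\max} = 100\,\mu s$ and $\gamma_j$ the correction factor of
its channel; ties at the threshold are retained. A cluster is a burst iff
its corrected donor-window counts satisfy $n'_A + n'_D > 80$. Background
rates start as total counts over total time and are re-estimated from
non-burst photons, iterating until the burst count is stable (at most 10
rounds; on all synthetic fixtures it converges in ≤ 3, matching the
experimental experience). The background rates refer to the
donor-excitation window of each channel, since those are the counts that
enter the correction.

**Filters.** Per burst, `burst_metrics()` computes
$E = n'_A/(n'_A + n'_D)$, the PIE stoichiometry
$S = (n'_{DD}+n'_{DA})/(n'_{DD}+n'_{DA}+\gamma_{PIE}\,n_{AA})$
($\gamma_{PIE} = 2.5$ by default, configurable since it is an instrument
property), the burst asymmetry
$\alpha_{DA} = \langle t_D\rangle - \langle t_A\rangle$ and its shot-noise
width $\sigma_{DA} = \tfrac{T}{2\sqrt 3}(1/n'_D + 1/n'_A)^{1/2}$.
`filter_bursts()` keeps bursts with $|\alpha_{DA}| \le \sigma_{DA}$
(removing acceptor-bleaching events, which show late donor photons and
hence positive asymmetry) and then $S < 0.8$ (removing donor-only
molecules, which sit at $S \approx 1$). Design choices here: the mean
arrival times use the raw channel photons within the donor-excitation
window (the closed form uses corrected counts only in $\sigma_{DA}$), and
no lower $S$ bound is imposed — acceptor-only molecules carry almost no
donor-window signal and rarely survive the count threshold.

**Bound fraction.** `fit_fret_histogram()` bins `E` (default bin width
0.02 over `[-0.1, 1.1]`; the binning is a convention, not a measured
value) and fits a superposition of peaks whose positions and widths are
*fixed* — calibrated on a ligand-free and a saturating measurement via
`calibrate_fret_peak()` — leaving only non-negative amplitudes free, a
linear problem. The bound fraction is the integrated area of the bound
component over the total. Gaussian peaks are the default; for
subpopulations near `E = 0` or `1` a moment-matched log-normal (mirrored
above 0.5) captures the shot-noise skew.

## 2. The synthetic photon generator

`simulate_photon_stream()` inverts the analysis model: per transit, the
donor-window channel split is chosen so that applying the *forward*
correction recovers the component's true `E`; donor-only molecules use the
leakage-only inversion (no direct-excitation term, as they carry no
acceptor); direct acceptor-excitation photons arrive in the acceptor
window at brightness reduced by $\gamma_{PIE}$; bleaching switches
acceptor-channel donor-excitation photons to the donor channel after a
uniformly distributed time within the burst and stops acceptor-window
emission — the simplest mechanism producing the positive-asymmetry
signature the filter looks for. Donor microtimes are exponential with
lifetime $\tau_D(1-E)$; macrotimes are quantized to the 32 ps electronics
grid. Defaults: 5 transits/s, 180 donor-excitation photons per transit
(placing bursts comfortably above the 80-count threshold), background
(300, 700) photons/s in the acceptor/donor channel, intra-burst photon
spacing 10 µs.

What the generator deliberately omits: diffusion through a real confocal
volume (burst sizes are Poisson, not transit-path weighted), detector
afterpulsing and dead time, and acceptor photophysics beyond a single
bleaching switch. Passing end-to-end tests therefore demonstrates the
correctness of the burst-search/correction/filter chain and its
statistical calibration — not robustness to instrument artefacts absent
from the model. At the default brightness the asymmetry filter rejects
about 95% of bleach-marked bursts; the remainder bleach so late in the
transit that they are statistically indistinguishable from intact
molecules, which leaves a small (≈ 0.01–0.02) downward bias in recovered
bound fractions that stays inside the ±0.03 end-to-end tolerance.

## 3. Lifetime–efficiency analysis

For a molecule sampling a Gaussian distance distribution $P(r)$ (mean
$\mu$, width $\sigma$, truncated at $r > 0$) slowly compared to the
fluorescence decay, `dynamic_curve()` evaluates the photon-weighted donor
lifetime $\langle\tau_{DA}\rangle = \int \tau^2 P / \int \tau P$ and the
mean efficiency $\langle E\rangle = \int E P / \int P$ with
$\tau(r) = \tau_D[1+(R_0/r)^6]^{-1}$, $E(r) = R_0^6/(R_0^6+r^6)$,
$R_0 = 5.4$ nm and $\tau_D = 3.6$–4 ns. At $\sigma = 0$ the curve is the
static line $\tau/\tau_D = 1 - E$; width lifts it above the line, and
`fit_distribution_width()` inverts that deviation with $\sigma$ as the
single free parameter, treating $\mu$ as an implicit per-point variable
(perpendicular least squares in the $(E, \tau/\tau_D)$ plane). Quadrature
runs at relative tolerance $10^{-8}$ over $\mu \pm 10\sigma$; widths below
$10^{-3}$ nm switch to the closed static form. The denominator $\int P$ is
kept explicitly rather than assumed 1 to guard against truncation effects
at small $\mu/\sigma$. For equal, spherically symmetric donor and acceptor
clouds `dye_cloud_width()` returns $\sigma_{dye} = \sigma/\sqrt 2$
(reported to two decimals, matching the precision at which such widths are
quoted: 0.76 → 0.54 nm, 0.66 → 0.47 nm).

## 4. B-DNA reference profile

`dye_distance()` evaluates the cylindrical-helix geometry
$$R_{DA} = \sqrt{(L + \Delta_{bp} z_{bp})^2 + r_A^2 + r_D^2
 - 2 r_A r_D \cos(\alpha + \Delta_{bp}\beta_{bp})}$$
with the published dye-pair calibration ($L = 0.617$ nm, $z_{bp} = 0.338$
nm, $r_A = 1.177$ nm, $r_D = 1.247$ nm, $\beta_{bp} = 36^\circ$,
$\alpha = 89.8^\circ$); separations are non-negative integers because
labelled positions are discrete bases. The midpoint efficiency
$E_{mp} = R_0^6/(R_0^6 + R_{DA}^6)$ is converted to the linker-averaged
$\langle E\rangle$ through the empirical cubic
$E_{mp} = 0.008 + 0.679\langle E\rangle + 1.470\langle E\rangle^2
 - 1.141\langle E\rangle^3$, which is strictly increasing on `[0, 1]`
(range 0.008–1.016), so `mp_to_mean()` inverts it by bracketed root
finding at tolerance $10^{-9}$. `fit_r0()` refits only $R_0$ with the
geometry fixed, as a consistency check on measured profiles. The
comparison is inherently approximate: it assumes marginal DNA distance
fluctuations and linker motion slower than transfer.

## 5. Cooperative binding thermodynamics

**KNF-type model.** A two-box promoter has four sites. The partition
function follows from sequential binding: association constant $K$ for the
first ligand in a box, $\sigma K$ for the second ligand into the same box
(protein–protein contacts), $JK$ for opening the second box once the
first is saturated, and $J\sigma K$ for the final site. With $s = Kx$:
$$Q = 1 + 4s + 2\sigma s^2 + 4J\sigma s^3 + J^2\sigma^2 s^4, \qquad
f_{\text{full}} = J^2\sigma^2 s^4 / Q,$$
and $f = \sigma s^2/(1+2s+\sigma s^2)$ for an isolated box. Cross-box
doubly-bound states are excluded by the mechanism.
`enumerate_states()` lists all 12 microstates explicitly and serves as the
exhaustive oracle: the closed forms agree with it to $10^{-12}$ over a
$10^\times10\times10$ parameter grid in the test suite. Parameters are free
energies in $k_BT$ with $K$ referenced to 1 nM (`dg_K = -ln(K\cdot 1\,nM)`);
the standard state is a convention the data cannot determine. Free ligand
is approximated by total ligand — promoter concentrations are picomolar,
orders of magnitude below $1/K$.

**Fitting protocol.** `fit_knf_global()` mirrors the experimental
calibration: isolated-box isotherms are fit globally with `dg_sigma`
shared and `dg_K` local; then, with `dg_sigma` fixed, each two-box
promoter (possibly several constructs sharing one coupling) is fit for a
global `dg_J` and local `dg_K`. Standard errors come from the numerical
Hessian of the least-squares objective. At strong coupling the likelihood
is nearly flat along the trade-off $K \to aK$, $J \to J/a^2$ (only the
sparsely populated intermediate states break it), so the optimizer runs a
small multi-start over the coupling plus a refinement restart; this
flatness, not noise alone, is why couplings near 6 $k_BT$ carry the
largest uncertainties. `fit_hill()` provides the standard empirical
comparison $f = x^n/(K_{\text{Hill}}^n + x^n)$.

**Occupancy statistic.** From a distribution $p(i)$ of ligands per
particle (e.g. single-particle image classes),
`hill_from_occupancy()` computes
$n = (\langle i^2\rangle - \langle i\rangle^2) /
 [\langle i\rangle(1 - \langle i\rangle/N)]$ — the observed variance over
the binomial variance at the same mean. It is exactly 1 for independent
sites and exactly $N$ for all-or-none binding, and on simulated KNF
occupancies agrees with the isotherm Hill exponent to a few percent.
Mapping image classes with density on only one box to $i \in \{1,2,3\}$
assumes two ligands per occupied box.

**Study conditions for recovery tests.** Titrations use 20 log-spaced
concentrations from 0.3 nM to 1.6 µM in triplicate with additive truncated
Gaussian noise of SD 0.01 on the bound fraction — the precision of a
bound-fraction estimate from a few thousand analyzed bursts — and two
two-box constructs sharing each coupling, as when both boxes are mapped
with separate FRET constructs. Under these conditions the coupling free
energies {1.9, 4.5, 5.8} $k_BT$ are recovered within 10%.

## 6. Elastic coupling through DNA

**Model.** A worm-like chain under tension $f$ transmits a localized bend
over the decay length $\xi = (k_BT\,l_p/f)^{1/2}$. Two kinks of angle
$\alpha$ separated by $\Delta s$ cost
$\Delta E = 2\alpha^2(l_p/\xi)(1 \pm e^{-\Delta s/\xi})$ in $k_BT$ —
`kink_energy()`, with $+$ for symmetric (repulsive) and $-$ for
antisymmetric (attractive) arrangements and a common single-site asymptote
$2\alpha^2 l_p/\xi$. The helical twist (period $\lambda = 10.5$ bp)
interpolates between the parities, giving the coupling free energy
`coupling_energy()`:
$$|\Delta g_J| = 2\alpha^2\frac{l_p}{\xi}\Big(1 -
 \cos\big[\tfrac{2\pi}{\lambda}(\Delta s + \Delta s_0)\big]
 e^{-\Delta s/\xi}\Big).$$
The sign of the cosine is the one genuinely open design point: the kink
derivation is written for proteins that *introduce* bending, whereas a
protein that *reduces* intrinsic curvature swaps the roles of the
symmetric and antisymmetric branches. Only the subtracted-cosine branch
places promoters whose boxes sit an integer number of turns apart on the
high-coupling side and reproduces the observed monotone decrease
5.8 → 4.5 → 1.9 $k_BT$ across the 8/18/31-bp native spacers, so it is the
default (`branch = "native_high"`); the literal added-cosine form remains
available (`branch = "printed"`). The entropic contribution of the kinks
is small and omitted. Unit conventions: 0.34 nm/bp, $k_BT = 4.11$ pN nm
(23 °C).

**Fits.** `hill_vs_spacer()` is the same damped modulation with empirical
scale/offset, $n = a(b - \cos[\cdot]e^{-\Delta s/\xi})$, whose plateau
$ab$ is the isolated-box limit. The sequential protocol
(`fit_elastic_sequential()`) extracts $\xi$ from a Hill-exponent series
first, then fixes it and fits $\alpha$ to the coupling-energy series —
with the three natural-promoter energies and $\xi = 14$ bp this gives
$\alpha \approx 25^\circ$, inside the published $24 \pm 7^\circ$ (the
published fit also used designed promoters not tabulated in the main
text). When only $\alpha$ is free the model is linear in $\alpha^2$ and is
solved in closed form. `tension_and_bend()` converts $\xi$ to the tension
$f = k_BT\,l_p/\xi^2$ (≈ 7 pN at $\xi = 14$ bp) and $\alpha$ to the mean
bend per bp over a two-box span ($2\alpha/44 \approx 1.1^\circ$/bp). The
phase shift has two estimates — 8 bp adopted as the default `ds0`, and
7.2 ± 0.5 bp from the direct gel fit — both are exposed.
`fit_periodicity()` fits the empirical gel response
$c_0 + c_1\cos[2\pi(\Delta s + \Delta s_0)/\lambda] + c_2 e^{-\Delta s/c_3}$
with a multi-start over the phase to avoid the periodic local minima.

## 7. Centerline curvature

`segment_angles()` takes an ordered 3D centerline (one point per bp), fits
an interpolating or smoothing spline per coordinate against chord-length,
resamples to arclength-uniform segments of $b = 0.34$ nm, and returns the
angles between successive segment vectors (cosines clamped to `[-1, 1]`
against rounding). Extracting centerlines from density maps is out of
scope — any tracing tool can supply the XYZ input — and the smoothing
parameter absorbs the difference between spline flavours. A straight line
gives zeros, a circular arc of radius $R$ gives $b/R$ per segment
(1.95° at $R = 10$ nm) to better than 1%, and totals are stable under
halving $b$. `average_profiles()` centre-aligns profiles (middle of the
DNA), trims to common support, and reports the mean per-bp difference
between two groups, e.g. free versus bound classes (0.6°/bp at the
simulated contrast 1.6 vs 1.0°/bp).

## 8. Two-state unfolding on Stokes radii

`predicted_radius()` combines the two-state fraction
$f = e^{-\Delta G/RT}/(1 + e^{-\Delta G/RT})$,
$\Delta G = mx + \Delta G_0$ (folded-minus-unfolded, so stability means
$\Delta G_0 < 0$), a linearly denaturant-swollen unfolded volume
$v_u = m_u x + n_u$, and the sphere-equivalent radius
$\langle R\rangle = [\tfrac{3}{4\pi}(f v_f + (1-f)v_u)]^{1/3}$, at
$RT = 2.48$ kJ/mol (298 K). `fit_unfolding()` does full nonlinear least
squares over the five parameters with data-driven starts. Recovery tests
use duplicate 25-point curves over 0–6 M with radius noise of 0.005 nm —
the precision of a calibrated dual-focus FCS radius — under which the
stability $\Delta G_0 = -8.8$ kJ/mol is recovered within 5%, consistent
with the ±0.3 kJ/mol at which such stabilities are quoted.

## 9. Dye-cloud FRET from rotational isomeric states

`enumerate_conformers()` builds all $3^7 = 2187$ conformers of a
seven-bond polyethylene linker on a tetrahedral backbone (bond length
0.153 nm, bond angle 109.5° — standard polyethylene geometry), each bond
sampling anti/gauche±; conformers are Boltzmann-weighted with a
configurable gauche penalty (default 2.1 kJ/mol — the classic
polyethylene rotamer energetics, documented as an assumption since the
source parameterization is not tabulated here). The anchor geometry
(nitrogen 132 pm from a purine C8, in-plane, N–C8–N9 = 123°) is built by
`dye_anchor_from_base()`. Chains clash-test their atoms (vdW 0.17 nm)
and the terminal fluorophore sphere against an excluded-volume atom list;
the first 0/1/4/7 linker atoms can be exempted, reflecting how unreliable
tight base packing is in low-resolution maps. `predicted_fret()` evaluates
$E = \sum_{ij} p_i q_j R_0^6/(R_0^6 + r_{ij}^6)$ over two clouds, checked
in the tests against closed-form quadrature over the pairwise-distance
density of Gaussian clouds. Orientation factors are assumed dynamically
averaged; dyes are not modelled atomistically.

## 10. Problem sizes, determinism, degenerate inputs

Every generator takes a seed and is deterministic given it; fits are
deterministic given their inputs. The test suite runs at desk scale: 5000
simulated transits for the end-to-end bound-fraction check (≈ 2 × 10⁶
photons), 120-s calibration streams, 10³-point oracle grids, 2187-conformer
enumerations, and Monte-Carlo clouds of 5000 points — sizes chosen so the
statistical tolerances (±0.03 bound fraction, 10% coupling recovery, 1%
Monte-Carlo agreement) are comfortably resolved. Degenerate inputs fail
loudly rather than silently: unsorted photon streams, non-normalized
mixtures, isotherms without a transition, flat denaturation curves,
repeated centerline points, all-clashing conformer sets and underdetermined
width fits all raise errors with actionable messages.

The command-line layer is intentionally thin: the exported functions are
the interface, `scripts/acceptance.R` reproduces the headline numbers, and
this vignette plus the README document the workflows.
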