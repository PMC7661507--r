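---
title: "Ternary-complex kinetics of disordered polyelectrolyte complexes: models, estimators, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ternary-complex kinetics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyion)
```

## The scientific problem

Prothymosin-α (P, net charge −44) and linker histone H1.0 (H, net charge
+53) form a fully disordered complex of sub-nanomolar affinity. Naively,
K_D ≈ 1 nM with diffusion-limited association (k_on ≈ 1.5×10⁹ M⁻¹s⁻¹)
implies k_off ≈ 1.7 s⁻¹, i.e. bound states lasting about a second — yet at
micromolar concentrations single-molecule FRET histograms and ¹⁵N NMR
titrations both show fast exchange on the millisecond scale. The package
implements the quantitative explanation: an additional chain can invade the
dimer, and the resulting ternary complexes (PPH, PHH) live for only ~0.5 ms,
so their transient formation opens a concentration-dependent dissociation
channel ("competitive substitution"). This vignette documents the models,
the estimators, the numerical choices, and what the synthetic-data
validation can and cannot show.

## Equilibria

All concentrations are molar and all times seconds internally; user-facing
helpers (`as_molar`) parse unit suffixes to avoid silent nano/micro mix-ups.

Three exact closed forms cover the titration experiments:

* the depletion isotherm for P\* + H ⇌ P\*H (`two_state_bound_fraction`),
  written in the rationalized-root form 2c_H/(s + √(s² − 4c_H c_P\*)) —
  the textbook (s − √·)/2c_P\* form cancels catastrophically when the
  labeled concentration is picomolar;
* the coupled competition expression for trace-labeled P\* sharing H with
  an unlabeled competitor (`competition_bound_fraction`); its denominator
  vanishes on a measure-zero set (e.g. no competitor with equal
  affinities), where we evaluate through the free-ligand route instead;
* the second-ligand isotherm for P\*H + H ⇌ P\*HH
  (`phh_bound_fraction`), valid where unbound P\* is negligible.

The five-species system (P, H, PH, PPH, PHH) is solved by
`solve_species_concentrations`. Given free c_H, the P mass balance is a
quadratic in free c_P with an analytic positive root; the remaining scalar
residual in c_H is monotone on [0, c_H_tot] and bracketed, so a 1-D root
find is exact and unconditionally convergent. We chose this nested
closed-form scheme over a damped fixed-point iteration because it has no
damping constant to tune and cannot cycle; a damped fixed point (geometric
averaging) survives in the test suite as an independent oracle. Mass
conservation is asserted to 10⁻⁹ relative (`check_conservation`).

The labeled species is treated as strictly infinitesimal everywhere except
the isotherms that explicitly carry a labeled total. With equal labeled and
unlabeled affinities of 0.73 nM and 10 nM total H1, the competition
midpoint (absolute θ = ½) computes to 18.5 nM — a useful end-to-end check
of the coupled equilibria. We adopt 0.73 nM exactly rather than a rounded
value; the midpoint is insensitive at the 0.04 nM level.

## Kinetic generators and observed rates

`build_K2`, `build_K3P`, `build_K4P`, `build_K4H` assemble the
continuous-time Markov generators for a labeled molecule, with the bulk
concentrations entering as pseudo-first-order factors (the labeled species
never depletes them, which makes the generator independent of the labeled
concentrations). The PPH complex contains two equivalent P chains; since
configurational equilibration inside the complex is orders of magnitude
faster than its millisecond lifetime, it releases either chain with equal
probability — the ½ branching factors. The branching is exposed as an
argument (`branch_PPH`) but defaulted and tested at ½. The labeled-H
generator mirrors this with ½ factors on PHH instead.

Observed rates are aggregate quantities at stationarity: the mean dwell
time of a state aggregate equals its equilibrium occupancy divided by the
equilibrium probability flux leaving it (`mean_dwell_times`, computed by
linear algebra, not simulation). For the three-state system the bound-state
dwell has a rational closed form (`tau_high_3state`); its equality with the
aggregate-flux route over random parameter draws, and with dwell times
measured on long Gillespie trajectories, are both tested.

One quantitative subtlety deserves emphasis. The dwell-based exchange rate
k_ex = 1/τ_low + 1/τ_high counts *every* excursion into the ternary
complex, but half of those excursions return the labeled chain to the state
it came from. The relaxation of the *bound fraction* — what stopped-flow
actually measures — is governed by the slowest relaxation eigenvalue of the
generator, which we find to be 0.55–0.67 × k_ex across the relevant
concentration range even when the eigenvalue separation exceeds 100×. Both
quantities are exposed (`exchange_rate` and the `relaxation_rate` attribute
of simulated stopped-flow traces); fits of simulated relaxations are
validated against the eigenvalue, and the tests assert the physically
correct ordering k_ex(2-state) < λ_slow < k_ex(dwell). The acceleration
claim is unaffected — both quantities exceed the two-state rate by orders
of magnitude at micromolar concentrations.

`global_fit_ternary` fits observed-rate curves from different methods
jointly, with k_on and k_off fixed from low-concentration measurements and
(k_on^PPH, k_off^PPH) shared across datasets in log space
(Levenberg–Marquardt on weighted residuals). The two trimer association
rate coefficients are tied, k_on^PHH = k_on^PPH, reflecting their
similarity in the underlying coarse-grained potentials of mean force.
Weighting is inverse-variance; rows without a stated uncertainty receive
relative 10% weights, and the weights are recorded in the fit object.
Identifiability is monitored through the condition number of the weighted
Jacobian.

## Photon-by-photon maximum likelihood

For immobilized-molecule traces the likelihood of a photon sequence with
colors c_i and inter-photon times τ_i is

L = **1**ᵀ ∏ᵢ **n**_{c_i} exp[(**K** − **n**_D − **n**_A) τ_i] **p**_eq,

with per-state diagonal photon-rate matrices. The two-state propagator is
evaluated in closed form from the eigenvalues of the 2×2 evolution matrix
(compiled; ~45 ns per photon), with a first-order series branch when the
eigenvalue gap underflows. The propagated vector is renormalized at every
photon and the log-norms accumulated, so the exact log-likelihood is
returned without underflow; a photon arriving in a channel with zero rate
in all states yields −∞ rather than an error. For three or more states an
eigendecomposition route is used; the two routes agree to 10⁻¹² on
two-state problems, and both are checked against a plain Taylor-series
matrix exponential oracle.

`fit_two_state` maximizes the joint likelihood over the shared kinetic
parameters and per-trace emission rates (molecules sit at different
positions in the focus, so brightness varies trace to trace). The
maximization is block-coordinate ascent in log space: conditional on the
kinetics, the emission rates are updated in closed form from the Viterbi
path (photon counts over occupancy times — the hard-assignment M step);
conditional on the emissions, Nelder–Mead maximizes over
(log k_on_obs, log k_off_obs). Three cycles suffice here because the
emission states are strongly separated (donor:acceptor rate ratios of 3:1
versus 1:3), making the Viterbi assignment essentially exact; the
final kinetic optimization runs on the exact likelihood either way.
Initialization binned-classifies each trace at 10 ms resolution.
Bootstrap errors resample whole traces with replacement (20 rounds),
refitting the shared rates warm-started at the full-data optimum.

Problem sizes: the full-scale recovery experiment uses 40 traces × 30 s at
a 20 kHz total photon rate (≈2.4×10⁷ photons, k_on_obs = 7.25 s⁻¹ at 5 nM
ligand, k_off = 1.7 s⁻¹), which completes in a few minutes; the module
tests exercise the same code at 6–12 traces × 8–20 s.

## Bursts and recurrence

Burst selection follows the two-pass rule set exactly, with strict
inequalities: photons separated by *less than* 30 µs merge into a burst;
bursts with *more than* 100 photons are sliced into half-open 100-µs
intervals from the burst start; slices with *more than* 50 photons are
kept and inherit their parent-burst identity. All four thresholds are
arguments with these defaults. Transfer-efficiency corrections
(background, crosstalk, direct excitation, detection/quantum-yield factor)
default to identity so uncorrected synthetic data round-trip exactly.

Histogram series are fit globally: peak positions and widths shared across
a titration, amplitudes free per condition. Because the model is linear in
the amplitudes, they are profiled out by linear least squares inside the
shape optimization, leaving a 4-parameter nonlinear problem regardless of
the number of histograms. Binning is 50 bins on [0, 1].

Recurrence analysis scans the time-ordered burst table for all pairs (not
only adjacent ones) whose first burst falls in an initial-E range and whose
second burst starts within a delay window; the same-molecule probability
p_same(t) is estimated by Poisson-background subtraction: the pair rate in
a long-delay window (default 5–10× the largest analysis delay, where
recurrences have decayed) estimates the unrelated-burst rate λ_bg, and
p_same(t) = max(0, 1 − λ_bg / pair_rate(t)). This estimator is our design
choice; it is validated against ground-truth molecule identities in the
synthetic burst experiment (within ±0.1 across the delay grid) rather than
against any external implementation. The relaxation model

⟨E⟩(t) = (1 − p_same)⟨E⟩_eq + p_same[⟨E⟩_eq + (⟨E⟩(0) − ⟨E⟩_eq)e^{−k_ex t}]

is fit globally over bound-start and unbound-start series with one shared
k_ex and plateau.

## Bulk observables

FCS curves are fit with the translational-diffusion × triplet model; the
focus aspect ratio can be fixed or fitted (both modes provided, since
calibration practice varies). Stopped-flow relaxations are fit as single
exponentials after max–min normalization and dead-time exclusion, with a
3σ amplitude test flagging unidentifiable (offset-only) traces.
Gradient-echo decays are fit with the Stejskal–Tanner attenuation using the
measurement constants (γ = 26752 rad G⁻¹s⁻¹, δ = 3 ms, Δ = 250 ms as
defaults); hydrodynamic radii come from reference ratios (dioxane,
R_H = 2.12 Å, for NMR; the 1:1-complex diffusion time for FCS). All fits
are exercised for idempotence on their own noise-free forward models and
for small bias under noise.

## NMR lineshapes

Transverse magnetization of an exchanging residue evolves under
(−iΩ − R₂ + K); note the damping sign of the relaxation term — an
evolution operator with +R₂ would grow exponentially, so the package
implements the physically decaying convention. Frequencies are stored as
offsets from a configurable carrier, keeping time grids short. The FID is
propagated by diagonalization of the complex evolution matrix (with a
scaling-and-squaring fallback for numerically defective matrices); the
spectrum is the real part of the one-sided Fourier integral, evaluated by
trapezoidal quadrature with an explicit Nyquist check that errors with a
suggested dwell time instead of aliasing silently. The exact resolvent
expression −Re 1ᵀ(A + iωI)⁻¹M₀ provides an independent closed-form route,
used for cross-checks and limit tests (slow exchange: population-weighted
Lorentzians; fast exchange: one Lorentzian at the weighted mean shift;
single state: FWHH = 2R₂).

Automatic FID grids use duration 5/min(R₂) and 4× Nyquist oversampling of
the largest offset; quantitative quadrature/resolvent comparisons in the
tests extend the duration to 12/min(R₂) because the ~e⁻⁵ truncation tail
is visible at the 10⁻³ level.

The titration driver solves the equilibria at each titrant concentration
and simulates spectra under either the full four-state generator or the
two-state (dimer-only) reference; the two-state branch uses the dimer-only
free-ligand concentration, since it represents the hypothesis "no ternary
complexes exist". With rate coefficients from the low-concentration
fluorescence fits, the two-state model predicts two fixed, well-separated
peaks at 20 µM-scale concentrations while the four-state model predicts a
single population-averaged peak that shifts continuously — the package's
bimodality detector (single- versus two-Lorentzian fit, F-ratio > 3 with
separation and amplitude guards) formalizes the contrast. Projection fits
report peak position and FWHH after volume normalization and constant
background removal; state frequencies of the invisible ternary species are
estimated by linear least squares of measured positions against
population-weighted model means, with the free-state frequency pinned to
the titrant-free measurement and rank-deficiency flagged.

The synthetic reporter residue (`default_spin_system`) places the bound
state 2π×20 Hz from the free state — the upper end of the observed ¹⁵N
perturbations — with ternary shifts within ±8% of the dimer shift and
disordered-protein line widths (R₂ = 6–8 s⁻¹). Real spectra have many
residues, overlapping peaks and baseline artifacts; passing tests on this
synthetic residue validate the propagator and the estimators, not peak
picking in crowded spectra.

## PMF post-processing

`wham_1d` implements the standard self-consistent histogram reweighting
with two numerical details worth noting: the bias weight of each bin is
averaged over seven sub-points rather than evaluated at the bin center
(center-point evaluation accumulates a systematic offset drift of order
1 kJ/mol across 32 windows at the default bin width), and convergence is
declared on the window offsets (10⁻⁸ kJ/mol). W is anchored to zero at the
largest sampled distance. The umbrella-window generator draws exact
Boltzmann samples of the biased density by inverse-CDF on a fine grid, so
WHAM recovery is tested against analytic ground truth with no molecular
dynamics involved: with the 32-window, 10 kJ mol⁻¹ nm⁻² protocol and 10⁴
samples per window, a double-well potential spanning ~18 kJ/mol is
recovered within 0.3 k_BT RMSD (the residual is a statistical random walk
of the window offsets; it shrinks as 1/√n and vanishes when WHAM is fed
exact expected counts).

The effective two-body potential F(r) = W(r) + 2k_BT ln r is re-zeroed
over the outer 10% of the grid, making downstream quantities invariant to
the arbitrary additive constant of W. K_D follows from
K_D⁻¹ = 4πN_A ∫₀ᶜ e^{−βF} r² dr and the association rate from the reactive
flux onto an absorbing boundary at radius b,
N_A k_on⁻¹ = ∫_b^c e^{βF}/(4πr²D) dr + (4πDc)⁻¹. Both integrals use a
doubling composite trapezoid rule: the integrands span 10+ orders of
magnitude, where generic adaptive quadrature met its tolerance estimate
but not the true error (~1% jitter). The capture radius is the outer edge
of the contiguous plateau of k_on(b) scanned from the smallest boundary
(relative change per step below 1%, default); a potential without an
attractive well has no plateau and returns NA rather than an error. b is
a required input to k_on — it is not printed by the source material — and
the capture-radius scan is reported alongside so the choice is visible.

## Synthetic-data generators and their limits

Every generator takes a mandatory seed and returns its ground truth.
Design choices: bursts last a fixed 1 ms (the average diffusion-limited
burst duration), brightness is piecewise constant within bursts (no
Gaussian-focus intensity profile), photon emission has no dead time or
afterpulsing, and recurrence structure is modeled as geometric return
visits with exponential gaps while the hidden kinetic state evolves
continuously. These reproduce the statistical structure the estimators
rely on — state-dependent Poisson photons, shot-noise-broadened E
distributions, same-molecule correlations decaying with delay — but not
instrument-specific artifacts (detector afterpulsing, out-of-focus
excursions, photobleaching kinetics beyond trace truncation). Recovery
tests therefore demonstrate estimator correctness under the model, not
robustness to every laboratory artifact.

Default study conditions follow the experiments the modules emulate:
50 pM labeled species in titrations (8 H1 concentrations spanning
0.05–20 nM, ≥1500–3000 bursts per histogram), surface kinetics at 5 nM H1
with 15/5 and 5/15 kHz donor/acceptor rates, recurrence at 1 µM H1 + 3 µM
competitor, NMR at 20 µM labeled protein, and the 32-window umbrella
protocol with 10 kJ mol⁻¹ nm⁻² force constants.

## Orchestration

`run_recipe()` chains the modules into figure-level analyses
("titration-fit", "surface-kinetics", "global-kinetics", "nmr-titration",
"pmf-rates", ...), validates configuration keys, and writes results plus a
manifest (recipe, seed, package version) to an output directory; runs are
bit-identical under a fixed seed. The package is a library, not a shell
tool — the exported functions, this vignette, and `scripts/acceptance.R`
are the intended interfaces.

## Known limitations

* Oligomers beyond ternary complexes are not modeled; at millimolar-scale
  excess of one partner the observed-rate curves would deviate.
* Ionic strength enters only through user-supplied rate coefficients per
  condition; there is no activity-coefficient model.
* The p_same estimator assumes stationary Poisson arrivals of unrelated
  molecules; strong drift in molecule flux would bias it.
* The stopped-flow single-exponential convention follows the field, but
  the three-state relaxation is bi-exponential; the dominant-eigenvalue
  prediction is exposed for honest comparison (see the dwell-versus-
  relaxation discussion above).
* Photon-level inference ignores donor/acceptor photophysics (triplet
  blinking, spectral fluctuations) inside the likelihood.
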