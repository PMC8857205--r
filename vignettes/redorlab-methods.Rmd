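---
title: "From REDOR dephasing to structural restraints: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From REDOR dephasing to structural restraints: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`redorlab` implements the quantitative chain by which magic-angle-spinning
(MAS) solid-state NMR observables on a membrane protein bound to a
fluorinated ligand become structural and dynamical conclusions:

1. **spinsim** — simulation of two-spin ¹H–¹⁹F REDOR dephasing under MAS
   (finite pulses, ¹⁹F CSA, RF inhomogeneity, powder averaging) and
   distance extraction from measured S/S₀ curves;
2. **restraints** — four-fold-ambiguous H–F distance restraints, violation
   scoring of candidate structures, and structural disambiguation;
3. **ensemble** — pairwise RMSD, ensemble-averaged distances, and
   binding-pocket water counting on multi-model PDB ensembles;
4. **exchange** — exponential fits of 2D ¹⁹F–¹⁹F exchange buildup/decay
   with SNR-propagated errors and Monte Carlo uncertainties;
5. **hydration** — saturation-recovery R₁ fits and relaxation-corrected
   water-edited intensity ratios with full error propagation;
6. **titration** — global Henderson–Hasselbalch pKa fits, composite
   chemical-shift asymmetry, water-shift temperature calibration, and ITC
   buffer-ionization extrapolation;
7. **synthetic data** — seeded generators so every stage is testable with
   no external downloads.

Upstream steps (spectral acquisition and processing, chemical-shift
assignment, torsion-angle prediction, docking, MD refinement) are out of
scope: the package consumes their tabulated or deposited outputs.

# The REDOR spin simulation

## Model

REDOR reintroduces the heteronuclear dipolar coupling, averaged out by
MAS, through a train of rotor-synchronized π pulses on the dephasing
(¹⁹F) channel.  For an isolated ¹H–¹⁹F pair the coupling is

d = (μ₀/4π) γ_H γ_F ħ / (2π r³)   [Hz],

about 2.06 kHz at r = 3.8 Å, falling as r⁻³ — this steep dependence is
what makes the dephasing a distance ruler out to ~1.5–2 nm.

The full Hamiltonian (heteronuclear dipolar term + ¹⁹F CSA + ¹⁹F RF) is
block-diagonal in the observed-spin Iz basis.  With the observed ¹H
coherence treated as ideally refocused (a spectator — its own CSA and
¹H–¹H couplings are refocused by the detection sequence and are
non-goals here), the normalized signal reduces to

S/S₀ = ⟨ Re Tr[ U₊(T) U₋(T)† ] / 2 ⟩_powder,

where U± are 2×2 propagators of the fluorine spin under
H±(t) = ω_CSA(t) Sz ± ω_D(t) Sz + ω_RF(t) Sx.  This keeps the problem in
a two-dimensional Hilbert space while treating finite pulses and the CSA
exactly.

## Numerical scheme

* **Piecewise-constant propagation**, 256 steps per rotor period by
  default.  Step boundaries are aligned to the exact pulse edges, so the
  nominal pulse length is honoured independent of the grid.  During free
  evolution the Hamiltonian is diagonal, so consecutive steps collapse
  into a single accumulated z-phase (exact within the piecewise-constant
  sampling); full 2×2 propagators are only needed during pulses.
* **Periodicity.**  With two π pulses per rotor period at τr/4 and 3τr/4
  and constant pulse phase, the Hamiltonian is periodic with the rotor
  period; the one-period propagators are raised to the number of rotor
  cycles in each mixing time.  Phase-cycled trains (xy-4/xy-8) would
  break this periodicity; they differ only in finite-pulse error
  compensation, which is below the accuracy that matters for 0.1 Å grid
  fitting, so constant phase is used.
* **Rotor synchronization.**  Mixing times must be integer multiples of
  the rotor period (tolerance 0.02 periods).  The default mixing times
  are 64, 96 and 144 rotor periods at 38 kHz MAS (1.68, 2.53, 3.79 ms) —
  commonly printed rounded to two decimals.
* **Powder averaging.**  Orientations come from a deterministic
  golden-section spiral refined by electrostatic repulsion (a
  REPULSION-style quasi-uniform set; no randomness at all), with a
  uniform rotor-phase (γ) loop.  Defaults: 320 orientations × 32 γ
  angles.  Convergence is dominated by the γ count: at 16+ γ angles,
  doubling the orientation count changes S/S₀ by < 1e-3.
* **RF inhomogeneity** is modelled as a distribution of flip angles,
  180°–145° in 5° steps, weighted by a half-Gaussian centred at 180°
  with σ = 15°; weights are normalized to 1.
* **CSA defaults.**  The ¹⁹F CSA of an aryl fluorine is taken as span
  60 ppm with asymmetry η = 1, converted to Hz at the ¹⁹F Larmor
  frequency (564.6 MHz at a 600 MHz spectrometer), with the tensor frame
  coincident with the dipolar vector ("default orientation").  All of
  these are configuration inputs; the defaults are documented
  assumptions, not measured values.
* **Oracle.**  In the ideal-pulse, zero-CSA limit the simulator
  reproduces the analytic universal REDOR curve
  ΔS/S₀ = 1 − (π√2/4) J₁·₄(√2λ) J₋₁·₄(√2λ), λ = d·T, to < 1e-3 — and
  that analytic curve is itself validated in the tests against an
  independent brute-force time-sliced phase integral.

## Distance fitting

A library of simulated curves is built on a 3.0–15.0 Å grid in 0.1 Å
steps.  For a measured curve, the RMSD between simulated and measured
S/S₀ over the available mixing times is minimized on the grid; the
uncertainty interval is the contiguous sub-threshold region
(RMSD ≤ 0.2) around the minimum.  Rules at the edges:

* equal-RMSD minima resolve to the *shorter* distance (the more
  conservative restraint);
* several disjoint sub-threshold intervals return the widest enclosing
  interval with a warning (this occurs legitimately for noisy weak
  dephasing);
* a curve indistinguishable from S/S₀ = 1 within the threshold is
  reported as a lower bound: the site is at least 10 Å from every
  fluorine, with the upper uncertainty set to 40 Å (about the longest
  distance across the dimer);
* overlapped peaks get their lower uncertainty interval widened by a
  configurable factor (default 2), clipped at the grid edge.

Note a physical subtlety: S/S₀ decreases monotonically with coupling
only below the universal-curve overshoot (λ ≲ 1.2); at stronger
coupling·time products the curve oscillates.  Grid-search fitting over
full curves is unaffected, but single-point intuition ("more dephasing =
closer") only holds in the weak regime.

# Ambiguous restraints and structure scoring

A tetrahedral ligand with four chemically equivalent fluorines makes
every measured coupling four-fold ambiguous.  Measured fits become one
ambiguous restraint each, whose effective distance in a structure is the
*minimum* over the four H–F distances (or the single assigned pair once
disambiguated).  No-dephasing fits expand to four independent
single-fluorine constraints of ≥ 10 Å each — so a campaign with 92 weak
and 24 measurable couplings yields exactly 4·92 + 24 restraints, a
bookkeeping identity the tests pin down.

Structures are scored by two criteria — the sum-total of violations and
the number of violated restraints (ties broken by the sum, then input
order) — producing two rankings, and the best structure is used to
assign each measured restraint to its nearest fluorine.  Exact distance
ties (< 1e-6 Å) are left ambiguous with a warning.  Assigning the
minimizing fluorine can never increase a violation in the reference
model, which is tested as an invariant.

# Ensemble statistics

Pairwise RMSD superposes every model pair with the Kabsch algorithm
*on the same selection being measured* (the self-consistent reading for
per-selection tables); a backbone-superpose-then-measure mode is
available via `superpose_on`.  Selections use a small grammar
(`chain:resrange:atoms`) plus presets — `backbone`, `heavy`, and
`ligand_center`, the latter operationally defined as the ligand
phosphorus and its four directly bonded carbons.

Pocket waters are counted as water oxygens within 15 Å of any ligand
atom *and* inside the z window spanned by two boundary atoms (the top
and bottom of the transmembrane bundle).  Coordinates are used in the
deposited frame; membrane alignment (z = bilayer normal) is assumed
done upstream.  The count is monotone in both the cutoff and the window,
which is tested.

# Exponential fits and Monte Carlo errors

Exchange decay/buildup (I = (Y₀−P)e^{−kt} + P), saturation recovery
(I = P(1−e^{−R₁t})) and the Henderson–Hasselbalch titration are all
*linear in their amplitude parameters at fixed rate (or pKa)*.  All
three fits therefore use separable least squares: a one-dimensional
profile over the nonlinear parameter (coarse log-spaced grid + local
refinement) with the amplitudes solved exactly at each step.  This
cannot fail to converge and needs no starting values — a deliberately
more robust equivalent of multi-start nonlinear least squares.
Constant data collapse to k = 0 with P = Y₀.  Fits are invariant under
time-unit rescaling (k rescales inversely).

Point errors follow the SNR model ε = 2·I·√(SNR_peak⁻² + SNR_norm⁻²)
(a 2σ error bar).  Parameter uncertainties use the Monte Carlo scheme:
1000 replicate datasets with each point shifted by N(0, 0.3)·ε, refit,
and the replicate standard deviation reported.  Note that 0.3 of a *2σ*
bar is 0.6σ of point noise; the convention is kept exactly as stated in
the workflow this package implements, and the tests compare the MC
spread against a covariance-matrix σ computed at the same injected
noise level.

The water-edited hydration ratio is corrected for ¹H T₁ relaxation
between the edited (t₁ = 30 ms) and equilibrated (t₂ = 325 ms) mixing
times, H = (S/S₀)·e^{R₁(t₁−t₂)}; which mixing time is t₁ vs t₂ is an
assumption recorded here (the correction formula itself does not label
them; assigning t₁ to the shorter, edited mixing gives H < S/S₀ for
R₁ > 0, the physically sensible direction).  Its uncertainty propagates
both the SNR term and σ_R₁ (Gauss error propagation), verified against
a finite-difference Jacobian.

# Titration and thermodynamics

The global pKa fit shares a single pKa across residues while every
residue keeps free endpoint shifts; ¹H and ¹⁵N data are fit separately,
with an inverse-variance combination available as a convenience
(`combine_pka`) since no principled combination rule is implied by a
shared-pKa model.  Flat series (< 1e-3 ppm range) carry no pKa
information and are excluded with a warning.  pKa recovery bias over
100 seeded synthetic datasets at 0.01 ppm noise is below 0.05.

The effective MAS sample temperature uses the water-shift calibration
T_eff(K) = 96.9·(7.83 − δ_H2O); δ = 4.89 ppm gives 285 K.  ITC
enthalpies measured in buffers of different ionization enthalpy are
regressed linearly; the intercept is the buffer-independent binding
enthalpy, the slope the number of protons released, and
−TΔS = ΔH − ΔG.

# The synthetic-data generators

The generators emulate the *statistical structure* each analysis stage
assumes, with a machine-readable truth table:

* `gen_redor_curves` — library-simulated S/S₀ at the three default
  mixing times plus Gaussian noise (σ = 0.05 by default), with a
  92-weak / 24-measurable site composition;
* `gen_toy_complex` — two idealized antiparallel poly-alanine helices
  flanking a tetrahedral four-fluorine ligand.  Chain B is chain A
  rotated 180° about y; this two-fold also maps the fluorine set onto
  itself, so per-residue minimum H–F distances agree exactly between
  chains — an exact symmetry the tests exploit.  Waters are placed in
  known counts inside/outside the pocket criteria; extra models are
  Gaussian-perturbed copies with a prescribed per-atom RMS.
* `gen_exchange` — 4-site buildup/decay at rates spanning 165–318 s⁻¹
  with plateau 0.25 and SNR-consistent noise;
* `gen_recovery`, `gen_titration` — single-exponential recovery and
  six-residue shared-pKa titrations (pKa drawn from [6, 8] per seed
  unless fixed).

What the toy data do **not** emulate: real helix geometry and packing,
spin diffusion, relaxation during REDOR, multi-spin couplings, peak
overlap, or spectral integration noise structure.  Passing round-trip
tests therefore demonstrates the correctness of the estimators under
their stated models, not spectrometer-grade realism.

# Problem sizes and runtimes

The package defaults (320 orientations × 32 γ × 8 flip angles, 256
steps/period, 121-distance grid) reproduce measurement-grade simulation
conditions; a full library builds in a few minutes on one core.  The
test suite uses a lighter, convergence-checked powder (144 × 8) for its
shared library and 233 × 16 for comparisons against the analytic curve,
which keeps the whole suite under a minute while testing the same code
paths at the same step resolution.

# Known limitations

* Two-spin approximation: multi-fluorine dephasing of one proton is
  handled only through the minimum-distance convention of the restraint
  layer, not in the spin dynamics.
* The observed spin is an ideal spectator; finite-pulse effects on the
  ¹H channel are not modelled.
* mmCIF input is not wired; multi-model PDB covers the package's I/O.
* The MC error convention (0.3 of a 2σ bar) understates classical 1σ
  parameter errors by ~40%; it is kept for fidelity with the workflow
  being reproduced and documented here.
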