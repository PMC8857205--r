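# redorlab

Solid-state NMR analysis of membrane-protein complexes with fluorinated
ligands: REDOR distance restraints, structure scoring, exchange and
hydration analysis, and pKa titration fitting.

## The problem

Magic-angle-spinning (MAS) NMR can measure distances between protein
amide protons and the fluorines of a bound fluorinated ligand (such as
tetra(4-fluorophenyl)phosphonium, F₄-TPP⁺) through REDOR: a train of
rotor-synchronized π pulses on the ¹⁹F channel reintroduces the
heteronuclear dipolar coupling, and the intensity ratio S/S₀ between
dephased and control spectra decays with mixing time at a rate set by
the H–F distance.  Turning those dephasing curves — plus ¹⁹F–¹⁹F
exchange spectra, water-edited spectra, and pH titrations — into a
ligand-bound structure and its dynamics/hydration picture requires a
chain of quantitative steps that this package implements as tested,
reusable R functions:

* **Spin simulation and distance extraction.**  Two-spin REDOR
  dephasing is simulated by piecewise-constant propagation of the ¹⁹F
  spin under its CSA, the dipolar coupling d = (μ₀/4π)·γ_Hγ_F·ħ/(2πr³),
  and the finite π-pulse train, powder-averaged over crystallite
  orientations and an RF-inhomogeneity flip-angle distribution
  (180°–145°, half-Gaussian weights, σ = 15°).  Distances are extracted
  by grid search (3.0–15.0 Å in 0.1 Å steps), minimizing the RMSD
  between simulated and measured S/S₀ with an RMSD ≤ 0.2 uncertainty
  interval; non-dephasing sites become ≥ 10 Å lower bounds (upper
  uncertainty 40 Å).
* **Ambiguous restraints and scoring.**  Each measured coupling is
  four-fold ambiguous over the chemically equivalent fluorines; the
  effective distance in a model is the minimum over the four pairs.
  Ensembles are scored by the sum-total of violations and by the number
  of violations, and the best structure disambiguates each restraint to
  its nearest fluorine.
* **Ensemble statistics.**  Kabsch superposition, average pairwise
  RMSDs, ensemble-averaged atom–atom distances, and binding-pocket
  water counts (water oxygens within 15 Å of any ligand atom and inside
  the transmembrane z window).
* **Exchange and hydration.**  Single-exponential fits
  I = (Y₀−P)e^(−kt) + P of 4-site ¹⁹F exchange curves and saturation-
  recovery R₁ fits, with 2σ point errors ε = 2I√(SNR_i⁻² + SNR_norm⁻²)
  and Monte Carlo parameter uncertainties; relaxation-corrected
  water-edited ratios H = (S/S₀)e^(R₁(t₁−t₂)) with Gauss error
  propagation.
* **Titration and thermodynamics.**  Global Henderson–Hasselbalch fits
  sharing one pKa across residues, composite shift differences
  √(½[Δω_H² + (0.10·Δω_N)²]), the water-shift temperature calibration
  T_eff = 96.9(7.83 − δ_H2O), and ITC buffer-ionization extrapolation.

A seeded synthetic-data module generates inputs with known ground truth
for every stage (including a toy antiparallel helix-dimer +
four-fluorine ligand complex), so the full pipeline runs and is tested
without downloading anything.

## Worked example

```r
library(redorlab)

## simulate the curve library and extract a distance
params <- redor_params(n_orient = 144, n_gamma = 8)   # lighter powder
lib <- build_curve_library(params)
#> REDOR curve library: 121 distances ( 3 - 15 A ), 3 mixing times

curve <- simulate_redor(spin_pair(4.3), params)
noisy <- redor_curve("S43A-H", curve$mixing_times,
                     curve$s_ratio + c(0.03, -0.02, 0.04))
fit_distance(noisy, lib)
#> S43A-H: 4.2 A [3.0, 5.7]
fit_distance(redor_curve("T56B-H", lib$mixing_times,
                         c(0.99, 1.01, 1.0)), lib)
#> T56B-H: no significant dephasing; distance >= 10.0 A (upper 40.0 A)
```

The first fit recovers the generating distance (4.3 Å) to within one
grid step, with the RMSD ≤ 0.2 interval [3.0, 5.7] Å as its
uncertainty; the flat curve triggers the lower-bound rule.

```r
## restraints, scoring, and ensemble statistics on a synthetic complex
tc <- gen_toy_complex(n_models = 4, model_rms = 0.8,
                      n_waters_inside = 12, n_waters_outside = 20, seed = 1)
rs <- build_restraints(list(fit, flat),
                       list("S43A-H" = "A:8:H", "T56B-H" = "B:3:H"),
                       tc$truth$fluorine_sites)
length(rs)      # 1 measured + 4 lower-bound constraints
#> [1] 5
score_structures(tc$ensemble, rs)$reports
#>   model sum_violation n_violations
#> 1     1     0.5648105            1
#> 2     2     0.2705393            1
#> 3     3     0.9785859            1
#> 4     4     0.3079933            1
pairwise_rmsd(tc$ensemble, "backbone")[c("mean", "sd")]
#> backbone pairwise RMSD: 0.96 +/- 0.18 A
count_pocket_waters(get_model(tc$ensemble, 1), "L:1:*", 15,
                    tc$truth$z_bound_atoms)
#> [1] 12
```

Model 2 violates the restraints least and would be used to
disambiguate the H–F assignments (`disambiguate()`); the water count
returns exactly the 12 oxygens placed inside both pocket criteria.

```r
## exchange rates and the sample-temperature calibration
ex <- gen_exchange(seed = 2)
fit_exchange(ex$mixing_times, ex$intensities[4, 4, ], ex$errors[4, 4, ],
             "diagonal", n_mc = 1000, seed = 3)
#> diagonal exchange fit: k = 319 s^-1 (sd 3.1), Y0 = 0.995, P = 0.25
effective_temperature(4.89)
#> [1] 284.886
```

The diagonal decay recovers the generating rate (318 s⁻¹) within its
Monte Carlo uncertainty, and a water shift of 4.89 ppm corresponds to a
285 K effective sample temperature.

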