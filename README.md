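# oxafoul

Quantifying serum-protein fouling on PMOXA-*b*-PDMS-*b*-PMOXA polymersomes
by fluorescence correlation spectroscopy (FCS), and characterising the
hydration structure of their membranes from atomistic slab trajectories.

Protein adsorption ("fouling", protein-corona formation) on nanoparticles
drives macrophage uptake and blood clearance. For water-filled vesicles it
is hard to measure with standard techniques; an in-situ FCS assay solves
this by labelling the *serum proteins* and mixing them with unlabelled
~100 nm polymersomes. Because FCS amplitudes weight each species by its
brightness squared, even a little label bound to bright, slowly diffusing
vesicles dominates the autocorrelation curve. The package implements the
assay's analysis and the complementary membrane-hydration observables, each
with a synthetic-data generator carrying exact ground truth, so the whole
chain is verifiable end to end.

## What it computes

**FCS fouling assay** (`fcs_model`, `fit_curve` and friends)

The triplet-corrected two-component model for 3D diffusion through a
Gaussian confocal volume,

    G(tau) = (1/N) [1 + T e^(-tau/tau_T)/(1-T)]
             sum_i f_i (1 + tau/tau_Di)^(-1) (1 + tau/(S^2 tau_Di))^(-1/2),

is fitted with **both diffusion times fixed** (fast = free labelled
protein, slow = vesicle), so only the occupancy N and the amplitude split
are free. Readouts:

* **F2** — particle fraction, the slow-component amplitude fraction × 100;
  the fouling readout.
* **CPP** — counts per particle, mean count rate / N (kHz), a brightness
  proxy that flags aggregates.
* **Stokes–Einstein sizing** — `d = k_B T / (3 pi eta D)` with
  `tau_D = w_xy^2/(4D)`, for free-dye / labelled-protein calibration.
* Aggregate exclusion (configurable F2/CPP thresholds) and
  median-per-experiment, mean ± s.e.m.-across-experiments aggregation.

**Synthetic FCS data** (`simulate_fcs_trace`, `autocorrelate_multitau`,
`autocorrelate_direct`, `generate_fcs_curve`) — Brownian-dynamics photon
traces of fast-dim + slow-bright mixtures in a periodic box (Rcpp kernel,
bit-reproducible per seed), a multi-tau correlator with a brute-force
direct-correlator oracle, and a fast closed-form curve generator.

**Membrane hydration** (`density_profile`, `membrane_thickness`,
`interface_metrics`, `rmsf`, `read_trajectory`) — cross-sectional mass
densities of PDMS / PMOXA / interfacial water / bulk water (water within
0.4 nm of any PMOXA atom is interfacial), core thickness (50%-of-plateau
crossing), interfacial water-layer FWHM, PMOXA/bulk-water cross-over
height, interfacial AUC, and PMOXA RMSF (COM-aligned, PBC-unwrapped).
Readers for multi-frame XYZ and GRO-style text trajectories, and a layered
slab generator with analytic ground truth.

**Formulation bookkeeping** (`parse_copolymer_name`,
`hydrophilic_fraction`, `blend_summary`) — ABA triblock parsing ("6-65-6"
= DPs of the blocks), hydrophilic weight fractions from repeat-unit
masses, blend mole/mass fractions and mean PMOXA DP.

## Worked example

```r
library(oxafoul)

# a fouling mixture: 60 free labelled proteins (tau_D 40 us, 4 kHz) and
# 3 protein-coated vesicles (tau_D 2 ms, 20 kHz) in a 2x2x5 um box
species <- data.frame(count = c(60, 3),
                      D = c(diffusion_from_tau_d(4e-5),
                            diffusion_from_tau_d(2e-3)),
                      brightness = c(4, 20))
cfg   <- fcs_sim_config(species, n_steps = 2^20, seed = 1)
curve <- autocorrelate_multitau(simulate_fcs_trace(cfg))
spec  <- fcs_model_spec(list(fcs_component(4e-5, 0.5, fixed_tau_d = TRUE),
                             fcs_component(2e-3, 0.5, fixed_tau_d = TRUE)))
fit_curve(curve, spec)
#> FCS fit 'multitau': N = 0.8813, tau_D = 4e-05/0.002 s, F2 = 49.60%,
#>   cpp = 2.63 kHz, red. chi2 = 0.000502, converged
100 * fcs_sim_truth(cfg)$amplitude_fractions[2]   # analytic truth: 55.56 %
```

The fitted particle fraction (49.6% on this seed; the analytic
brightness²-weighted truth is 55.6%, and the median over seeds converges
on it) says that about half the correlation amplitude comes from the slow,
vesicle-bound label — a heavily fouled sample. `cpp` is the mean count
rate per diffusing particle; values far above the free-dye control flag
aggregates.

```r
traj <- generate_membrane_trajectory(membrane_sim_config(seed = 3))
interface_metrics(density_profile(traj))
#> membrane thickness 3.993 nm; interfacial water layer 1.815 nm;
#> crossover height 3.659 nm; interfacial AUC 1789.1 kg/m^3 nm
```

The synthetic slab was built with a 2 nm core half-width, so the recovered
thickness (3.99 nm) matches the 4 nm truth; the interfacial water-layer
thickness and cross-over height grow with the brush extent, which is the
hydration signature separating long- from short-PMOXA membranes.

Config-file driven runs (with hashed-input manifests) are available through
`run_workflow()`; see `inst/cli/oxafoul.R` for a shell entry point.

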