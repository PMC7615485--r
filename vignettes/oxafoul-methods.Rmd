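---
title: "Methods: the in-situ FCS fouling assay and membrane hydration analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the in-situ FCS fouling assay and membrane hydration analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxafoul)
```

# Scope

`oxafoul` implements two computational procedures for quantifying protein
fouling on PMOXA-*b*-PDMS-*b*-PMOXA polymersomes and the hydration
structure underlying it:

1. an **in-situ FCS fouling assay** — constrained two-component fitting of
   fluorescence autocorrelation curves from mixtures of randomly labelled
   serum protein and unlabelled ~100 nm vesicles, yielding the particle
   fraction *F2*, counts-per-particle (CPP) and Stokes–Einstein sizes; and
2. a **membrane hydration analysis** — cross-sectional density profiles of
   atomistic slab trajectories with an interfacial/bulk water split,
   membrane thickness, interfacial water-layer metrics and PMOXA RMSF.

Both are paired with synthetic-data generators with exact ground truth, so
every stage is testable without instrument data or production MD
trajectories. The package analyses trajectories; it does not generate
physics, and it does not model protein–surface binding itself.

# The FCS model and the particle fraction

The canonical model is the triplet-corrected multi-component autocorrelation
for 3D diffusion through a Gaussian confocal volume,

$$G(\tau) = \frac{1}{N}\,
  \Big[1 + \tfrac{T e^{-\tau/\tau_T}}{1-T}\Big]\,
  \sum_i f_i\,\Big(1+\frac{\tau}{\tau_{D,i}}\Big)^{-1}
  \Big(1+\frac{\tau}{S^2\,\tau_{D,i}}\Big)^{-1/2},$$

with occupancy $N$, amplitude fractions $f_i$ (summing to 1), diffusion
times $\tau_{D,i} = w_{xy}^2/4D_i$ and structure parameter $S = w_z/w_{xy}$.
$S$ is a fixed instrument calibration constant (default 5, typical for a
confocal setup), never fitted; $w_{xy}$ defaults to 0.25 µm.

The fouling assay's defining constraint is that **both diffusion times are
fixed** — the fast one at the free labelled-protein value, the slow one at
the vesicle value — leaving only $N$ and the amplitude split free
(`fit_curve()` enforces this for two-component specs). The particle
fraction is $F2 = 100\,f_{\mathrm{slow}}$. Because correlation amplitudes
weight species by brightness², a small *number* fraction of label bound to
bright, slow vesicles produces a large $F2$; this is precisely what makes
the readout sensitive, and $F2$ is reported as fitted, without any
brightness de-weighting (a documented interpretation choice — $F2$ is an
operational fouling readout, not a bound-protein mole fraction).
CPP is the mean detected count rate divided by the fitted $N$ of the same
curve. Technical repeats whose $F2$ exceeds a configurable threshold
(default 50% on free-dye-scale controls) are excluded as aggregates before
averaging; the aggregation convention is median over the technical repeats
of each independent experiment, then mean ± s.e.m. across experiments.

Fitting is bounded Levenberg–Marquardt least squares (`minpack.lm`), with
the fractions parameterised by a single $f_{\mathrm{slow}}\in[0,1]$ so the
sum constraint is structural. Weights are $1/\sigma_G^2$ when the curve
carries uncertainties, uniform otherwise. Non-convergence is a flag, not an
exception, so calibration routines can count and exclude such curves.

# The Brownian-dynamics simulator and correlators

`simulate_fcs_trace()` integrates free diffusion (Gaussian steps of per-axis
variance $2D\,\mathrm{d}t$, periodic wrapping) for each species and
accumulates the detected rate through the Gaussian detection function
centred in the box. The default photon mode is the deterministic expected
rate per bin: the fit consumes correlation functions, not photons, so shot
noise is optional (`"poisson"` mode exists for realism checks). Boxes must
be at least $8\,w_{xy}$ laterally and $4\,w_z$ axially to bound periodic
artifacts, and a warning fires when the rms step exceeds $w_{xy}/4$.

Both correlators use the same estimator, the windowed covariance with the
global trace mean,
$\hat G(\tau) = \langle \delta I_t\,\delta I_{t+\tau}\rangle / \bar I^2$.
The multi-tau correlator evaluates lags 1..2m at full resolution and then
coarsens the trace by factors of two, evaluating lags m+1..2m per stage, so
each stage is *exactly* the direct estimator applied to the coarsened
trace. This makes the direct correlator a strict oracle for the multi-tau
implementation (agreement at machine precision at shared lags), at the
price of the small $O(1/n)$ finite-trace bias this estimator family shares;
at the trace lengths used here ($\geq 2^{20}$ bins) that bias is orders of
magnitude below the statistical errors.

## Study conditions for the closed-loop checks

The recovery experiments fix a priori physically motivated conditions: fast
species at $\tau_D = 40$ µs (free labelled protein scale), slow at 2 ms
(~60 nm vesicle in water at 25 °C; $\tau_D$ ratio 50), brightnesses 4 and
20 kHz (ratio 5), $\mathrm{d}t = 4$ µs, a 2×2×5 µm box with 60 fast and 3
slow particles ($N_{\mathrm{fast}}\approx 1.3$,
$N_{\mathrm{slow}}\approx 0.065$). The seed-to-seed scatter of the fitted
$F2$ is governed by $N_{\mathrm{slow}}\times(\text{duration}/\tau_{D,\mathrm{slow}})$,
i.e. by how many independent slow-particle passages the trace contains;
the closed-loop recovery therefore uses $2^{22}$-step traces (16.8 s),
which brings the scatter to ~5 percentage points so a ±5-point property is
measurable from 10 seeds. The monotone-fouling ladder (slow-particle counts
0/1/2/4/8) uses $2^{19}$-step traces: the spacing between its ground-truth
fractions (~13–16 points) is far above the ~2-point uncertainty of the
seed medians there. The analytic amplitude-fraction truth for a
configuration is $f_i = N_i B_i^2 / \sum_j N_j B_j^2$ with
$N_i = c_i\,\pi^{3/2} w_{xy}^2 w_z$, and the apparent occupancy is
$(\sum N_i B_i)^2/\sum N_i B_i^2$.

A finite closed box leaves a fingerprint on the correlation itself: with a
fixed particle number, the estimator's mean subtraction removes the
non-vanishing box average of the detection function, which sits the
measured curve a constant $\approx 1/n_{\mathrm{box}}$ below the
open-volume model until particles start re-entering the focus across the
periodic boundary. Single-species calibration fits therefore enable a free
baseline term (`fit_baseline = TRUE`) and restrict the window to lags well
below the box traversal time (`subset_curve()`); with that procedure the
recovered $\tau_D$ and $N$ are accurate to ~1%. The two-component fouling
fit is left without a baseline: the effect largely cancels in the
amplitude *split*, and the recovery criterion measures the assay as
practised.

What these simulations do *not* emulate: detector afterpulsing, triplet
photophysics, bleaching, optical saturation, polydispersity of the vesicle
population, and grand-canonical particle exchange (species counts are fixed
in the box). Passing the closed-loop tests shows the estimator chain is
unbiased under ideal mixture statistics, not that instrument artefacts are
handled.

# Membrane slab analysis

`density_profile()` centres each frame on the PDMS centre of mass along the
membrane normal (z by default), histograms each component's mass into
uniform bins (default 0.1 nm) and divides by the bin slab volume; means and
standard deviations are taken across frames. Water within a cutoff
(default 0.4 nm, minimum-image) of any PMOXA atom in that frame is
interfacial water, the rest bulk. The distance cutoff is the one
methodological free parameter of the split and is exposed in every entry
point; the split is exact by construction (interfacial + bulk equal total
water bin-wise to rounding).

Metric definitions, chosen for determinism and testability:

* **Membrane (core) thickness** — distance between the two z where the mean
  PDMS density crosses 50% of its plateau maximum, linearly interpolated.
  This convention reproduces the generator's core width exactly on
  synthetic slabs and is the common convention for core thickness.
* **Interfacial water-layer thickness** — per leaflet, the FWHM of the
  interfacial-water density peak (a threshold-above-bulk variant would be a
  straightforward alternative; FWHM was chosen because it is parameter-free).
* **Cross-over height** — the |z| at which mean PMOXA density equals mean
  bulk-water density, taking the innermost intersection walking outward
  from the core, linearly interpolated. A missing intersection is flagged,
  not fatal.
* **Interfacial AUC** — trapezoidal integral of interfacial-water density
  over z, per leaflet.

Leaflet values are averaged; uncertainties are across-frame standard
deviations of the per-frame metrics. **RMSF** removes the per-frame
membrane (PDMS+PMOXA) centre-of-mass translation, unwraps displacements
against the first frame (minimum image) so periodic wrapping never counts
as motion, and reports the per-atom root mean squared displacement about
the time-averaged position, averaged over the selection.

# The membrane generator

`generate_membrane_trajectory()` realises a parametric slab: a uniform PDMS
core (default half-width 2 nm, 965 kg/m³), PMOXA brush layers (plateau
550 kg/m³ over 1.5 nm with an exponential tail, decay length 0.1 nm,
truncated at 3 decay lengths; a linear tail is available), and water at
997 kg/m³ everywhere outside the core. Pseudo-atoms (default 18 amu) are
placed by **stratified inverse-CDF sampling** along the normal: with
persistent atom sites, Poisson placement noise (~15–20% per bin) would not
average out across frames, whereas stratified placement realises the
parametric density to within one atom per bin, leaving only the
fluctuation jitter as noise. Frames displace each atom by Gaussian noise
(per-component sd; iid by default, or an AR(1) Ornstein–Uhlenbeck sequence
with the same stationary sd, for which the RMSF closed form
$\sigma\sqrt{3}$ still holds). Densities above 2000 kg/m³ are rejected as
unphysical.

This generator is a geometric fixture: layer densities superpose with no
excluded volume, water has no structure, and the brush tail shape is a
fixture choice, not a physics claim. Passing the recovery tests shows the
analysers compute their definitions correctly, not that the definitions
match any particular force field's reality.

# Copolymer bookkeeping

Copolymers are named "A-B-A" by block DPs (only symmetric ABA supported;
asymmetric names are rejected loudly). The hydrophilic weight fraction is
$100\,(2\,\mathrm{DP_A} m_A + m_{\mathrm{end}})/(2\,\mathrm{DP_A} m_A +
\mathrm{DP_B} m_B + m_{\mathrm{end}})$ with repeat masses defaulting to
85.10 g/mol (2-methyl-2-oxazoline) and 74.15 g/mol (dimethylsiloxane) and
end-group mass defaulting to zero. The end-group-free formula reproduces
the reference value for the long 21-65-21 copolymer (42.6% → 43%); for
very short chains the end groups are not negligible and published
fractions for such chains are not reproduced by repeat masses alone, which
is why the end-group mass is an explicit parameter rather than a guessed
constant. Blends report mole and mass fractions and the mole-weighted mean
PMOXA DP; the ~35 ± 10% vesicle-forming window for the hydrophilic
fraction is an annotation for the user, never enforced.

# Numerical and reproducibility choices

* All generators consume integer seeds and are bit-reproducible per seed;
  the Brownian-dynamics kernel draws from R's RNG so `set.seed()` governs
  it too.
* Degenerate inputs are errors with names in them: truncated trajectory
  frames report the frame index, unmapped atom names are listed, empty
  aggregation groups name the group.
* `run_workflow()` writes a manifest (package version, seed, parameters,
  MD5 of inputs and outputs) next to every output, and emits no
  timestamps, so identical configs produce byte-identical results.
* Problem sizes in the test-suite and acceptance script (10 seeds,
  $2^{19}$–$2^{22}$-step traces, ~7000-atom slabs, 20–2000 frames) were
  chosen as the smallest sizes at which the statistical tolerances above
  are comfortably resolved.

# Known limitations

* $F2$ is brightness²-weighted; converting it to a bound-protein fraction
  would need per-species brightnesses, which the assay deliberately avoids
  measuring.
* The exclusion threshold for aggregate-contaminated repeats is a
  configurable operational choice (default 50%), not a derived quantity.
* One- and two-component 3D diffusion with an optional triplet term only:
  no anomalous diffusion, flow, FCCS, or diffusion-time distributions.
* Orthorhombic boxes and slab (planar) geometry only; curvature effects on
  the brush are out of scope.
* The interfacial/bulk water split depends on the distance cutoff; report
  it alongside any interfacial metric.

# A worked example

```{r example, eval = FALSE}
# simulate the fouling mixture, correlate, fit
species <- data.frame(count = c(60, 3),
                      D = c(diffusion_from_tau_d(4e-5),
                            diffusion_from_tau_d(2e-3)),
                      brightness = c(4, 20))
cfg <- fcs_sim_config(species, n_steps = 2^20, seed = 1)
curve <- autocorrelate_multitau(simulate_fcs_trace(cfg))
spec <- fcs_model_spec(list(fcs_component(4e-5, 0.5, fixed_tau_d = TRUE),
                            fcs_component(2e-3, 0.5, fixed_tau_d = TRUE)))
fit_curve(curve, spec)

# analyse a synthetic membrane slab
traj <- generate_membrane_trajectory(membrane_sim_config(seed = 1))
prof <- density_profile(traj)
membrane_thickness(prof)
interface_metrics(prof)
rmsf(traj, "PMOXA")
```
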