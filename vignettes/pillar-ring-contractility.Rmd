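---
title: "Modelling and measuring actomyosin contractility on pillar rings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring actomyosin contractility on pillar rings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actopillar)
```

## The assay and the model

A ring of soft, 3D-printed protein-hydrogel pillars is coated with a thin
reconstituted actomyosin cortex. When myosin II motors are activated by
ATP, the cortex contracts and bends every pillar inward; the pillars act
simultaneously as the mechanical frame and as calibrated force sensors.
`actopillar` implements the full quantitative loop of this assay:
simulating the contraction dynamics, predicting and inverting pillar
deflection profiles, extracting those profiles from confocal z-stacks,
counting myofilaments from fluorescence standards, and calibrating the
dynamic model to measured trajectories.

The contraction dynamics are described by a deliberately one-dimensional
viscoelastic model. Per pillar, with `x` the tip displacement toward the
ring centre:

$$\gamma_{am}\,\dot x = F_A - (k_p + k_{am})\,x, \qquad
  \dot n_b = k_{on,0}\,(N_m - n_b) - k_{off}(f)\,n_b .$$

The pillar (spring `k_p`) and the network's elastic response (spring
`k_am`) act in parallel on the network's viscous drag (dashpot
`gamma_am`), which sets the slow stress build-up timescale
`gamma_am / (k_p + k_am)`. The active force comes from a pool of `N_m`
myofilaments per pillar that bind and unbind transiently; each bound
filament contributes `f_s`, so `F_A = n_b f_s`. The essential nonlinearity
is the load dependence of unbinding: with the load per bound filament
`f = (k_p + k_am) x / max(n_b, 1e-6)`, the unbinding rate is

$$k_{off}(f) = k_{off,0}\, e^{-f/f_d},$$

a catch-bond-like law in which load stabilises engagement. This closes a
positive feedback loop — stress recruits motors, motors build stress —
that produces the two observed hallmarks: an acceleration phase of order
one minute followed by a decelerating approach to a plateau, and a steady
pillar force that is nearly independent of `k_p`. The latter is easy to
see at the fixed point: force balance pins the per-filament load to
exactly `f_s`, so the bound fraction and the active force are independent
of stiffness, and `F_pillar = F_A \, k_p/(k_p+k_am)` varies only through
the small factor `k_p/(k_p+k_am)` (a 4.8% spread over
`k_p` in 20–500 pN/µm at `k_am = 1` pN/µm).

```{r}
p <- model_parameters(k_p = 35)
traj <- simulate_contraction(p, t_end = 1200, dt_out = 1)
peak_velocity(traj)
mechanical_power(traj)$P_peak     # W, whole 10-pillar ring
steady_state(p)$F_pillar_ss       # pN per pillar
```

### The density-only control

A common alternative is to let contractility track only the local actin
density. The control variant implements this with load-independent
kinetics and a geometric densification factor,
`F_A = n_b f_s \rho(x)/\rho_0` with `rho(x) = rho0 R/(R - x)` — the
simplest law for a network shrinking toward the ring centre. The two
variants are compared the way the assay itself compares models: both are
anchored to the same measured steady force at one stiffness
(`calibrate_to_force()`, the "fit once" protocol), then swept across
`k_p`. Anchored at 126 pN for `k_p = 35` pN/µm, the density-only variant
mispredicts the sweep qualitatively: for soft pillars its fixed-point
equation `n_b f_s R/(R-x) = (k_p + k_am) x` has no stable root — the
densification feedback runs away and the ring contracts to closure
(`steady_state()` reports `collapsed = TRUE` with the limiting force
`k_p R`) — while stiff pillars see a much smaller force. Its max/min force
spread over the sweep is ~2.8 versus 1.048 for the load-dependent model.
We chose the measured force scale as the anchor because the comparison is
meaningless at mismatched amplitudes: at the raw reference parameters the
density-only variant binds so few motors (`n_b ≈ 0.48`) that `x << R` and
densification is invisible, which would make the "control" trivially
flat for the wrong reason.

### Reference parameters

The reference set (the `model_parameters()` defaults) is a documented
working point, not a fit to data: `k_am = 1` pN/µm (network much softer
than any pillar), `gamma_am = 2000` pN s/µm, `N_m = 10`, `f_s = 40` pN
(mid-range of the 20–60 pN forces single myofilaments generate),
`k_on0 = 0.05` s⁻¹, `k_off0 = 1` s⁻¹, `f_d = 10` pN, `R = 13` µm,
10 pillars. At `k_p = 35` pN/µm it yields a steady pillar force of
~285 pN (order 10² pN), peak velocity at ~1.9 min, and a ring peak power
of ~3.6 × 10⁻¹⁷ W. Only `N_m f_s` and `N_m f_d` are identifiable from a
single displacement curve (the model is invariant under rescaling `N_m`
against them), so fits hold `N_m` fixed.

### Numerics

Integration uses `deSolve`'s adaptive stiff-capable `lsoda` with
`rtol = 1e-8`, `atol = 1e-10`; the fast binding kinetics and slow stress
build-up make the system moderately stiff. Parameter-schedule switches
(ATP removal/re-addition, light activation of preloaded motors) restart
the integrator exactly at each switch time. The per-filament load floors
`n_b` at 1e-6 to avoid 0/0 at full detachment. Bound counts are clamped
to `[0, N_m]` at output against integrator-tolerance leakage. The
"unloaded" initial condition is the zero-load binding equilibrium
`n_b(0) = k_{on,0} N_m/(k_{on,0}+k_{off,0})` with `x(0) = 0` (motors are
present before activation); "preloaded" starts from the loaded steady
state, which responds strictly faster.

## Beam mechanics

Pillars are slender circular cantilevers treated in linear
Euler–Bernoulli theory (`I = pi d^4/64`, tip stiffness `k_p = 3EI/L^3`,
with E in kPa = 1000 pN/µm²). The observed shear strains (`Δx/L` up to
0.3) are handled within the linear theory, as is standard for this assay.
A point load `F` at attachment height `a` gives the piecewise-cubic
profile implemented in `predict_profile()`; the default `a = L` (tip
loading) is exposed for sensitivity analysis because where the network
engages the pillar is not directly observable. Since the profile is
linear in `F`, `fit_force()` solves the one-parameter least-squares
problem in closed form; samples below `foot_cutoff = 2` µm are excluded
(printed pillars have a stiffer, hardly deflected foot), per-sample
uncertainties switch the fit to weighted least squares, and a
pre-contraction profile, when available, is fitted first and its
predicted shape subtracted (raw subtraction is available as an option).

```{r}
g <- pillar_geometry(L = 15, d = 2, E = 57)
pillar_stiffness(g)                       # pN/um
prof <- predict_profile(g, F = 126)
fit_force(prof, g)$F_hat                  # exact round trip
```

## Image pipeline

Deflection profiles come from confocal z-stacks processed slice by slice,
mirroring the standard particle-tracking protocol: per-slice binarization
(Otsu by default; fixed and percentile thresholds are config options
because the acquisition's threshold choice is not universal), watershed
splitting of touching pillar footprints seeded from the Euclidean
distance transform, removal of small components, nearest-centroid linking
of labels across slices, and intensity-weighted centroids ("centre of
mass") in physical coordinates. Before/after centrelines are paired by
base position and the per-slice displacement is projected onto the unit
vector from the pillar base toward the ring centre, so purely tangential
motion contributes nothing. Voxel centres sit on a 0-based physical grid
with z measured from the substrate-side slice.

## Synthetic data and what it does (not) show

Every generator returns ground truth next to its data and requires a
seed. `gen_trajectory()` adds i.i.d. Gaussian position noise and rebuilds
velocity by central differences; `render_pillar_ring()` renders pillars
as circular cross-sections along straight or beam-deflected centrelines,
blurs with an anisotropic Gaussian PSF (defaults 0.3 µm axial, 0.15 µm
lateral — nominal confocal values), and adds mixed Poisson + Gaussian
read noise; `gen_calibration_series()` emulates the 0.001–1 µM
serial-dilution standard with additive noise. Default voxel size is
(0.5, 0.099, 0.099) µm: the lateral value is the confocal pixel scale of
the assay, the axial step a typical choice since acquisitions vary.

The renderer emulates geometry, PSF and shot noise, but not the actin
meshwork texture, uneven cortex coverage, pillar autofluorescence
gradients, refractive-index aberrations, or stage drift. Passing the
closed-loop tests therefore validates the extraction and inference
machinery, not the imaging model of any particular microscope.

## Model calibration

`fit_model_to_trajectory()` does bounded Levenberg–Marquardt least
squares on the displacement curve from seeded Latin-hypercube multistarts
and returns the best local optimum, with approximate standard errors from
the local quadratic expansion — unless the Gauss–Newton Hessian's
condition number exceeds 1e8, in which case it warns about sloppy
directions instead of reporting misleading errors. The default free set
is `{gamma_am, f_d, f_s}` with the kinetic rates fixed from the
literature block: freeing `k_off0` too leaves the single-curve problem
sloppy (condition numbers ~1e10, parameter errors of tens of percent at
2% measurement noise), while the three-parameter fit recovers
`gamma_am` to ~1% and `f_d` to ~7% median at the same noise. The split
is configurable. Data with no acceleration phase (pure exponential
saturation) cannot constrain the load feedback; the fit then runs `f_d`
into a bound and says so (`at_boundary`).

`predict_across_stiffness()` turns one calibrated fit into the full
stiffness sweep — flat steady force, peak velocity falling with `k_p` —
which is the model's main falsifiable prediction.

## Myofilament quantification

`fit_standard_curve()` is ordinary least squares on the dilution series;
`count_myofilaments()` inverts a measured local intensity to labelled
concentration, divides by the labelling ratio (10%), converts
concentration × local volume (inner 1,055 + ring 1,225 µm³, summed
because one count is reported for the two regions; per-region counts are
also emitted) through Avogadro's number to monomers, and divides by
monomers per filament (560 µm⁻¹ × 0.56 µm = 313.6). Uncertainty in the
curve coefficients and the measured intensity propagates to the count by
the first-order delta method with t-based intervals.

## Problem sizes used in the shipped checks

The test-suite and acceptance computations run at documented reduced
sizes chosen to probe the same regimes at desk scale: rendered stacks use
0.2 µm lateral voxels (leaving ten voxels across each 2 µm pillar; the
0.099 µm default remains for production use), end-to-end recovery uses 20
seeds × 10 pillars, parameter recovery 20 noisy trajectories sampled
every 5 s for 15 min, and the quantification round trip 200 replicates.

## Known limitations

The model is strictly 1D: no spatial gradients, no network rupture or
plastic remodelling, no sarcomeric coordination, and any printed
structure enters only through its effective stiffness. The beam theory is
linear and the cross-section uniform. The watershed/linking pipeline
assumes pillars remain separate objects per slice; completely merged
footprints at very high PSF widths will under-segment. The density-only
collapse state (`x = R`) is a model statement, not a physical prediction
— real rings jam before the tips meet.
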