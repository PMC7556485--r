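---
title: "Space-resolved modeling of rod single-photon response variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Space-resolved modeling of rod single-photon response variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

A vertebrate rod photoreceptor signals the absorption of a single photon
with a highly amplified, stereotyped drop in its circulating membrane
current (the single-photon response, SPR). Two stochastic elements make the
SPR variable. First, the photoisomerized rhodopsin (R\*) lands at a random
transverse position on the face of one internal disk: an R\* at the disk rim
hydrolyzes cGMP next to the plasma-membrane channels, while an R\* at the
disk centre acts far from them, so the local cGMP deficit must diffuse
radially before any channel closes, delaying and diluting the response.
Second, R\* is quenched by a random sequence of phosphorylation steps, each
of exponential duration, so the total catalytic output varies from trial to
trial. `rodspr` implements a fully space-resolved reaction-diffusion model
of the rod outer segment to quantify both sources of variability as
functions of disk radius, incisure pattern and cGMP diffusivity, with
parameter presets for mouse (disk radius 0.685 um, one incisure) and
salamander (5.5 um, 23 symmetric incisures).

## Model structure

**Geometry and homogenization.** The outer segment is a stack of hundreds of
disks (axial repeat ~30 nm) separated by 14.5-nm interdiskal cytosol layers
and surrounded by a thin (15 nm) cytosolic "outer shell" between the disk
rims and the plasma membrane. The cytosol is reduced to three coupled
domains:

* the *interior volume*, a homogenized cylinder in which cGMP and calcium
  diffuse transversally within interdiskal layers (conductances scaled by
  the interdiskal volume fraction) and have **no axial flux** except through
  incisures, because the disks are impermeable;
* the *outer shell*, a cylindrical surface carrying azimuthal and axial
  diffusion plus all membrane fluxes (CNG channel influx, exchanger
  extrusion);
* the *special-disk layer*, the single interdiskal layer adjacent to the
  photoisomerized disk face, resolved in polar coordinates, where
  E\*-driven hydrolysis acts.

Incisures act twice: on the disk surface they are reflecting barriers for
the membrane-bound activated transducin/PDE (E\*), and in the cytosol they
are axial conduits. The conduit is homogenized: the open slit cross-section
of every radial ring (slit width x radial overlap, summed over incisures,
i.e. the parallel sum per unit disk) is smeared uniformly in azimuth as an
effective axial conductance. The default effective slit width (0.2 um) was
chosen so that the resulting longitudinal cGMP diffusivity of a salamander
rod falls in the measured 40-60 um^2/s range; it is exposed in the geometry
(`incisure_eff_width_um`) for audit.

**R\* shutoff.** R\* passes through 7 activity states (0-6 phosphates). The
mean state durations are the published per-species values; stochastic mode
draws each dwell independently from an exponential with that mean, and
deterministic mode uses the means themselves. Catalytic activity is
decremented by a factor 0.85 per phosphate. That factor was fixed by a
consistency argument: the activity-weighted mean lifetime
`sum(nu_j tau_j)/nu_0` then equals 0.41 s for salamander and 0.075 s for
mouse, matching the species' published mean R\* lifetimes, which are *not*
the sums of the dwell means (0.63 s and 0.11 s). Complete quench is folded
into the exit from the 7th state (`quench_model = "sequential"`); no
competing arrestin branch is modelled.

**E\* spread.** The surface density of activated PDE on the special disk
obeys a diffusion-decay equation with a point source at the R\* site,
`dE/dt = D_E Lap E - k_E E + nu(t) delta(x0)`, with zero-flux conditions at
the rim and on both sides of every incisure slit. The point source is
deposited over a Gaussian patch of fixed half-width 0.3 um (masked so no
weight crosses a slit). This keeps the near-source density - and therefore
the local hydrolytic load on the thin interdiskal layer - comparable across
source positions and mesh resolutions; 0.3 um is also the natural
heat-kernel spread by the time enough E\* exists for hydrolysis to matter.
Tests that compare against point-source analytics set `source_sigma = 0`.
An optional two-transducin mode tracks singly- and doubly-bound PDE with a
finite second-binding rate; hydrolysis is driven by the doubly bound
species, and the mode reduces exactly to the single-transducin model in the
instantaneous-binding limit.

**Second messengers and current.** cGMP is synthesized by
guanylate cyclase with Ca-dependent GCAP regulation
(`alpha(Ca) = alpha_min + (alpha_max - alpha_min)/(1 + (Ca/K_cyc)^m_cyc)`),
hydrolyzed basally at `beta_dark` (spatially uniform) and locally by E\*
(`k_star` per molecule). Local CNG current density follows a Hill function
of shell cGMP (`m_cG = 3`, `K_cG = 20 uM`), the exchanger a Michaelis
function of shell Ca. Currents are integrated over the shell;
`I(t) = 1 - j_tot/j_dark` is the normalized response. In darkness the
exchanger current is `f_Ca/2` times the CNG current (one net charge moved
per Ca extruded, two carried per Ca entering), which fixes the partition of
`j_dark`.

**Buffering.** Both messengers are buffered in the rapid-equilibrium
approximation by capacity factors: `B_Ca = 20` for calcium and `B_cG = 2.5`
for cGMP (non-catalytic GAF-site binding on PDE). Buffering divides the
effective transport and reaction rates; with the aqueous input diffusivity
of 160 um^2/s this puts the effective cGMP transport at ~46 um^2/s, in the
measured range for rod cytoplasm. The buffered-capacity formulation keeps
the printed aqueous diffusivities as the model inputs.

## Parameter presets

Printed, species-specific values: disk radius (0.685 / 5.5 um), incisure
count and depth (1 x 0.31 um / 23 x 4.64 um, aligned), interdiskal spacing
(14.5 nm), cGMP diffusivity (120 / 160 um^2/s, alternate mouse value 330 =
2.75 x 120), and the seven mean dwell times per species. All other
constants are package defaults from the rod phototransduction literature,
chosen once and not tuned per experiment:

| parameter | mouse | salamander | units | role |
|---|---|---|---|---|
| `nu_max` | 400 | 600 | E\*/s | transducin/PDE activation rate of unphosphorylated R\* |
| activity decrement | 0.85 | 0.85 | per phosphate | fixes activity-weighted lifetime |
| `k_E` | 5 | 2 | 1/s | E\* inactivation |
| `D_E` | 0.8 | 0.2 | um^2/s | effective E\* surface diffusivity |
| `k_star` | 0.6 | 0.15 | um^3/s | hydrolysis per E\* molecule |
| `beta_dark` | 4.1 | 1.0 | 1/s | basal PDE activity |
| `g_dark`, `Ca_dark` | 3, 0.25 | 3, 0.40 | uM | dark operating point |
| `j_dark` | 14 | 66 | pA | dark current |
| `m_cG`, `K_cG` | 3, 20 | 3, 20 | -, uM | CNG Hill law |
| `K_cyc`, `m_cyc` | 0.132, 2 | 0.160, 2 | uM, - | cyclase regulation |
| `f_Ca`, `K_ex` | 0.12, 1.5 | 0.12, 1.5 | -, uM | Ca partition, exchanger |
| `B_Ca`, `B_cG` | 20, 2.5 | 20, 2.5 | - | buffering capacities |

The cyclase amplitude is not free: `init_dark_steady_state()` rescales
`alpha_max`/`alpha_min` so that synthesis exactly balances basal hydrolysis
at the dark operating point (and logs the rescale), and the exchanger
saturation current is derived from the dark calcium ledger. The dark state
is therefore an exact fixed point of the solver by construction, which the
test suite verifies to 1e-8.

The kinetic defaults were calibrated *jointly and once* against the
qualitative behaviour the model is known to produce: SPR peak times near
0.2 s (mouse) and 1-1.5 s (salamander), a damped oscillation in the
salamander recovery but not the mouse, amplitude augmentation by incisures,
deep cGMP depletion in the active layer for a centred R\*, and
position-insensitivity of the mouse response. They were not revisited after
the quantitative acceptance checks were run.

## Numerics

* **Discretization.** Structured (rho, theta, z) finite volumes with
  geometric metric terms; the disk mesh and the interior transverse mesh
  coincide. The axial grid is refined geometrically around the special disk;
  the special slab thickness equals one axial repeat (0.03 um), so its
  cytosolic content is exactly one interdiskal layer.
* **Time stepping.** Implicit (backward-Euler) diffusion with a Cholesky
  factor cached per engine; reactions advance per cell in closed form (an
  integrating-factor update for cGMP, which is linear in cGMP given Ca and
  E\*, and a closed-form backward-Euler quadratic for shell Ca). Every
  substep is unconditionally stable and positivity-preserving, and the
  discrete mass ledger closes to round-off; the solver reports the ledger
  drift with every trace. The E\* source is integrated exactly across state
  transitions via the integrating factor. A fixed conservative step
  (0.5 ms mouse, 5 ms salamander) replaces the adaptive controller an
  earlier design sketched; with the closed-form reactions there is no
  stability constraint to adapt to, and fixed steps make ensembles
  reproducible and cheap.
* **Symmetry reduction.** For a centred R\* the problem is axisymmetric
  (no incisures) or C_n-periodic (n symmetric incisures); `build_engine`
  can solve one azimuthal sector with periodic wrap. The reductions agree
  with the full mesh to machine precision and are used for set-2 ensembles.
* **Set-1 ensembles.** With deterministic shutoff the trace is a
  deterministic function of the R\* position, and the geometry is
  rotationally/mirror symmetric, so ensembles sample positions per trial
  and interpolate a response surface built from full solves at
  position-quadrature nodes (radial nodes uniform in rho^2; angular nodes
  across half an incisure sector). Sets 2 and 3 run the full pipeline per
  trial with per-trial seeds derived from the master seed.
* **Problem sizes.** The test suite and acceptance script use desk-scale
  settings chosen as the package's own accuracy/cost compromise:
  deterministic salamander runs on a 14 x 46 transverse mesh (the centre
  peak moves under 1% when every resolution is halved), mouse ensembles of
  500 trials on an 8 x 12 mesh, and salamander ensembles of 150 trials on a
  10 x 46 mesh. The full-fidelity study design (1000 trials per condition)
  is available through `n_trials`.

## What the presets do and do not emulate

The presets reproduce the study conditions: stochastic structure
(exponential dwells, uniform-by-area R\* placement), geometry, and the
printed kinetic constants. Basal PDE activity is modelled as spatially
uniform, so the continuous noise generated by discrete spontaneous PDE
activations is absent by design; CV estimates therefore isolate the two
modelled sources and say nothing about total biological variability at very
early times, where the response has not risen out of the continuous noise.
Channel gating is deterministic (a population model), axial R\* position
effects are out of scope (the R\* always sits on the central disk), and
rhodopsin oligomerization is not modelled.

## Known limitations

* The peak-amplitude contrast between rim and centre activation in a bare
  salamander disk converges to ~1.4-fold in this implementation. The
  homogenized architecture routes rim and centre cGMP deficits through the
  same outer-shell bottleneck, so the contrast rests on the slowed radial
  transfer (buffered diffusion) and on supply-limited hydrolysis; parameter
  settings that push it toward 2-fold break the incisure phenomenology and
  the position-uniformity bound, and were rejected.
* The location-driven CV of the mouse response decays on a ~3-4 ms scale
  here; its landmark value of ~0.09 is reached near 3.5 ms rather than
  7 ms, although the location-to-shutoff crossover itself falls at ~8 ms.
* Salamander CV crossovers occur later than the reduced-trial targets
  (0.7 s with incisures, 1.5 s without at these settings): the location CV
  decays more slowly than the shutoff CV rises over the simulated windows.
* The incisure axial conductance uses a single effective slit width;
  lobulated rims and depth variation along the outer segment are not
  modelled.

## Reproducing the analyses

```{r example}
library(rodspr)

# deterministic salamander SPRs at three R* positions, no incisures
geom <- build_geometry("salamander", incisures = list())
pars <- build_params("salamander")
traj <- sample_shutoff(pars, "deterministic")
eng <- build_engine(geom, pars, n_rho = 14, n_theta = 46, dt = 5e-3,
                    dz_grow = 1.45, dz_max = 1.5)
trace_centre <- engine_run(eng, traj, place_rstar(geom, "center"), t_end = 4.5)
trace_rim <- engine_run(eng, traj, place_rstar(geom, "rim"), t_end = 4.5)
peak_metrics(trace_rim)$peak / peak_metrics(trace_centre)$peak

# mouse variability: random location vs random shutoff
gm <- build_geometry("mouse"); pm <- build_params("mouse")
loc <- run_ensemble(experiment_condition(gm, pm, set = "set1",
                                         n_trials = 300, seed = 1, t_end = 0.05))
sht <- run_ensemble(experiment_condition(gm, pm, set = "set2",
                                         n_trials = 300, seed = 2, t_end = 0.05))
crossover_time(loc$cv_j, sht$cv_j, loc$time,
               default_gate(loc$mean_I, loc$time))
```
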