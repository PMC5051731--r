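---
title: "Models of centripetal MTOC motility: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of centripetal MTOC motility: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asterdrift)
```

During meiosis I in mouse oocytes, tens of acentrosomal microtubule
organizing centers (MTOCs) — small radial asters with microtubules of mean
length ~3 µm — converge from throughout a ~40 µm-radius cell onto the
central chromatin mass, where a bipolar spindle later assembles. The
distances involved are an order of magnitude larger than the asters'
microtubule reach, so simple search-and-capture cannot explain the observed
20–30 minute convergence. `asterdrift` implements two model tiers that probe
what spatial bias can: a phenomenological random walk in a drift field,
optimized against trajectory statistics, and a mechanistic microtubule–motor
simulation that asks which molecular mechanisms generate such a field.

This vignette records the models, their assumptions, the tunable parameters,
and the numerical and design choices made where the problem left the design
open. The problem sizes quoted are the ones the test suite and the
reproduction script actually run.

## Tier 1: random walk in a drift field (RWD)

The oocyte is a 2D disk of radius `r_cell` = 40 µm with a concentric
chromatin disk of radius `r_chr` = 10 µm. MTOCs are point particles
nucleated uniformly by area in the cytoplasmic annulus, advanced with step
time δt = 0.1 s for a total of 8000 s, and absorbed ("captured") when their
radial distance reaches `r_chr`. The speed of each step mixes a directed and
a Brownian component through two radially symmetric sigmoid weights,

$$\phi(r) = \frac{1}{1 + e^{(r - r_{1/2})/s}},$$

an attractive field measured from the chromatin edge and a repulsive field
measured from the cell boundary (both direct motion toward the cell centre —
"repulsion" from the cortex is centripetal):

$$\dot X_{net} = \phi_a\, v_{eff} + (1-\phi_a)\,
  \bigl[\phi_r\, v_{eff} + (1-\phi_r)\, \sqrt{4 D_{eff}/\delta t}\bigr].$$

The Brownian speed is `sqrt(4 D_eff / δt)`, so one step displaces the
particle by `sqrt(4 D_eff δt)` and the ensemble obeys the 2D diffusion law —
the only dimensionally consistent reading of the speed mixture that also
reproduces the mean-squared-displacement (msd) fit model below. The
direction mixes a uniform random angle with the centre-pointing angle by a
circular weighted average (angle of the weighted sum of unit vectors), with
the same nesting of weights as the speed. Whether the repulsive weight
should enter the angle average exactly as it enters the speed is not
determined by the problem; we mirror the speed weights.

Motility constants are fits to experimental msd profiles reported for this
system: `D_eff` = 0.006 µm²/s and `v_eff` = 0.008 µm/s. Two boundary rules
close the model: the cortex reflects (radial mirror — the minimal rule that
keeps particles inside), and captured particles are removed, not pinned.
`drift_field(r_half = Inf, s)` gives the degenerate all-drift field
(weight 1 everywhere), used for pure-drift controls, where the capture time
equals the initial chromatin distance over `v_eff` exactly (a closed-form
oracle in the tests).

The timestep was validated the standard way (`validate_timestep()`):
simulate a free, unbounded walk, fit the ensemble msd to `4 D δt`, and
require the fitted coefficient within 10% of the input at 100 particles and
8000 s.

## Motility statistics

All statistics operate on tibbles in the trajectory dialect
(`track_id, t_s, x_um, y_um`, cell-centred µm).

* **Down-sampling** (`downsample_tracks()`): simulated tracks are reduced to
  the experimental frame interval (~3.5 min) by keeping samples nearest to
  multiples of the interval; first and last samples are always preserved so
  capture semantics survive.
* **msd** (`track_msd()`, `ensemble_msd()`): overlapping windows at integer
  multiples of the sampling interval, cut at 3/4 of the track duration (the
  long-lag tail averages too few pairs to be useful). The estimator is
  tested for exact equality against a brute-force double loop.
* **Drift-diffusion fit** (`fit_msd_drift()`):
  $\langle r^2\rangle = 4 D_{eff}\,\delta t + (v_{eff}\,\delta t)^2$. The
  model is linear in $(4D_{eff}, v_{eff}^2)$, so the non-negativity
  constrained least-squares problem is solved exactly by an active-set scan
  of the four sign patterns; noiseless curves are recovered to machine
  precision.
* **Anomalous fit** (`fit_msd_anomalous()`):
  $\langle r^2\rangle = 4 D' t^{\alpha}$ with $\alpha \in [0, 2]$,
  initialized by log–log regression and refined by bounded
  Levenberg–Marquardt (`minpack.lm`, standing in for a trust-region
  reflective solver).
* **Directionality** χ = net displacement / path length, per whole track,
  binned by nucleation radius in 5 µm bins (the bin width matches the
  granularity of published profiles; it is not otherwise constrained).
  Whole-track χ blurs local structure, so `radial_profile()` also offers a
  windowed variant (`chi_window` frames per window, assigned to the window's
  starting radius) that resolves the U-shape — directed at the cortex and
  near chromatin, random in the mid-zone — which the whole-track statistic
  shows only weakly.
* **Distance–time fit** (`fit_distance_time()`):
  $d(t) = d_{max} t^n / (T_{half}^n + t^n)$ on the distance from the
  nucleation site, by bounded Levenberg–Marquardt. `n > 1` (sigmoid) is read
  as pulling-dominated transport, `n ≤ 1` (parabolic) as pushing; fits with
  R² ≤ 0.7 are flagged unreliable. Monotonicity of the distance series is
  not enforced.
* **Lognormal speed fit** (`fit_lognormal_velocity()`): closed-form ML in
  log space, reported as linear-scale mean and variance (the convention in
  which the experimental distribution is quoted: a mean of ~8.8·10⁻³ µm/s
  with a variance far below mean²).

## Fitting the drift field: weighted-error rank minimization

`rank_scan()` scores every parameter set $k$ = (attractive $r_{1/2}, s$;
repulsive $r_{1/2}, s$) against a reference dataset on two variables — the
binned χ(r) profile and the capture-time distribution — with the modified
weighted root-mean-square error

$$\epsilon(k) = \sqrt{\tfrac{1}{n}\sum_i w_i\,(e_i - s_i(k))^2},\qquad
  w_i = \begin{cases} n_i/n_{max} & s_i \in [e_i - sd_i,\, e_i + sd_i] \\
  w_m = 2 & \text{otherwise}, \end{cases}$$

so sparsely observed reference points count less when the simulation already
agrees, and any out-of-band point pays a uniform penalty larger than any
in-band weight. Each variable's errors are ranked across the grid (average
ranks on ties — order-independent) and the sum rank $R_s = \sum_v R_v(k)$ is
minimized. Capture-time distributions are compared as per-600-s-bin
proportions of all tracks (a floor of 0.02 on the bin standard deviation
avoids zero-width acceptance bands at small track counts).

The full grid is 600 combinations (attractive $r_{1/2} \in \{0,5,10,15,20,
25\}$ × $s \in \{0.5,1,2,4,8\}$ crossed with repulsive $r_{1/2} \in
\{0,2,4,8\}$ × the same $s$ axis); the published count fixes 600 but not the
axes, so `param_grid()` is configurable. Self-consistency tests and the
reproduction script run a reduced 20-set grid (3 replicates of 40–50
particles per set) that contains the generating values; the scan returns
attractive $r_{1/2}$ = 10 µm as top-ranked on pseudo-data generated from the
optimal fields (attractive $r_{1/2}$ = 10 µm, $s$ = 1; repulsive $r_{1/2}$ =
0 µm, $s$ = 2).

## Tier 2: microtubule–motor engine

`run_scenario()` integrates, in compiled code, MTOCs modelled as rigid
0.2 µm bodies carrying `n_mt` filaments at uniform angular spacing,
surface-immobilized minus-end-directed motors, and diffusible two-headed
cross-linking motor complexes, in the same cell geometry. The chromatin disk
is mechanically passive here: capture is a measurement (centre crossing
`r_chr`), not an absorbing event.

**Filaments.** Discrete polymers with 0.5 µm segments undergoing the
four-parameter dynamic-instability model: growth at $v_g$, shrinkage at
$v_s$, catastrophe and rescue as Poisson events
(probability $1 - e^{-f\,dt}$ per step). In the bounded regime
($v_s f_{cat} > v_g f_{res}$) the steady-state mean length is
$\langle L\rangle = v_g v_s / (v_s f_{cat} - v_g f_{res})$ — 3.23 µm for the
cytoplasmic parameter set ($v_g$ = 0.178 µm/s, $v_s$ = 0.205 µm/s,
$f_{cat}$ = 0.075 s⁻¹, $f_{res}$ = 0.023 s⁻¹). A filament reaching zero
length immediately regrows: the nucleation site persists and the filament
count per aster stays constant.

**Motors.** A motor binds the nearest filament contour point within
`d_attach` = 0.02 µm at rate `r_attach` = 12 s⁻¹, walks toward the minus end
with the piecewise-linear force–velocity law (full speed `v_m` = 2 µm/s
under zero or assisting load, linear ramp to stall at $f_0$), and detaches
at the Kramers rate $r'_{detach} e^{|f_{ex}|/f_0}$ with basal rate 1.5 s⁻¹
($f_{ex}$ is the extension force of its `k_mot` = 0.1 pN/nm spring). The
same exponential force factor multiplies the end-of-filament rate
(1 s⁻¹) — a force-independent end rate would make minus-end-bound motors
unbreakable tethers. Complexes diffuse with $D_c$ = 20 µm²/s (per-step
Gaussian displacement of total variance $4 D_c\, dt$), bind two distinct
filaments with the same kinetics, and exert equal-and-opposite zero-rest-
length spring forces that cluster asters. Stall forces of 2 and 7 pN span
the values reported for cytoplasmic dyneins.

**Mechanics.** The engine simplifies constrained Langevin dynamics into
three sub-steps per `dt` = 0.01 s, chosen so that every stiff term is
handled stably without implicit solves:

1. *Rigid translation.* All forces on an aster's vertices and body —
   cortical confinement, motor and complex springs, body confinement —
   are summed and the MTOC (with its filaments) translates by
   $F\,dt/\Gamma$, where $\Gamma$ adds a Stokes body drag ($6\pi\eta a$,
   $a$ = 0.2 µm) and a cylinder-transverse drag per 0.5 µm segment at
   η = 0.05 Pa·s. Thermal displacement with variance $2 k_B T\, dt/\Gamma$
   per axis gives the Einstein relation for bare bodies (verified in a
   property test). Motor and complex spring forces act *only* at this rigid
   level: their stiffness (100 pN/µm against a per-vertex drag of
   ~0.08 pN·s/µm) makes the per-vertex explicit update unstable at this
   timestep, while the rigid response is stable and is what the scenario
   statistics measure. A step cap of 0.45 segment lengths guards the
   remaining stiff limit (many springs on one small aster).
2. *Shape relaxation.* Vertices move under confinement forces and vertex-
   level thermal noise (capped at 0.45 segment lengths), the contour is
   re-projected to exact segment rest lengths from the anchored minus end
   outward (follow-the-leader — contour length changes only through
   polymerization), and consecutive segments relax toward alignment with
   the analytic overdamped factor $1 - e^{-\kappa\,dt/(L_{seg}^3
   \gamma_v)}$. With κ = 2·10⁻²³ N·m² (persistence length ≫ cell size) this
   keeps filaments quasi-straight, which is the physical regime for 3 µm
   microtubules.
3. *Confinement.* Vertices beyond `r_cell` feel a harmonic inward force
   (10 pN/µm), capped per filament at the Euler buckling load
   $\pi^2 \kappa / (4 L^2)$ — the maximum force a growing filament clamped
   at the aster can transmit before buckling. This reproduces
   polymerization-limited cortical pushing without resolving buckled
   shapes.

**Scenarios.** `"no_gradient"` (uniform immobilized motors),
`"clustering"` (complexes only), `"di_gradient"` (uniform motors, with
$f_{cat}, f_{res}$ interpolated toward stabilized values 0.0397/0.0122 s⁻¹
by the attractive field evaluated at the filament tip), `"motor_gradient"`
(anchors placed by rejection sampling with acceptance ∝ the attractive
field), and `"hybrid"` (motor gradient plus complexes). Cortical pushing
acts in all scenarios. The full preset runs 80 MTOCs for 1200 s; the smoke
preset (10 MTOCs, 20 filaments each, 120 s) keeps property tests inside a
few minutes.

**Smoke-scale scenario contrast.** At full scale the motor gradient drives
net inward drift of ~0.01 µm/s across the sigmoid transition zone, which
over 20 minutes yields the experiment-scale capture fractions; in a 120 s
smoke window the same drift moves an aster ~1 µm, so only MTOCs nucleated
about 1 µm from the chromatin edge can physically be captured. The
scenario-contrast property therefore initializes the 10 MTOCs on a ring at
r = 11 µm (a fixed-nucleation-distance cohort, the same device used for
the filament-number sensitivity analysis), uses the strong-pulling corner
of the studied motor range ($N_{mi}$ = 3000, $f_0$ = 7 pN), and compares
pooled captures across 5 paired seeds (shared initial positions). Gradient
captures exceed uniform captures decisively under these conditions (18 vs
8 of 50 in the frozen configuration).

## Synthetic pseudo-experiment

The experimental tracks this class of model is calibrated against are not
redistributable, so `generate_pseudo_experiment()` emulates their
statistical structure: the RWD model with the optimal fields and reference
motility constants is run at fine resolution, resampled at jittered frame
intervals (uniform on 180–240 s — "3 to 4 minutes"), and degraded with
isotropic Gaussian localization noise (0.2 µm, the MTOC size scale; no
noise floor is published, so this is an explicit assumption recorded in the
dataset metadata, as are the track count — 30 by default, "tens" being all
that is known — and the jitter law). Noise draws are rejected until samples
stay inside the cell and captured endpoints stay inside the chromatin disk,
so capture semantics survive degradation. The generator emits the binned
χ(r) and capture-time reference structures the optimizer consumes.

What passing recovery tests on this generator shows is *estimator and
pipeline self-consistency* — that the scan finds the fields that generated
the data at experimental sparseness and noise. It cannot show that the real
oocyte's drift is sigmoid, that localization noise is Gaussian, or that
real capture-time distributions match; those claims would need the original
tracks.

The enucleated-cell control (`generate_enucleated_control()`) is uniform-
by-area placement on the disk: with the chromatin cue removed, MTOC
positions should show a flat radial density, and `radial_density()`
(counts per annulus area, normalized to unit integral) is the comparison
statistic.

## Numerical choices and degenerate inputs

* Exact non-negative least squares for the drift-diffusion fit (no
  iterative solver); degenerate all-zero curves return $D_{eff} = v_{eff}
  = 0$ rather than erroring.
* Bounded Levenberg–Marquardt elsewhere, with log-space initialization for
  the power law and data-driven starts for the Hill fit; α is clamped to
  [0, 2].
* Tracks shorter than 3 samples (captured within two frames) carry no lag
  information and are dropped from msd ensembles; an error is raised only
  if nothing remains.
* χ of a zero-length path is undefined and excluded from binned profiles.
* All randomness flows through R's RNG (also inside the compiled engines),
  so a single `set.seed()` — or the `seed` argument any simulation function
  accepts — makes every pipeline bit-reproducible.
* Ties in optimizer ranks take average ranks; the reported best set is the
  sum-rank minimizer with the smallest index on exact ties.

## Problem sizes used in the checks

The bundled tests and `scripts/acceptance.R` run: 100-particle, 8000 s RWD
ensembles for the estimator self-consistency checks; a 20-set grid × 3
replicates × 40–50 particles for field recovery; a 10⁵ s single-filament
simulation for the mean-length cross-check (length fluctuations
decorrelate over ~10² s, so shorter averages sit outside 10% of the closed
form for some seeds); and the 120 s smoke preset described above for the
scenario contrast. Full-scale scenario reproductions (80 MTOCs × 1200 s ×
10 runs per condition) are supported by the same functions but are long-
running computations left to the user.

## Known limitations

* The geometry is 2D; centering in a 3D oocyte is a slower search problem,
  and all parameter values here are tied to the 2D calibration.
* The engine's mechanics are scenario-grade, not solver-grade: rigid aster
  translation plus quasi-straight filaments reproduces force scales and
  capture statistics, but not buckled filament shapes, steric exclusion,
  or torque-resolved aster rotation.
* Motor binding resolves the nearest eligible filament deterministically;
  at `d_attach` = 0.02 µm true ties have measure zero.
* Whole-track χ binned by nucleation radius (the default) only weakly
  resolves the cortical directionality bump; use the windowed variant when
  the local structure matters.
* Velocity autocorrelation, turning-angle statistics and pause-state
  segmentation are out of scope.
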