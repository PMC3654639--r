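---
title: "Methods: a simplified torso-embedded whole-heart bidomain ECG simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a simplified torso-embedded whole-heart bidomain ECG simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`bidecg` simulates whole-heart electrical activity inside a passive torso
and derives surface electrocardiograms from it. Three fields are evolved:
the intracellular potential $V_i$, the extracellular potential $V_e$ (with
transmembrane potential $V_m = V_i - V_e$) and a recovery variable $u$, on a
regular voxel grid. On the myocardium the bidomain equations couple the two
potentials through the transmembrane current,

$$\frac{\partial V_m}{\partial t} = \nabla\cdot(\sigma_i \nabla V_i) - i_{ion},
\qquad
\nabla\cdot\big((\sigma_i+\sigma_e)\nabla V_e\big)
  + \nabla\cdot(\sigma_i \nabla V_m) = 0,$$

while outside the heart the extracellular potential obeys the Laplace
equation $\nabla\cdot(\sigma_o \nabla V)=0$ in torso, lungs and chamber
blood. The membrane kinetics are a modified FitzHugh--Nagumo model with a
normalised excitation $v = (V_m - B)/A$:

$$i_{ion} = k\,c_1 (V_m - B)\,(a - v)(1 - v) + \text{recovery},
\qquad
\frac{\partial u}{\partial t} = k\,e\,\big[v - d\,u - b\big].$$

The recovery current is $k c_2 u$ in the sinoatrial node (SAN) and
$k c_2 u (V_m - B)$ everywhere else. With $u = 0$ the ionic current is a
cubic in $V_m$ with roots at $B$, $B + aA$ and $B + A$; `cubic_roots()`
exposes this structure, and its span equals the action-potential amplitude
$A$. In the SAN, $a < 0$ and $b < 0$ make the rest state unstable, so the
node oscillates spontaneously: with the default parameters an isolated SAN
cell fires with a cycle length of roughly 0.84 s. The printed form of the
recovery equation and ionic current is read with $(V_m - B)/A$ (the division
is required for the bracket terms to be dimensionless and for the cubic to
have the standard root structure), and the rate product $k\,e$ is the
product of the two separately tabulated parameters. The membrane capacitance
and surface-to-volume ratio are normalised to one, so ionic currents are
carried in V/s; potentials are stored in volts internally and exposed in mV.

Seven heart regions carry heterogeneous parameter sets (SAN, atria, AV node,
His bundle, bundle branches, Purkinje layer, ventricular myocardium). The
parameter `e` chiefly sets action-potential duration (APD shrinks as `e`
grows; the test suite checks this monotonicity), and the conductivities
$\sigma_e, \sigma_i$ set conduction velocity; the AV node's low conductivity
produces the atrioventricular delay.

## Numerics

**Reaction.** The membrane ODEs are advanced with fixed-step RK4, compiled
in C++. The SAN parameter set, whose excitation coefficient $c_1$ is nearly
three orders of magnitude above the working-myocardium value, has a Jacobian
of order $10^6\,\mathrm{s^{-1}}$, far stiffer than any sensible global time
step. The requested `dt` is therefore treated as the communication/output
interval and each step is internally subdivided until an RK4 stability bound
(scanned numerically from the parameter set over the physiological range of
$v$, with a safety factor) is met. For the ventricular set the bound admits
`dt = 0.1 ms` in a single substep, so single-cell results there are plain
fixed-step RK4.

**Splitting.** The tissue solver uses operator splitting per time step
(default `dt = 0.05 ms`): (1) the reaction update at every heart node;
(2) an implicit backward-Euler diffusion solve for $V_m$ through the
intracellular operator; (3) a quasi-static elliptic solve for the
extracellular/passive potential. Step (3) treats heart and passive nodes as
one composite-conductivity Poisson problem ($\sigma_i + \sigma_e$ inside,
$\sigma_o$ outside), which enforces potential continuity $V = V_e$ and flux
matching at the heart boundary simultaneously. Both linear systems are
symmetric positive definite after grounding and are factorised once
(sparse Cholesky), so each step costs two triangular solves.

**Discretisation.** 7-point finite-volume Laplacians with harmonic
face-averaged conductivities. Harmonic averaging makes the zero-flux
condition for $V_i$ at the heart boundary automatic ($\sigma_i = 0$ outside
the heart zeroes the face conductance), and the exterior torso boundary is
reflecting (insulating). One surface node — the right-leg electrode
`VGND` — is pinned to exactly 0 V, fixing the gauge of the elliptic
problem; its trace is identically zero.

**Electrograms.** Electrode potentials are sampled at single snapped
surface nodes every 1 ms. The lead calculus (Einthoven, Goldberger-augmented,
Wilson precordial, Frank X/Y/Z, RMS and SAECG curves) is per-sample linear
algebra on those traces and satisfies its algebraic identities
($II = I + III$, $aVR+aVL+aVF=0$, Frank common-mode rejection) to rounding
error.

## Geometry

The anatomy is deliberately parametric rather than image-derived: torso and
lungs are extruded ellipses, a spherical cavity in the lung field holds a
spherical two-chamber heart split by the AV plane — a ventricular shell with
septum and chamber blood below, an atrial shell with a myocardial floor and
blood above, and an insulating gap between them bridged only by the His
column in the septum. Axes are x lateral (+x subject's left), y anterior,
z cranial. A voxel belongs to the region covering its centre; identical
configurations rasterise to bit-identical label fields.

Three conduction-system choices deserve comment, because the coarse grid
makes the weak-to-strong conductivity junctions fragile (the reaction
boundary layer of the weak side is sub-voxel, so harmonic face averaging
underestimates the junction current):

* the SAN--atrial interface is interdigitated — a one-voxel atrial tongue
  reaches into the nodal patch, so nodal tissue surrounds its tip on
  several faces and can ignite it (the real SAN--atrial junction is
  likewise interdigitated);
* the His bundle originates *inside* the AV node block and only then
  crosses the insulating gap, so nodal tissue surrounds its origin;
* the bundle branch runs subendocardially through chamber-blood voxels
  along the septal surface (blood-insulated, like the fibrous sheath of the
  real branches), so its only myocardial contacts are the Purkinje layer
  and ventricular myocardium is always reached through that layer.

With these choices the default and fixture geometries reproduce the
physiological first-activation ordering SAN, atria, AVN, His, bundle
branches, Purkinje, ventricles, with a nodal delay of several tens of
milliseconds. Activation times are measured as the first upward crossing of
$V_m$ above $B + 0.75A$; 75 % of the amplitude is robust against boundary
smoothing and electrotonic ramps.

## Infarct lesions

Following the infarct protocol, the intracellular conductivity and the rate
constant `k` are zero in the lesioned myocardium and its initial potentials
are $V_i = -60$ mV, $V_e = -20$ mV. Two treatments of the lesion boundary
are conceivable, and they lead to qualitatively different electrograms:

* with strictly harmonic averaging the zero-conductivity lesion is
  decoupled from the surviving tissue; it is then electrically invisible in
  diastole, no injury current flows, and the ST segment of a facing lead is
  *depressed* (a pure "missing activation window" effect);
* if the interface keeps intracellular coupling, the depolarised lesion
  interior (held at $V_m = -40$ mV) drives a persistent diastolic injury
  current, and a facing lead shows the classical pattern — baseline (TQ/PQ)
  depression that reads as ST *elevation* after baseline referencing.

The second is the textbook electrophysiology of transmural infarction
(anterior apical MI: ST elevation in V1; inferior apical MI: V1
depression), so `bidecg` implements it: lesion
nodes are frozen at their injury potential, the intracellular operator
keeps the regional conductivity on lesion faces (scaled by a border-zone
coupling factor, default 0.5), and the lesion is surrounded by a two-voxel
"stunned" border zone — unexcitable (`k = 0`) but conductive myocardium
that smooths the 45 mV standing gradient. Without the stunned zone the
standing gradient slowly drives rim voxels over threshold and the lesion
becomes an ectopic focus; the two-voxel shell keeps every excitable voxel
several millivolts below threshold while preserving most of the injury
dipole ($\sigma_i$ times the core-to-rest potential difference). A
morphological closing absorbs surviving slivers enclosed by lesion. The
reported conductivity and rate maps still show $\sigma_i = 0$, $k = 0$
throughout the lesion, per the protocol. ST comparisons are made by sign
and ordering only — no ST amplitudes are printed in the source material —
at J + 40 ms against the median of the P--Q segment, with QRS bounds at
10 % of the beat's maximal $|dV/dt|$.

One caveat on limb leads: in this package's upright spherical heart both
apical lesions face the inferior limb lead, so their injury dipoles project
*positively* onto lead II. The model therefore discriminates the two
infarcts in V1 (anterior elevated, inferior depressed) and preserves the
anterior-below-inferior ordering in lead II, but does not show the
II-below-normal depression that a tilted anatomical heart axis can produce;
the ST pattern of limb leads is well known to hinge on the heart's
orientation within the torso, and the test suite records this limitation
explicitly.

## Fixtures and problem sizes

The default geometry (4 mm grid over a 0.35 x 0.25 x 0.6 m torso, heart
radius 6 cm) is used for geometry-level validation. PDE-level tests and the
infarct experiments run on the `tiny-3d` fixture: an 8 mm grid, under
$24^3$ voxels, with a 5.5 cm heart whose walls are thickened to stay
resolvable (every modelled thickness at least two voxels). The package's
own test suite simulates 1.8 s of the normal heart (two spontaneous beats)
and 0.9 s per infarct case, and measures conduction velocity on 5 cm
single-region strips at 2 mm and 1 mm. These sizes were chosen so the whole
suite exercises every code path at desk scale; they are configuration
values, and every dimension is overridable from the YAML configuration.

What the fixture does *not* emulate: anisotropic fibre architecture (all
conductivities are scalar), image-derived anatomy, ionic-channel-level
membrane models, and rate-dependent restitution. Passing tests therefore
certify the solver and the lead calculus, the topology of conduction and
the sign structure of the infarct electrograms — not quantitative clinical
morphology. Absolute interval durations (P-R, QRS width) follow the
parameter tables literally under the unit-capacitance normalisation and
have no independently printed reference values.

## Numerical choices and degenerate inputs

* Linear solves: direct sparse Cholesky; the elliptic residual is at
  machine precision relative to the source, and the test suite checks
  conservation (zero column sums of the intracellular operator) and gauge
  invariance (solutions unchanged under constant offsets of the potential).
* A globally infarcted heart (all $\sigma_i = 0$, `k = 0`) is a valid
  configuration: nothing activates, traces are flat.
* Degenerate lesions with a zero radius are no-ops; lesions that intersect
  no myocardium are rejected.
* The cubic-root finder reports "no cubic" when $c_1 = 0$.
* Electrode targets must lie in the unit cube of fractional positions;
  targets far from any surface node (interior points) are rejected, and
  electrodes snapping to a shared node produce a warning naming both.

## Known limitations

* At 8 mm the fixture's QRS is broad and blocky; lead morphology sharpens
  under refinement (the conduction-velocity self-convergence test
  quantifies the resolution effect on wave speed).
* The equal-anisotropy-ratio parameter tables ($\sigma_e = \sigma_i$
  everywhere) limit how much extracellular waveform detail the bidomain
  formulation can add over a monodomain model; the full bidomain machinery
  is nevertheless retained, as the volume conductor coupling requires it.
* Multi-resolution convergence of full-torso lead traces is not part of the
  default suite (three full simulations would dominate its runtime);
  spatial refinement is instead covered by the strip conduction-velocity
  convergence check and temporal refinement by the single-cell dt-halving
  check.
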