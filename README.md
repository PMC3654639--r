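# bidecg

A simplified, computationally light 3D bidomain simulator of whole-heart
electrical activity inside a human torso, with synthesis of the standard
12-lead electrocardiogram, the Frank-lead vectorcardiogram and RMS /
signal-averaged ECG curves — plus tools for myocardial-infarction
experiments, ECG fiducial detection and ST-segment quantification.

It is aimed at researchers and students of computational
electrophysiology who want a whole-heart-to-ECG forward model that runs on
a desk machine: a stepping stone between single-cell / tissue-patch models
and anatomically detailed whole-torso solvers, useful for exploring how
cell, tissue and lesion properties shape the surface ECG.

## The model

Three fields live on a regular voxel grid: the intracellular and
extracellular potentials V<sub>i</sub>, V<sub>e</sub> (transmembrane
potential V<sub>m</sub> = V<sub>i</sub> − V<sub>e</sub>) and a recovery
variable u. On the heart the bidomain equations

∂V<sub>m</sub>/∂t = ∇·(σ<sub>i</sub>∇V<sub>i</sub>) − i<sub>ion</sub>,  ∇·((σ<sub>i</sub>+σ<sub>e</sub>)∇V<sub>e</sub>) + ∇·(σ<sub>i</sub>∇V<sub>m</sub>) = 0

are closed by modified FitzHugh–Nagumo kinetics with normalised excitation
v = (V<sub>m</sub> − B)/A:

i<sub>ion</sub> = k c₁ (V<sub>m</sub> − B)(a − v)(1 − v) + k c₂ u ·
{1 in the SAN; (V<sub>m</sub> − B) elsewhere},  du/dt = k e (v − d u − b)

Torso, lungs and chamber blood are passive conductors,
∇·(σ<sub>o</sub>∇V) = 0, with an insulating torso surface and one grounded
electrode (the right leg, V<sub>GND</sub> = 0 V). Seven heart regions —
sinoatrial node (self-oscillatory: a < 0, b < 0), atria, AV node, His
bundle, bundle branches, Purkinje layer and ventricular myocardium — carry
heterogeneous parameters; activation starts spontaneously in the SAN and
propagates down the conduction chain, the low-conductivity AV node
providing the atrioventricular delay. Surface electrode potentials yield
leads I, II, III, aVR, aVL, aVF, V1–V6, the Frank X/Y/Z leads and the
derived RMS and SAECG curves.

See the methods vignette (`vignettes/bidecg-methods.Rmd`) for the
discretisation, the stability handling of the stiff sinoatrial kinetics,
the conduction-system geometry and the infarct border-zone model.

## Worked example

```r
library(bidecg)

## the ventricular ionic-current cubic: roots at B, B + aA, B + A
cubic_roots(region_defaults("Ventricles"))
#> [1] -85.0 -66.8  55.0

## the sinoatrial cell fires spontaneously
tr <- integrate_cell(region_defaults("SAN"), duration = 2)
pk <- which(diff(sign(diff(tr$Vm_mV))) == -2) + 1
round(tr$time_s[pk[tr$Vm_mV[pk] > 0]], 3)
#> [1] 0.315 1.155 1.996

## a coarse torso simulation: 0.6 s on a < 24^3 grid (~25 s of wall time)
cfg <- make_fixture("tiny-3d")
cfg$solver$duration <- 0.6
res <- run_simulation(cfg)
round(res$activation, 4)
#>        SAN      Atria        AVN        His        BNL   Purkinje Ventricles
#>     0.3149     0.3333     0.4060     0.4671     0.4835     0.4977     0.5094

leads <- derive_leads(res)
round(range(leads$lead_II), 2)
#> [1] -0.64  4.01
```

The activation table is the heart's first-activation time per region: the
SAN fires spontaneously at 0.315 s, the atria follow within ~20 ms, the AV
node imposes a ~70 ms delay, and the His–Purkinje system distributes
activation to the ventricles. `leads` holds the full 12-lead + Frank
channel set in mV at 1 ms resolution; lead II shows a ~4 mV R wave.

Infarct experiments place transmural apical lesions
(`lesions: [anterior-MI]` in the YAML config, or `lesion_preset()`) and
`compare_st()` quantifies the resulting ST-segment shifts against a normal
run.

A thin command-line wrapper covers the same pipeline:

```sh
inst/cli/bidecg fixture  --kind tiny-3d --out tiny.yml
inst/cli/bidecg validate --config tiny.yml
inst/cli/bidecg simulate --config tiny.yml --out-dir out/
inst/cli/bidecg leads    --in out/electrodes.csv --out out/leads.csv
inst/cli/bidecg features --in out/leads.csv --lead lead_II --out out/features.csv
```

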