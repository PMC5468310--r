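---
title: "Compartmental cable models in uniform electric fields: methods and design"
author: "cableEF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartmental cable models in uniform electric fields: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cableEF)
```

## The model

cableEF simulates how a spatially extended neuron responds to a uniform
extracellular electric field (EF), the stimulus delivered (in idealized form)
by transcranial direct-current stimulation or parallel-plate in vitro setups.
The neuron is a rooted tree of cylindrical sections — a soma, an axon toward
−y, and dendrites toward +y, with the y axis the somato-dendritic axis and
the field axis. Each section is discretized into compartments governed by
the cable equation

$$C_m \frac{\partial V}{\partial t} + I_{ion}(V, t)
  = \frac{d}{4 R_a} \frac{\partial^2 V_{in}}{\partial x^2},$$

where $V = V_{in} - V_{ext}$ is the transmembrane potential. Discretized,
the axial current between adjacent compartment centers $j,k$ is
$g_{jk}\,[(V_k + V_{ext,k}) - (V_j + V_{ext,j})]$ with $g_{jk}$ the series
combination of the two half-compartment cytoplasmic resistances. A uniform
field of amplitude $E$ (mV/mm) at angle $\varphi$ from the y axis (always 0
here) sets $V_{ext}$ at each compartment center to $E$ times the distance
along the field axis from the cathode reference plane. Only differences of
$V_{ext}$ enter the dynamics (the solver is gauge-invariant, and a test
asserts this), so the reference plane — the minimum-y bounding plane for
positive fields, maximum-y for negative — is a reporting convention. A
positive field places the anode on the dendritic side: dendritic membrane
hyperpolarizes, the axonal end depolarizes. Transverse field coupling is
neglected, as is any feedback through the extracellular medium.

$I_{ion}$ is leak plus four voltage-gated currents of the CA1 pyramidal
repertoire: transient Na ($m^3 h$), delayed-rectifier K, A-type K (with slow
inactivation), and the hyperpolarization-activated cation current h. Peak
densities follow distance rules: Na and Kdr uniform at 200 and 100 pS/μm²;
A-type K 250 pS/μm² at the soma rising by 250 pS/μm² per 100 μm of path
distance on dendrites; h from 0.5 pS/μm² rising by 1.5 pS/μm² per 100 μm on
dendrites; axonal sections carry the somatic densities. Passive constants:
$C_m$ = 1 μF/cm², $R_a$ = 80 Ω·cm, $R_m$ = 28 kΩ·cm² (leak conductance
$1/R_m$), leak reversal −65 mV. Path distance is measured from the soma
midpoint, which is also the default recording point.

## Gating kinetics: a pluggable, versioned parameter file

The channel rate equations are not part of the geometric model; they live in
a YAML parameter file (`inst/extdata/kinetics/ca1_default.yaml`) with, per
gate, a sigmoid steady state $x_\infty(v) = 1/(1+e^{(v_{1/2}-v)/k})$
($k<0$ for inactivation or hyperpolarization-activated gates) and a constant
or bell-shaped time constant
$\tau(v) = \tau_{min} + a/(e^{(v-v_m)/k_1}+e^{-(v-v_m)/k_2})$. Reversal
potentials (Na +55, K −90, h −30 mV) are stored in the same file and never
hard-coded. The shipped default is an independent transcription of the
Migliore-family CA1 channel set recast into this parameterization;
half-activation voltages and slopes follow the published family (Na
activation ≈ −38 mV with 7.2 mV slope, Na inactivation −50/−4, Kdr +13/8.8,
A-type +11/12 and −56/−8, h −81/−8), and the bell time constants are smooth
fits chosen once for standard CA1 physiology: resting potential near −70 mV
(the full model rests at −69.4 mV), somatic spike threshold near −50 mV,
overshooting axonal action potentials. Any scheme in the same format can be
swapped in through `readKineticScheme()` or the workbench config; result
sidecars record the file's md5 hash.

Temperature scaling is not modeled. The scheme places the cell in the
*integrator* excitability class: near threshold it can fire arbitrarily
slowly, so measured firing rates just above threshold are at the quantum set
by the rate window (2 Hz for the default 500 ms field). A resonator-class
variant (delayed-rectifier half-activation near 0 mV) was evaluated during
development; it produces an abrupt ~30 Hz onset but couples the firing
threshold to total membrane load so strongly that most morphology–threshold
relationships below become non-monotonic. The integrator variant is both
the more faithful transcription and the better-behaved model, so it ships
as the default; the f–E onset discontinuity is the one signature of the
reference phenomenology it does not show.

## Numerics

The voltage system is advanced by a first-order implicit (backward Euler)
step: gating variables are updated first by the exact exponential relaxation
toward $x_\infty(V^n)$ over one step, conductances are frozen at the updated
gate values, and the resulting linear tree system is solved by Hines
(parent-ordered) elimination in compiled code — $O(n)$ per step,
unconditionally stable on stiff cables. Default dt = 0.025 ms; a
self-convergence test bounds the dt = 0.05 → 0.025 change of a passive
somatic trace below 0.1 mV. Gating rates are evaluated through lookup tables
on a 0.05 mV grid over [−150, 80] mV with linear interpolation (rebuilt per
run, so they track dt); `use_tables = FALSE` evaluates the closed forms
exactly, and the solver-equivalence test compares the compiled path against
an independent dense-matrix R implementation to 10⁻⁶ mV.

Sections are split into equal compartments of length at most `max_dx`
(default 10 μm), always an odd count so every section has a true midpoint
compartment — recording sites and the spatial-convergence comparison use
exact midpoints at every resolution. Initialization relaxes the full system
field-free until the largest |dV/dt| falls below 10⁻³ mV/ms (a passive
membrane is set to the leak reversal exactly). Divergence (|V| > 500 mV)
aborts with the time and site. Correctness anchors: the analytic solution of
a two-compartment passive system (per-step error < 10⁻⁶ mV), the closed-form
polarization of a sealed passive fiber in a uniform field,
$\Delta V = \pm E\lambda \sinh((x - L/2)/\lambda)/\cosh(L/2\lambda)$ with
$\lambda = \sqrt{R_m d / 4 R_a}$ (< 1% sup-norm error at Δx ≤ λ/50), and a
per-step junction current balance residual below 10⁻⁹.

## Protocols

*Spike detection* marks upward crossings of −10 mV at the soma midpoint with
a 2 ms refractory period. The −10 mV default (rather than 0 mV) reflects the
shipped kinetics: strong delayed-rectifier clipping keeps somatic AP peaks
near +7 mV while subthreshold somatic excursions stay below −35 mV, so
−10 mV separates the two with a wide margin on both sides.

*EF firing threshold* (`findEFThreshold`) scans field magnitude upward in
coarse steps (default 10 mV/mm, 25 in the sweep suite) from a quiescent
baseline until a spike occurs, then bisects to the requested resolution
(default 0.5 mV/mm, configurable to 0.1). The field is a step, on from 100
to 600 ms of a 700 ms run. Every result carries its bracket and full search
log, and tests re-simulate both bracket ends.

*f–E curves* report the firing rate over the field-on window. *Sweeps*
(`sweepThreshold`, `monotonicitySuite`) rebuild the artificial morphology
per grid point and search the threshold; `thresholdRelationships()` is the
catalogue of 15 parameter–direction relationships with their desk-scale
grids. *EPSC co-stimulation* injects a rectangular current pulse (the
EPSP surrogate) into distal dendrite "dend8" — deterministically the first
distal branch of the rightmost proximal dendrite — spanning the field
window; pulse timing is configurable since synaptic kinetics are out of
scope. *AP diagnostics* record all compartments and report per-site peaks
during the first AP and the earliest-crossing (initiation) site.
*Polarization* protocols settle the membrane under subthreshold fields and
fit the somatic deflection against E.

## What the artificial neuron does and does not reproduce

The default cell spans ~115 μm, about 5% of its cable length constant, so
its interior is nearly isopotential and the steady polarization at height
$y$ is close to $E(\bar y - y)$, where $\bar y$ is the conductance-weighted
mean height. Several robust consequences follow, and the test suite
measures all of them rather than asserting any by fiat:

- Both field polarities trigger APs, at asymmetric thresholds (the
  dendritic A-current gradient makes the negative polarity harder; with the
  shipped kinetics +398 vs −642 mV/mm at 0.1 mV/mm resolution).
- The axonal AP peak exceeds the somatic peak, which exceeds dendritic
  peaks.
- Thresholds fall with dendritic/somatic cable added above the soma and
  with axon length, rise with dendrite bend/bifurcation angles and under
  successive dendrite removal — ten of the fifteen catalogued relationships
  match the reference directions.
- A subthreshold EPSC lowers the EF threshold dramatically (≈398 → ≈69
  mV/mm at 0.01 nA). The 0.03 nA pulse is suprathreshold on its own in this
  small high-impedance cell and is reported as such (`epsc_alone_spikes`).

Two signatures are *not* reproduced, for reasons the isopotential analysis
makes mechanistic rather than numerical. First, with uniform Na density the
most field-depolarized site is always the lowest axonal point, so APs
initiate at the distal (cathodal) axon end, not the initial segment, and
the four axon-structure relationships (threshold rising with axon diameter
and terminal count, falling with axon bend and terminal branch angle) come
out inverted: they presuppose that the axon acts purely as a current sink
on a soma-governed initiation site, whereas here adding or straightening
axonal cable also deepens the most excitable tip. No uniform-excitability
kinetics can make the less-depolarized soma fire first, so this is a
structural property of the printed densities and geometry, not a solver
artifact. Second, the integrator-class onset discussed above means the f–E
curve rises from zero through the rate quantum instead of jumping to a
finite rate. Both are left as measured.

## Synthetic asymmetric morphologies

`generateTree()` grows seeded random dendritic trees (default 16 branches,
length 60 ± 20 μm, diameter 1 μm, depth ≤ 3) on a 10 × 10 μm soma with a
50 × 2 μm axon, assigning each branch to the +y or −y side greedily to track
a target *anode-side cable fraction*, then rescaling the +y-side lengths
once so the realized fraction (computable via `asymmetryIndex()`) matches
the target. Branch tilts stay within 60° of vertical, so side assignment is
exact. These trees emulate one structural property of real reconstructions
— how much dendritic cable lies on each side of the soma along the field
axis — and none of their other statistics (taper, tortuosity, 3-D
structure, realistic branch-order distributions), so passing the
polarization tests below says nothing about absolute polarization values in
real cells, only about the sign mechanism. Passive membranes are used for
these analyses, keeping the polarization exactly linear in E.

Anode-heavy trees (fraction > 0.6) polarize their soma positively with
increasing field, cathode-heavy trees (< 0.4) negatively, across seeds, and
the slope trends monotonically with the asymmetry index (Spearman
correlation > 0.9 across a ten-tree ensemble): the cell's center of
electrical mass sits on the dendrite-rich side, and the soma, below it,
behaves like the cathode-directed end of an equivalent fiber.

## Problem sizes and determinism

Default discretization gives 18 compartments for the reference neuron
(~10⁵ implicit steps per 700 ms run); the sealed-fiber benchmark uses
λ/50 ≈ 19 μm compartments on a 3λ fiber (151 compartments); the
monotonicity suite is 15 sweeps × 4 grid points with a 25 mV/mm coarse scan
at 0.5 mV/mm resolution; polarization ensembles use 10–20 generated trees.
These are the package's declared desk-scale settings; every protocol accepts
finer grids. There is no stochastic element anywhere in the dynamics — the
only randomness is the seeded tree generator — so every protocol is
bit-reproducible from its configuration, which the workbench writes next to
every result together with the kinetics file hash and package version.
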