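---
title: "Modelling dentate granule cells with gcell: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dentate granule cells with gcell: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gcell)
```

# The model

`gcell` simulates dentate gyrus granule cells (GCs) as compartmental
conductance-based neurons. A neuronal tree (read from SWC or generated
synthetically) is discretized into electrically coupled isopotential
compartments, and each compartment's membrane potential obeys the cable
equation

$$C_i \frac{dV_i}{dt} = -\sum_k \bar g_{k,i}\, o_k(V_i, [\mathrm{Ca}]_i)\,
  (V_i - E_k) \;+\; \sum_{j \sim i} g_{ij} (V_j - V_i) \;+\; I_i(t),$$

with membrane capacitance $C_i$ (specific capacitance times frustum surface
area), maximal conductances $\bar g_{k,i}$ set per channel and per region,
open fractions $o_k$ from the channel kinetics, axial couplings $g_{ij}$
derived from the axial resistivity $R_a$ and the frustum geometry, and
electrode or synaptic current $I_i$. Currents are outward-positive; units
follow the conventions of compartmental simulators throughout: mV, ms, nA,
µS, mS/cm², µF/cm², µM, µm.

## Regions

Seven regions key all spatial specificity: **soma**, **axon**, **AIS** (axon
initial segment) and the four dendritic bands **GCL**, **IML**, **MML**,
**OML** (granule cell layer and inner/middle/outer molecular layer).
Channel densities, synapse placement and the morphology generator's layer
annotations all use these labels. Reconstructions in plain SWC carry no
layer planes, so `assign_regions()` supplies two conventions:

* **fractional** (default): the GCL/IML border sits a configurable GCL
  thickness (default 10 µm) from the soma along the first principal
  component of the dendritic point cloud, the maximal dendritic extent
  defines depth 1, and IML/MML/OML are the equal thirds of that span. This
  is a stand-in for true anatomical layer planes, which SWC files do not
  encode; when boundary depths are known they should be supplied instead.
* **explicit**: boundary ranges in µm from the GCL/IML border.

The AIS similarly has no SWC type code; it is declared as an arc-length
window on the axon (the generator labels the first 30 µm).

## Channel inventory and kinetics

The shipped mature mouse GC model (`granule_cell_model()`) carries the full
region-keyed density table of the cell's known channel isoform inventory:
Nav (somatic/axonal, strongly enriched in the AIS), the K2P leak, inwardly
rectifying Kir2, dendritic HCN with a cAMP-dependent activation shift,
axonal Kv1.1/Kv1.4/Kv3.4/Kv7, somatic Kv2.1, dendritic A-type Kv4.2/3,
L-, N- and T-type Cav (the L-types with Ca-dependent inactivation),
Ca-activated BK (α and α+β4) and SK2. Densities are in mS/cm² per region
and drive everything downstream: multiplying them is how all named variants
work.

Kinetics are declared, not hard-coded: a channel is `passive`,
`instantaneous` (open fraction follows voltage with no dynamics — used for
Kir rectification), `hh` (a product of gates with Boltzmann or α/β rate
steady states and constant, bell-shaped or rate-derived time constants,
including Hill-type calcium gates for BK/SK and Ca-dependent inactivation),
or `markov` (an arbitrary state scheme with voltage- and Ca-dependent
transition rates). The whole model round-trips through a versioned YAML
schema (`write_model_config()` / `read_model_config()`) with strict
validation, so experimentally fitted kinetic parameter sets can be dropped
in without touching code.

The *shipped* kinetic parameterizations are generic templates chosen so the
full protocol battery runs and behaves qualitatively like a GC — strong
inward rectification that shuts off with depolarization (the basis of the
cell's low rheobase relative to its resting conductance), AIS spike
initiation near −48 mV, ~1 ms spikes, fast AHPs carried by BK/Kv3 —
not fitted reproductions of measured kinetics. Quantitative feature-table
matching requires loading fitted parameter sets through the config schema;
the package's accuracy claims are therefore made against analytic and
numerical oracles, not against experimental feature tables.

Temperature enters through per-gate Q10 factors (default 2.3 for time
constants, reference 24 °C; conductances carry no Q10 by default):
compiled time constants are divided by $Q_{10}^{(T-T_{ref})/10}$.
Protocol-level defaults follow the experimental conditions: room
temperature for most measurements, 33 °C for backpropagation.

## Calcium and synapses

Each compartment has a phenomenological submembrane calcium shell
(depth 0.1 µm, instantaneous buffering factor κ = 100, decay to a 0.05 µM
resting level with τ = 150 ms): inward Ca-channel current contributes
$-I_{Ca}/(2 F V_{shell} \kappa)$ and the shell relaxes exponentially. These
four numbers are config-exposed (`ca_dynamics()`); the weighted decay time
constant measured from simulated transients recovers the shell τ, which is
what the recovery tests assert. AMPA-type synapses are normalized double
exponentials (defaults: rise 0.2 ms, decay 2.5 ms, peak 1 nS, reversal
0 mV) superposed linearly per presynaptic spike; presynaptic trains are
homogeneous Poisson (`poisson_train()`) or the regular volleys of the
synaptic-drive protocol. Synaptic time constants and peak conductance are
deliberately exposed as unconstrained knobs.

# The synthetic morphology generator

`generate_granule_cell()` follows the cone-and-MST recipe for GC dendrites:

1. sample `n_target_points` uniformly in a 3D cone (apex at the soma, axis
   along the layer normal; default half-angle 35°, height 300 µm for the
   young tree);
2. add *directed* points between k-means clusters of the targets and the
   soma (default 4 clusters, placed halfway), which seed realistic proximal
   trunk structure;
3. connect all points by a greedy minimum-spanning-tree extension that
   attaches the point minimizing *(Euclidean distance to the tree)* +
   `balancing_factor` × *(path distance of the attachment node to the
   root)*. At balancing factor 0 this **is** Prim's algorithm, so the total
   cable length equals the classical Euclidean MST — the correctness anchor
   verified against an independent oracle. Ties attach to the lowest node
   id for reproducibility;
4. prune terminal segments shorter than 20 µm, iteratively to a fixed
   point;
5. stretch the young tree to mature size (default ×1.35 along the cone
   axis);
6. taper diameters monotonically root→tip (quadratic in normalized path
   distance, 2.2 µm down to 0.8 µm);
7. jitter positions with zero-mean AR(1) noise along the tree (3 µm
   amplitude, 20 µm correlation length), keeping the root fixed, then
   re-prune once — jitter can re-shorten a terminal, and the no-short-
   terminal invariant is enforced on the final geometry;
8. attach a soma diameter profile (15 µm long, 12 µm max diameter) and a
   synthetic axon (100 µm, 0.7 µm diameter) whose first 30 µm are AIS, and
   assign molecular layers.

Where the anatomical literature pins a value (the 20 µm pruning threshold,
the layered cone geometry) the default is that value; the remaining knobs
(cone angle, directed-point rule, taper, jitter law, `n_target_points = 30`
chosen so post-prune branch-point counts land in the range of reconstructed
mouse GCs, balancing factor 0.5) are exposed in `mst_params()` and
documented as this package's choices. Identical parameters and seed yield
byte-identical SWC output.

What the generator emulates: realistic total dendritic length, branch-point
counts, layer spans, taper and the cable load they impose on somatic
measurements. What it does not: spines, boutons, reconstruction artifacts,
diameter noise, or the correlated tortuosity of real dendrites — so tests
passing on synthetic trees demonstrate engine and protocol correctness and
qualitative robustness across morphologies, not anatomical fidelity of any
single cell.

# Numerics

**Spatial discretization.** Unbranched sections (split at branch points and
region changes) are divided into an odd number of compartments by the
d_lambda rule — a tenth of the AC length constant at 100 Hz by default — or
a fixed maximum length. Surface areas are conical frusta; axial resistances
integrate $R_a/(\pi r^2)$ exactly over the linearly tapered frusta and
couple adjacent compartment centres. A lone soma node becomes a sphere.
Total membrane area is independent of the discretization by construction.

**Time stepping.** The voltage solve is a θ-method (backward Euler θ = 1 by
default; Crank–Nicolson θ = ½ optional) with membrane conductances frozen
at the step's start — a tree-structured (Hines-ordered) symmetric
elimination, one O(n) sweep down and one up, unconditionally stable for the
passive subsystem. Gates then advance by exponential Euler (exact for the
frozen voltage), Markov occupancies by backward Euler (an M-matrix solve,
hence nonnegative, renormalized to unit sum), and shell calcium implicitly.
The compiled core tabulates each gate's steady state and per-step decay
factor on a 0.25 mV grid (linear interpolation) — the standard trick that
makes the per-step cost a pair of lookups; the table is rebuilt per run for
the current dt and temperature. Default dt is 0.025 ms.

**The module-level Markov propagator.** `markov_update()` — the exposed
single-step operation, as opposed to the engine-internal update — uses
*uniformization*: the exact matrix exponential of the frozen-rate generator
evaluated as a Poisson-weighted power series of a stochastic matrix. Rates
are frozen over a step by the staggering convention anyway, so exactness
costs nothing; the propagator is unconditionally stable, keeps every entry
nonnegative, and conserves total occupancy to round-off (the vector is
renormalized each step, keeping drift below 10⁻¹² over 10⁵ steps). A plain
backward-Euler step has a local defect of order $(Q\,\Delta t)^2/2$ — about
5×10⁻⁵ at dt = 0.01 ms with rates of order 1/ms — which cannot meet the
10⁻⁸ agreement with an independent matrix-exponential oracle that the test
suite demands; the engine's internal backward-Euler path is retained for
robustness in the stiff in-simulation setting.

**Clamps and holding.** Voltage clamp pins the clamped compartment through
a 10⁶ µS series conductance (a 1 Ω series resistance): this keeps the Hines
structure symmetric, reproduces the capacitive transient in the electrode
current, and leaves a voltage error of order $R_s/R_{in} \sim 10^{-8}$
relative — the "optional series resistance" reading of an ideal clamp.
Current-clamp holding potentials are realized as a constant somatic bias
current found by bisection (500 ms equilibration, soma within 0.1 mV of
target over the final 50 ms), cached per model/mesh/target within a
session. Spike detection is an upward 0 mV crossing with a 2 ms refractory,
both config-exposed. All protocol potentials are treated as already
corrected for the 12.1 mV liquid junction potential; the engine performs no
LJP arithmetic, and the flag on each protocol records that frame.

**Degenerate inputs.** Zero-length sections, non-positive radii, forward
parent references, unknown regions and non-finite states all raise classed
errors (`swc_*`, `morph_*`, `engine_diverged` with a time stamp);
single-node trees yield zero-valued morphometrics rather than errors.

# Protocols and feature definitions

The battery mirrors standard GC electrophysiology:

* **I–V**: voltage-clamp steps (default −152.1 … −62.1 mV from −82.1 mV,
  200 ms), steady-state current as the mean over the final 10% of the step
  — "steady state" needs a window and this is the package's reading.
* **F–I**: 200 ms current steps from −80 mV, default 0–100 pA in 5 pA
  increments; counts are not forced monotone (adaptation may break
  monotonicity).
* **Features** (`ephys_feature_table()` and the individual extractors):
  input resistance from a 10 mV depolarizing step at −92.1 mV; capacitance
  as the transient-charge integral of a −10 mV step; membrane τ by
  single-exponential fit after a 10 pA hyperpolarizing 500 ms step (fit
  window starts 2 ms after onset to skip fast equalization); AP threshold
  at the first sample with dV/dt > 15 mV/ms in a 10 ms pre-peak window
  (central differences); amplitude peak-minus-threshold; width at half that
  amplitude with linear interpolation at both crossings; fAHP as
  threshold-minus-minimum between consecutive APs only when the minimum
  falls within 5 ms of threshold (later minima are medium AHPs and the
  feature is *absent*, never a negative artifact); rheobase as the first
  spiking amplitude on a 5 pA grid — the source convention prints "5 mV
  intervals" for this current grid, which this package reads as a units
  typo; ISI adaptation ratio 1 − first/last ISI; Kir slope conductance as
  the I–V slope over −152.1…−122.1 mV minus the slope over −82.1…−62.1 mV;
  Ca-transient weighted τ from a biexponential decay fit
  ($\tau_w = (a_1\tau_1 + a_2\tau_2)/(a_1+a_2)$), implemented as a bounded
  Levenberg–Marquardt fit with a free offset (an unbounded slow component
  is otherwise collinear with the baseline).
* **bAP / Ca**: a brief (2 ms) suprathreshold somatic pulse; per-site
  maximal amplitude above baseline, delay of the maximum versus the somatic
  maximum, velocity = path distance / delay; the pulse amplitude is not
  pinned by the source conventions and defaults to 2 nA.
* **Synaptic drive**: 15 MML + 15 OML synapses placed uniformly over
  compartment surface area (seeded), regular volleys at 5–100 Hz, output
  spikes per input volley; `delta_t` shifts the OML onset, with negative
  values meaning the MML leads.
* **Sensitivity**: per-channel ×0.5 density reductions plus the canonical
  parameter shifts (E_K and E_pas +10 mV, E_Na −20 mV, +10 °C, cAMP
  0→1 µM); cells where a feature is undefined under a perturbation are
  flagged `NA`, never an error.

# Variants

`builtin_variants()` ships the named multiplicative variants: `barium`
(200 µM Ba²⁺ ≙ 99% Kir2 + 30% K2P blockade), `epilepsy` (doubled Kir2 and
HCN), `kv11_overexpression` (Kv1.1 ×3), `young_abgc` (the young adult-born
GC downregulation set: Kir2 ×0.27, Kv2.1/Kv4.2/Kv7/Cav1.3 ×0.5, Nav ×0.75,
BK-α ×0.6, BK-α/β4 ×0, with Kv1.4, Kv3.4 and Cav1.2 unchanged) and
`rat_mature` (increased Kir2; the factor is config-exposed because it is
fitted per dataset, default ×2). `apply_variant()` is pure, multiplies
region-restricted density factors, and composes by multiplication.

# What the tests establish

The suite is oracle-based: passive RC charging against the closed form
(< 10 µV), the sealed finite cable against the coth input-resistance
formula (< 0.5% converged), exponential-Euler gates against an adaptive
ODE solution (< 10⁻⁶), the Markov propagator against an independent matrix
exponential (< 10⁻⁸, conservation < 10⁻¹² over 10⁵ steps), spike counts of
the squid-type fixture against an adaptive ODE oracle (exact), balanced-MST
cable length at bf = 0 against an independent spanning-tree oracle (exact
to round-off), the Monte-Carlo cone centroid against the closed form
(3/4 height, < 1%), every extractor against planted trace parameters, and
the variant table against its printed factors with direction-of-effect
checks (Ba²⁺ raises input resistance, the epilepsy variant lowers it) on
the shipped model. Problem sizes are chosen for sharp oracles at modest
cost: single compartments and ≤ 201-compartment cables for analytic
checks, ≤ 50-point clouds for exact MST equality, 10⁵ samples for the
Monte-Carlo centroid, a ~140-compartment synthetic GC for the battery.

# Limitations

* The shipped kinetics are generic templates; absolute feature values of
  the GC model (rheobase, fAHP, gKir) are in the physiological range but
  are not fitted, and differ across morphologies — matching measured
  feature tables requires importing fitted kinetic parameter sets through
  the config schema.
* Ca channels are ohmic with a fixed +130 mV reversal (no GHK flux);
  calcium is a single unsaturated shell per compartment.
* No networks, no extracellular fields, no stochastic single-channel
  gating; simulations are single-process.
* The fractional-thirds layer convention is a stand-in for anatomical
  layer boundaries.
* The fAHP can be legitimately absent under its 5 ms rule at near-rheobase
  amplitudes when the interspike trough bottoms out late; reports that
  need a defined value measure it at the first amplitude of a family where
  the rule is met.
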