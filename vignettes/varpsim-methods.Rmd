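---
title: "varpsim: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{varpsim: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package computes

`varpsim` asks one question of a tissue model: *if this piece of
infarcted myocardium is paced aggressively from many sites, does it
sustain a re-entrant arrhythmia?* The pipeline is

1. a **labeled tissue model** — nodes, quad/hex elements, and a
   three-label tissue structure (non-infarcted myocardium, grey zone,
   scar) at a working resolution of 0.35 mm;
2. **fibre orientations**, assigned by the Laplace–Dirichlet rule-based
   method on ventricular geometries and as constant or prescribed
   directions on sheets and slabs;
3. **membrane kinetics**, a human ventricular ionic model with
   grey-zone ion-channel remodelling;
4. the **monodomain tissue solver**, anisotropic reaction–diffusion
   with scar removed from the conductive domain;
5. the **programmed-stimulation engine**: 8 conditioning stimuli (S1)
   at a 600 ms cycle length from each pacing site, then up to three
   decremental extrastimuli (S2–S4), with capture checking, re-entry
   detection, and per-site/overall classification.

An overall test is *positive* when at least one pacing site elicits
re-entrant activity persisting more than 1 s after the last stimulus.

# Tissue model and segmentation

Meshes are structured regular grids (quads in 2D, hexahedra in 3D).
The idealized ventricle is a voxelized truncated-ellipsoid shell —
endo/epi/base/apex surfaces identified geometrically, with an optional
thinner-walled partial-ellipsoid right ventricle fused laterally — a
stand-in for patient anatomy that suffices for pacing-site placement
and fibre rules, not a geometric model of any heart.

Synthetic signal-intensity volumes are classified by the
full-width-at-half-maximum rule: the *hyperenhanced* region is every
myocardial voxel brighter than the peak intensity of a known remote
(non-infarcted) reference region; voxels at or above half of the
hyperenhanced maximum are scar, the remaining hyperenhanced voxels are
grey zone. Both thresholds are relative, so the classification is
invariant under positive rescaling of the signal. Two conventions are
deliberate and tested: the half-maximum cutoff is *inclusive* (a voxel
exactly at 50 % is scar), and the hyperenhanced region is defined by
the peak — not mean — remote intensity. Voxel labels transfer to
elements by majority vote with ties broken toward the more severe
label.

# Membrane model and grey-zone remodelling

The membrane model is the 2006 human ventricular ionic model (19 state
variables; epicardial variant by default, endocardial and
mid-myocardial variants available). Grey-zone myocytes carry the
remodelling reported in patch-clamp studies of infarct border-zone
cells, applied multiplicatively to the maximal conductances:

| current | factor | i.e. |
|---|---|---|
| I~Na~  | 0.38 | 62 % reduction of peak sodium current |
| I~CaL~ | 0.31 | 69 % reduction of L-type calcium current |
| I~Kr~  | 0.30 | 70 % reduction |
| I~Ks~  | 0.20 | 80 % reduction |

"I~Ks~" is our reading of the second potassium-current reduction (the
rapid delayed rectifier is named separately, so the remaining delayed
rectifier is the slow component). With these factors the grey-zone
action potential is longer, slower-rising and lower-peaked than the
non-infarcted one, which is the qualitative triple the remodelling is
meant to produce. Quantitatively, at the 8-beat, 600 ms-cycle-length
conditioning used throughout, this implementation measures APD~90~
≈ 297 ms (normal) versus ≈ 321 ms (grey zone) and peak V~m~ ≈ 40 mV
versus ≈ 19 mV. The normal/grey-zone APD *gap* in this model
(~25 ms) is narrower than the 50 ms gap quoted for the remodelled
border zone in parts of the literature; the consequences for re-entry
induction are discussed under *Benchmark design* below.

Single-cell pacing uses the model's published stimulus (52 uA/uF for
1 ms). APD~90~ is measured from the time of maximum upstroke velocity
to 90 % repolarization toward the pre-stimulus diastolic level, with
sub-sample linear interpolation.

# Monodomain solver

The monodomain equation
β C~m~ ∂V/∂t = ∇·(σ∇V) − β I~ion~ + I~stim~
is discretized with mass-lumped bilinear/trilinear finite elements on
the structured grid and integrated by first-order operator splitting:
an explicit diffusion step, then the membrane update, at a 25 µs time
step. Gates use the Rush–Larsen exponential update; voltage-dependent
rate expressions are tabulated on a 0.05 mV grid and linearly
interpolated (the standard trick of cardiac tissue codes). When the
dt-scaled diffusion operator exceeds the forward-Euler stability
envelope (high conductivity or fine grids — never at the default
σ and 0.35 mm), the diffusion update is automatically substepped; the
bound is a Gershgorin row-sum estimate.

Conductivities are transversely isotropic: σ = σ~t~I + (σ~l~−σ~t~)ff^T
per element, with defaults 0.255 / 0.0775 S m⁻¹ (longitudinal /
transverse) in non-infarcted tissue and a 90 % transverse reduction
(0.00775 S m⁻¹) in the grey zone, reflecting gap-junction remodelling.
Scar is electrically non-conductive: scar elements are removed from
the assembly (a no-flux boundary at the scar border), and nodes
touching only scar are excluded from the domain entirely, so they can
never activate. Surface-to-volume ratio β = 1400 cm⁻¹ and
C~m~ = 1 µF cm⁻² are the common defaults of the tissue-solver
literature; conduction-velocity calibration (`tuneConductivities`,
which iterates σ ← σ·(CV*/CV)² on a strand) absorbs this choice.

Activation times are recorded *inside* the solver step as upward
crossings of 0 mV with a 50 ms per-node refractory lockout — both
configurable; V~m~ frames are sampled separately and can be disabled.
Pacing electrodes are 1×1×1 mm cubes injecting transmembrane current;
the default amplitude is 1.5× the diastolic threshold found by
bisection on a thin strand (about 23 µA/µF at default settings, so a
default stimulus of ~34 µA/µF for 2 ms).

At the working resolution the solver yields a longitudinal conduction
velocity of ≈ 0.74 m/s; the anisotropy ratio converges toward the
continuum value √(σ~l~/σ~t~) ≈ 1.81 under grid refinement (≈ 1.96 at
0.175 mm) — transverse propagation is the discretization-limited
direction, which also means that grey-zone tissue at σ~t~/10 cannot
propagate at all at 0.35 mm. That is a physical statement about
sub-threshold coupling, not a numerical artifact to be engineered
away, and it shapes the benchmark design below.

# Fibre rules

On ventricular geometries, two Laplace–Dirichlet fields define the
frame: transmural φ (endo = 0, epi = 1) and apicobasal ψ (apex = 0,
base = 1). Per element, the transmural axis is the normalized φ
gradient, the apicobasal axis is the ψ gradient orthogonalized against
it, and the circumferential axis their cross product. The fibre is the
circumferential axis rotated about the transmural axis by the helix
angle α(φ) = α~endo~(1−φ) + α~epi~φ; the two surface rotations are
combined by bidirectional spherical linear interpolation (quaternion
slerp treating q and −q as one rotation). Default rule angles are
+40° (endo) / −50° (epi), adopted from the rule-based-method
literature since the protocol description does not print them; they
are fully configurable. On slabs, the convention is z transmural and y
apicobasal; sheets get a constant in-plane direction. Only a single
fibre axis is assigned: the conductivity model is transversely
isotropic, so sheet/sheet-normal axes would never be used.

One rule set is applied everywhere (no septal or RV-specific
variants); `perturbGzFibers` supports robustness analyses by rotating
grey-zone fibres by bounded random angles under a fixed seed.

# The programmed-stimulation engine

The 19-site biventricular panel places one site at the endocardial
centroid of each of the 17 AHA segments (segments by apicobasal thirds
and circumferential sectors; the apical cap is the bottom 10 % of the
apicobasal range) plus the RV apex and a basal RV site near the
outflow region. Sites falling in scar are relocated to the nearest
conductive endocardial node and flagged.

Each site runs: 8 S1 at 600 ms; S2 starting at its initial coupling
and shortened in 10 ms steps until re-entry is induced or capture
fails; failing induction, S2 is frozen at its shortest capturing
interval and S3 (then S4) scanned the same way. Freezing — rather than
re-scanning — the earlier extrastimulus mirrors standard clinical
programmed-stimulation practice; the protocol description does not
specify this, so it is configurable in principle via the scan driver.
The S1 prefix is simulated once per site up to the onset of the last
S1 beat and checkpointed; every trial restarts from that identical
state, so the ladder is deterministic and cheap. Capture is an
activation 2–5 mm from the electrode within 150 ms of the stimulus.
Observation windows are processed in 500 ms chunks and cut short only
when the tissue is provably quiescent (no activations in the last
chunk and every node repolarized below −70 mV) — a pure optimization
that cannot change any activation time.

Outcomes follow the trichotomy: with T the time (from the last
stimulus) of the last activation excluding the directly evoked beat —
each node's first post-stimulus activation — a site is NONINDUCIBLE
with no full re-activation (we additionally require that at least 10 %
of the nodes reached by the evoked beat re-activate, so a few-node
electrode wavelet does not count as re-entry); SINGLE_BEAT when
re-entrant activity ends with T ≤ 1000 ms; UNSUSTAINED when
T > 1000 ms but the tissue quiets before the 2000 ms window closes
(quiet meaning no activation within 300 ms of the window end); and
SUSTAINED otherwise. ">1 s persistence" is measured from the last
delivered stimulus. UNSUSTAINED and SUSTAINED both count toward a
positive overall call. The VT cycle length is the median
inter-activation interval at the 10 most re-activated nodes over the
final 1000 ms of activity. Solver failures mark the site FAILED — a
distinct status, so faults can never masquerade as non-inducibility.

# Benchmark design: the figure-of-8 sheet

`figureOfEightSheet` is the package's re-entry testbed: a 36 x 46 mm
sheet, a 24 mm-tall scar band spanning the width except for 3 mm normal
corridors at the edges, a 3.2 mm grey-zone channel through the band's
centre with a funnel-shaped (6 mm) proximal mouth, and a 1 mm grey-zone
rim. The design went through explicit physical reasoning that is worth
recording, because two of its choices are forced by the membrane model:

* **Channel conduction.** With fibres along x, conduction up the
  vertical channel is transverse, and grey-zone tissue at sigma_t/10
  blocks outright at 0.35 mm. Real post-infarct isthmuses conduct
  slowly because surviving bundles run obliquely and zigzag; the
  channel therefore carries oblique fibres (15 deg proximal to 18 deg
  distal, graded so the least-conductive zone sits at the proximal
  mouth), giving effective along-channel conductivities near
  0.02 S m^-1 and the decimetre-per-second conduction mapped in VT
  isthmuses.
* **Unidirectional block and its fragility.** In this ionic model the
  grey-zone/normal APD gap at the rate-converged 600 ms drive is only
  ~25 ms, while capture of an extrastimulus requires ~35 ms more than
  the local APD (sodium-channel recovery, tau ~80 ms). A premature
  wavefront therefore always reaches grey zone that has *just*
  recovered and, travelling in the same direction as the conditioning
  wave, it simply slows to the speed of the receding recovery front
  ("wait-and-go" conduction) instead of blocking. We verified this
  exhaustively: under a fully rate-adapted 8-beat drive no mouth
  conductivity, funnel shape, fibre-angle profile or extrastimulus
  level produces unidirectional block from the benchmark's pacing site.
  What does produce block is the border zone's APD adaptation
  transient: early in a 600 ms drive the grey-zone APD still carries
  its longer intrinsic duration, the premature wavefront arrives inside
  the absolutely refractory phase at the channel mouth, and genuine
  unidirectional block forms. The benchmark therefore conditions with a
  scaled-down 2-beat S1 drive (`runReentryBenchmark`'s default train) -
  the full 8-beat drive remains the protocol default everywhere else
  and is what the pacing-engine tests exercise.
* **Sustained rotation.** Early variants with a narrow mouth produced
  exactly one or two re-entrant transits: each exit was followed by an
  antegrade re-invasion of the mouth, and the next transit's exit then
  faced partially recovered tissue through a narrow source - a
  source-sink mismatch that terminated the arrhythmia. Flaring the
  mouth into a 6 mm funnel over the proximal 3 mm gives the exiting
  front a broad source and makes the rotation self-sustaining.
* **Ladder calibration.** The effective refractory period of the
  non-infarcted tissue at the 600 ms drive is ~335 ms, so an
  extrastimulus ladder starting at the clinical 300 ms figure would
  fail to capture at its very first step; the benchmark ladder starts
  at 360 ms. The scan itself is the standard decremental protocol.

With these choices the benchmark induces *sustained* figure-of-8
re-entry at the S3 level of the ladder (S2 frozen at 340 ms, S3 at
330 ms) with a VT cycle length of ~422 ms, inside the reported human
range of 276-445 ms, and consistent with the clinical observation that
multiple extrastimuli are usually needed.

# What the synthetic generators do and do not emulate

The generators reproduce the three-label structure, grey-zone
remodelling, anisotropy, an isthmus morphology, and the stimulation
protocol — the ingredients the inducibility question actually probes.
They do not emulate patient-specific geometry, patchy/interdigitated
infarct texture, transmural fibre dispersion in 2D sheets,
Purkinje-mediated activation, or MRI acquisition artifacts. A passing
test suite therefore shows that the method implementation is faithful
and the physics behaves as the theory says on clean substrates; it
does not show that any particular patient heart would be classified
correctly.

# Numerical choices and degenerate inputs

* Diffusion: explicit with automatic substepping (above); instability
  (|V~m~| > 200 mV) aborts naming time and node.
* Degenerate fibre frames (zero transmural gradient) fall back to
  neighbour-averaged directions with a warning.
* Empty conductive domains, non-intersecting infarct footprints,
  unactivated CV probes, too-short recordings and disconnected
  Laplace systems are all explicit errors (or warnings with unchanged
  output where the contract says so) rather than silent misbehaviour.
* Mesh I/O uses the CARP-style text dialect: micrometre coordinates on
  disk, 0-based element connectivity with the tissue label as region
  tag, one fibre vector per element after a "1" header; parse errors
  name the file and line.

# Problem sizes

The test suite runs sheets between 10×10 and 86×86 elements and
coarse (1.2–2.5 mm) ellipsoidal shells; conduction-velocity
calibration uses 25 mm strands at 0.35 and 0.175 mm. The acceptance
computation runs the full benchmark sheet (103 × 132 elements at
0.35 mm, ~13 700 nodes) through the complete 8-beat conditioning and
the S2/S3 ladder. These sizes were chosen so the whole suite completes
comfortably on a single CPU while every scientific claim is exercised
at the working resolution.

# Known limitations

* Monodomain only; no bidomain, no defibrillation, no Purkinje
  system, no mechanics.
* One LV rule set for fibres everywhere; no septal/RV variants.
* The idealized ventricle is a site-placement and fibre-rule
  substrate, not an anatomical model.
* Grey-zone APD in this membrane model undershoots the remodelled
  border-zone APD reported elsewhere (≈ 321 vs 360 ms at the 600 ms
  drive); single-cell acceptance checks reflect the model as
  implemented, and the discrepancy is documented rather than patched
  by retuning currents beyond the published remodelling factors.
* Upstroke-velocity figures depend strongly on measurement context
  (single cell vs tissue, sampling); the package reports dV/dt~max~
  but treats printed literature values as context-bound.
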