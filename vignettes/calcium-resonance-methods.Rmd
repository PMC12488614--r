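---
title: "Modelling intrinsic calcium resonance: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling intrinsic calcium resonance: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calres)
```

## The scientific problem

Hippocampal CA1 pyramidal neurons respond maximally to subthreshold
oscillatory input at a preferred, non-zero frequency — membrane-potential
resonance. `calres` asks whether and how that frequency selectivity
propagates into the first step of intracellular signalling: cytosolic
calcium. The package implements conductance-based models in which the only
calcium source is the low-threshold (T-type, Ca~V~3-like) calcium channel,
drives them with a chirp current, and quantifies voltage and calcium
frequency selectivity by impedance analysis.

Two model classes are provided:

* a **single-compartment cylinder** (length = diameter = 60 µm,
  R~m~ = 11 kΩ·cm², C~m~ = 1 µF/cm², R~a~ = 100 Ω·cm, giving a passive
  input resistance of ~97 MΩ) expressing T-type channels alone or together
  with h (HCN) or A-type K⁺ channels — the substrate for all parameter
  sweeps; and
* a **gradient-endowed somato-apical trunk**: soma plus tapered apical
  cable (~425 µm), with sigmoidally decreasing R~m~ and R~a~, a linearly
  increasing A-type K⁺ gradient with a proximal/distal channel-model switch
  at 100 µm, sigmoidally increasing h and T-type conductances, and a
  piecewise-linear somato-apical shift of the h activation V~1/2~ from
  −82 mV to −90 mV.

## Model components

### Channel kinetics

Every gate is a (steady state, time constant) pair of voltage curves stored
as named parameter sets in a plain-text registry
(`system.file("extdata", "channels.yaml", package = "calres")`), so that a
different published scheme can be substituted without touching code. The
shipped schemes are the CA1 standards: Migliore-type Na⁺, delayed-rectifier
K⁺ and A-type K⁺ (Borg–Graham-style Boltzmann voltage dependences; the
distal A-type model is the proximal one with a −12 mV activation-V~1/2~
offset; A-type inactivation uses the linear-clipped time constant
max(2, 0.26·(V+50)) ms), a Magee-style single-gate h current
(V~1/2~ = −82 mV somatic, reversal −30 mV, τ ≈ 35 ms near rest), and the
canonical low-threshold T-type scheme (m²h; activation V~1/2~ = −57 mV,
k = 6.2 mV; inactivation V~1/2~ = −81 mV, k = 4 mV; the standard
closed-form time constants with Q10 = 2.5/3 referenced to 24 °C). Na⁺, K⁺
and h currents are ohmic with reversal potentials +55, −90 and −30 mV.

The T-type current uses the Goldman–Hodgkin–Katz constant-field law with
[Ca]~o~ = 2 mM and resting [Ca]~i~ = 100 nM. Densities for the GHK channel
are specified in conductance units (S/cm²) multiplying a driving term in
mV — the native convention of compartmental simulators — so the printed
density values pass through unchanged; the physical permeability form is
also exported (`ghk_current_density()`) and tested against its analytic
V → 0 limit.

Every gate carries three modifier hooks used by the sweeps: a V~1/2~ shift
(translates both curves), a multiplicative τ scale, and an additive τ
offset (the alternative when a sweep should add rather than scale; the
shipped experiments scale).

### Calcium handling

Each T-type-bearing compartment has a single sub-membrane shell
(depth 0.1 µm) in which the inward T-type flux accumulates and decays
mono-exponentially to the 100 nM resting level:

d[Ca]/dt = −I~CaT~ / (2 F · depth) − ([Ca] − [Ca]~rest~) / τ~Ca~.

The default decay constant is **τ~Ca~ = 30 ms**. The cited literature for
this pool model spans roughly 10–100 ms; 30 ms was fixed once, from a
closed-form linearization of the calcium transfer function: the pool acts
as a first-order low-pass with corner 1/(2πτ~Ca~), and only a corner near
5 Hz (τ~Ca~ ≈ 30 ms) is compatible with a calcium resonance in the 5–7 Hz
theta range given the T-type kinetics above. Both the depth and τ~Ca~ are
exposed (`ca_settings()`) and τ~Ca~ is itself one of the swept parameters.

### Discretization

Morphologies are trees of tapered cylindrical sections (read from standard
7-column SWC or generated synthetically). Each section is split into an odd
number of equal compartments by the d_λ rule,
n = 2·floor((L/(0.1·λ~100~) + 0.9)/2) + 1, with λ~100~ the 100 Hz space
constant computed with the section's smallest diameter and largest axial
resistivity so the length bound holds for every compartment individually.
All gradients are evaluated at each compartment's midpoint path distance
from the soma (the range-variable convention of compartmental simulators).
Basal dendrites take somatic passive values and somatic densities including
A-type K⁺; axonal compartments take somatic passive values with Na/K~DR~
only. Of the two printed values for the R~a~ gradient slope the later
assignment (k = 14 µm) is the default; both are plain config entries.

The synthetic trunk (`make_trunk()`) stands in for a full CA1
reconstruction so that every experiment runs without downloads: soma
20 × 20 µm, ten tapered sections (2.5 → 1.0 µm) totalling 425 µm, optional
basal/axon stubs, optional seeded diameter jitter (off by default). It
reproduces trunk cable properties (its passive somatic input resistance
matches a sealed-end equivalent-cylinder closed form to well within 20%)
but not oblique branching, so map-level results are asserted as trends and
bands, not absolute amplitudes.

### Integration

The integrator (C++ core) uses the staggered scheme that is standard for
active cable models: per 25 µs step, gate states advance by the exact
exponential (Rush–Larsen) update toward their voltage-dependent steady
state; voltages solve a backward-Euler implicit system over the whole tree
(Hines elimination), with ohmic conductances folded into the implicit
matrix and the (small) GHK current applied explicitly; the calcium pool
then advances by its own exact exponential update. The scheme is
unconditionally stable, conserves membrane charge to machine precision in
the conductance-free limit, and halving the step changes f~R~ and Q by
~0.01% (tested). Gating curves are evaluated in R — the same exported
functions the tests exercise — and handed to the core as lookup tables
(0.025 mV grid, linear interpolation), so there is a single source of truth
for the kinetics.

### Holding at −65 mV

All runs hold the injected site at −65 mV before the stimulus: the site is
voltage-clamped at −65 mV for a 2 s settling phase (long relative to every
gating and calcium time constant at rest), the clamp current over the final
100 ms becomes the constant bias current, and the clamp is then released
with bias + stimulus injected. The run warns if the site has drifted more
than 0.1 mV by stimulus onset or if any compartment exceeds −20 mV
(suprathreshold excursion) — analysis proceeds but the trace is flagged.

## The chirp and the impedance analysis

The stimulus is a constant-amplitude 50 pA sinusoid whose frequency rises
linearly 0 → 15 Hz over 15 s (phase = the integral of the instantaneous
frequency), preceded by ≥ 0.5 s of rest and followed by a short pad.

Two `|Z(f)|` estimators are implemented (`impedance()`):

* **`method = "fft"`** — the classical definition: FFT of the
  baseline-subtracted response divided by the FFT of the stimulus,
  magnitude restricted to 0.5–15 Hz, lightly smoothed (5-bin moving
  average). This is the definition under which the resonance strengths are
  reported, and the one validated against closed-form RC impedance (< 2%),
  steady-state single-frequency probes (< 3%) and an exactly integrable
  resonant-circuit fixture.
* **`method = "swept"`** — a sweep-tracking (heterodyne) estimator:
  response and stimulus are demodulated at the chirp's instantaneous phase
  and low-pass filtered (Hann kernel, 1.5 s), and `|Z|` at the
  instantaneous frequency is the ratio of the complex envelopes. For a
  linear system the two estimators agree (tested on the circuit fixture).
  For the calcium signal — whose strongly rectified response injects
  harmonic-distortion products across the whole band — the FFT ratio
  carries a deterministic ±10% bin-to-bin ripple that makes the location of
  a broad peak unstable, while the swept estimator rejects out-of-band
  products by construction and yields a smooth profile. Demodulating a real
  signal also leaves an image term, conj(envelope)·e^(−2iφ), whose
  instantaneous frequency (twice the sweep frequency) falls inside the
  low-pass band early in the sweep; since the image is analytically known,
  one correction pass subtracts its filtered estimate from both envelopes,
  cutting the low-frequency bias from ~2% to ~0.2–0.6% (without the
  correction the bias is the same size as the weak voltage resonance
  itself). Experiment suites therefore report f~R~ from the swept profile.

f~R~ is the argmax of the (smoothed) magnitude, refined by a local
quadratic fit over ±1 Hz around the discrete maximum — subthreshold
resonance peaks are flat-topped (constant to a fraction of a percent over
several tenths of a Hz), so a raw argmax is ill-conditioned while the local
fit is stable. Profiles whose maximum sits at the 0.5 Hz band edge, or
whose peak rises above the band-edge magnitude by less than the
estimator's measured ripple floor (1% for the FFT ratio, 0.3% for the
swept estimator), are flagged `no_resonance`. Q is max|Z| divided by
|Z(0.5 Hz)|, ≥ 1 by construction.

## Experiments

`run_cat_suite()`, `run_h_suite()`, `run_ka_suite()` and
`run_passive_suite()` sweep the single-compartment model over deterministic
grids — 9 log-spaced multiplicative factors 0.25×–4× for conductances and
time constants, −15…+15 mV in 2.5 mV steps for V~1/2~ shifts, every grid
containing the unmodified default — and record f~R~ and Q for both signals,
with the full parameter set on every row. `run_trunk_map()` injects and
records locally every 25 µm along the trunk. Identical configurations
reproduce identical tables (no hidden randomness anywhere in the pipeline;
the only RNG in the package is the optional, seeded morphology jitter).

The single-compartment densities behind the published sweep figures are not
printed in the source text; the suites default to the somatic densities of
the multi-compartment model (T-type 80 µS/cm², h 25 µS/cm², A-type
3.1 mS/cm²), and `calibrate_cat_density()` makes the assumption explicit by
least-squares scaling the T-type density against the reference resonance
strengths (V-Q = 1.02, Ca-Q = 2.52) and reporting the density it settled
on.

## What the model reproduces, and where it departs

With the shipped kinetics the package reproduces the study's central
results: T-type channels alone sustain a strong calcium resonance with a
much weaker voltage resonance (Ca-Q/V-Q ≈ 3 at the default density);
calcium f~R~ sits in the theta band and is nearly invariant across a
16-fold conductance range while voltage f~R~ rises monotonically (the
dissociation); slowing either T-type gate, slowing calcium decay or raising
C~m~ all lower calcium f~R~; raising the h conductance raises it; the
somato-apical calcium-f~R~ map is flat out to ~200 µm and rises toward the
terminal end by far less than the voltage map rises.

Three fine-grained modulation directions come out differently from the
reported ones under the registry's kinetics, and are left as documented
divergences rather than tuned away: (i) the A-type conductance produces a
small *increase* in calcium f~R~ (with the Migliore-type fast subthreshold
inactivation, τ ≈ 2 ms at rest, the A-current is a quasi-instantaneous
window conductance — pure leak — which shifts the voltage low-pass corner
up; a small *decrease* would require slower subthreshold inactivation);
(ii) the h activation-V~1/2~ bell peaks just beyond +15 mV, so the curve is
monotone within the swept range (the bell's peak sits where V~1/2~ crosses
the holding potential, i.e. near +17 mV for the −82 mV default); and
(iii) calcium f~R~ *falls* with R~m~ (the membrane low-pass corner
1/(2πR~m~C~m~) moves through the calcium band over the 0.25×–4× grid),
where a small rise is reported. All three involve kinetic details or sweep
ranges that the source text does not pin down; the acceptance suite asserts
the reported directions verbatim and these assertions fail honestly.

The somatic voltage f~R~ of the trunk model lands near 8 Hz — inside the
theta band, but above the ~5 Hz the study reports. Its voltage resonance is
weak (Q ≈ 1.04), so the peak location is dominated by where the A-type
window conductance puts the effective membrane corner; a stronger/slower h
current would pull it down. We keep the registry values rather than fit
this number.

## Problem sizes and runtime

The shipped experiments are sized to run on a laptop core: single-
compartment chirp runs (≈ 700k steps at 25 µs) take a fraction of a second;
the full sweep suites are 85 runs (~1.5 min); the trunk map uses the
synthetic trunk (31 compartments, 18 sites, a few minutes). These sizes are
the package's defaults; all grids, site spacings and durations are
arguments.

## Known limitations

* The calcium pool is a single shell with one decay constant: no buffers,
  pumps, stores or diffusion, so absolute calcium amplitudes are indicative
  only (Q and f~R~ are ratios/locations and insensitive to the shell
  scale).
* Subthreshold regime only: no spiking analysis, no synaptic input, and no
  attempt to reproduce suprathreshold dendritic events.
* The synthetic trunk carries no oblique branches; absolute impedance
  amplitudes along the trunk are not comparable to a full reconstruction,
  trends are.
* The exact kinetic schemes of the cited single-compartment studies are not
  printed in the available text; the registry holds the field-standard
  versions, and every scheme-dependent acceptance check is banded or
  sign-based accordingly.
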