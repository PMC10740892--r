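---
title: "Simulating ramped-pulse vestibular stimulation: models, conventions, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating ramped-pulse vestibular stimulation: models, conventions, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vestibsim)
```

## The problem this package models

A vestibular prosthesis restores rotation sensing after bilateral vestibular
loss by delivering charge-balanced biphasic current pulses to the ampullary
nerves of the three semicircular canals, with head velocity encoded as
instantaneous pulse rate. Two engineering questions dominate pulse design:
how efficiently a pulse shape recruits afferent fibers (threshold, growth
function, dynamic range up to facial-nerve spillover), and how selectively it
recruits the *target* nerve branch (misalignment between the evoked
eye-rotation axis and the target canal's anatomical axis). `vestibsim` is a
desk-scale simulator for exactly those questions: it renders rectangular and
ramped pulse shapes, drives multicompartment models of vestibular afferents
through a volume conductor, synthesizes the electrically evoked compound
action potential (eCAP) that an implanted electrode would record, and scores
each pulse shape by threshold, charge, growth slope, and predicted
vestibulo-ocular reflex (VOR) axis.

Everything runs on a procedurally generated synthetic labyrinth; no imaging
data, meshing, or finite-element solver is required. That substitution is the
package's central idealization and is discussed throughout.

## Pulse shapes and the slope convention

A pulse is two phases of opposite polarity separated by an interphase gap of
10% of the phase duration (`gap_frac = 0.10`), sampled at the pulse
generator's 2 µs resolution and quantized to its 20 µA current step.
Cathodic-first means the first phase is negative. Four shapes are supported:
rectangular, ramp-up (current rises from zero at phase onset), ramp-down
(mirrors ramp-up in time), and a symmetric rise/fall ramp (`ramp_up_down`).
The symmetric shape was chosen as the fourth member of the shape family;
only three shapes are unambiguous from the protocol description this design
follows, so the fourth is a documented package choice.

Ramp "slope in degrees" has no canonical geometry, so the package fixes one:
the angle is measured on normalized axes where one phase duration and the
nominal amplitude both equal 1. The phase envelope rises at `tan(θ)` in those
units until it reaches the nominal amplitude, then plateaus:

* `tan(θ) > 1` (e.g. 60°): a trapezoid — ramp then plateau;
* `tan(θ) = 1` (45°): a pure triangle that reaches the nominal amplitude
  exactly at phase offset;
* `tan(θ) < 1` (15°, 30°): a pure under-peaked ramp with peak `tan(θ) × A`.

This convention is the one that makes the standard charge bookkeeping exact:
charge per phase equals the rectangular (plateau) part times the amplitude
plus the triangular (ramp) part divided by two. `charge_per_phase()`
implements the closed form and the test suite checks it against fine-grid
numeric integration of the rendered waveform to better than 0.1% for every
shape and slope. An alternative convention (fixed peak amplitude with the
slope setting ramp duration) can be emulated by adjusting `phase_us` and
`amp_uA` jointly; the rendering pipeline only ever sees the envelope.

Quantization rounds half away from zero, which keeps a waveform and its
polarity-flipped twin exact mirror images; consequently net charge per pulse
is exactly zero even after quantization. The gap carries exactly zero current
(open-circuit idealization). Pulse-frequency-modulated trains are generated
by integrating the rate function `r(t) = base + depth·sin(2π f t)` and
emitting a pulse at each integer crossing of the integral — deterministic,
with no jitter.

## The volume conductor

The finite-element solve over segmented anatomy is replaced by the analytic
point-source potential in an unbounded homogeneous medium,
`V = I / (4π σ r)`, with an optional closed-form anisotropic variant
(`σ_long` along the nerve axis, `σ_trans` across it, by coordinate scaling)
that reduces continuously to the isotropic form. With current in µA,
distance in mm and conductivity in S/m the potential is in mV. Default
conductivities are 0.3 S/m (soft tissue) and 1.4 S/m (0.9% saline, bench
mode); the 10:1 longitudinal:transverse nerve anisotropy option is a
configurable default, not a measured value. Grounded-boundary and
mixed-boundary conditions of a full FEM have no analog here: the medium is
unbounded. Every function that consumes a `medium()` works through the same
potential kernel, so a numerical backend could be slotted in without touching
the downstream machinery.

What this buys: quasistatic linearity and reciprocity hold *exactly*, so the
package's core eCAP identity — lead-field weights equal forward coefficients
— is testable to round-off rather than to mesh tolerance. What it costs: no
bone/membrane heterogeneity, no electrode surface effects, and current spread
falls off as ideal 1/r.

## Afferent fibers and the two model tiers

The synthetic labyrinth places three crista branches (LH, LA, LP) with 100
model afferents each by default, distributed 40/30/30 over
peripheral/intermediate/central zones of a 0.3 mm crista disc, with straight
trajectories converging toward a common nerve trunk. Nodes of Ranvier are
spaced at 100× the fiber diameter; diameters are drawn from a truncated
normal (mean 3 µm, sd 0.5, bounds 2–4 µm) to grade thresholds across the
population. A stimulating electrode sits 0.2 mm from each crista center —
chosen so that default thresholds land in the tens of µA, the range reported
for real ampullary stimulation — plus a distant return and a
recording/reference pair per branch. Everything is reproducible from a seed
and serializes exactly through JSON.

### HH cable tier

Spike initiation uses a myelinated-cable model: Hodgkin–Huxley kinetics
concentrated at nodes of Ranvier, internodes purely resistive (ideal
myelin). The published spike-initiation parameter sets this design
emulates are not restated in the protocol source, so the package uses
squid-derived HH rates with a Q10 = 3 temperature factor at 30 °C and
channel densities scaled to mammalian-node levels
(`gNa = 1200, gK = 90, gL = 20 mS/cm²`, `Cm = 2 µF/cm²`), with the leak
reversal solved at construction so rest is an exact equilibrium. All
parameters sit in the single `hh_node_model()` block so any published nodal
model can be substituted. With these defaults the model's chronaxie
(Weiss fit over 50–1000 µs phases) is ≈ 230 µs and default-geometry
thresholds are ≈ 10–40 µA — both in the physiological range for myelinated
afferents, verified by the test suite rather than asserted.

Integration is semi-implicit: gating variables advance by exponential Euler
at the previous voltage, then the voltage advances by backward Euler, which
is linear in the new voltage once gated conductances are frozen — one
tridiagonal solve per 2 µs step (the stimulus resolution; halving dt moves
spike times by < 10 µs). A spike is an upward crossing of 0 mV at three or
more consecutive nodes, which excludes local non-propagating
depolarizations. Transmembrane currents are computed from the axial side of
the cable equation, so they telescope to zero when summed over compartments
— the physical prerequisite for eCAP synthesis.

One numerical policy deserves emphasis. Under supramaximal fields (hundreds
of µA at 0.2 mm), the nodes flanking the stimulated locus are driven beyond
−500 mV from rest by the extracellular forcing term. That is strong-forcing
behavior of the cable equation, not integrator instability (the spike has
already fired microseconds earlier), but it exceeds any physiological range.
`simulate_fiber()` therefore treats a > 500 mV excursion as an error by
default (`on_divergence = "error"`, naming dt), while the sweep machinery
runs with `on_divergence = "clamp"`, which saturates the offending node at
±500 mV from rest and keeps the spike-carrying nodes integrating.
Non-finite voltages always raise.

### Threshold-surrogate tier

For sweeps and property tests a deterministic surrogate replaces the cable
solve: the activating function (axial second difference of the extracellular
potential, scaled by fiber diameter) is leaky-integrated with τ = 100 µs at
each node, and the fiber activates when the peak integrated depolarization
reaches `thr_mV`. The response is linear in amplitude, so each fiber has one
exact threshold and recruitment is exactly monotone — which is what makes
the planted-threshold recovery and monotonicity properties testable as
identities. `thr_mV = 2` was calibrated once against the HH tier on the
default geometry so the two tiers agree in scale (same decade of µA) and
ranking (Spearman ≈ 0.77 across fibers on unquantized pulses); the
calibration is frozen and the cross-tier ranking is itself a test. The
surrogate also accepts planted per-fiber thresholds outright, bypassing the
field computation, for parameter-recovery tests.

## eCAP synthesis, filtering, and thresholds

By reciprocity, the weight mapping a compartment's transmembrane current to
the voltage on a recording electrode equals the potential a unit current at
that electrode would impress at the compartment. The recorded trace is then

```
v_rec(t) = Σ_fibers Σ_compartments  w_j · i_m,j(t)
```

with the bipolar differential subtracting the same synthesis at a nearby
reference electrode. In this homogeneous analytic medium the lead-field and
forward coefficients are equal by construction, and the test suite verifies
the identity to 1e−10 relative error on randomized geometries via
independent forward summation.

Traces are low-pass filtered with a causal 4th-order Butterworth at 7.5 kHz
(half-power verified within 2% by measurement in the tests; a zero-phase
forward–backward variant is available behind a flag). The filter is designed
in-package — analog prototype poles, bilinear transform with pre-warping, DC
gain exactly 1 — because no signal-processing package is assumed. Filter
order is a package choice; only the cutoff is inherited from the emulated
recording chain.

The eCAP amplitude is the P–N peak-to-peak difference over the
post-stimulus window. The direct capacitive stimulus artifact is not
modeled, so the window simply opens at pulse offset; real eCAP systems blank
the artifact interval instead. The eCAP *detection* threshold — the lowest
amplitude whose filtered differential trace reaches `detection_uV` — uses a
1 µV default criterion; the emulated protocol states none, so this is a
configurable package choice. Growth functions regress eCAP amplitude on
stimulus level over the supra-threshold rising segment, ending at
saturation (within 5% of the maximum); amplitude is the default abscissa,
with charge available via `charge_per_phase()`.

Fiber-level thresholds follow the standard rules: the sensory threshold (ST)
is the lowest grid amplitude activating at least 10% of the target branch's
fibers; the discomfort threshold is exactly DT = 1.4 × ST; the upper limit
(UL) is the lowest amplitude activating any facial-nerve fiber when a facial
branch is present; the usable dynamic range runs from ST to min(DT, UL).

## VOR axis prediction

The predicted eye-rotation axis is the normalized weighted sum of the canal
rotation axes. The weight definition is genuinely open — axial-current
magnitude and fraction-of-fibers-active are both defensible — and the
package defaults to fraction-active (the quantity its recruitment module
computes directly and the quantity plotted in the empirical tradition),
with any non-negative weights accepted. Misalignment is the clamped-arccos
angle between predicted and target axes. eVOR traces map instantaneous
pulse rate linearly to velocity about the predicted axis; gain and baseline
rate are free parameters (eye-velocity calibration is animal-specific), with
gain 1 and the train's base rate as defaults.

Default canal axes are the orthonormal set LH = (0,0,1),
LA = (1,1,0)/√2, LP = (1,−1,0)/√2 in the {horizontal, LARP, RALP} frame —
i.e. the canal-pair axes themselves; real canal axes deviate from
orthogonality by ~10–20° and can be supplied via `axes =`.

## What the synthetic labyrinth does and does not establish

The generator emulates the *structure* of an implanted labyrinth: three
fiber populations with graded diameters and zones, electrode placement at
realistic distances, a more distant facial branch for upper-limit detection.
It does not emulate real inter-ampullary geometry: the synthetic cristae are
several mm apart, so off-target recruitment at sensory threshold is
essentially zero and predicted misalignment at ST is ≈ 0° on the default
anatomy. Real misalignment arises from current spread between closely
apposed ampullae and individualized electrode positions — a green
misalignment test here establishes the geometry of the weighted-sum
prediction, not a claim about anatomical selectivity. Likewise, absolute
eCAP thresholds and growth slopes depend on animal-specific geometry; only
*relative* statements across pulse shapes on a fixed synthetic anatomy (for
example, that ramped slopes reach eCAP threshold with less charge per phase
than the rectangular baseline — which the default geometry reproduces) are
meaningful, and those are what the regression tests pin down.

## Numerical and policy choices, collected

| Choice | Value | Rationale |
|---|---|---|
| Sample interval `dt_us` | 2 µs | emulated generator resolution; also the cable-model step |
| Current step `step_uA` | 20 µA | emulated generator limitation; round half away from zero |
| Interphase gap | 10% of phase | emulated protocol; exactly zero current |
| Ramp slope geometry | tan(θ) on normalized axes | reconciles the triangle description with the plateau charge formula |
| HH kinetics | squid rates, Q10 = 3, 30 °C, 10× Na density | chronaxie and thresholds in physiological range; fully substitutable |
| Divergence guard | 500 mV from rest; error or clamp | distinguishes instability from strong forcing |
| Spike criterion | 0 mV upward at ≥ 3 consecutive nodes | excludes non-propagating depolarizations |
| Activation window | 2 ms after pulse onset | recruitment definition |
| Surrogate τ, thr | 100 µs, 2 mV | thr calibrated once to align tier medians; frozen |
| Butterworth | order 4, causal, fc 7.5 kHz | cutoff inherited; order and causality are package choices |
| eCAP detection | 1 µV | no stated criterion; configurable |
| ST / DT | ≥ 10% target fibers; DT = 1.4 ST | standard threshold rules |
| Bisection tolerance | 1 µA (thresholds) | below the hardware current step |

## Known limitations

* Unbounded homogeneous medium: no tissue heterogeneity, boundaries, or
  electrode interface impedance; bench "current spread" is open-circuit
  potential (an optional load-divider is the only concession).
* No stochastic channel noise, hair-cell synapse, efferent feedback, or
  regular/irregular afferent phenotypes; recruitment is fully synchronous,
  which inflates eCAP amplitude and growth-slope estimates relative to
  desynchronized physiology.
* The oculomotor mapping is algebraic: no plant dynamics, quick phases, or
  adaptation.
* Misalignment on the default anatomy is near zero by construction (see
  above); studying selectivity requires a user-supplied anatomy with
  realistic inter-ampullary distances.
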