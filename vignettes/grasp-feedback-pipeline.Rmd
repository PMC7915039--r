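---
title: "Secure-grasp detection and agency-based feedback training: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Secure-grasp detection and agency-based feedback training: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graspglove)
```

## The problem

Instrumented gloves for movement rehabilitation can sense when a user has
achieved a *secure grasp* — a stable hold on an object — and feed that
information back as sensory cues (a beep, an LED). Timing those cues is
itself a lever: delivering feedback at progressively shorter delays after
the grasp action exploits *intentional binding*, the perceived compression
of time between a voluntary action and its sensory consequence, which is an
implicit marker of the sense of agency. The hypothesis is that
agency-oriented feedback timing accelerates motor learning on a functional
grasp-move-place task.

`graspglove` implements the full computational chain of such a study at
desk scale: a seeded synthetic-data generator standing in for the glove's
sensor streams and the motion-capture trajectories, secure/insecure frame
labeling, a per-subject neural-network grasp detector with an analytical
baseline, feedback scheduling, kinematic performance metrics, and the
normalization/outcome/statistics layer. Because the original raw data are
not publicly available, every quantitative claim the package makes is about
what the pipeline computes on its own generator — the tests say so
explicitly.

## The sensor model

The emulated glove reports ten voltages at 40 Hz: one force and one flex
sensor per digit, clipped to \[0, 3.3 V\]. Training trials are 10 s long
and come in three protocols per grip (precision pinch, tri-pod,
whole-hand): *hold* (grasp, hold steady ~5 s, release), *tap* (repeated
short contacts), and *rest*. A session comprises 20 hold and 20 tap trials
per grip plus 5 rest trials (125 trials).

Hold trials follow a logistic rise/fall envelope with a steady plateau; the
annotated hold window (3–7 s) sits where the envelope is within 0.2% of the
plateau. The generator adds structure that matters for the downstream
comparisons, with every default fixed in `sensor_params()`:

* **Light grip forces.** Active force channels plateau at 0.34 V — just
  above 10% of the sensor range. This is the regime in which an analytical
  force-equilibrium detector with a 10%-of-maximum floor degrades: the
  grip-force fluctuation (97% common-mode across the engaged digits, 2% of
  the plateau in SD) intermittently drops a reading below the floor while
  the frame is still inside the ±10% secure band. Flex channels, which
  measure digit bend rather than contact force, plateau at 1.2 V.
* **Near-equal pinch opposition.** For precision pinch the thumb and index
  force plateaus differ by at most 1% per trial, plus a transient
  thumb-force overshoot (16%, Gaussian bump at ~2.45 s) during grip
  formation, before force equilibrium settles.
* **Weak thumb opposition for multi-digit grips.** For tri-pod and
  whole-hand grips the thumb pad opposes several digits at once, so its
  force plateau is 0.15 of the other digits' — below both the analytical
  floor and the labeling activity floor.
* **Taps stay insecure.** Tap contacts last ~0.3 s with peaks at 50–85% of
  the hold plateau, below the secure band.

Randomness is disciplined: one master seed, per-trial sub-seeds via the
counter derivation `derive_seed()`, and all generator functions restore the
caller's RNG state.

## Labeling

A frame is *secure* (label 1) iff every **active** channel lies within ±10%
of that channel's mean over the steady-hold window; everything else is
insecure (label 0). "Active" means the hold mean exceeds
`activity_floor * v_max` (default 0.05): applying a relative band to a
near-zero channel would be vacuous. Setting the floor to 0 recovers the
literal all-channels rule. Hold trials are labeled against their own hold
statistics; tap trials borrow the pooled hold statistics of the same grip,
and rest trials those of precision pinch — implementing "everything outside
the steady hold band is insecure" with one uniform rule.

Frames from all 125 trials are pooled per subject and split 70/15/15 into
train/validation/test at random by frame (the study's convention). A
by-trial split mode is provided because frame-level splitting leaks
temporally correlated samples into the test set; with it, reported test
rates drop slightly, which is the honest number for streaming deployment.

## The detector and its baseline

The detector is a feedforward network with one hidden layer of ten tanh
units and a logistic output; inputs are affinely scaled per channel to
\[-1, 1\] using training-split ranges. It minimizes mean binary
cross-entropy (natural log) with Møller's scaled conjugate gradient:
conjugate directions, Hessian–vector products by forward differencing of
the gradient (σ = 5e-5), and a Levenberg–Marquardt scaling parameter
(initial λ = 5e-7) instead of a line search. Rejected steps leave the
weights unchanged and inflate λ, so training cross-entropy is
non-increasing over successful iterations — a property the tests assert.
Early stopping watches the validation split (6 consecutive
non-improvements, max 1000 iterations) and the returned model carries the
best-validation weights plus the full iteration trace. Continuous outputs
round at 0.5; exactly 0.5 maps to insecure, the conservative side for
triggering feedback.

The analytical baseline mirrors simple pinch force equilibrium: a frame is
secure iff thumb and index force voltages are both above 10% of the sensor
range and within 10% of each other. On the default corpus the network's
pinch true-positive rate is ~99% against ~73–80% for the analytical rule
(the floor condition fails on common-mode force dips), and the analytical
rule scores 0% on tri-pod/whole-hand grips, whose weak thumb never clears
the floor — reproducing the qualitative ordering the method comparison is
about. Cross-entropy is reported as the per-sample mean in nats; the
original report's cross-entropy magnitudes imply an unstated normalization,
so they are not comparable and the package standardizes on the mean.

## Feedback scheduling

Three modes: `NF` (no feedback), `IF` (immediate), `IBF`
(intentional-binding: the delay between detection and cue ramps linearly
from 1 s on trial 1 to 0 s on trial 30). Anchoring the endpoints gives a
step of 1/29 s ≈ 34.5 ms — consistent with the protocol's "~34 ms" — and
the delays sum to `n_trials/2` seconds (15 s), a closed-form invariant the
tests check. Detection scans the rounded network output for the first
debounced run of secure frames (default debounce 1 frame, as the hardware
triggers directly on the network output); events are records with
timestamps — a 100 ms beep at detection + delay and an LED interval lasting
until release. If the delayed cue would land after release the event is
emitted flagged with an empty LED interval; the source protocol does not
specify this case.

## Kinematic metrics

Object trajectories (nominally 120 Hz) are linearly resampled to 100 Hz
before any metric is computed. Speed is the Euclidean norm of
central-difference velocity (one-sided at the ends); "moving" means speed
above `v_gate`.

* **Completion time** = moving samples × 10 ms.
* **Pathlength** = summed 3-D displacements over segments touching the
  moving mask.
* **Placement error** = in-plane distance between the final resting
  position (mean over the trailing non-moving segment, robust to jitter)
  and the target centre, both orthogonally projected onto the table plane.

`v_gate = 0` is the literal non-zero-velocity rule and the default here,
appropriate because the generator's trajectories are kinematically smooth;
for measured (noisy) data a gate around 0.01 m/s is recommended, since a
strict zero test marks every sample as moving. Completion time is
intrinsically quantized: counting samples resolves 10 ms, and boundary
samples (central differences straddling a movement edge, plus 120→100 Hz
interpolation) contribute up to ±2–3 samples through the full generator
chain. The tests therefore assert pathlength and placement error at 1e-3
relative / exact, and completion time at one sample period for trajectories
built directly on the 100 Hz grid (0.035 s through the generator chain).

## The synthetic functional-task study

Each subject performs three sessions, one per feedback mode: 15 pre-training,
30 training, 15 post-training trials of a grasp-move-place task (~20 cm
transport, 2 cm lift). `learning_params()` encodes the study conditions:
group baselines 1.48 s / 0.25 m / 5.6 mm; per-mode intra-training slopes
and post-training offsets taken from the study's outcome tables (no
feedback drifts mildly worse — e.g. +0.0067 s/trial for completion time —
while immediate and intentional-binding feedback improve, the latter most);
per-trial noise SDs (0.13 s, 0.02 m, 0.5 mm); and inter-subject baseline
CVs (0.24, 0.07, 0.12), realized exactly by standardizing the subject
draws. Where the source does not state a value (noise shapes, trajectory
dynamics), the choices are the package's own and are exposed in the
parameter object.

A trial's *drawn* metric triple (expected value + noise) is the ground
truth carried in the study table; the trajectory builder realizes it
exactly — a minimum-jerk time profile along a chord-plus-lift-bump path
whose lateral detour amplitude is solved by `uniroot` so the arc length
equals the drawn pathlength, ending the drawn error from the target in a
seeded direction, padded with ≥0.2 s of rest at both ends. Round-trip tests
confirm scored metrics equal drawn values to the tolerances above, which is
what licenses running the statistics on the drawn values (and makes
noise-free parameter recovery exact to 1e-6 rather than bounded by sample
quantization).

## Normalization, outcomes, statistics

Each metric is normalized within subject by that session's pre-training
mean (the pre block included, so its normalized mean is exactly 1;
`include_pre = FALSE` gives the literal convention of normalizing only
training/post), then de-normalized to real units with the group
pre-training mean. Two outcomes per subject × mode × metric: the
**intra-training rate** (OLS slope across the 30 training trials) and the
**post-training effect** (post mean − pre mean); negative is improvement
for both, and the block-difference table also reports the pre−later
orientation used in the source's layout.

The battery: a one-factor repeated-measures ANOVA per metric over the nine
mode×block cells (subject as the blocking factor, sphericity assumed, one F
per metric as in the source's table layout) with within-mode pairwise block
differences using the pooled error term (SE = √(2·MSE/n)) and
studentized-range post hoc p-values; one-way ANOVAs across feedback modes
for each outcome with Tukey HSD, optionally Bonferroni-scaled across metric
families (default family count 1 — the source's "Tukey with Bonferroni" is
a nonstandard combination, so the scaling is explicit and off by default);
and one-sample t-tests of each outcome against zero. Standard fits go
through `stats::aov`, `oneway.test`, `TukeyHSD` and `t.test`; the test
suite checks them against independent hand-written partitioned
sums-of-squares and closed-form t constructions on randomized designs.
Degenerate inputs (zero variance anywhere) are flagged, never silently
tested. Multiple testing across the three metrics is otherwise
uncorrected, matching the analysis it mirrors.

## Problem sizes and determinism

The shipped tests and the acceptance script run, per invocation: one
125-trial corpus (50,125 frames) with one network training (~6 s); a
17-subject study (3,060 trials) through the full statistics battery; 200
replicate 17-subject studies for the power check of the intentional-binding
slope test (the one-sample t-test on 17 subject slopes rejects zero in
essentially every replicate at the configured effect −0.005 s/trial and
trial SD 0.13 s); 100 randomized designs per statistical oracle; and the
duplicated-XOR benchmark over 10 seeds for the optimizer. Everything is
seeded; identical arguments give byte-identical outputs.

## Limitations

The generator emulates the statistical structure the analysis assumes — it
is not a biomechanical hand model. Sensor envelopes, noise shapes,
trajectory dynamics and the learning-curve model are parametric choices;
passing tests demonstrate that the pipeline's computations are correct and
that the study's qualitative effect structure is recoverable under those
conditions, not that the original device data would reproduce any specific
number. Frame-level splitting inflates classifier test rates relative to
streaming use (use `split_by = "trial"` for the pessimistic view). The
repeated-measures ANOVA assumes sphericity and the pairwise error model is
the pooled within-subject term, both documented choices where the source is
silent.
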