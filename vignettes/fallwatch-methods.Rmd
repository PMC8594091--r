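---
title: "Methods: signal models, detectors and protocols in fallwatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal models, detectors and protocols in fallwatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

fallwatch is a desk-scale re-implementation of the signal-processing core of
a wearable elder-care platform: a waist-worn inertial measurement unit (IMU)
streams tri-axial acceleration and angular rate, a GPS unit streams
position, and the system must (a) recognise falls while ignoring confusable
activities of daily living (ADLs), (b) attribute a detected fall to one of
six situations, (c) adapt its per-user detector thresholds from
caregiver-annotated alarm records, and (d) report location events (fence
crossings, home/away, loitering) and trajectory summaries. Because no public
recording of the original device exists, the package ships a first-class
synthetic-signal generator; every claim the package makes is tested against
signals whose ground truth is known by construction.

```{r, eval = FALSE}
library(fallwatch)
trial <- simulate_fall("FALL_FORWARD", simulation_config(seed = 1))
detect_falls(noise_filter(trial$series))
```

## The four-phase fall model and the simulator

A fall appears in the acceleration magnitude
$\mathrm{SVM} = \sqrt{a_x^2 + a_y^2 + a_z^2}$ as four consecutive phases:

1. **Weight loss** — at the onset of the fall the body is briefly in partial
   free fall and the resultant acceleration drops below the resting 1 g.
2. **Impact** — the body hits the ground; the SVM spikes well above 1 g and
   the first difference of the SVM reverses sign at the peak.
3. **Motionless** — the person lies still; body-motion acceleration is near
   zero for a sustained interval.
4. **Changed final state** — the final orientation of the gravity vector
   differs from the pre-fall orientation; a large change marks the event
   severe.

The generator realises these phases with a piecewise magnitude profile: a
half-cosine dip from 1 g to `freefall_floor`, an asymmetric impact spike
(rise over the first quarter of `impact_duration`, half-cosine decay over
the rest) to `impact_peak`, and a constant 1 g motionless tail, all with
additive white Gaussian noise per channel. Smooth half-cosines were chosen
over linear ramps so the profile is differentiable and the impact peak is a
genuine sign reversal of the first difference rather than a plateau.
Orientation is a rotation of the body-frame gravity direction from upright
to `final_tilt` degrees along the azimuth of the fall type: forward falls
pitch, left/right falls roll with opposite signs (mirror images in the
lateral axis), back-left/back-right combine backward pitch with
opposite-signed roll, and a trip ends like a forward fall. Gyroscope
channels carry the angular rate implied by the tilt trajectory about the
fall axis, plus noise; trip-over trials additionally carry a sharp
(200 deg/s) pitch-rate transient during the weight-loss phase — the foot
catching the obstacle — which is what distinguishes a trip from a plain
forward fall for the classifier without perturbing any accelerometer
property.

Defaults (all configurable through `simulation_config()`): sampling rate
`fs = 50` Hz (a typical wearable-IMU rate; the hardware rate is not fixed
by the platform), `freefall_floor = 0.4` g, `impact_peak = 2.5` g,
`freefall_duration = 0.35` s, `impact_duration = 0.16` s,
`motionless_duration = 3` s, `noise_sd = 0.03` g, `gyro_noise_sd = 0.5`
deg/s, `final_tilt = 80` degrees. These are mid-range values from the
wearable fall-detection literature: published threshold detectors trigger
between 0.3 and 0.6 g for free fall and 2 to 3 g for impact, and we centred
the generator inside those bands once, before any detector tuning.

Non-fall ADLs are generated so the fall signature is absent *by
construction*: walking is a 2 Hz magnitude oscillation (SVM within roughly
0.7–1.3 g), sit-down and lie-down are slow orientation changes (20 and 80
degrees) with a gentle unload/contact wobble whose minimum stays above
`freefall_floor` and whose maximum stays far below `impact_peak`, and
standing is pure noisy gravity. Sit-down deliberately grazes the detector's
stage-1 trigger (its dip reaches about 0.75 g) to exercise the confusable
case: the state machine enters the free-fall state and must reset when no
impact follows.

What the generator does **not** emulate: biomechanically realistic
whole-body dynamics, soft-tissue impact shapes, the sensor's actual noise
spectrum, or the difference between young volunteers and elderly wearers.
A detector that is perfect on these synthetic signals is therefore verified
to implement the four-phase logic exactly — not certified to reach the same
accuracy on device recordings.

## Features

* `svm_g()` — the Euclidean norm of the acceleration vector, in g.
* `sma_g()` — the signal magnitude area: the time-average over a window of
  $|a_x| + |a_y| + |a_z|$. The continuous definition is an integral over a
  window; we discretise with the rectangle rule (a plain mean over
  samples), which is exact for the uniformly sampled series the package
  produces.
* `tilt_angles()` — the inclination angles
  $\rho = \arctan(a_x / \sqrt{a_y^2 + a_z^2})$,
  $\varphi = \arctan(a_y / \sqrt{a_x^2 + a_z^2})$ and
  $\theta = \mathrm{atan2}(\sqrt{a_x^2 + a_y^2},\, a_z)$. The atan2 form
  for $\theta$ keeps vertical and inverted postures well defined: an
  upside-down wearer maps to $\theta > 90^\circ$ instead of a division by
  zero. Orientation-change computations use the gravity component rather
  than raw acceleration, so posture is not confounded by body motion.

Preprocessing: `noise_filter()` applies a kernel-3 median filter (removes
single-sample spikes) followed by a zero-phase order-3 Butterworth low-pass
at 20 Hz per channel. `separate_gravity()` estimates gravity as a zero-phase
order-3 Butterworth low-pass (default 0.3 Hz) of each acceleration channel
and defines body motion as the exact per-sample remainder, so
`gravity + body = original` holds to machine precision. Both filters anchor
the signal at its mean and pad by odd extension before the forward/backward
pass; without this the zero-initial-state transient of `filtfilt` corrupts
the series ends, and with it a constant series passes through bit-for-bit.
Filter families, orders and cutoffs are implementation choices (the
platform description says only "noise filters"); all are arguments.

`sliding_windows()` cuts fixed-width windows of `round(width * fs)` samples
with stride `width * (1 - overlap)`; the default 2.56 s / 50 % overlap gives
128-sample windows at 50 Hz, the standard human-activity-recognition
convention. A trailing partial window is dropped rather than padded.

## The four-stage threshold detector

`detect_falls()` scans a filtered series with a state machine whose
contract is documented exactly (the test suite re-implements it
independently as a naive per-sample loop and requires identical event
sets):

* IDLE → FREEFALL when a sample's SVM drops below `freefall_g`
  (default 0.75 g — strictly below the 1 g resting magnitude).
* FREEFALL → IMPACT when the SVM exceeds `impact_g` (default 2.0 g) within
  `max_gap` (1 s) *and* the SVM first difference subsequently reverses
  sign (the scan advances to the local peak). A missed deadline resets to
  IDLE at the first sample after the deadline.
* IMPACT → confirmed when a `motionless_window` (2 s) of body-component
  SMA below `motionless_sma_g` (0.2 g) begins within
  `motionless_deadline` (5 s) of the peak. The event is stamped at the
  window's end.
* Severity: the angle between the mean gravity vector over the second
  before free fall and the half second after confirmation;
  `severe = TRUE` at or above `orientation_delta_deg` (45 degrees).

The motionless stage reads the body component from a 1 Hz gravity estimate
rather than the 0.3 Hz default used elsewhere: a fall changes orientation
in a fraction of a second, and a 0.3 Hz estimate lags that step long enough
that its residual leaks into the body signal through most of the motionless
phase. At 1 Hz the residual decays within the confirmation deadline while
walking bounce (about 2 Hz) still lands in the body component. The cutoff
is an argument of `detect_falls()`.

Degenerate inputs: non-finite samples are rejected (filter first); a series
shorter than one motionless window can never confirm an event; events are
disjoint by construction because scanning resumes after each confirmation.

## The six-class LSTM window classifier

The server-side classifier maps a 128-sample, 7-channel window (six raw
axes plus per-sample SVM) to a probability vector over the six fall
situations, in fixed class order (forward, left, right, back-left,
back-right, trip). The architecture is a single LSTM hidden layer, a
dropout layer, and a dense layer feeding a softmax. The implementation is
written directly in dense linear algebra (forward pass, backpropagation
through time, Adam with gradient-norm clipping); the backward pass is
verified against central finite differences in the test suite. Two design
choices matter:

* **Mean-pooled readout.** The dense layer reads the temporal mean of the
  hidden states rather than the last state alone. Transient cues — the
  trip's gyro spike sits a hundred timesteps before the window end — then
  reach the output without having to survive a hundred gate updates, which
  materially improves training on small window sets.
* **Stored standardisation.** Channels are standardised with training-set
  statistics kept inside the model, so prediction-time inputs (including
  degenerate all-zero windows) are handled identically and always produce
  a valid probability vector.

Defaults: 32 hidden units, dropout 0.5, 50 epochs, learning rate 1e-3,
batch size 16. Training is fully seeded (initialisation, shuffling and
dropout masks all derive from `config$seed`), so two runs give identical
weights. Checkpoints are versioned single-file JSON; restored models
reproduce predictions to double-precision round-trip accuracy.

The classifier *attributes* fall types to events the state machine has
already confirmed (`attribute_fall_types()`); fall/no-fall arbitration
stays with the threshold machine, mirroring the front-end/server split in
which only two-minute alarm windows reach the server.

## Adaptive thresholds from annotated alarm records

When the front-end raises an alarm, the surrounding two minutes of IMU
signal (`extract_alarm_window()`, interpreted as ±60 s around the trigger
and clipped at series bounds) are submitted, and a caregiver annotates the
record true or false. `derive_thresholds()` re-fits the per-user pair
`(freefall_g, impact_g)` by exhaustive grid search (20 × 20 candidates plus
the current pair) minimising the count of false-alarm records that still
trigger plus true-alarm records that no longer trigger, with ties broken
toward the current thresholds — so with consistent records the update never
drifts without evidence, and with no records it is the identity. The
objective and grid are implementation choices; the platform specifies only
that optimised thresholds flow back to the device, which is the
`write_thresholds_json()` payload.

## Location analytics

* Distances are haversine on a 6,371,000 m sphere.
* Fence boundaries are closed (a boundary point is inside), a deterministic
  tie-break; circle membership carries nanometre slack so the convention is
  stable under floating-point rounding. Polygon membership is even-odd ray
  casting with an explicit on-edge test; no planar-geometry package in the
  stack provides point-in-polygon, so it is implemented directly.
* `detect_fence_events()` derives the initial state from the first track
  point (no spurious event at start) and emits ENTER/EXIT per transition,
  plus HOME/AWAY for the `is_home` fence.
* Loitering is anchored-radius dwell: a maximal interval in which every
  point stays within `radius_m` of the interval's *first* point for at
  least `dwell_s`. Anchoring at the first point (rather than a running
  centroid) makes the scan order-independent within the interval and
  exactly translation invariant.
* `track_summary()` counts steps as SVM peaks above 1.1 g with a 0.3 s
  refractory period — a conventional pedometer heuristic — and reports
  calories as a fixed 0.04 kcal per step, documented as cosmetic.

## Device messages and privacy

Measurements and alarms travel as canonical JSON (sorted keys, ISO-8601
UTC timestamps, absent optional fields omitted) keyed by an opaque
`member_id`. Identity-document fields (national ID, certificate number and
the like) are rejected outright at both encode and decode time rather than
silently stripped, so a privacy violation is loud. Decoding is strict:
unknown keys and out-of-enumeration kinds are errors that name every
offending field.

## The evaluation protocols

Confusion counts are fall-oriented: TP is a detection in a fall trial, TN a
non-detection in a non-fall trial, FP a detection in a non-fall trial, FN a
missed fall. The three metrics are
$\mathrm{ACC} = (TP + TN)/(TP + TN + FP + FN)$,
$\mathrm{FPR} = FP/(FP + TN)$ and $\mathrm{FNR} = FN/(TP + FN)$, reported
as percentages rounded half-up to one decimal (half-up, not banker's
rounding, is what reproduces the conventional printed one-decimal figures).

`run_adl_protocol()` simulates a 300-trial campaign: 155 fall trials spread
evenly over the six situations and 145 non-fall ADL trials. The 155/145
split is implied by the reported device-campaign counts (TP + FN = 155
fall samples, TN + FP = 145 non-fall samples) even though the campaign is
nominally described as six fall situations at 50 trials each; both counts
are parameters. A trial scores as a detected fall when at least one
confirmed event occurs. With noise removed the detector matches the
generative model exactly and the protocol accuracy is 100 % — the
noiseless-limit property the test suite asserts.

`run_location_protocol()` runs ten synthetic tracking scenarios — two daily
home stays, three nursing-facility stays, five city trips (two of them
inter-city with a destination fence) — and reports the pass fraction; each
scenario asserts its own expected fence, home/away, loiter and summary
outcomes against tracks whose geometry is known by construction.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use: 100 seeded fall
simulations for the weight-loss property, the full 300-trial detection
protocol, 100 mixed series for the state-machine/brute-force equivalence
check, a 60-window (10 per class) set for classifier memorisation, and ten
location scenarios. These sizes make every result reproducible on a single
CPU in well under a minute per protocol while keeping each check at the
scale its claim refers to. All randomness flows through explicit integer
seeds; per-trial seeds are derived deterministically from one master seed.

## Known limitations

* Synthetic-only validation: no claim transfers to device recordings
  (see the generator caveats above).
* The threshold grid adapts only the two SVM triggers; the motionless and
  orientation parameters are considered population-level.
* Loitering uses raw GPS points; with very noisy fixes a rolling-median
  pre-smoother should be applied before the dwell scan.
* The classifier is intentionally small and trains full-sequence BPTT in
  plain R; it is sized for alarm-window attribution, not for large offline
  corpora.
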