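---
title: "Comparing clothing- and body-mounted IMUs during walking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing clothing- and body-mounted IMUs during walking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitsva)
```

`gaitsva` quantifies how faithfully IMUs mounted in everyday loose clothing
reproduce the gait signals of IMUs taped to the body. This vignette is the
package's own account of its models and the design decisions behind them:
what each stage assumes, which parameters matter, what the synthetic data
generator does and does not emulate, and where the numerical choices come
from.

## 1. The measurement model

Each sensor records synchronized 3-axis acceleration (in g) and angular rate
(in deg/s) at 50 Hz — the rate of the low-cost MEMS IMUs this kind of study
uses, with a ±16 g accelerometer range so that shank impacts do not clip.
Six sensors are worn: waist, thigh and lower shank, each once taped to the
body and once mounted in the clothing.

The quantity compared across a clothing/body pair is the
**sensor-to-vertical angle (SVA)**. With per-sample unit quaternions
$q = (q_0, q_1, q_2, q_3)$ describing the sensor's orientation, the SVA is

$$\theta = \arccos(2 q_0 q_2 + 2 q_1 q_3) - 90^\circ.$$

The arccos argument is the vertical component of the world-frame sensor
x-axis, so $\theta$ measures how far the x-axis dips out of the horizontal
plane: $0^\circ$ for a vertical segment, oscillating about $0^\circ$ during
walking. The alternative z-axis angle
$\theta_z = \arccos(q_0^2 - q_1^2 - q_2^2 + q_3^2)$ is computed as an
auxiliary but cannot distinguish a limb leaning forward from one leaning
backward (it is an unsigned inclination), which is why the x-axis form is
used for gait.

**Quaternion convention.** The package stores quaternions in the
orientation estimator's native convention, in which sensor-frame vectors
rotate into the world frame via the conjugate sandwich $q^* v q$. Under this
convention the SVA formula above is *exactly* the brute-force computation
"rotate the sensor x-axis into the world and take its angle from the
vertical, minus 90°" — an identity the test suite checks to $10^{-9}$ over
$10^4$ random quaternions. One consequence worth stating: with the package's
axis orientation (see §3) the medial-lateral gyro channel equals
$+\,d\theta/dt$, the swing phase is a large positive gyro peak, and initial
contact / toe-off appear as prominent gyro minima. Published figures of
shank-to-vertical angles sometimes use the mirrored sign convention
(positive = reclined); the two differ only by an overall sign of $\theta$,
and pair-agreement statistics are unaffected.

## 2. Sensor-to-segment alignment

Sensors are mounted in unknown orientations, so two rotations bring each
data stream into a common participant frame:

1. **Gravity rotation.** While the wearer stands still, the accelerometer
   measures only gravity. The rotation is built with Rodrigues' formula
   about the axis perpendicular to the mean acceleration and the z-axis, by
   the angle between them. Preconditions: at least 2 s of standing and a
   mean magnitude inside the quasi-static band 0.8–1.2 g (a cheap guard
   against mislabelled segments). A mean acceleration anti-parallel to z
   (angle > 179°) leaves the rotation axis undefined; since it corresponds
   to a physically implausible upside-down mounting, it is surfaced as an
   error rather than resolved by an arbitrary 180° choice.
2. **Sagittal rotation.** Movements like sit-to-stand, leg raises and
   walking accelerate the sensor mostly along the anterior-posterior
   direction. That direction is estimated as the first principal axis of
   the zero-meaned horizontal acceleration over all labelled dynamic
   segments, and a rotation about z maps it onto x. The principal axis has
   a sign ambiguity; it is resolved so that the strongest horizontal
   accelerations — the top decile by magnitude, summed — project positively
   onto the new x-axis. An aggregate is used rather than the single largest
   sample because one sample is a coin flip under heavy fabric noise. In
   the pipeline the sign decision is made on the walking segment, whose
   anterior-posterior accelerations are by far the most stereotyped, while
   the direction estimate still pools all dynamic segments equally.

Both rotations are exact isometries; filtering and alignment commute on
noise-free data (both are linear), and the order (gravity first, then
sagittal) is fixed purely for reproducibility.

## 3. Filtering, orientation, and two choices that matter

The event-detection and reporting streams are low-pass filtered with a
zero-phase (forward-backward) 2nd-order Butterworth at 3 Hz — DC gain
exactly 1, no phase distortion. Edge transients are suppressed by
odd-reflection padding of one second of samples; short pads leave startup
ringing whose integral would survive downstream as a permanent angle
offset.

Orientation comes from the IMU (accelerometer + gyroscope, no magnetometer)
variant of the Madgwick filter: the quaternion is propagated with the gyro
and nudged toward the accelerometer's gravity direction by a normalized
gradient step of size $\beta$ (default 0.1 rad/s, exposed in
`pipeline_config()`). Heading relative to north is unobservable without a
magnetometer and irrelevant here — only the attitude enters the SVA. Two
implementation decisions proved decisive on walking data and are therefore
defaults:

* **Exponential-map gyro integration.** The textbook Euler step
  $q \leftarrow q + \tfrac12 q \otimes \omega\, dt$ has a per-step error
  cubic in $\omega\,dt$ that does not cancel over a gait cycle
  ($\propto \int \omega^3 dt$); at 50 Hz and 300–400 deg/s swing rates it
  drifts by roughly 0.9°/min. The package instead multiplies by the exact
  axis-angle increment of the trapezoid-averaged rate, which is exact for
  fixed-axis rotation.
* **Quasi-static gating of the accelerometer correction.** During walking
  the specific force is dominated by motion, not gravity. Because the
  normalized gradient step moves the attitude at the constant rate
  $\beta$ whenever it is misaligned, an ungated filter settles on the
  *duration-median* of the apparent gravity direction — a systematic bias
  of several degrees on gait data, independent of $\beta$. The correction
  is therefore applied only when a trailing 0.5 s window is quiet
  ($\lvert\,\lVert a\rVert - 1\,\rvert \le 0.05$ g and
  $\lVert\omega\rVert \le 15$ deg/s): the attitude is anchored during
  standing and quiet stance and integrates drift-free through the dynamic
  phases. The gyro bias is estimated as the mean aligned gyro over the
  standing segment and subtracted, so pure integration is genuinely
  drift-free over a walking bout of a minute or two.
* **The orientation input is not low-pass filtered.** Filtering an angular
  rate before integrating it removes real rotation content: the harmonic
  attenuation adds ~1–2° RMS of angle distortion and the transient at gait
  onset integrates into a permanent offset. The 3 Hz filter is applied to
  the streams used for event detection and for reported signals, not to
  the Madgwick input. With these three choices the pipeline recovers a
  noise-free synthetic shank angle to well under 1° RMS; with any of them
  reverted the error is several degrees.

## 4. Gait-cycle extraction

* **Mid-swing (MS)**: local maxima of the lower-shank acceleration
  magnitude above 1.8 g (body) or 2.0 g (clothing); within any 1 s window
  only the largest peak is kept, matching one-MS-per-stride physiology at
  normal cadence. Detection runs on the *raw* magnitude by default
  (`ms_use_filtered` switches this): zero-phase filtering the channels and
  then taking the nonlinear magnitude shifts the per-cycle peak several
  samples early, whereas the raw magnitude peaks where the swing
  angular velocity does.
* **Fixed-length cycles**: the cycle length is the rounded mean gap
  between consecutive MS points — one length per record, avoiding
  time-normalisation; windows that would run past the end of the record
  are dropped, and windows may overlap slightly where individual strides
  deviate from the mean.
* **IC and TO**: within each cycle window, the first and last prominent
  local minima of the filtered medial-lateral shank gyro (prominence
  threshold 8 deg/s). Cycles lacking two distinct prominent minima are
  flagged and excluded from downstream statistics instead of failing —
  the same mechanism that absorbs spurious MS points from turns in real
  recordings.
* The waist and thigh streams are synchronised with the shank, so the
  body-shank cycle windows segment every stream of both attachments; this
  keeps the pair matrices cycle-aligned. Clothing-shank detection is also
  run and reported separately (its thresholds differ), mirroring how
  detection accuracy is quoted per attachment.

The stance fraction per cycle is $(\mathrm{TO}-\mathrm{IC})/L$; healthy
adult walking spends close to 60 % of the cycle in stance, which is also
the generator's default.

## 5. The synthetic session generator

The generator replaces participant recordings, so its defaults *are* the
study conditions. A session follows the five-activity protocol (standing,
sitting, five sit-to-stand cycles, five leg raises, walking back and forth;
about two minutes each in the default protocol). Every non-walking activity
starts and ends at the standing pose with zero rate, and walking amplitude
ramps in over ~2 s and out over 1 s, so assembled trajectories are smooth
across activity boundaries.

**Walking kinematics.** Cycle-periodic sagittal SVA trajectories per
segment with defaults: cycle duration 1.25 s (comfortable cadence), stance
fraction 0.60, angle half-ranges 22° (shank), 18° (thigh), 5° (waist) —
shank largest, waist smallest, as lower-limb kinematics go — with 2 %
cycle-duration jitter and a 3 % slow amplitude drift. The shank template is
a 6-harmonic Fourier series for the medial-lateral angular velocity, fitted
once per parameter set to a bump-mixture gait morphology (broad positive
swing peak, negative IC/TO dips, mild mid-stance hump) under six linear
constraints: stationarity at the MS, IC and TO phases of both the raw
series *and* its 3 Hz zero-phase-filtered image (zero-phase filtering
scales Fourier harmonics by real gains, so this is linear). The second
constraint set pins the detected filtered-gyro minima to the ground-truth
event phases within a sample. A ridge penalty proportional to the angle
distortion the 3 Hz filter would inflict on each harmonic keeps the angle
trajectory essentially inside the filter pass-band. Thigh and waist use
fixed smooth one- and two-harmonic templates (the pelvis oscillates once
per step, i.e. twice per stride).

**Forward IMU model.** The segment attitude is the rotation about the
medial-lateral axis given by the SVA; the accelerometer measures gravity in
the segment frame plus the lever-arm linear acceleration from
double-differentiated angles (4th-order central differences; relative error
~$10^{-4}$ at gait frequencies), plus a world-frame translational
acceleration bump at mid-swing (peak 1.4 g at the shank, 0.55 g thigh,
0.25 g waist, direction (0.5, 0, 0.87)). The bump models the swing-leg
deceleration that dominates real shank accelerometry: rotation about a
fixed pivot alone cannot produce the >2 g magnitude peaks the MS thresholds
expect while keeping the angle trajectory inside the 3 Hz band. It also
gives every sensor a deterministic "anterior" reference for the alignment
sign rule. Mounting misorientations are random rotations (up to 10° body,
25° clothing), gyro bias is drawn per sensor (SD 0.3 deg/s), and white
noise defaults are 0.02 g and 1 deg/s — ordinary MEMS figures.

**Fabric coupling.** The clothing angle $\theta_c$ tracks the body angle
$\theta_b$ through a linear spring-damper with gain,
$\ddot\theta_c = -k(\theta_c - g\,\theta_b) - c\,\dot\theta_c$, integrated
with a fixed-step semi-implicit scheme (spring explicit, damping implicit,
sub-stepped so $\sqrt{k}\,d\tau \le 0.2$; stable and accurate far beyond
the default stiffness range). This is the simplest model that reproduces
the two qualitative observations about loose clothing: the cycle shape is
preserved while the angle range widens ($g > 1$), and agreement degrades
with fabric slack. Defaults per placement (calibration choices, not
reproductions of any particular garment): resonance $\sqrt{k}$ at 40–50
rad/s — above the gait band, so shape is preserved — gains 1.05 / 1.12 /
1.18 and movement-modulated band-limited fabric noise of 2.4° / 2.0° / 1.5°
(waist / thigh / shank). The noise is modulated by the smoothed body
angular speed because fabric flutters when the wearer moves and hangs still
otherwise; unmodulated noise would shake the clothing sensors during quiet
standing, which neither matches reality nor leaves the orientation filter
any quasi-static anchor. With these defaults, synthetic sessions give
pooled per-cycle correlations of roughly 0.88 at the waist and 0.98 at the
thigh and shank — the waist pair worst, as the waistband and pouch
interference observed with real garments would predict — and standing angle
differences of essentially 0°.

**What passing tests do and do not show.** The generator is sagittal-plane
only: no frontal/transverse kinematics, no magnetometer, no foot-contact
forces, no soft-tissue artifact beyond the linear fabric model, and the
per-segment pivot is fixed (segment translation enters only through the
prescribed mid-swing bump). Recovery results on synthetic sessions
demonstrate that the pipeline's machinery is correct and self-consistent;
they do not certify performance on real recordings, where turning,
variable cadence, sensor repositioning and richer soft-tissue dynamics
intrude.

## 6. Numerical and interface choices

* Gyro units are deg/s at every interface, radians internally; arccos
  arguments are clamped to [-1, 1]; quaternion sign continuity is enforced
  by flipping when successive dot products are negative.
* Degenerate inputs error early with classed conditions
  (`gaitsva_not_standing`, `gaitsva_insufficient_excitation`,
  `gaitsva_cannot_segment`, ...); cycles with missing IC/TO are flagged
  and excluded rather than fatal.
* The shank-vertical instant is the first zero crossing of the body-shank
  SVA within [IC, TO], nearest-sample convention — sample-level precision
  is adequate at 50 Hz.
* A Shapiro-Wilk normality screen of the per-cycle correlations is
  computed and reported (`shapiro_p`) but never blocks the Pearson
  statistics.
* Sessions, activity annotations, ground-truth events and mounting
  matrices serialise to plain CSV (9-decimal round trips) with strict
  schema validation; configurations to YAML.

## 7. Problem sizes used by the test suite

The packaged tests simulate sessions of 40–50 gait cycles with 30 s of
standing and short dynamic segments; the event-recovery and correlation
properties aggregate 10–20 sessions (500–1000 cycles), and the SVA identity
is checked on $10^4$ random quaternions. These sizes give stable statistics
(Monte-Carlo error well below the asserted tolerances) while the whole
suite runs in well under a minute.

## 8. Known limitations

* Absolute heading is unobservable (by design: no magnetometer), so only
  attitude-derived quantities are meaningful.
* The fixed cycle length assumes reasonably steady cadence; strongly
  accelerating or turning gait violates it and surfaces as flagged cycles.
* The Madgwick gating assumes some quasi-static moments exist; a recording
  with no quiet phases would rely on the standing-segment anchor alone.
* The fabric model is linear; real garments show hysteresis, slip and
  posture-dependent drape that the model deliberately omits.
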