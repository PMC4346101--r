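---
title: "Two-feature fall detection from waist-worn accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-feature fall detection from waist-worn accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quatfall)
```

## The detection model

A waist-worn triaxial accelerometer measures, at rest, the reaction to
gravity: a unit vector (in g-units) whose direction in the device frame
encodes body orientation. `quatfall` detects falls from two features of the
raw stream:

* **Impact.** The sum acceleration $|a| = \sqrt{a_x^2 + a_y^2 + a_z^2}$ is
  orientation-free and equals 1 g at rest. A fall's collision with the
  ground produces a peak of several g; the detector opens a candidate event
  at the first sample with $|a| \ge a_\mathrm{threshold}$.
* **Body rotation.** A genuine fall takes the wearer from upright to lying,
  rotating the device-frame gravity direction by roughly $90^\circ$. The
  gravity direction is captured while the wearer is still — every sample of
  a short window inside the band $1 \pm 0.3$ g — once at the start of wear
  ($g_\mathrm{before}$) and again after the impact settles
  ($g_\mathrm{after}$).

The rotation between the two captures is factored into three elementary
unit quaternions. Writing $\rho = \sqrt{g_x^2 + g_y^2}$ for the horizontal
norm:

* $Q_1$ tilts $\hat g_\mathrm{before}$ into the horizontal $(i,j)$ plane:
  angle $\theta_1 = \arctan(g_z/\rho)$ about the horizontal axis
  $(\sin\alpha, \cos\alpha, 0)$, $\sin\alpha = -g_y/\rho$,
  $\cos\alpha = g_x/\rho$;
* $Q_2$ rotates about $k$ by the azimuth difference $\theta_2 =
  \operatorname{atan2}(g'_y, g'_x) - \operatorname{atan2}(g_y, g_x)$;
* $Q_3$ tilts back out of the plane by $\theta_3 = -\arctan(g'_z/\rho')$
  about $(\sin\beta, \cos\beta, 0)$.

Their composition $Q = Q_3 \otimes Q_2 \otimes Q_1$ satisfies
$\hat g_\mathrm{after} = Q \otimes \hat g_\mathrm{before} \otimes Q^*$, and
the total rotation angle is
$\theta = 2\arctan\!\big(\sqrt{q_1^2+q_2^2+q_3^2}\,/\,q_0\big)$.
An alarm is raised iff $|\theta|$ falls inside the angle band. The
single-feature baseline detector (`method = "acceleration"`) alarms on the
impact alone and exists as the comparison arm for benchmarks.

```{r example}
sim <- generate_motion(motion_spec("fall_forward", seed = 42))
detect_falls(sim$trace)
```

## Geometry of the decomposition

Three properties of the composed angle drive both the design of the
synthetic data and the package's claims, and all three are exercised by the
test suite.

**It maps before onto after.** For any two non-vertical directions the
composed $Q$ carries $\hat g_\mathrm{before}$ exactly onto
$\hat g_\mathrm{after}$ (the suite checks a residual below $10^{-9}$ over
1000 random pairs).

**Its angle is azimuth-invariant only.** $|\theta|$ is unchanged when both
gravity vectors are rotated together about the device $k$ axis, since
$\theta_1$, $\theta_3$ and the azimuth *difference* are unchanged. It is
*not* invariant under an arbitrary common rotation: writing $e$, $e'$ for
the two elevations and $\Delta$ for the azimuth difference, the scalar part
of $Q$ works out to $q_0 = \cos(\Delta/2)\cos((e - e')/2)$, which depends
on elevations and azimuths separately — not only on the angle between the
two directions. A fixed $95^\circ$ posture change can therefore read as
anything from $95^\circ$ to $180^\circ$ depending on how the device is
mounted. The often-stated claim that a magnitude-plus-relative-rotation
detector needs no particular mounting orientation holds for $|a|$ and for
the *geodesic* angle between the gravity directions, but only partially for
this decomposition: the acceptance suite states the full claim as a test
and documents its failure, while the module tests assert the (true)
azimuthal invariance.

**It is unstable for planar tilts beyond $90^\circ$.** If the lying
direction stays in the device $x$–$z$ plane, a tilt of $90^\circ + \delta$
flips the after-azimuth by $180^\circ$ and the composed angle jumps to
$\approx 180^\circ$ instead of $90^\circ + \delta$. Landing directions with
a substantial device-$y$ component are well behaved; this motivates the
generator's landing-roll model below, and plausibly explains why detectors
of this family miss a small fraction of straight backward falls.

**Sign.** $\theta_2$ is kept as the raw difference of the two azimuths
(range $(-360^\circ, 360^\circ)$) rather than wrapped into
$(-180^\circ, 180^\circ]$. Wrapping only flips the overall sign of
$\theta$ — never $|\theta|$, which is what the alarm uses — and the
unwrapped form is what yields the negative angles seen when the azimuth
crosses the $\pm180^\circ$ cut, matching how such detectors report angles
like $-100^\circ$ for backward falls in practice.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `a_threshold` | 2.0 | g | impact peaks of real falls are 3–6 g; deliberate lying down peaks at 1.4–1.8 g |
| `t_threshold` | 2.0 | s | a fallen person is lying still well within 2 s of impact |
| `gravity_band` | (0.7, 1.3) | g | $\pm 0.3$ g tolerance on stillness; loose enough for residual tremor |
| `angle_band` | (60, 120) | degrees on $\|\theta\|$ | $90 \pm 30$: allows ground tilt and non-flat lying postures |
| `still_window_s` | 0.5 | s | averages residual oscillation yet is short against `t_threshold` |
| `lowpass_cutoff_hz` | 1.0 | Hz | posture is quasi-static; voluntary dynamics sit at roughly 2 Hz and above |
| `sample_rate` | 100 | Hz | standard rate for human-movement capture |

All are bundled in `detector_config()` and round-trip through YAML for the
command-line tools.

## Numerical choices

* Gravity vectors are normalised before decomposition; the three angles
  depend only on direction, so this removes sensitivity to the $\pm 0.3$ g
  capture tolerance.
* If a (normalised) gravity vector has horizontal norm below
  $\epsilon_h = 10^{-8}$, its azimuth is the undefined ratio $0/0$; the
  axis angle is then set to zero (axis $= j$), the azimuth to 0, and a
  degeneracy flag is recorded instead of raising an error — the limit
  rotation is well defined up to azimuth and the composed $Q$ still maps
  before onto after.
* `quat_angle` evaluates the arctangent with the signed scalar part and
  returns exactly $180^\circ$ at $q_0 = 0$; quaternion sign is not
  canonicalised.
* The low-pass gravity filter is a 2nd-order Butterworth applied
  forward-only (causal, as an online device would run it); its state is
  initialised by padding with the first sample held constant, so constant
  input is reproduced exactly, and the first three time constants are still
  flagged as warm-up for callers that cannot assume an initially still
  signal.
* Still-window search is earliest-first: calibration uses the earliest
  qualifying window before any impact, and the settle search accepts the
  first window starting within `t_threshold` of the impact (earliest-alarm
  bias). After an event — alarmed or rejected — monitoring resumes after the
  settle window (or after the search span when none was found) so one
  impact's oscillation is never double counted.
* `g_before` is captured once at the start of the trace; the trace must
  open with a still period or `detect_falls()` refuses with a calibration
  error naming the required duration and band.
* Unit-quaternion checks are asserted at $10^{-9}$, algebraic identities at
  $10^{-12}$ (absolute, since products of unit-scale quaternions can have
  catastrophically cancelled components).

## The synthetic-data generator

No accelerometer hardware is assumed anywhere: the generator produces the
nine motion classes with ground truth, and everything downstream is tested
against it. Each trace is a scalar magnitude profile carried by a smoothly
rotating gravity direction (geodesic interpolation between the initial and
final directions, so intermediate samples are physically coherent), plus
additive white Gaussian noise of $\sigma = 0.02$ g per axis — comfortably
above the few-mg resolution of consumer MEMS parts.

* **Mounting**: device $x$ along the trunk with a random tilt of up to
  $8^\circ$; an optional `device_orientation` quaternion rotates the whole
  trace (and the ground truth) for orientation experiments.
* **Falls** (four directions): $\ge 1$ s still, a free-fall dip to
  $\approx 0.3$ g for 0.2–0.4 s, a half-sine impact spike of 3–6 g lasting
  30–80 ms, a damped 15 Hz ring-down of $\approx 0.5$ s, then lying still.
  The lying direction sits $90 \pm 15^\circ$ (uniform) from the initial
  gravity direction. Its device-frame azimuth is the class tip direction
  plus an axial landing roll — $\pm(0$–$30)^\circ$ for the sagittal classes
  (which tip toward device $\pm y$), $\pm(45$–$85)^\circ$ for the lateral
  ones (which tip toward device $\pm z$). Bodies pivot about their long
  axis as they collapse; the roll ranges are chosen so landing postures
  avoid the decomposition's unstable $x$–$z$ plane, and the resulting
  detected angles span roughly $75$–$119^\circ$, the range such detectors
  report on real falls.
* **Walking**: $1 \pm (0.35$–$0.5)$ g at 1.8–2.2 Hz, orientation constant —
  never crosses 2 g.
* **Jumping**: three jump cycles with flight dips near 0.15 g and landing
  spikes of 2.5–3.5 g; posture restored to within $8^\circ$. The landings
  open impact events whose rotation angle is near zero, so the two-feature
  detector rejects them while the acceleration-only baseline false-alarms —
  the designed discriminating case.
* **Squatting / sitting**: sub-2 g dips and rises with a transient lean
  below $15^\circ$ (squatting) or a persistent recline below $30^\circ$
  (sitting).
* **Resting**: deliberate lying down — the fall-like dip/peak shape with a
  peak of only 1.4–1.8 g and a rotation drawn from $92$–$118^\circ$ toward
  device $\pm y$ ($\pm 8^\circ$ jitter), so its rotation is fall-like but
  its peak never reaches the impact threshold. The margins inside the
  nominal $90$–$120^\circ$ lying range keep the *captured* angle inside
  that range under capture noise.

`generate_cohort()` derives one seed per trace from a master seed, with 60
traces per class by default (matching a protocol of 20 repetitions by each
of three volunteers); the acceptance script and suite run the full
540-trace cohort, which generates and benchmarks in a few seconds.

**What passing on synthetic data does and does not show.** The generator
reproduces the qualitative waveform structure of real falls and ADLs —
phase ordering, peak ranges, orientation changes — but not biomechanical
detail: no soft or staged falls, no gait variability beyond a sinusoid, no
sensor saturation, bias or temperature drift, and landing geometry drawn
from the benign region by design. Synthetic sensitivity/specificity are
regression snapshots of the implementation under these stated conditions,
not estimates of human-subject performance.

## Evaluation conventions

A trace counts as alarmed if at least one of its events has
`is_alarm = TRUE` (one motion per trial). Fall-class trials are positives,
ADL trials negatives;
$\mathrm{sensitivity} = 100\,TP/(TP+FN)$ and
$\mathrm{specificity} = 100\,TN/(TN+FP)$. Printed rates are rounded half-up
to one decimal, with the exact fraction always shown alongside — two
conventions (half-up rounding vs truncation) differ by 0.1 points exactly at
fractions like $220/240 = 91.67\%$, which is why `fall_metrics` reports
both. Per-class counts are always emitted next to the two scalars.

## Known limitations

* The angle feature degrades for mountings that place standing gravity near
  the device $k$ axis (degenerate azimuth) and for landing postures in the
  $x$–$z$ plane past $90^\circ$; full mounting-rotation invariance holds
  only for the impact feature and for the geodesic angle, not for the
  decomposition angle.
* Heavy deliberate lying down (peaks above 2 g) is indistinguishable from a
  fall for this detector — the impact threshold is the only guard.
* `g_before` is captured once at wear time; posture drift during long wear
  is not tracked (periodic recalibration would need an upright-stillness
  heuristic).
* The detector is single-pass and causal with a bounded settle buffer, so
  it could run on-device, but no real-time scheduling guarantees are made.
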