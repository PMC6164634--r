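---
title: "Quantifying upper-limb movement from wearable IMU and EMG sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying upper-limb movement from wearable IMU and EMG sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(araquant)
```

## The measurement problem

Standardized upper-limb assessments such as the Action Research Arm Test
(ARAT) score each reach–grasp–transfer–release–return task on a coarse
ordinal scale assigned by a therapist. A wearable system — one inertial
measurement unit (IMU) on the sternum and one on each hand, wrist and upper
arm, plus an eight-electrode surface-EMG armband on the forearm — lets the
same task executions be quantified continuously. `araquant` implements the
full processing chain from raw sensor streams to five per-phase movement
parameters, together with a synthetic task generator that makes every stage
testable without clinical recordings.

## Arm kinematics from gyroscopes

The arm is modelled as a 7-degree-of-freedom chain (shoulder
flexion/extension, abduction/adduction, internal/external rotation, elbow
flexion/extension, wrist pronation/supination, ulnar/radial deviation,
wrist flexion/extension), proximal to distal, expressed in a right-handed
trunk frame (x forward, y left, z up). The hand pose is the product of the
seven link transforms,

$$T^{H} = \prod_{j=1}^{7} T_j^{j-1}(\vartheta_j),$$

and with all angles zero the arm hangs along the trunk axis — the
calibration stance. The printed sources for this class of model do not fix a
unique link table; the one used here (axes $\pm x, \pm y, \pm z$ with
segment offsets after joints 3, 5 and 7) reproduces the stated joint order
and zero posture and is locked by a unit test, since any such assignment is
kinematically equivalent for the quantities computed downstream.

The three arm-mounted gyroscopes measure the stacked angular velocity
$\Omega = (\omega_1; \omega_2; \omega_3) \in \mathbb{R}^9$, linear in the
joint speeds through a configuration-dependent Jacobian,
$\Omega = J(\vartheta)\,\dot\vartheta$. Because nine measurements constrain
seven speeds, the least-squares inverse
$\dot\vartheta = J^{\dagger}\Omega$ (Moore–Penrose, singular values below
$10^{-8}\sigma_{\max}$ truncated and flagged) exploits the redundancy.
Angles are recovered by trapezoidal integration from the known calibration
posture; a Heun predictor–corrector evaluates the Jacobian at the predicted
posture. Arm gyros measure absolute rates while all quantities are defined
relative to the trunk, so the trunk sensor's angular velocity, rotated into
each sensor frame at the current posture estimate, is subtracted first.

Gyroscope bias makes pure integration drift. When a stream of absolute
joint-angle observations is available (derived from accelerometer +
magnetometer orientations), each integration step adds
$K_\Delta\,\mathrm{wrap}(\vartheta_{\mathrm{abs}} - \hat\vartheta)$. The
gain defaults to $1\,\mathrm{s}^{-1}$ — a first-order complementary
structure with a one-second time constant — giving a steady-state error of
$b/K_\Delta$ under bias $b$, which the tests verify against the closed
form.

Absolute orientation itself comes from the Wahba-problem optimum (the
q-method): the principal eigenvector of Davenport's $K$ matrix built from
the measured gravity and magnetic-field directions. The default reference
field has a 60° inclination, which places it 150° from gravity; the
attitude error under per-vector noise is proportional to that noise with a
geometry factor of about 4 at the 95th percentile (about 2 with orthogonal
references), a bound verified by simulation. Trunk orientation fuses
gyro propagation with these absolute estimates in a complementary filter
(blend weight 0.02 toward the field solution per step at 100 Hz, i.e. a
0.98/0.02 split); the stream must open with at least one second of
quasi-static calibration, whose mean orientation defines the trunk
reference. Roll–pitch–yaw deviations from that reference are reported.

## Arc-length segmentation

The hand path $p(t)$ is re-parameterized by normalized arc length
$\bar s = s(t)/L \in [0,1]$, which separates the *shape* of the movement
from its *speed*: dwells (manipulation phases) collapse to single points and
all path-based quantities become invariant to the time course. Positions are
resampled on a uniform $\bar s$ grid (default step 1/500, resolving
millimetre-scale features of half-metre paths) after removing zero-velocity
runs (speed below 2% of the peak — a threshold robust to the sensor noise
floor).

Phase boundaries are stop-and-turn events: a local maximum of the
direction-change profile
$\nu(\bar s) = \mathrm{atan2}(\|r \times r'\|, r \cdot r') \in [0, \pi]$
(the angle between successive unit tangents) coinciding — within 2% of
$\bar s$ — with a local minimum of the speed profile below 20% of the peak.
Direction-change peaks are detected on the raw profile with a prominence
threshold of $\pi/6$; smoothing is deliberately avoided there because it can
push a genuine but tremor-smeared corner below the threshold, while the
coincidence and speed conditions already reject noise peaks. Candidates
closer than 2% of $\bar s$ merge (higher prominence wins), the
`expected - 1` most prominent boundaries are kept (ties to earlier
$\bar s$), and grasp/grip/pinch tasks expect three movement phases, gross
movement tasks two. If fewer candidates exist than required, a
segmentation-failure condition carrying the candidate table is raised.

Mapping boundaries back to time is not unique (a dwell is one arc point but
many time samples). The implementation matches each queried arc point to the
time sample whose cumulative normalized path length is nearest, searching
only forward of the previous match — which resolves paths that revisit a
position — and walks matches inside an exactly-repeated-position dwell back
to the dwell start, the first causal visit. Each movement phase is then
anchored on its dwell by a positional walk (radius of three grid steps of
path length, robust to sensor noise): arrival gives the termination
neighbourhood, departure the onset neighbourhood.

Exact onsets and terminations come from the minimum-acceleration
(cubic-onset) model,

$$x(t) = x_o \;\; (t \le t_o), \qquad
  x(t) = x_o + \tfrac{1}{6}\eta_m (t - t_o)^3 \;\;
  (t_o \le t \le t_o + \Delta T),$$

fitted to the hand's displacement from the dwell rest position by grid
search over $t_o$ (window ±0.5 s) with closed-form $(x_o, \eta_m)$ per
candidate. Two numerical choices matter. First, the cubic segment is
anchored at a fixed endpoint inside the movement (the 15% departure
crossing), so no candidate can score a perfect fit on purely static data.
Second, the support is then tightened in passes
($\Delta T = 0.2\,\mathrm{s}$ down to $0.05\,\mathrm{s}$) toward the
running estimate — the cubic is exact only in the earliest part of a
bell-shaped movement — but only while the support's rise stays at least
five standard deviations above the static-region noise, because on
noise-dominated data every candidate fits the static level equally well.
Terminations are handled by time reversal. On noise-free cubic and
minimum-jerk test signals the detector is accurate to well under one sample
at 100 Hz.

## The five quantification parameters

For each movement phase $i$ (and the whole task):

* **Movement time** $T_{mi} = T_{ti} - T_{oi}$; the task value spans first
  onset to last termination, dwells included.
* **Rotational jerk index**
  $\eta_{rot}^i = \log\!\big(\frac{T_{mi}^5}{\theta_p^2}
  \int \|\ddot\omega\|^2 dt\big)$, computed from the hand gyroscope after a
  zero-phase 10 Hz low-pass (above voluntary-movement bandwidth) and a
  fourth-order central second difference — two numeric derivatives amplify
  noise, so both choices are load-bearing. $\theta_p = 1$ by default (hand
  orientation is held in the supported tasks; a configuration hook exists
  for tasks with substantial angular displacement). The form is
  dimensionless and invariant to pure time scaling, which a test verifies;
  constant angular velocity returns $-\infty$ with an undefined-smoothness
  flag. Natural log; constant offsets do not affect any comparison.
* **Trajectory similarity** $\chi_i = \alpha D_i + \beta \hat\nu_i$ with
  equal weights $\alpha = 0.5\,\mathrm{m}^{-1}$, $\beta = 0.5$: the RMS
  Euclidean distance from a healthy-median reference path
  ($D_i$, trapezoidal quadrature of $\|p - p_r\|^2$ over the phase's
  $\bar s$ interval) plus the $\pi$-normalized RMS direction change
  ($\hat\nu_i \in [0,1]$). The reference is the coordinate-wise median of
  healthy-group arc-parameterized trajectories (lower-median convention for
  even counts, so the reference is always an observed value), with per-point
  IQR as dispersion. Similarity is computed on full 3-D positions;
  left-arm paths are mirrored across the sagittal plane before comparison
  with a right-arm reference so healthy arms can be pooled.
* **Trunk stability** $\rho_i$: the maximum over the phase of the
  root-sum-of-squares deviation of the three trunk angles from their values
  at phase start — a proxy for compensatory trunk movement, exact for
  piecewise-linear single-axis profiles by construction.
* **Normalized EMG activity** $\hat w_{ni}$: the RMS over all eight
  electrodes, $\sqrt{\frac{1}{T_{mi}}\int \sum_n w_n^2\,dt}$ (insensitive
  to armband orientation), divided by the same quantity over a designated
  maximal-effort recording. Values above 1 are permitted but flagged as a
  submaximal reference.

Group differences are assessed with the two-sided Mann–Whitney rank-sum
test: exhaustive permutation enumeration of the rank-sum distribution
(average ranks, exact under ties) when $\binom{m+n}{m}$ is small, otherwise
the normal approximation with tie and continuity corrections. Relations to
ordinal clinical scores use the Spearman coefficient (Pearson correlation of
average ranks, two-sided t-approximation p-value). No multiple-comparison
correction is applied; raw p-values at the 0.05 level are reported, and the
significance grid mirrors the matrix layout used in instrumented-assessment
reports.

## The synthetic task generator

No public recordings exist for this protocol, so the generator defines the
study conditions under which the pipeline is validated. A task is a
joint-space posture sequence — rest, object, target (shelf or lateral peg),
rest; for gross movement, rest–head–rest — connected by minimum-jerk strokes
(healthy durations 1.1–1.3 s per stroke, ±10% jitter) separated by 0.5 s
manipulation dwells, with 1.5 s and 1 s holds at the ends. Postures are
chosen so consecutive strokes meet at distinct corners in hand space (the
stop-and-turn signature segmentation relies on); waypoints are the forward
kinematics of those postures, so no inverse kinematics is ever solved.
Everything downstream is derived: the hand path via forward kinematics,
gyroscopes via the Jacobian plus trunk coupling, accelerometers as gravity
plus numerically differentiated linear acceleration in the sensor frame,
magnetometers as the rotated 60°-inclination reference field.

Impairment is modelled as four graded profiles — healthy (H), patients'
unaffected arm (UAF), affected arm with normal execution (AF3), affected arm
with moderate execution (AF2) — whose fields increase monotonically:
duration scaling (1 / 1.1 / 1.5 / 3; the AF2 value keeps tasks inside the
5–60 s window that defines a completed-but-slow execution), corrective
submovements per stroke (0 / 0 / 2 / 4, smooth out-and-back joint-space
bumps of ~0.5–0.9 s), 4–8 Hz kinetic tremor on the distal joints windowed
to the strokes (0 / 0.01 / 0.05 / 0.12 rad/s RMS), sagittal trunk lean
ramping during reach (0.01 / 0.02 / 0.05 / 0.15 rad) and EMG co-activation.
These mechanisms were chosen because they move the four kinematic
parameters in the clinically reported directions; they are a caricature,
not a patient model — real impaired movement has richer structure
(spasticity-dependent coupling, fatigue, variable strategies), so passing
tests demonstrate that the pipeline recovers what the generator put in, not
that it measures patients accurately. EMG is amplitude-modulated Gaussian
noise with per-channel gains drawn once per recording: a grasp burst spans
the grasp-to-release interval with amplitude proportional to a grasp-force
proxy (effort level × object size / 0.1 m; healthy effort 0.33 reproduces
the roughly one-third-of-maximum activation expected for the largest block,
AF2 effort 0.95 approaches the maximum), and a 2 s maximal-effort segment at
envelope 1 provides the normalization constant. Sensor corruption (white
noise, default gyro sd 0.005 rad/s, plus optional constant bias) is applied
separately and never touches the ground truth.

All randomness is seeded: a recording is a pure function of (task
descriptor, impairment profile, seed).

## Validation scale and known limitations

The bundled acceptance checks run at desk scale, chosen to exercise the
claims without excess: a 30 s round trip for kinematics (RMS error well
under 0.5°), 100 seeded healthy tasks for segmentation recovery (≥95%
within 3% of path length), 30 recordings per group for the H/AF3/AF2
separation of transfer-phase $T_m$, $\eta_{rot}$, $\chi$ and $\rho$
(one-sided Mann–Whitney), and 30 seeds × 4 block sizes for EMG
monotonicity.

Known limitations: magnetometer hard/soft-iron calibration is out of scope
(fields are assumed clean); finger kinematics are not modelled, so
manipulation phases are delimited kinematically as inter-movement dwells
rather than from grasp events; the water-pouring task's non-unit angular
normalization is exposed only as the `theta_p` configuration hook;
executions that cannot complete a task (clinical scores 0–1) are outside
the segmentation model by design; and with the default sensor noise the
asymptotic stop at each stroke end is hidden below the ~0.5 mm position
noise floor for one to two tenths of a second, which bounds how precisely
onsets of *real* noisy recordings can be timed regardless of the detector.

## A worked example

```{r example, eval = FALSE}
rec <- generate_task(task_spec("grasp", object_size = 0.1),
                     impairment_profile("H"), seed = 7)
rec <- corrupt_sensors(rec, seed = 8)
dir <- tempfile()
write_recording(rec, dir)
res <- run_pipeline(read_recording(dir))
res$metrics
```

The metrics table has one row per movement phase plus a task row; without a
reference trajectory the similarity columns are `NA`. Build a reference from
healthy recordings with `build_reference()` and pass it via the `reference`
argument to fill them in.
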