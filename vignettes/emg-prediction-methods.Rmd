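---
title: "Predicting muscle activation envelopes from hand kinematics and grip force"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting muscle activation envelopes from hand kinematics and grip force}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgmlp)
```

## The problem

A functional electrical stimulation (FES) neuroprosthesis needs, for every
muscle it drives, a time-varying stimulation template. One way to obtain such
templates is to learn the mapping from intended limb motion to muscle
activity in able-bodied subjects: record surface EMG from the major arm
muscles during free movements, record the hand's trajectory and — when
objects are handled — the thumb's normal contact force, and regress the EMG
envelopes on the kinematic and force signals. `emgmlp` implements that whole
pathway: a synthetic recording-session generator with known ground truth,
the signal-conditioning chain, the time-delay multilayer perceptron (MLP)
regressor, and the two experiment designs that probe it (the loaded/unloaded
cross-training matrix and the network-capacity comparison).

Because no public recordings exist for this protocol, the package treats the
*synthetic generator as a first-class module*: every claim the test-suite
makes is a claim about the pipeline's behaviour on sessions whose true
muscle activations are known exactly.

## The model

The regressor is a fully connected feed-forward network. Its inputs at time
$t$ are the seven conditioned signals — normalized hand position $x, y, z$,
scaled orientations (pitch, roll, yaw), and grip force — at $t$, $t-1$ and
$t-2$ (a tapped delay line, giving $7 \times 3 = 21$ inputs; 18 when force
is excluded for unloaded-movement training). Hidden units apply
$\tanh$; the 12 output units (one per muscle) are linear:

$$\hat{y}(t) = W_L\,\tanh\!\big(W_{L-1}\cdots\tanh(W_1 u(t) + b_1)\cdots\big) + b_L.$$

Training is full-batch gradient descent with momentum on the mean squared
error,

$$v \leftarrow \mu v - \eta \nabla_\theta \mathrm{MSE}, \qquad
  \theta \leftarrow \theta + v,$$

run for a fixed number of epochs with no early stopping, validation split,
regularization or output post-processing — deliberately, because the
protocol it reimplements used exactly this bare training recipe, and the
overfitting of the large four-hidden-layer network on limited training data
is one of the findings to reproduce, not a defect to engineer away.
Weights and biases initialize from
$\mathrm{Uniform}(\pm 1/\sqrt{\mathrm{fan~in}})$. Inputs are affinely
mapped to $[-1, 1]$ using extremes of the training partition only; targets
are left on their MVC-normalized scale. Two architecture families matter:
single hidden layers of 1, 2, 5, 10 or 30 units (`MLP1` … `MLP30`) and the
four-hidden-layer `MLP20_9_9_20`.

The protocol's "100 iterations" is read as 100 full-batch epochs (the
original toolbox's momentum trainer is batch-mode). The learning rate and
momentum were never reported; the package defaults to $\eta = 0.01$,
$\mu = 0.9$ and exposes both. The experiment drivers in this package train
longer (120–150 epochs at $\eta = 0.3$ on scaled inputs) because a
from-scratch implementation at the defaults is visibly under-trained; this
choice affects absolute scores, not the qualitative contrasts the
experiments measure. If training diverges the fit aborts with an error
naming the epoch rather than returning silently clipped numbers.

Prediction quality is the **squared Pearson correlation** between predicted
and actual envelope, per muscle, over the full test record ("$R^2$ based on
the correlation"). Two consequences are documented and tested: the score is
invariant to affine rescaling (and sign) of the predictions, and it ignores
bias. The bias-sensitive $1 - SS_{res}/SS_{tot}$ definition is available via
`r_squared(..., method = "variance_explained")` and in
`evaluate_model(..., verbose = TRUE)`.

## Signal conditioning

All filters are Butterworth designs applied forward–backward (zero phase),
realized as second-order sections. The SOS realization is not cosmetic: a
6th-order low-pass at 2 Hz on 2500 Hz data has denominator roots so close
to $z = 1$ that the expanded transfer-function form is numerically
unstable. "Sixth order, zero phase" is implemented as a 6th-order design
per pass, so the zero-phase magnitude response is that order squared; halve
the design order if a net 6th-order magnitude is wanted.

* **EMG**: 0.1 Hz 6th-order high-pass (DC removal), full-wave
  rectification, 2 Hz 6th-order low-pass, linear resampling onto the
  120 Hz kinematic grid (safe because the envelope is band-limited far
  below the target Nyquist), then division by the per-muscle MVC reference
  amplitude. Negative filter ringing is clipped at zero. Envelopes may
  exceed 1 where a session burst exceeds the MVC reference.
* **Kinematics**: hand position re-expressed relative to the shoulder and
  divided by one scalar — the session's maximal absolute shoulder-relative
  displacement ("maximal displacement" being singular; per-axis scaling is
  available behind `per_axis = TRUE`). Orientations are unwrapped (so a
  sensor wrap at ±180° cannot ring through the filter) and divided by
  180°. All six channels then pass the 6 Hz 6th-order zero-phase low-pass.
* **Grip force**: whether force was filtered before use as an input was
  never stated; the package applies the same 6 Hz low-pass for
  consistency, then resamples to the kinematic grid.
* Whether MVC bursts were processed with the identical 2 Hz chain before
  taking the maximum is also unstated; the generator's MVC emulation
  assumes yes.

Zero-phase filtering needs initial conditions: each biquad initializes at
the steady state of its input's first sample ("constant history"), with
odd-reflection padding sized to about six time constants of the slowest
pole. Interior agreement with an independent reference implementation is at
the 1e-11 level; all edge behaviour is covered by the DC-gain, cutoff
attenuation and zero-lag tests rather than by comparison to any particular
library.

## What the synthetic generator emulates

A session mirrors the recording protocol: ~2-minute epochs alternate
between free movement and moving a brass object (100, 200, 500, 1000 g,
drawn without replacement per pass, two passes in a full-length loaded
session), 12 EMG channels at 2500 Hz, kinematics at 120 Hz, thumb force at
the raw rate.

* **Trajectory**: a band-limited Gaussian process (white noise low-pass
  filtered at `trajectory_bandwidth_hz`, default 0.5 Hz) rescaled into the
  workspace (±0.8 m per axis), as the simplest model of "random,
  unrestricted movements"; minimum-jerk segmenting was rejected as adding
  structure the analysis never uses. Orientations are generated continuous
  (no wrap events) by construction; a `wrap_stress` flag produces wrapping
  yaw traces for robustness testing. The generator trims filter burn-in so
  edge transients never enter a session.
* **Grip force**: within loaded epochs, proportional to load weight plus an
  inertial term proportional to the acceleration magnitude of the
  (twice centrally differenced) hand position, with half-second ramps at
  epoch boundaries, band-limited at 2.5 Hz — grasp force is neurally
  smooth, and the rectified acceleration magnitude would otherwise carry
  frequency-doubled content past the 2 Hz envelope band. The paper never
  reports force magnitudes or sensor calibration, so the gains
  (`grip_gain`, `inertial_gain`, both 1) are free parameters.
* **Teacher plant** (the ground truth): each muscle owns a small bank of
  $\tanh$ units (2 by default) reading the same current-plus-two-delays
  feature vector the predictor sees, so the mapping is *exactly
  representable* by a single-hidden-layer student with at least
  $12 \times 2 = 24$ units — which makes noiseless parameter recovery a
  sharp test. Distal muscles (biceps through FCR) receive strengthened
  force weights; shoulder-girdle muscles receive none, mirroring the
  physiological asymmetry that makes the loaded/unloaded contrast
  informative. A `force_dependent = FALSE` flag zeroes all force pathways
  (the ablation), and `mismatched_plant = TRUE` adds an unmodelled velocity
  dependence for realism studies. Output gains are calibrated per muscle
  against a reference session drawn from the generator itself, targeting a
  modulation SD of 0.18 within $[0, 1]$ — without this, an unlucky draw
  leaves a muscle nearly frozen and its score meaningless.
* **Activation noise** (SD 0.05) is band-limited to 3 Hz: motor-command
  variability is slow, and band-limited noise passes the envelope chain,
  creating a genuine, measurable noise ceiling. White noise would be
  silently removed by the 2 Hz smoothing and the ceiling would be a
  fiction.
* **EMG synthesis**: each channel is unit-variance Gaussian noise
  band-passed to the surface-EMG passband (100–475 Hz at 2500 Hz raw
  rate), amplitude-modulated by the activation, plus a small DC offset and
  additive sensor noise. The MVC reference is the envelope maximum of a
  synthesized 2 s full-activation burst pushed through the standard chain.
* **Noise ceiling**: two sessions sharing trajectory, schedule and plant
  but with independent noise realizations are processed and their
  envelopes correlated; for envelopes $e_i = m + d_i$ with independent
  noise $d_i$, $\mathrm{cor}(e_1, e_2) = \sigma_m^2/(\sigma_m^2 +
  \sigma_d^2)$, exactly the best squared correlation any predictor of the
  common signal can achieve.

What the generator does **not** emulate: finger-level grasp mechanics,
object geometry and slip, musculoskeletal moment arms, motor-unit-level EMG
statistics, electrode placement artifacts, or fatigue. Passing tests
therefore demonstrate that the pipeline recovers the structure this
generative family contains — not that real sessions would yield the
original study's absolute scores, which came from nine subjects'
non-deposited recordings.

## Scales and numerical choices

The full-length ("paper") profile — 25–32 minute sessions at 2500 Hz, a
1000 s training split — is available through
`default_experiment_config("paper")` and `session_config()` defaults. The
package's tests and experiment drivers run a reduced profile: 5–6 minute
sessions, raw rate 1000 Hz with the carrier band at 100–400 Hz (the
protocol band does not fit under a 500 Hz Nyquist, so the suggested
500 Hz reduced rate was raised to 1000 Hz instead of moving the band
further), 30 s epochs, a two-thirds/one-third temporal split. The
teacher-student recovery test additionally drops the kinematic rate to
60 Hz — its signals are band-limited far below 30 Hz, and halving the rows
buys optimization depth. Problem sizes: condition matrix 300 s × 5
replicate seeds; architecture grid 300 s × 5 seeds; recovery 240 s × 5
seeds at 3000 epochs.

Other numerical choices: the two embedding rows straddling the train/test
boundary belong to neither partition (no leakage through the delay
window); constant design columns are centered, not rescaled; scaler
statistics derive from the training partition only; replicate seeds stand
in for "subjects", and each replicate re-draws trajectory, noise and
initialization through named substreams of one base seed, so any stage can
be reproduced in isolation. Gradient correctness is verified against
central finite differences with the deviation measured relative to the
gradient's largest magnitude — at $h = 10^{-6}$ the cancellation noise in
the loss difference is ~$10^{-10}$, so entrywise relative error is
meaningless exactly where a gradient entry vanishes (e.g. early layers of
the deep net).

## A worked example

```{r example, eval = FALSE}
cfg <- reduced_profile(duration_s = 300, seed = 1)
session <- simulate_session(cfg)
dataset <- preprocess_session(session)
split <- split_train_test(session_design(dataset, include_force = TRUE),
                          train_duration_s = 200)
fit <- mlp_fit(split$train, hidden = 30, epochs = 120,
               learning_rate = 0.3, momentum = 0.9, seed = 2)
evaluate_model(fit, split$test)
```

The condition matrix and capacity grid are one call each
(`run_condition_matrix(cfg)`, `run_architecture_grid(cfg)`), and
`run_experiment(default_experiment_config("reduced"), "out/")` drives the
whole pipeline from a declarative config into a deterministic directory
tree.

## Known limitations

* Absolute $R^2$ levels depend on the generator's noise settings; only the
  contrasts (condition-matrix ordering, capacity ordering, ceiling
  proximity) are meaningful claims.
* The correlation-based score cannot see prediction bias; use the
  variance-explained option when bias matters.
* Full-batch momentum descent needs hundreds of epochs at these scales;
  the protocol's nominal 100 epochs under-trains a from-scratch
  implementation, which is faithful to the original recipe but worth
  knowing before comparing absolute numbers.
* Across-subject transfer is represented only by its synthetic analogue
  (`across_session_transfer()` between sessions of different teacher
  plants); no claim about human generalization follows from it.
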