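---
title: "Methods: EMG-driven hybrid rehabilitation simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EMG-driven hybrid rehabilitation simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emghybrid)
```

# Overview

`emghybrid` implements, as tested simulation code, the computational core of
an EMG-driven hybrid rehabilitation workflow for 2-DOF wrist pointing
(flexion–extension on X, radial–ulnar deviation on Y). The chain is:

1. **Preprocessing** — multichannel surface EMG → per-channel amplitude
   envelopes → calibrated, sum-to-one muscle-coordination feature vectors
   `x(t)` and an overall activation level `F(t)` that gates the system.
2. **Motion-intent estimation** — a recurrent log-linearized
   Gaussian-mixture network (R-LLGMN) turns short feature windows into
   class posteriors; the argmax at the window's final sample is the
   intended movement.
3. **Instruction** — a minimum-jerk reference trajectory from the current
   posture to the decided class's target, executed by the (simulated)
   assistance robot.
4. **Stimulation** — a calibrated sigmoid current–angle model, inverted to
   derive open-loop FES current commands for the direction's main active
   muscle.
5. **Evaluation** — six pointing indices plus reaching time quantify
   accuracy, stability and smoothness of recorded trials.
6. **Experiment pipeline** — simulated subjects progress through
   pre-evaluation, alternating training and sequential evaluation,
   post-evaluation and retention; group statistics use Bonferroni-adjusted
   Wilcoxon tests within groups and Mann–Whitney U between groups.

Every stage is driven by explicit seeds, and all data are produced by the
package's own generators, so the full workflow is reproducible without any
recorded human data.

# Signal processing

Raw EMG sampled at `fs = 1000` Hz passes a causal second-order Butterworth
bandpass (1–250 Hz), full-wave rectification, and a causal second-order
low-pass at 1 Hz giving the envelope `E_l(t)`. Filtering is single-pass
(not zero-phase) because the chain emulates an online system; the group
delay of the 1 Hz smoother (time constant ≈ 0.16 s) is therefore inherited
by all downstream features, and the first three time constants (≈ 0.48 s)
are treated as settle-in and excluded from calibration statistics.

Calibration uses a rest recording (baseline `E_l^st`, taken as the *mean*
rest envelope — the mean is preferred over a max/quantile for noise
robustness) and a voluntary-maximum recording (`E_l^max`, per-channel peak).
The normalized envelope is

$$E'_l(t) = \frac{E_l(t) - E^{st}_l}{E^{max}_l - E^{st}_l},$$

clipped below at zero: values under the rest baseline carry no contraction
information, and the downstream ratios assume non-negativity.

The coordination vector divides by the channel sum, `x_l = E'_l / \sum_l
E'_l`, so `x(t)` sums to one and is invariant to overall contraction
intensity; the activation level is the channel mean `F(t) = (1/L)\sum_l
E'_l`. Near rest the ratio is undefined, so channel sums below
`eps = 1e-6` return the uniform vector `1/L`, flagged sub-threshold — the
gate excludes such samples anyway. The gate opens when `F` stays at or
above `gate_threshold` (default 0.2) for `debounce_ms` (default 50 ms)
consecutively; both are configuration values since only the existence of a
threshold is prescribed by the workflow.

# The R-LLGMN classifier

The classifier embeds a `C`-class Gaussian-mixture hidden Markov model
(`K` states per class, `M` components per state) in a log-linear network.
Inputs are expanded onto the quadratic basis
`X = [1, x_1..x_L, x_i x_j (i ≤ j)]` of dimension `H = 1 + L(L+3)/2`
(15 for `L = 4`). Each network unit computes `a_{c,k',k,m}(t) =
\exp(w_{c,k',k,m}^\top X(t))`; on this basis the log of
(transition probability × mixture weight × Gaussian density) is exactly
linear, so the network family contains every Gaussian-mixture HMM — the
property `rllgmn_from_hmm()` exploits and the test suite verifies against
an independently written forward-algorithm oracle (agreement to 1e-6 and
better over 100 random sequences).

The recurrence sums each unit group over components, propagates the
previous normalized state `Q`, renormalizes across all `(c, k)` at every
step, and reads the class posterior as the within-class state sum. Because
the per-step normalization makes a common positive scaling of all unit
activations neutral, the implementation subtracts the per-sample logit
maximum before exponentiation; overflow is then impossible for finite
weights, which is essential at `H = 15` where quadratic logits grow fast.

**Training.** Full-batch gradient descent on the negative log posterior of
the true class at the window's final sample, with analytic gradients by
backpropagation through time, an Armijo backtracking line search (step
halving on rejection, doubling on acceptance), and a weight initialization
from a seeded zero-mean Gaussian (`sd = 0.01`). One reference unit's
weights are pinned at zero for identifiability. Defaults: `maxit = 2000`,
relative-loss tolerance `1e-8`, plus a loss floor (`mean NLL < 1e-4`) that
stops training once posteriors have saturated. An L-BFGS option is exposed
(`optimizer = "lbfgs"`) since the training schedule is not intrinsic to the
model. Training recordings are sliced into overlapping `seq_len = 50`
decision windows; the window stride is exposed and defaults to 10 samples,
which retains the sequences' redundancy at a fraction of the cost of
stride-1 slicing (on the synthetic task, stride 1 and stride 10 reach the
same held-out accuracy).

**Decisions.** `estimate_motion()` classifies the trailing 50-sample window
when the gate turns on, emits a single event, and re-arms only after the
gate has dropped — mirroring a system in which one intent decision triggers
one instruction. Ties at the argmax break toward the lowest class index
(documented and tested).

# Instruction trajectories

Instruction mode moves the wrist along the minimum-jerk quintic

$$P(\tau) = P_0 + (P_T - P_0)\,(6\tau^5 - 15\tau^4 + 10\tau^3), \qquad
\tau = t/T,$$

with `T = t_instruct = 2` s and 20-degree targets in the four directions
(flexion = +X, radial deviation = +Y; the sign convention is a package
choice, documented here, as only the four direction names are prescribed).
The profile has zero boundary velocity/acceleration, closed-form jerk cost
`360 A²/T⁵` per axis of amplitude `A`, and normalized mean velocity `8/15`.
Endpoints beyond the ±45-degree actuator range raise a validation error
rather than silently clipping. The simulated "realized" motion during
hybrid training equals the commanded trajectory plus Gaussian plant noise
(default SD 0.3 deg): the robot dominates the FES torque, so robot–FES
conflict dynamics are deliberately not modelled.

# FES current–angle model

Steady-state stimulation response follows the logistic model
`θ = d / (1 + exp(b(c − I)))` with `b` (1/mA) the rise rapidity, `c` (mA)
the half-maximum current and `d` (deg) the saturation angle; its exact
inverse `I = c − (1/b) log(d/θ − 1)` produces open-loop current commands.
Calibration fits the model to stepwise (current, angle) ladders by
Levenberg–Marquardt nonlinear least squares with data-driven starts
(`d₀ = 1.05·max angle`, `c₀` at the half-maximum current, `b₀` from the
local slope, `b` and `d` bounded positive). Angles are clipped into
`[εd, (1−ε)d]` with `ε = 1e-3` (with a warning) before inversion to keep
the logarithm finite. One parameter set is fitted per muscle; the
direction→muscle map is configuration data because electrode placement
cannot be computed. Muscle dynamics under stimulation are out of scope:
only the steady-state map is modelled, and units are taken as mA.

# Pointing metrics

Trials are decomposed into components parallel (`P_∥`) and perpendicular
(`P_⊥`, signed by the right-hand convention) to the start→target direction.
The indices are: endpoint error `e` (Euclidean miss distance), maximum
lateral deviation `max|P_⊥|`, endpoint spread `s` (mean distance of trial
endpoints to their mean endpoint — implemented exactly in that printed
form, not as a conventional SD), orbit correlation (mean pairwise Pearson
correlation of the `P_∥` series; the double sum over ordered pairs equals
the unordered mean because Pearson r is symmetric — an equality the tests
verify), jerk cost `½∫(d³P_∥/dt³)² dt`, and normalized mean velocity
`mean(v_∥)/max(v_∥)`. Reaching time runs from onset (parallel velocity
first exceeding 5% of its peak) to arrival (position staying within 2 deg
of the endpoint for 100 ms); all three thresholds are configuration values
since only the concept is prescribed.

Numerical choices: the third derivative uses the 7-point central stencil
(exact through degree six in the interior, so the quintic's cost is exact
up to boundary effects) with odd-reflection padding; integration is
trapezoidal; first derivatives are central with one-sided second-order
ends. Unequal-length trials are linearly time-resampled to the longest
trial before correlation. An optional low-pass pre-smoothing for noisy
measured data exists and is off by default so analytic trajectories are
untouched — without it, jerk cost on tremor-bearing simulated trials is
tremor-dominated (a 0.4-degree tremor at 9 Hz contributes of order
`(2π·9)⁶` to the squared third derivative), which is the intended reading
of jerk cost as a non-smoothness measure. `metric_report()` evaluates the
smoothness indices over the onset→arrival movement window by default
(`window = "full"` is available, and is what the closed-form checks use).

# Synthetic data

The EMG generator amplitude-modulates band-limited Gaussian noise
(20–450 Hz) — the standard surrogate for interference-pattern EMG — with a
modulation envelope `rest + amplitude · pattern_l · shape(t)` times slow
(5 Hz low-passed) multiplicative noise; the carrier is scaled so its mean
rectified level is one, making the preprocessing envelope an estimator of
the designed modulation. The default montage has four classes, each
dominated by one channel (pattern 0.6/0.2/0.1/0.1 rotated), emulating
four wrist muscles with partial co-activation. What it does *not* emulate:
motor-unit physiology, electrode crosstalk changes over time, hum, or
fatigue — so passing tests demonstrate correctness of the chain, not
robustness to every artefact of measured EMG.

The trial generator composes a minimum-jerk backbone toward
`target + bias + isotropic endpoint noise`, a half-sine lateral bow
(curvature), and sinusoidal tremor (default 9 Hz, faded by `sin(πτ)` so
endpoints stay interpretable). Each skill parameter maps to a metric —
bias/noise → `e` and `s`, curvature → lateral deviation, tremor → jerk
cost, duration → reaching time — and the tests verify each dial moves its
paired metric monotonically (Spearman rank correlation > 0.9). Motor
learning is modelled phenomenologically as per-session multiplicative
decay of the error-like parameters with the movement duration relaxing
toward a target duration; this produces monotone learning curves without
claiming a cognitive model.

# Experiment pipeline

The simulated study runs both arms through: 3 pre-evaluations → 20 ×
(training + sequential evaluation) → 3 post-evaluations → retention, with
one trial per direction per evaluation (the per-evaluation trial count is
exposed). Evaluation trials always come from the subject's own skill;
hybrid training trials are instruction + plant noise. The two arms differ
only in their learning-rate profiles: the hybrid arm's duration converges
to the 2 s instruction time (so its reaching times concentrate near the
instructed movement time after training — a designed property the tests
check), while the visual-feedback arm's early endpoint learning is faster
but its retention multiplier is worse (1.25 vs 1.0 on the error-like
parameters) — an emulation of feedback-dependence phenomenology, not a
perceptual model. Improvement ratios are normalized to pre-training,
`100(pre − post)/pre` for lower-is-better indices and `100(post − pre)/pre`
for orbit correlation and normalized mean velocity. Group comparisons use
`stats::wilcox.test` (asymptotic p-values throughout, so ties never switch
the method) and `stats::p.adjust(..., "bonferroni")`.

# Problem sizes and tolerances

The test and acceptance workloads use the study-scale signal settings
(1000 Hz, 4 channels, `C = 4`, `K = M = 2`, `T = 50`, 0.5 s training
recordings per movement = 500 samples each, 2000 in total) and desk-scale
replication counts chosen once: 5 simulated subjects × 100 held-out
windows for the identification benchmark (trained with `maxit = 150`,
which on this task reaches the same held-out accuracy as the full default
budget), 100 sequences for the HMM-oracle comparison (tolerance 1e-6),
500 replicate fits for FES noise robustness, 1000 trials for the
Rayleigh-mean check (5%), and 1–2 subjects × 2 sessions for pipeline
structure tests. Closed-form checks use 1% (jerk cost), 0.5% (normalized
mean velocity) and 1e-9 (endpoints, round trips) tolerances.

# Known limitations

- Open-loop FES only; no musculoskeletal dynamics, antagonist
  co-stimulation or robot–FES conflict model.
- The learning model is a monotone phenomenological decay; it cannot
  reproduce plateaus, fluctuation bursts, or feedback-schedule effects
  beyond what the retention multiplier encodes.
- Human-subject outcome values are not reproduction targets; the
  simulated cohort supports protocol-level and property-level validation
  only.
- The classifier is trained per subject and has no rejection option;
  posterior-entropy gating is out of scope.
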