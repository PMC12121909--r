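---
title: "A success-efficient/failure-safe model of whole-body motor adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A success-efficient/failure-safe model of whole-body motor adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecomotor)
```

## The task and the body

`ecomotor` simulates squat-to-stand movements under a velocity-proportional
backward pull and the hierarchical learning architecture that adapts to it.
The body is a two degree-of-freedom inverted pendulum: a point mass `m` (the
centre of mass, COM) on a massless prismatic leg of length `r` hinged at the
ankle with angle `theta` from vertical (+ forward). The COM sits at
`(x, y) = (r sin(theta), r cos(theta))`; one translational actuator produces
a force along the leg and one rotational actuator a torque at the ankle. The
perturbation is a horizontal backward force at the COM,

    F_pert = K * max(ydot, 0) * m,

with `K = 3 /s` and `m = 77 kg` by default, so a COM rising at 1 m/s draws a
231 N pull. The pull is clamped to upward COM motion: the experimental
apparatus it abstracts pulls only while the body rises, and a forward push
during descent has no physical counterpart.

Balance is summarized by the zero-moment point (ZMP) of the ground reaction.
Because the pull acts at the COM of a point-mass body it exerts no moment
about the COM, and moment balance at the foot gives

    x_zmp = x - y * (xdd - F_pert / m) / (ydd + g).

Resisting the pull therefore shifts the ZMP backward even when the COM does
not move — exactly the mechanism that forces an adapted movement to lean
against the pull. (The exported `zmp_point()` computes the classic
unperturbed form `x - y xdd/(ydd + g)`; the simulator's per-sample `zmp_x`
trace includes the pull term.)

A trial is a *failure* when the ZMP leaves the foot support interval for
longer than a grace time, the analogue of needing a corrective step; the
fall direction is the side of the deepest sustained excursion. Defaults:
support `[-0.10, +0.17]` m around the ankle (a heel lever of 10 cm and toe
lever of 17 cm, at the generous end of anatomical values because the
point-mass body has neither a hip strategy nor stepping), grace 80 ms. With
a 40 ms grace the model fails half of its post-adaptation trials on brief
borderline saturations that a standing human absorbs without stepping.

## The hierarchical learner

Four mechanisms run concurrently; each is a module with its own state.

**Motor plans** are COM-space via-point splines. The vertical profile is a
rest-to-rest minimum-jerk rise of 0.5 m (squat COM at 0.55 m, stand at
1.05 m) over 1.2 s. The horizontal profile is a clamped cubic spline through
three via points anchored at 25/50/75 % of movement time (about 10/50/90 %
of the rise); only the three horizontal offsets are learned, and the stand
position inherits the third offset, so an adapted plan ends in a held
forward lean. Anchoring the horizontal spline in *time* is essential: if
horizontal position is slaved to height, horizontal accelerations scale
with the squared vertical velocity and concentrate at the peak of the rise,
and no admissible plan keeps the ZMP inside the support — the feasible
strategy is to build the lean up early, while the body is low and the pull
still weak.

**Policy learning** maintains a diagonal Gaussian over the three offsets
(fixed exploration SD 0.005 m) updated by plain REINFORCE with an
exponential-moving-average reward baseline (factor 0.9). The step is
trust-region limited to the distance of the executed sample, so a large
advantage shifts the mean *to* the newly discovered plan, never past it.
The baseline restarts whenever the reward context changes (perturbation
onset, cost switching, de-adaptation), because safety and effort rewards
live on different scales.

**The internal model** provides feed-forward commands. Its base term is the
exact closed-form inverse dynamics of the unperturbed body; novel dynamics
are absorbed by an additive term, linear in the feature basis
`(1, r, theta, rdot, thetadot, ydot, ydot sin(theta), ydot r cos(theta))`
per actuator channel, adapted every millisecond by normalized LMS on the
command-space prediction error (rate 0.0035 per tick). The last two
features carry the shapes of the pull's generalized forces, so a
velocity-proportional horizontal force is exactly representable; without
them the representation error is irreducible, the prediction-error trace
plateaus, and the feedback gains never return to baseline. A running RMS of
the acceleration prediction error (forgetting factor 0.9998 per tick, a
time constant of roughly four trials) summarizes the model's current
accuracy.

**Feedback control** is a PD controller on the Cartesian COM tracking error
(kp = 3000 N/m, kd = 500 N s/m per axis, mapped to the actuators through
the configuration Jacobian transpose), scaled by a single multiplier
`g = min(3, 2 * trace)`. The gains are therefore inversely related to
internal-model accuracy: near zero during baseline, rising within the
first trials of the perturbation, and decaying towards zero as the internal
model converges — while failures, which spike the prediction error,
coincide with high multipliers.

**Ecological control** arbitrates the cost the policy optimizes. The reward
is `1[success] - w * cost`, with the active cost either *safety* — the
normalized backward ZMP margin `(front - min zmp)/support`, plus three
times the forward overshoot `(max zmp - front)+/support` so that
over-leaning past the toes is unsafe too, not rewarded — or *effort*, the
integral of squared normalized actuator commands. Effort is engaged once a
run-specific "confidence" count of successes is reached, drawn once per
run from Normal(50, 50) truncated below at 1. On failure the controller
reverts to safe mode (confidence progress retained), restores the policy
mean to a memorized safe plan, and biases sampling forward by a graded
via-point shift (3/7.5/9 mm per unit bias) that decays over the next
three successes. Two asymmetries matter:

* the bias is applied after *backward* falls only — after a forward fall
  more lean is not safer;
* successful trials discount the bias from the REINFORCE update (a success
  achieved under bias is credited to the bias, not the policy), while
  failed trials let the policy absorb the biased exploration. This
  realizes plan learning that happens during failures and leaves
  consecutive successes drifting gently back towards efficiency, and it is
  what produces the S-F-S increase / S-S decrease signature of the
  trajectory areas.

The safe-plan memory only adopts a new successful plan when it was at
least as safe as the remembered one, so the restore anchor cannot drift
onto marginal plans.

## The experimental paradigm

`run_experiment()` executes, per simulated participant: 15 unperturbed
baseline trials (effort-driven; the last successful plan becomes the
"unperturbed" memory), a perturbed block until 60 successes (budget 300
trials; exhausting it marks the run incomplete), one unannounced catch
trial (the pull silently absent), five more perturbed trials, and 15
announced de-adaptation trials. The announcement is modelled by three
resets: the plan returns to the unperturbed memory, the internal-model
weights shift towards zero by `rho = 0.1`, and the feedback-gain state
(the prediction-error trace) returns to its unperturbed near-zero level —
the announcement restores trust in the feed-forward pathway. The third
reset is what lets the residual internal model express itself: without it
the catch-trial surprise leaves the gains high and the first de-adaptation
trial never fails, contradicting the aftereffect the paradigm is designed
to expose. `rho` is deliberately small; it is calibrated so that the first
de-adaptation trial typically fails while the block still washes out to
baseline within its 15 trials.

Trials are compared across participants on a normalized index,
`(trial / N) * 84` rounded to integer bins, and `run_population()` runs
independent seeded participants and aggregates per-bin series. All
randomness in a run flows from its single integer seed; identical seeds
give bit-identical results.

## Measures

* **Trajectory Area (TA)**: signed `int x dy` of the normalized trajectory
  (translated to the origin, isotropically scaled to a 0.5 m rise) over the
  rising portion, in cm²; positive = forward = against the pull. The
  quadrature runs over a monotone-height resampling up to the first
  attainment of peak height, which the path-integral definition permits
  and which keeps failed (non-monotone) trials well-defined.
* **Initial Trajectory Area (ITA)**: the same integral up to 2.5 cm of
  rise (5 %), a proxy for the feed-forward plan before feedback can act.
* **Smoothness**: dimensionless squared jerk
  `(int ||jerk||^2 dt) D^3 / v_mean^2`, jerk by Savitzky-Golay smoothed
  triple differentiation (window 11 samples, polynomial order 5; the
  window keeps the metric stable on sampled data while leaving
  polynomial profiles exact). For a 1-D minimum-jerk profile the analytic
  value is 720, independent of amplitude and duration. Lower is smoother;
  the value is stored raw and may be negated for plotting.
* **Co-contraction**: each EMG channel is band-pass filtered with a
  zero-lag 4th-order Butterworth at 20-500 Hz (at the 1000 Hz sampling
  rate the upper edge coincides with Nyquist, so the filter reduces to a
  20 Hz high-pass), full-wave rectified, enveloped by a moving 50 ms RMS
  window, and integrated; the index is the ratio of the two integrals.
* **Peak displacements**: extrema of the normalized horizontal excursion.

The analysis layer fits `a exp(-x/b) + c` learning curves by multi-start
nonlinear least squares (`minpack.lm`), flagging negative time constants
and straight-line degenerations (`|b|` beyond five times the trial span);
the 95 % plateau is `b log(20)`, read as 95 % of the asymptotic change —
the only reading finite for both signs of `a`. Outcome-conditioned
contrasts sum metric changes between consecutive successes (S-S) and
successes bracketing failures (S-F-S) per run, excluding forward-direction
failures from pair construction, and compare the sums across runs with a
paired t-test. `relative_reduction()` implements
`RD = 1 - (A_D1 - A_B)/(A_C - A_B)`, and `run_reference_correlations()`
builds the all-pairs Pearson table between simulated and reference
trial series on the common 84-bin grid.

## Synthetic fixtures

`make_trial_series()` generates human-like trial series so the metric and
analysis layers are testable without the simulator: parabolic COM bows
whose amplitude follows an exponential trend plus noise, sporadic failures
with backward excursions, and antagonist EMG bursts (Gaussian-windowed
multi-tone carriers) whose co-contraction is elevated on and after
failures. The fixtures emulate the *statistical structure* of real
recordings — trends, outcome sequences, envelope ratios — not their
biomechanical detail: passing tests on fixtures validates the analysis
arithmetic, not the physiological realism of any conclusion drawn from
real data.

## Reference optima

`solve_optimal_trajectory()` reproduces the safety-versus-efficiency
contrast on the point-mass body. The COM path is parameterized by the same
via-point family plus the movement duration (1.05-1.45 s, around the
experimental movement time), and the exact tracking commands follow in
closed form from the inverse dynamics, so the program reduces to a smooth
4-parameter search solved by `nlminb` from a deterministic start lattice.
The safety objective maximizes the worst-case forward ZMP margin within
the support; the efficiency objective minimizes the squared net force
through the COM (normalized by body weight) *unconstrained* by the
support — the point mass has no separate torque channel, and the balance
infeasibility of the fast, straight energy minimum under the pull is
precisely the point of the contrast. The safe optimum is slower and
arched forward (larger TA and ITA); the efficient optimum is faster and
straight, and its higher vertical velocity draws a larger peak pull.

## Numerical choices and degenerate inputs

* Fixed-step RK4 at 1 ms with zero-order-hold commands; deterministic and
  accurate to well under 0.1 mm against a fine-step integrator over a
  trial. Unit tests run parts of the battery at 2 ms.
* Simulation aborts (and the trial truncates, counting as a fall) if the
  state leaves a generous validity box or becomes non-finite.
* Policy draws are clipped to the via-point bounds `[-0.05, 0.35]` m.
* `normalize_trajectory()` refuses trajectories without a vertical rise;
  `co_contraction()` refuses a degenerate denominator channel;
  `paired_t()` refuses zero-variance differences; constant series yield
  `NA` correlations rather than errors.
* The learning-curve fitter falls back to a linearity check when exactly
  collinear data defeats every nonlinear start.

## Problem sizes

The shipped defaults are the study conditions: 60-participant populations,
~85-130 perturbed trials per run at 1 ms control resolution. A full
population simulates in under a minute on one core; the test suite and the
acceptance script both regenerate everything from scratch.

## What a run looks like

```{r example, eval = FALSE}
run <- run_experiment(seed = 1)
run
#> <run_result> seed 1 - 120 trials, 25 failures, first success at
#>   perturbed trial 19
#>   completed: TRUE  confidence threshold: 19

pop <- run_population(60, base_seed = 100)
pop
#> <population_result> 60 runs, 60 completed
#>   failures: 25.32 +/- 27.83
#>   first success: 15.22 +/- 6.38 trials
outcome_contrasts(pop, "trajectory_area")$mean_delta_SFS  # > 0
```

## Known limitations

* No muscle model, no impedance/co-contraction control in the simulator:
  co-contraction is computed only for EMG-bearing (synthetic or recorded)
  data, and feedback is a scalar-scaled PD law.
* The point-mass pendulum cannot step or use a hip strategy; the fall
  criterion compensates with a wide support interval and an 80 ms grace,
  and absolute area magnitudes (hundreds of cm² when adapted) are larger
  than human values, so only signs, orderings and time courses are
  comparable across the two.
* The exploration noise is diagonal Gaussian in via-point space; rare
  zig-zag samples are physically jerky plans, which bounds the usable
  exploration SD.
* One run in roughly sixty draws a very low confidence threshold, switches
  to effort optimization almost immediately, and accumulates an outlier
  failure count before completing — the model's version of a pathological
  participant.
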