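---
title: "Optimal-control analysis of motor preparation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal-control analysis of motor preparation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Before a delayed reach, motor cortex shows vigorous preparatory activity that
produces no movement. `motorprep` asks when such preparation is *rational*:
if external inputs to a recurrent network of motor-cortical units are chosen
to perform a reach at minimum cost, do those inputs arise before the go cue,
and what properties of the network make early inputs worthwhile?

The package treats the question as a deterministic optimal-control problem.
The plant has two halves:

* a rate network, `tau dx/dt = -x + W phi(x) + h + u(t)`, with rates
  `r = phi(x)` (rectified linear by default) and `N = 200` units split
  80/20 into excitatory and inhibitory populations;
* an effector: either a planar two-link arm driven by torques read out
  linearly from the rates, or — for the two-unit motif analyses — a 1D
  point "hand" whose acceleration equals a one-dimensional readout of the
  network.

A trial runs from `t = -Delta_prep` (target onset) to `t = T` (end of the
movement window), with the go cue at `t = 0`. Inputs `u(t)` are free over
the whole window. The cost has three parts: an urgency-weighted target error
`sum ||theta - theta*||^2 (t/T)^2 dt/T` over the movement epoch, a stillness
penalty `alpha_null sum (||theta - theta0||^2 + ||thetadot||^2 + ||m||^2)
dt/T` over the delay, and an effort term
`alpha_effort sum ||u||^2 dt/(N T)` over the whole window. The *preparation
index* — delay-epoch input energy over movement-epoch input energy —
measures how much the optimal strategy relies on the delay.

## The arm

The arm follows the standard planar two-link rigid-body model:
`m = M(theta) thetaddot + X(theta, thetadot) + B thetadot`, with the inertia
matrix built from `a1 = I1 + I2 + M2 L1^2`, `a2 = M2 L1 D2`, `a3 = I2`,
Coriolis/centripetal vector `X`, and symmetric joint friction `B`. Defaults
(`L1 = L2 = 0.30` m, `M1 = 1.4`, `M2 = 1.0` kg, `I1 = 0.025`,
`I2 = 0.045` kg m^2, `D2 = 0.16` m, `B = [[0.05, 0.025], [0.025, 0.05]]`)
give a human-forearm-scale limb. There is no gravity term (planar model) and
no joint limits. The start posture places the hand at `(0, 0.30)` m in
shoulder coordinates through the elbow-down inverse-kinematics branch, and
targets sit on a circle of radius 12 or 20 cm around it; both choices are
arguments, since neither is intrinsic to the model.

Target error is measured in *joint* space: Cartesian targets are converted
to joint angles once, by inverse kinematics on the same elbow branch as the
start posture.

## Networks

`generate_isn()` builds the main plant: sparse log-normal excitatory weights
(connection probability 0.2), dense nonpositive inhibitory columns, and a
stabilization loop that performs projected gradient descent on the squared
H2 norm of the shifted system `W - s I` restricted to the inhibitory
entries (gradient `2 Q P` from the shifted system's Gramians), with a
backtracking line search, until the spectral abscissa of `W` drops below
0.8 — so the continuous-time dynamics `(-I + W)/tau` are stable with margin.
The shift `s` tracks the abscissa closely (margin
`max(0.05, 0.02 |a|)`); a tight shift makes the rightmost modes dominate the
objective, which is what lets the loop actually move them. The default
excitatory scale (5) makes the unstabilized network strongly connected
(initial abscissa around 5); after stabilization the networks are strongly
nonnormal, with pulse responses transiently amplified an order of magnitude
before decaying.

Baseline activity is a fixed point by construction: target rates `r*` are
drawn with mean 5 Hz and s.d. 5 Hz across neurons (Gaussian, rectified at
zero, with moment-restoring passes), and `h = (I - W) r*` makes `x = r*`
an exact equilibrium under the rectified-linear nonlinearity.

The torque readout `C` has i.i.d. Gaussian entries with s.d.
`0.05/sqrt(N)`. This calibration decodes rate fluctuations of ~30 Hz into
torques of ~1.5 N m, the scale the reaches require; an `N^-1` scaling is
available for comparison but produces torques too weak by an order of
magnitude. Torques are read out as deviations from baseline,
`m = C (phi(x) - r*)`. This choice matters: with a raw readout `C r`, the
baseline rates would exert a constant torque, the resting arm would not be
an equilibrium, and merely holding still would consume input energy that
grows linearly with the delay duration — inconsistent with a preparation
index that saturates at long delays. The deviation readout can be thought of
as downstream (spinal) compensation of tonic drive.

Motif networks (`generate_2d()`) isolate the two dynamical phenomena of
E/I circuits: a feedforward ("nonnormal") motif in which a source unit
drives a sink unit, and an antisymmetric oscillatory motif; both are run
with linear dynamics and a one-dimensional readout at a configurable angle,
leaving a one-dimensional output nullspace. Random, skew-symmetric, and
diagonally shifted skew-symmetric ensembles (`generate_ensemble()`) provide
out-of-family tests for the Gramian predictor; entries are scaled `R/sqrt(N)`
so the circular-law radius equals the nominal `R`.

## The solver

`ilqr_solve()` is an iterative linear-quadratic regulator: linearize the
dynamics and quadratize the cost around the current trajectory, solve the
local LQ problem by a backward dynamic-programming pass, and update with a
backtracking line search on the feedback-controlled rollout. Numerical
choices that matter:

* *Regularization.* The backward pass adds `mu` to the value Hessian
  (entering the control Hessian through `fu' (Vxx + mu I) fu`), raised
  multiplicatively (default 2x, bounds `1e-9`–`1e9`) on an indefinite
  control Hessian or a failed line search, lowered (1.6x) after good steps.
  For linear-quadratic problems `mu` starts at zero, so a single sweep
  returns the exact Riccati optimum.
* *Trust-region coupling.* On the rectified-linear plant the quadratic
  model is only locally valid — active-set flips make full steps overshoot.
  If a step is only accepted after heavy backtracking (`alpha < 0.05`) the
  regularizer is raised even though the iteration "succeeded"; near-full
  steps (`alpha >= 0.3`) relax it. Without this rule the solver accepts
  thousands of microscopic steps; with it, accepted steps are mostly
  near-full.
* *Convergence.* Stop when the relative cost decrease falls below `tol`, or
  when (with the regularizer at rest) the backward pass predicts no
  attainable improvement. `u = 0` is the standard initial guess; on the
  rectified plant the cost decreases monotonically over accepted iterations
  by construction of the line search.
* *Warm starts across delays.* A solution of the no-delay problem, padded
  with leading zeros, is a feasible solution of any delayed problem at
  identical cost. The experiment drivers therefore solve delays in
  increasing order and warm-start each solve from the previous one. This
  turns a soft expectation into a structural guarantee: granting a delay
  can only lower the optimized cost, and whatever input the optimizer then
  places into the delay period is a genuine improvement over not preparing
  — important on the rectified plant, where cold starts can settle into
  local optima whose delayed cost exceeds the no-delay cost.
* *Discretization.* Explicit Euler at `dt = 10` ms (`tau/15`) uniformly,
  for the network (unit-free `dt/tau`) and the effector (SI seconds). All
  cost integrals are left-endpoint Riemann sums.

One discretization detail deserves emphasis. If the stillness penalty is
summed over the *open* window `[-Delta_prep, 0)`, the input applied during
the final delay step — whose effect lands exactly at the go cue — is never
penalized for moving the hand. At a coarse `dt`, the optimizer exploits
this loophole and dumps output-potent input into that single step, which
inflates the preparation index for *every* readout (including readouts that
cannot benefit from genuine preparation at all). The package therefore
evaluates the stillness penalty on the *closed* window, including the state
at the go cue. With this convention output-null preparation remains free,
output-potent "preparation" is charged, and the preparation index becomes
insensitive to `dt`; in particular the feedforward motif read out at its
source — for which the only still direction seeds no output — shows exactly
zero preparation, as it should.

## Gramian summaries

For the linearization `A = (-I + W)/tau` (observability and controllability
are linear-system notions, so the rectification is dropped here) the package
solves the continuous Lyapunov equations `A'Q + QA + C'C = 0` and
`AP + PA' + I = 0` by diagonalizing `A` (with a dense vectorized fallback
for defective matrices such as the nilpotent feedforward motif, and a
residual check in all cases). Two scalars summarize the plant:

* `alpha = tr(Cperp Q Cperp') / (N - k)` — observability of the readout
  nullspace: how much future output is seeded by unit-norm output-null
  states. Basis-independent and invariant to orthogonal state changes.
* `beta = tr(C P C') / k` — controllability of the readout: how much
  variance isotropically driven trajectories express along the readout.

The hypothesis encoded in `fit_prep_predictor()` is that preparation pays
when the nullspace is observable (`alpha` large) but the readout is hard to
drive directly (`beta` small): an ordinary least-squares fit of the
preparation index on z-scored `alpha` and `beta`, with k-fold (default 5)
cross-validated R^2 and single-predictor ablations. No particular functional
form is claimed beyond the signs.

## Subspace analysis

Preparatory- and movement-epoch activity (a 300 ms window before the delay
end; a 300 ms window starting 50 ms after the go cue) is soft-normalized per
neuron (`r / (range + 5)`) and mean-centered across reach conditions at each
time point. `identify_subspaces()` maximizes the mean normalized captured
variance `0.5 (tr(W1' C1 W1)/Z1 + tr(W2' C2 W2)/Z2)` over jointly
orthonormal bases (`W1' W2 = 0`), where `Z_d` is the best unconstrained
d-dimensional capture (top-d eigenvalue sum). The optimizer is Riemannian
gradient ascent on the combined Stiefel frame with polar retraction and
backtracking, started from a deflation-based spectral initialization plus
random restarts (default 10); the objective is monotone and bounded by 1.
Subspace dimensions default to 6 + 6. Mean-centering inside the covariance
is per-epoch across samples; the per-time across-condition centering of the
normalization step is applied first (both conventions are exposed).

`occupancy()` projects activity onto a basis and sums across-condition
variance per time bin — the signature used to detect renewed preparation
inside movement sequences, where inputs themselves are ambiguous (a late
input could serve the ongoing movement or the next one). Movement onset for
alignment is the first hand-speed crossing of a threshold (default 5% of
peak speed); the optional 120 ms lag exists only to compare against recorded
behavior, which incurs conduction delays absent from the model.

## Sequences

Two-reach sequences modify the cost: target 1 is urged on
`[0, move1 + pause]` with the `(t/T)^2` clock, joint speed is penalized
(`alpha_pause = 100`) during the pause, and target 2 is urged on the
remainder with a clock restarted at the pause end. "Double" reaches use a
600 ms pause; "compound" reaches use a 6 ms token pause that only makes the
hand stop on the intermediate target rather than fly through. All terms keep
the single-reach normalizers so that weights are comparable across tasks
(the sequence defaults are `alpha_null = 10`, `alpha_effort = 5e-7`).
Note that because the second urgency clock restarts, a sequence whose two
targets coincide is *close to* but not identical with a single reach — the
exact-equality reading of that degenerate case is inconsistent with the
piecewise cost.

## What the generator does and does not emulate

The synthetic networks reproduce the structural facts the analyses rest on:
Dale's law, 80/20 E/I split, sparse log-normal excitation, optimized
inhibition, spectral abscissa below 0.8, strong nonnormal amplification,
baseline rates 5 +/- 5 Hz, and a readout calibrated to arm-scale torques.
They do not emulate spiking variability, conduction delays, sensory
feedback, muscle dynamics, trial-to-trial noise, or any learning of `W` or
`C` — the connectivity is explicitly *not* optimized for the task. Passing
tests therefore speak to the optimal-control theory of these rate models,
not to fits of recorded data.

## Problem sizes and reproducibility

Every generator takes an integer seed and is bitwise reproducible; the
solver is deterministic given the problem and options. The experiment
drivers default to sizes chosen for a single CPU core: the headline
delayed-reach analyses use the full `N = 200` plant with 8 targets; the
Gramian sweep runs a deliberately reduced ensemble (tens of networks of
`N = 40`, a target subset per network) that preserves the sign structure and
ordering of the full analysis rather than its exact R^2; sequence analyses
use a handful of target pairs. Solver budgets (`max_iter`, `tol`) are
arguments everywhere and are reported alongside results.

## Known limitations

* On the rectified-linear plant the optimization landscape has long, flat
  valleys; the cost keeps creeping downward for hundreds of iterations, and
  the preparation index creeps upward with it. Reported indices at finite
  iteration budgets are therefore conservative lower bounds on the fully
  converged preparatory share. The same network solved as a linear plant
  (identity nonlinearity) converges quickly and prepares substantially more.
* The preparation index magnitudes of the two-unit motif analyses depend on
  discretization conventions near the go cue (see above); the package's
  artifact-free convention yields somewhat lower sink/oscillatory values
  than naive coarse-grid evaluation.
* Gramian metrics require a stable linearization; networks whose `W` has
  abscissa at or above 1 are skipped by the sweep drivers, with a record of
  the skip.
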