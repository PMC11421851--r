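# motorprep

Optimal-control analysis of motor preparation in recurrent network models
of motor cortex.

## The problem

Neural activity in primate motor cortex starts changing hundreds of
milliseconds before a delayed reach begins, even though this preparatory
activity produces no movement. `motorprep` asks when such preparation makes
sense *normatively*: if the external inputs `u(t)` to a recurrent rate
network are chosen to perform a reach at minimum cost, do they arise before
the go cue — and which properties of the network make early, output-null
inputs worthwhile?

The plant couples a rate network to an effector. Network:

    tau dx/dt = -x + W phi(x) + h + u(t),    r = phi(x)

with `N = 200` units (80% excitatory, 20% inhibitory; inhibition optimized
until the spectral abscissa of `W` falls below 0.8), rectified-linear
`phi`, baseline rates of 5 +/- 5 Hz. Effector: a planar two-link arm,
`m = M(theta) thetaddot + X(theta, thetadot) + B thetadot`, driven by
torques read out linearly from the rates — or, for two-unit motif analyses,
a 1D hand with acceleration equal to a 1D readout. The control objective
over a trial running from `-Delta_prep` (target onset) to `T` (end of the
movement window, go cue at 0) is

    J[u] = sum_{t>=0} ||theta - theta*||^2 (t/T)^2 dt/T        (urgency)
         + a_null sum_{t<=0} (||theta - theta0||^2 + ||thetadot||^2
                              + ||m||^2) dt/T                  (stillness)
         + a_eff  sum ||u||^2 dt/(N T)                         (effort)

minimized with an iterative linear-quadratic regulator (iLQR). The
*preparation index* — delay-epoch over movement-epoch squared input norm —
quantifies reliance on the delay. Gramian summaries relate it to network
structure: `alpha`, the observability of the readout nullspace
(`tr(Cperp Q Cperp')/(N-k)`), and `beta`, the controllability of the
readout (`tr(C P C')/k`), with `Q`, `P` solving the Lyapunov equations of
the linearized dynamics `A = (-I + W)/tau`. Orthogonal preparatory and
movement subspaces of the population activity, and their occupancy time
courses, extend the analysis to two-reach sequences.

## A worked example

Two-unit feedforward ("nonnormal") motif, where a source unit drives a sink
unit, solved on the 1D reach task with the readout on either unit:

```r
library(motorprep)

tk <- toy_task(delta_prep = 500, T_move = 900, y_star = 20)
sink <- solve_reach(generate_2d("feedforward", w = 4, readout_angle = pi/2), tk)
src  <- solve_reach(generate_2d("feedforward", w = 4, readout_angle = 0),    tk)

round(c(prep_sink = sink$prep_index, prep_source = src$prep_index,
        cost_ratio = src$breakdown$J_total / sink$breakdown$J_total), 3)
#>   prep_sink prep_source  cost_ratio
#>       0.313       0.000       1.504
```

Reading the sink lets the controller seed the source mode during the delay
for free (it is output-null) and harvest the network's own transient
amplification after the go cue: preparation is substantial, and the whole
movement is about 1.5-fold cheaper than with the source readout, for which
the only output-null direction seeds nothing and the optimal preparation is
exactly zero.

The full pipeline on the high-dimensional plant:

```r
plant <- prepare_plant(generate_isn(N = 200, seed = 1), seed = 1)
tg    <- reach_target_set(8, r = 0.20)
sweep <- run_delay_sweep(plant, delays = c(0, 300), targets = tg,
                         options = ilqr_options(max_iter = 25, mu_up = 10),
                         keep_solutions = TRUE)
sweep$summary[, c("delay", "J_total_norm", "prep_index")]
```

shows the total cost dropping once a delay period is granted, with nonzero
input energy moved into the delay. `stack_rates()`, `normalize_rates()`,
`identify_subspaces()` and `occupancy()` then decompose the population
activity into orthogonal preparatory/movement subspaces and their
occupancies; `gramian_summary()` and `fit_prep_predictor()` relate
preparation to the `alpha`/`beta` structure of each network.

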