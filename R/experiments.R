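#' Attach a readout and baseline to a network
#'
#' Convenience used by the experiment drivers: draws the random torque
#' readout and sets the baseline firing rates (for rectified-linear
#' models), leaving linear models at zero baseline.
#'
#' @param model A `network_model`.
#' @param seed Seed for readout and baseline draws.
#' @param n_outputs Readout rows (2 for the arm).
#' @param mean_rate,sd_rate Baseline rate statistics (Hz).
#' @return The prepared model.
#' @export
prepare_plant <- function(model, seed = 1, n_outputs = 2,
                          mean_rate = 5, sd_rate = 5) {
  model$C <- generate_readout(model$N, n_outputs, seed = seed)
  if (model$nonlinearity == "relu")
    model <- set_baseline(model, mean_rate, sd_rate, seed = seed + 1)
  model
}

#' Delay sweep: optimal reaches across preparation durations
#'
#' Solves the delayed-reach problem for every target and every delay
#' duration on the grid, and tabulates the cost breakdown (optionally
#' normalized by the total cost at the shortest delay) and the
#' preparation index.
#'
#' @param model A prepared `network_model` (readout + baseline).
#' @param delays Vector of delay durations (ms).
#' @param targets A [reach_target_set()]; all its targets are solved.
#' @param T_move Movement-epoch duration (ms).
#' @param alpha_null,alpha_effort Cost weights.
#' @param dt Time step (ms).
#' @param params Arm parameters.
#' @param options iLQR options.
#' @param keep_solutions Keep per-condition trajectories (needed for
#'   subspace analyses).
#' @param warm_start Solve delays in increasing order and initialize each
#'   solve from the previous delay's input trajectory padded with leading
#'   zeros. The padded trajectory is feasible at identical cost, so with
#'   warm starts the optimized cost is non-increasing in the delay by
#'   construction, and any delay-period input the optimizer adds is a
#'   genuine improvement. Default `TRUE`.
#' @return List with `table` (one row per delay x target), `summary` (per
#'   delay: mean costs, normalized costs, mean preparation index), and
#'   optionally `runs` (nested list of `solve_reach()` results).
#' @export
run_delay_sweep <- function(model, delays = seq(0, 800, by = 100),
                            targets = reach_target_set(8, r = 0.20),
                            T_move = 900, alpha_null = 1, alpha_effort = 5e-7,
                            dt = 10, params = arm_params(),
                            options = ilqr_options(), keep_solutions = FALSE,
                            warm_start = TRUE) {
  rows <- list()
  runs <- list()
  delays <- sort(delays)
  prev_us <- vector("list", nrow(targets$targets))
  for (d in seq_along(delays)) {
    for (g in seq_len(nrow(targets$targets))) {
      task <- reach_task(delta_prep = delays[d], T_move = T_move,
                         theta0 = targets$theta0,
                         theta_star = targets$targets[g, ],
                         alpha_null = alpha_null, alpha_effort = alpha_effort)
      u0 <- NULL
      if (warm_start && !is.null(prev_us[[g]])) {
        pad <- round((delays[d] + T_move) / dt) - nrow(prev_us[[g]])
        if (pad >= 0)
          u0 <- rbind(matrix(0, pad, ncol(prev_us[[g]])), prev_us[[g]])
      }
      res <- solve_reach(model, task, dt = dt, params = params,
                         options = options, u_init = u0)
      if (warm_start) prev_us[[g]] <- res$solution$us
      b <- res$breakdown
      rows[[length(rows) + 1]] <- data.frame(
        delay = delays[d], target = g,
        J_target = b$J_target, J_null = b$J_null, J_effort = b$J_effort,
        J_total = b$J_total,
        prep_index = if (delays[d] > 0) res$prep_index else 0,
        converged = res$solution$converged)
      if (keep_solutions)
        runs[[sprintf("d%g_t%d", delays[d], g)]] <- res
    }
  }
  tab <- do.call(rbind, rows)
  agg <- stats::aggregate(tab[c("J_target", "J_null", "J_effort", "J_total",
                                "prep_index")],
                          by = list(delay = tab$delay), FUN = mean)
  ref <- agg$J_total[which.min(agg$delay)]
  agg$J_total_norm <- agg$J_total / ref
  agg$J_target_norm <- agg$J_target / ref
  agg$J_effort_norm <- agg$J_effort / ref
  agg$J_null_norm <- agg$J_null / ref
  out <- list(table = tab, summary = agg)
  if (keep_solutions) out$runs <- runs
  out
}

#' Two-unit motif analysis
#'
#' Solves the 1D toy reach for each connectivity scale and readout angle
#' of a given motif, reporting preparation index, total cost, and total
#' preparatory input energy.
#'
#' @param kind `"feedforward"` or `"oscillatory"`.
#' @param w_grid Connectivity scales.
#' @param readout_angles Readout angles (rad); 0 = source/first unit,
#'   `pi/2` = sink/second unit.
#' @param task A [toy_task()].
#' @param dt Time step (ms).
#' @param tau Network time constant (ms).
#' @return Data frame, one row per (w, angle).
#' @export
run_2d_analysis <- function(kind = "feedforward",
                            w_grid = c(0, 1, 2, 4, 6),
                            readout_angles = c(0, pi / 2),
                            task = toy_task(), dt = 1, tau = 150) {
  rows <- list()
  for (w in w_grid) {
    for (ang in readout_angles) {
      model <- generate_2d(kind, w = w, tau = tau, readout_angle = ang)
      res <- solve_reach(model, task, dt = dt)
      tt <- res$trajectory$time
      prep_e <- sum(res$trajectory$u[tt < 0, ]^2) * res$trajectory$dt
      rows[[length(rows) + 1]] <- data.frame(
        kind = kind, w = w, angle = ang,
        prep_index = res$prep_index,
        J_total = res$breakdown$J_total,
        prep_input = prep_e,
        converged = res$solution$converged)
    }
  }
  do.call(rbind, rows)
}

#' Gramian sweep: predict preparation from alpha and beta
#'
#' For each supplied network, computes the Gramian summaries alpha and
#' beta at the linearization `(-I + W)/tau`, solves the delayed-reach
#' problem on a (possibly reduced) target set, and records the mean
#' preparation index. The linear predictor is fitted on the networks
#' whose family is in `fit_families` and evaluated in transfer on the
#' rest.
#'
#' @param networks List of prepared `network_model`s (readout set; baseline
#'   where applicable).
#' @param targets A [reach_target_set()].
#' @param target_subset Indices of targets to solve (reduced sets keep the
#'   sweep fast; the preparation index is averaged over them).
#' @param delta_prep,T_move Task window (ms).
#' @param alpha_null,alpha_effort Cost weights.
#' @param dt Time step (ms).
#' @param options iLQR options.
#' @param fit_families Families used to fit the predictor (default
#'   `"isn"`).
#' @param folds Cross-validation folds.
#' @return List with `records` (one row per network: family, alpha, beta,
#'   prep_index), `fit` (a `prep_prediction`), and `transfer` (predicted
#'   values and R^2 on held-out families, or `NULL`).
#' @export
run_gramian_sweep <- function(networks, targets = reach_target_set(8, r = 0.20),
                              target_subset = NULL, delta_prep = 300,
                              T_move = 900, alpha_null = 1,
                              alpha_effort = 5e-7, dt = 10,
                              options = ilqr_options(),
                              fit_families = "isn", folds = 5) {
  if (is.null(target_subset)) target_subset <- seq_len(nrow(targets$targets))
  rows <- list()
  for (i in seq_along(networks)) {
    model <- networks[[i]]
    gs <- tryCatch(gramian_summary(model), error = function(e) NULL)
    if (is.null(gs)) next  # unstable linearization: skip with no record
    pis <- numeric(0)
    for (g in target_subset) {
      # warm-start the delayed solve from the zero-padded no-delay solution
      # (feasible at identical cost), so the delay-period input that emerges
      # is a genuine improvement rather than an optimizer artifact
      task0 <- reach_task(delta_prep = 0, T_move = T_move,
                          theta0 = targets$theta0,
                          theta_star = targets$targets[g, ],
                          alpha_null = alpha_null,
                          alpha_effort = alpha_effort)
      res0 <- solve_reach(model, task0, dt = dt, options = options)
      task <- reach_task(delta_prep = delta_prep, T_move = T_move,
                         theta0 = targets$theta0,
                         theta_star = targets$targets[g, ],
                         alpha_null = alpha_null,
                         alpha_effort = alpha_effort)
      pad <- round(delta_prep / dt)
      u0 <- rbind(matrix(0, pad, model$N), res0$solution$us)
      res <- solve_reach(model, task, dt = dt, options = options,
                         u_init = u0)
      pis <- c(pis, res$prep_index)
    }
    rows[[length(rows) + 1]] <- data.frame(
      id = i, family = model$family, alpha = gs$alpha, beta = gs$beta,
      prep_index = mean(pis))
  }
  records <- do.call(rbind, rows)
  in_fit <- records$family %in% fit_families
  fit <- fit_prep_predictor(records[in_fit, , drop = FALSE], folds = folds)
  transfer <- if (any(!in_fit))
    predict(fit, records[!in_fit, , drop = FALSE]) else NULL
  list(records = records, fit = fit, transfer = transfer)
}

#' Solve a batch of two-reach sequences
#'
#' @param model A prepared `network_model`.
#' @param targets A [reach_target_set()].
#' @param pairs Two-column matrix of target indices (first, second reach).
#' @param pause Pause duration (ms): 600 for double reaches, 6 for
#'   compound reaches.
#' @param delta_prep,move1 Delay and first-reach durations (ms).
#' @param T_total Total movement window (ms); default `move1 + pause +
#'   1100`.
#' @param alpha_null,alpha_effort,alpha_pause Cost weights.
#' @param dt Time step (ms).
#' @param params Arm parameters.
#' @param options iLQR options.
#' @return List of `solve_reach()` results, one per pair.
#' @export
run_sequences <- function(model, targets, pairs, pause = 600,
                          delta_prep = 500, move1 = 300, T_total = NULL,
                          alpha_null = 10, alpha_effort = 5e-7,
                          alpha_pause = 100, dt = 10,
                          params = arm_params(), options = ilqr_options()) {
  if (is.null(T_total)) T_total <- move1 + pause + 1100
  pairs <- matrix(pairs, ncol = 2)
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    task <- sequence_task(delta_prep = delta_prep, move1 = move1,
                          pause = pause, T_total = T_total,
                          theta0 = targets$theta0,
                          theta_star1 = targets$targets[pairs[i, 1], ],
                          theta_star2 = targets$targets[pairs[i, 2], ],
                          alpha_null = alpha_null,
                          alpha_effort = alpha_effort,
                          alpha_pause = alpha_pause)
    out[[i]] <- solve_reach(model, task, dt = dt, params = params,
                            options = options)
  }
  out
}

#' Stack solved trajectories into a rate array
#'
#' Builds the `N x M x T` firing-rate array (conditions = reaches) that
#' the subspace analyses consume, together with the common time vector.
#' All trajectories must share the same time grid.
#'
#' @param results List of `solve_reach()` results (arm task).
#' @return List with `rates` array and `time`.
#' @export
stack_rates <- function(results) {
  trajs <- lapply(results, `[[`, "trajectory")
  time <- trajs[[1]]$time
  stopifnot(all(vapply(trajs, function(tr) length(tr$time) == length(time),
                       logical(1))))
  N <- ncol(trajs[[1]]$r)
  arr <- array(0, c(N, length(trajs), length(time)))
  for (m in seq_along(trajs)) arr[, m, ] <- t(trajs[[m]]$r)
  list(rates = arr, time = time)
}

#' Behavioral summary of a solved reach
#'
#' Post-hoc checks mirroring how the cost weights were balanced: maximal
#' hand displacement during the delay, time to first acquire the target
#' (hand within `tol_m` of it), and hold time within tolerance after
#' acquisition.
#'
#' @param traj A `reach_trajectory` from the arm task.
#' @param hand_target Cartesian target (m).
#' @param tol_m Acquisition tolerance (m), default 0.005 (0.5 cm).
#' @return List with `delay_disp` (m), `acquire_time` (ms, NA if never),
#'   `hold_ms` (ms within tolerance after acquisition), `final_dist` (m).
#' @export
behavior_summary <- function(traj, hand_target, tol_m = 0.005) {
  del <- traj$time < 0
  hand0 <- traj$hand[which(del)[1], ]
  delay_disp <- if (any(del))
    max(sqrt(rowSums(sweep(traj$hand[del, , drop = FALSE], 2, hand0)^2)))
  else 0
  dist <- sqrt(rowSums(sweep(traj$hand, 2, hand_target)^2))
  mov <- traj$time >= 0
  acq <- which(mov & dist <= tol_m)
  acquire_time <- if (length(acq)) traj$time[acq[1]] else NA_real_
  hold_ms <- if (length(acq)) sum(dist[acq[1]:length(dist)] <= tol_m) * traj$dt
             else 0
  list(delay_disp = delay_disp, acquire_time = acquire_time,
       hold_ms = hold_ms, final_dist = dist[length(dist)])
}
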