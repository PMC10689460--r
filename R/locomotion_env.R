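# Point-navigation task: the robot starts at the origin of a flat square
# arena and must pass through an ordered sequence of target points. Fitness
# rewards targets reached in order plus progress toward the next unreached
# target, and penalizes path length.

#' Task specification for point navigation
#'
#' @param targets list of 2D target points, in the order they must be reached
#'   (default P1 = (1, -1), P2 = (0, -2))
#' @param radius reach radius in metres (default 0.01)
#' @param duration evaluation duration in seconds (default 40)
#' @param arena side length of the square arena in metres (default 10)
#' @param omega path-length penalty weight (default 0.1)
#' @param sample_hz trajectory sampling rate (default 5)
#' @return object of class `task_spec`
#' @export
task_spec <- function(targets = list(c(1, -1), c(0, -2)), radius = 0.01,
                      duration = 40, arena = 10, omega = 0.1, sample_hz = 5) {
  stopifnot(radius > 0, omega >= 0, duration > 0)
  structure(list(targets = targets, radius = radius, duration = duration,
                 arena = arena, omega = omega, sample_hz = sample_hz),
            class = "task_spec")
}

#' Construct a trajectory object
#' @param pos matrix with columns x, y: positions sampled at `sample_hz`
#' @param duration duration in seconds
#' @param sample_hz sampling rate (default 5)
#' @return object of class `trajectory`
#' @export
trajectory <- function(pos, duration, sample_hz = 5) {
  pos <- as.matrix(pos)
  colnames(pos) <- c("x", "y")
  structure(list(pos = pos, duration = duration, sample_hz = sample_hz,
                 t = seq(0, duration, length.out = nrow(pos))),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d samples over %g s, ends at (%.3f, %.3f)>\n",
              nrow(x$pos), x$duration, x$pos[nrow(x$pos), 1],
              x$pos[nrow(x$pos), 2]))
  invisible(x)
}

#' Export a trajectory as CSV (t, x, y)
#' @param tr a `trajectory`
#' @param path file path
#' @export
write_trajectory_csv <- function(tr, path) {
  utils::write.csv(data.frame(t = tr$t, x = tr$pos[, 1], y = tr$pos[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Path length of a trajectory
#' @param tr a `trajectory`
#' @return sum of consecutive Euclidean segment lengths, in metres
#' @export
path_length <- function(tr) {
  p <- tr$pos
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Count targets reached in order
#'
#' Target i only counts after target i - 1 has been reached; a target is
#' reached when a sampled position lies within the task's reach radius.
#' @param tr a `trajectory`
#' @param task a `task_spec`
#' @return list with `k` (number of targets reached) and `reach_times`
#'   (seconds, one per reached target)
#' @export
count_targets <- function(tr, task) {
  k <- 0L
  times <- numeric(0)
  nxt <- 1L
  nT <- length(task$targets)
  for (s in seq_len(nrow(tr$pos))) {
    if (nxt > nT) break
    tgt <- task$targets[[nxt]]
    if (sqrt(sum((tr$pos[s, ] - tgt)^2)) <= task$radius) {
      k <- nxt
      times <- c(times, tr$t[s])
      nxt <- nxt + 1L
    }
  }
  list(k = k, reach_times = times)
}

#' Point-navigation fitness
#'
#' With k of N ordered targets reached, final position P_T, path length L and
#' P_0 = (0, 0):
#' \deqn{F = \sum_{i=1}^{k} d(P_i, P_{i-1}) + [d(P_{k+1}, P_k) - d(P_T, P_{k+1})] - \omega L}
#' where the bracketed progress term toward the next unreached target is
#' dropped when all targets are reached. A robot that reaches both default
#' targets along the shortest path scores 1.8 * sqrt(2), about 2.54.
#'
#' @param tr a `trajectory`
#' @param task a `task_spec`
#' @return fitness value (real)
#' @export
fitness <- function(tr, task) {
  k <- count_targets(tr, task)$k
  pts <- c(list(c(0, 0)), task$targets)
  dist <- function(a, b) sqrt(sum((a - b)^2))
  total <- 0
  if (k > 0)
    total <- sum(vapply(seq_len(k), function(i) dist(pts[[i + 1]], pts[[i]]),
                        numeric(1)))
  if (k < length(task$targets)) {
    pT <- tr$pos[nrow(tr$pos), ]
    total <- total + dist(pts[[k + 2]], pts[[k + 1]]) - dist(pT, pts[[k + 2]])
  }
  total - task$omega * path_length(tr)
}

# -- evaluation ledger --------------------------------------------------------

#' Create an evaluation ledger
#'
#' Mutable counters for evolution-level fitness evaluations, learning
#' assessments, pre-learning evaluations and simulated seconds. Counters are
#' monotone during a run.
#' @return an environment of class `eval_ledger`
#' @export
eval_ledger <- function() {
  e <- new.env(parent = emptyenv())
  e$evolution_evals <- 0L
  e$learning_assessments <- 0L
  e$pre_learning_evals <- 0L
  e$simulated_seconds <- 0
  class(e) <- "eval_ledger"
  e
}

#' @export
print.eval_ledger <- function(x, ...) {
  cat(sprintf(paste0("<eval_ledger: %d evolution evaluations, %d learning ",
                     "assessments, %d pre-learning evaluations, %g simulated s>\n"),
              x$evolution_evals, x$learning_assessments, x$pre_learning_evals,
              x$simulated_seconds))
  invisible(x)
}

.ledger_tick <- function(ledger, context, duration) {
  if (is.null(ledger)) return(invisible(NULL))
  field <- switch(context,
                  evolution = "evolution_evals",
                  learning = "learning_assessments",
                  pre_learning = "pre_learning_evals")
  assign(field, get(field, envir = ledger) + 1L, envir = ledger)
  ledger$simulated_seconds <- ledger$simulated_seconds + duration
  invisible(NULL)
}

# -- backends -----------------------------------------------------------------

#' Locomotion backends
#'
#' A backend is a list with a `simulate(body, network, task)` function
#' returning a [trajectory()]. `surrogate_backend()` is the built-in
#' deterministic kinematic surrogate; `external_backend()` is a stub for a
#' physics engine and raises an explicit error describing how to plug one in
#' (never a silent fallback). The surrogate's coefficients are package
#' choices, not measured constants: forward speed is proportional to the mean
#' absolute rate of change of the (steered) joint outputs times a
#' hinge-count efficiency factor, and turning rate to the left-right
#' actuation asymmetry.
#'
#' @param speed_gain metres per unit actuation vigour (default 0.15)
#' @param turn_gain heading change in rad/s per unit left-right asymmetry
#'   (default 2)
#' @param steer_gain steering gain passed to [steer()] (default 1)
#' @param ctrl_hz control sampling rate in Hz; must divide the integrator rate
#'   (default 25)
#' @param dt integrator step in seconds (default 0.005)
#' @return a backend list
#' @export
surrogate_backend <- function(speed_gain = 0.15, turn_gain = 2, steer_gain = 1,
                              ctrl_hz = 25, dt = 0.005) {
  list(
    name = "surrogate",
    simulate = function(body, network, task) {
      surrogate_simulate(body, network, task, speed_gain = speed_gain,
                         turn_gain = turn_gain, steer_gain = steer_gain,
                         ctrl_hz = ctrl_hz, dt = dt)
    }
  )
}

#' @rdname surrogate_backend
#' @export
external_backend <- function() {
  list(
    name = "external",
    simulate = function(body, network, task) {
      stop(paste("no external physics backend is configured; supply a list",
                 "with a simulate(body, network, task) function returning a",
                 "trajectory, or use surrogate_backend()"), call. = FALSE)
    }
  )
}

#' Deterministic kinematic locomotion surrogate
#'
#' Integrates the CPG network with fixed-step RK4 and drives a planar unicycle
#' model: forward speed is `speed_gain` times the mean absolute time-derivative
#' of the steered joint outputs times an efficiency factor
#' `n_hinges / (n_hinges + 2)`; heading turns toward the side with the larger
#' actuation after target steering ([steer()]). Positions are clipped to the
#' arena and sampled at the task's sampling rate. The model is deterministic
#' and makes no claim to physical fidelity; absolute fitness levels are not
#' comparable to a physics engine.
#'
#' @inheritParams surrogate_backend
#' @param body a `robot_body`
#' @param network a `cpg_network`
#' @param task a `task_spec`
#' @return a [trajectory()]
#' @export
surrogate_simulate <- function(body, network, task, speed_gain = 0.15,
                               turn_gain = 2, steer_gain = 1, ctrl_hz = 25,
                               dt = 0.005) {
  n_samp <- task$duration * task$sample_hz + 1
  if (network$n == 0) {
    pos <- matrix(0, n_samp, 2)
    return(trajectory(pos, task$duration, task$sample_hz))
  }
  steps_per_tick <- round(1 / (ctrl_hz * dt))
  ticks_per_samp <- ctrl_hz / task$sample_hz
  if (steps_per_tick < 1 || ticks_per_samp != round(ticks_per_samp))
    stop("ctrl_hz must divide the integrator rate and be a multiple of sample_hz")
  n_ticks <- task$duration * ctrl_hz
  M <- .cpg_system_matrix(network)
  P <- .rk4_transition(M, dt)
  Ptick <- diag(2 * network$n)
  for (i in seq_len(steps_per_tick)) Ptick <- P %*% Ptick
  # autonomous oscillator states at every control tick
  Z <- matrix(0, 2 * network$n, n_ticks + 1)
  Z[, 1] <- c(network$x, network$y)
  for (t in seq_len(n_ticks)) Z[, t + 1] <- Ptick %*% Z[, t]
  O <- cpg_output(Z[seq_len(network$n), , drop = FALSE])
  dO <- abs(O[, -1, drop = FALSE] - O[, -(n_ticks + 1), drop = FALSE]) * ctrl_hz
  # per-tick vigour by side (body-frame x sign of each joint)
  xs <- network$pos[, "x"]
  per_side <- function(mask) {
    if (!any(mask)) rep(0, n_ticks) else colMeans(dO[mask, , drop = FALSE])
  }
  vig_left  <- per_side(xs < 0)
  vig_right <- per_side(xs > 0)
  vig_axis  <- per_side(xs == 0)
  n_left <- sum(xs < 0); n_right <- sum(xs > 0); n_axis <- sum(xs == 0)
  # aggregate ticks into 5 Hz kinematic intervals
  agg <- function(v) colMeans(matrix(v, nrow = ticks_per_samp))
  vL <- agg(vig_left); vR <- agg(vig_right); vA <- agg(vig_axis)
  eff <- network$n / (network$n + 2)
  half <- task$arena / 2
  pos <- matrix(0, n_samp, 2)
  theta <- pi / 2   # spawn facing front (+y)
  nxt <- 1L
  nT <- length(task$targets)
  p <- c(0, 0)
  dt_samp <- 1 / task$sample_hz
  for (s in seq_len(n_samp - 1)) {
    if (nxt <= nT && sqrt(sum((p - task$targets[[nxt]])^2)) <= task$radius)
      nxt <- nxt + 1L
    if (nxt <= nT) {
      tgt <- task$targets[[nxt]]
      phi <- atan2(tgt[2] - p[2], tgt[1] - p[1])
      bearing <- -.wrap_angle(phi - theta)   # positive: target to the right
    } else bearing <- 0
    fac <- max(0, 1 - steer_gain * abs(bearing) / pi)
    l <- vL[s]; r <- vR[s]
    if (bearing > 0) r <- r * fac else if (bearing < 0) l <- l * fac
    tot <- n_left + n_right + n_axis
    vig <- (l * n_left + r * n_right + vA[s] * n_axis) / tot
    speed <- speed_gain * vig * eff
    dtheta <- -turn_gain * (l - r) * dt_samp
    theta <- .wrap_angle(theta + dtheta)
    p <- p + speed * dt_samp * c(cos(theta), sin(theta))
    p <- pmin(pmax(p, -half), half)
    pos[s + 1, ] <- p
  }
  trajectory(pos, task$duration, task$sample_hz)
}

.wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  if (a <= -pi) a + 2 * pi else a
}

#' Evaluate an individual's task performance
#'
#' Composes network construction (if not already done), the backend's
#' simulation and the fitness function, and increments the evaluation ledger
#' exactly once. Rewards for learning and fitness for evolution are the same
#' quantity, distinguished only by the ledger context.
#'
#' @param body a `robot_body`
#' @param network a `cpg_network`
#' @param backend a backend list (see [surrogate_backend()])
#' @param task a `task_spec`
#' @param ledger an [eval_ledger()] or NULL
#' @param context one of "evolution", "learning", "pre_learning"
#' @return list of class `evaluation_result`: `fitness`, `targets_reached`,
#'   `path_length`, `trajectory`
#' @export
evaluate <- function(body, network, backend = surrogate_backend(),
                     task = task_spec(), ledger = NULL, context = "evolution") {
  tr <- backend$simulate(body, network, task)
  .ledger_tick(ledger, context, task$duration)
  structure(list(
    fitness = fitness(tr, task),
    targets_reached = count_targets(tr, task)$k,
    path_length = path_length(tr),
    trajectory = tr
  ), class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation: fitness %.4f, %d target(s) reached, path %.3f m>\n",
              x$fitness, x$targets_reached, x$path_length))
  invisible(x)
}
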