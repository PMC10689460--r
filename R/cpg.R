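# CPG brain phenotype. Each active hinge i carries one oscillator with states
# (x_i, y_i) obeying
#   dx_i/dt = w_i * y_i + sum_{j in N_i} w_ji * x_j
#   dy_i/dt = -w_i * x_i
# with antisymmetric couplings (w_ij = -w_ji) between joints at tree distance
# <= 2. The commanded joint angle is tanh(x_i), bounded in (-1, 1). Initial
# states are sqrt(2)/2 so an uncoupled unit-weight oscillator traces a
# unit-amplitude sine wave.

#' Construct a CPG network for a body
#'
#' @param b a `robot_body`
#' @param w_internal numeric vector of internal weights, one per active hinge
#'   (decode order)
#' @param coupling antisymmetric coupling matrix (`coupling[i, j]` = w_ij);
#'   entries must vanish outside the tree-distance-2 neighbourhood
#' @return object of class `cpg_network`
#' @export
cpg_network <- function(b, w_internal = NULL, coupling = NULL) {
  j <- body_joints(b)
  n <- length(j)
  if (is.null(w_internal)) w_internal <- numeric(n)
  if (is.null(coupling)) coupling <- matrix(0, n, n)
  if (length(w_internal) != n || !all(dim(coupling) == c(n, n)))
    stop("weight dimensions do not match the number of joints")
  if (n > 0 && max(abs(coupling + t(coupling))) > 1e-12)
    stop("coupling matrix must be antisymmetric")
  m <- b$modules
  neigh <- matrix(FALSE, n, n)
  if (n > 1) {
    td <- .module_tree_dist(b)[j, j, drop = FALSE]
    neigh <- td <= 2 & !diag(TRUE, n)
    if (any(coupling[!neigh & !diag(TRUE, n)] != 0))
      stop("coupling between non-neighbouring joints")
  }
  structure(list(
    n = n,
    joint_ids = m$id[j],
    pos = cbind(x = m$x[j], y = m$y[j], z = m$z[j]),
    w_internal = w_internal,
    coupling = coupling,
    neighbours = neigh,
    x = rep(sqrt(2) / 2, n),
    y = rep(sqrt(2) / 2, n)
  ), class = "cpg_network")
}

#' Build the CPG network of a body from its brain genome
#'
#' Convenience wrapper around [develop_brain()]: one CPG per active hinge,
#' neighbour couplings for joints at tree distance <= 2, states initialized to
#' sqrt(2)/2.
#' @param b a `robot_body`
#' @param g a `brain_genome`
#' @return a `cpg_network`
#' @export
build_network <- function(b, g) develop_brain(g, b)

#' @export
print.cpg_network <- function(x, ...) {
  cat(sprintf("<cpg_network: %d CPGs, %d couplings>\n", x$n,
              sum(x$coupling[upper.tri(x$coupling)] != 0)))
  invisible(x)
}

# System matrix of the linear ODE on z = (x_1..x_n, y_1..y_n):
#   dz/dt = M z,  M = [ t(C) | diag(w) ; -diag(w) | 0 ],  C[i,j] = w_ij
.cpg_system_matrix <- function(n) {
  k <- n$n
  if (k == 0) return(matrix(0, 0, 0))
  M <- matrix(0, 2 * k, 2 * k)
  M[1:k, 1:k] <- t(n$coupling)
  M[cbind(1:k, k + 1:k)] <- n$w_internal
  M[cbind(k + 1:k, 1:k)] <- -n$w_internal
  M
}

# One-step transition matrix of classical RK4 on the linear system: the
# degree-4 Taylor polynomial of expm(dt * M). RK4 applied to a linear
# autonomous system is exactly this polynomial, so stepping states with it is
# bit-identical to running RK4.
.rk4_transition <- function(M, dt) {
  I <- diag(nrow(M))
  A <- dt * M
  I + A + A %*% A / 2 + A %*% A %*% A / 6 + A %*% A %*% A %*% A / 24
}

#' Advance a CPG network by one integrator step
#'
#' Fixed-step classical 4th-order Runge-Kutta on the coupled oscillator system.
#' @param n a `cpg_network`
#' @param dt step size in seconds (default 0.005)
#' @return the network with advanced states
#' @export
step_network <- function(n, dt = 0.005) {
  if (dt <= 0) stop("dt must be positive")
  if (n$n == 0) return(n)
  M <- .cpg_system_matrix(n)
  z <- c(n$x, n$y)
  f <- function(z) M %*% z
  k1 <- f(z)
  k2 <- f(z + dt / 2 * k1)
  k3 <- f(z + dt / 2 * k2)
  k4 <- f(z + dt * k3)
  z <- z + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  if (!all(is.finite(z)))
    stop(sprintf("non-finite CPG state after step (max |w| = %.3g)",
                 max(abs(c(n$w_internal, n$coupling)))))
  n$x <- z[1:n$n]
  n$y <- z[(n$n + 1):(2 * n$n)]
  n
}

#' CPG output nonlinearity
#'
#' The commanded joint angle for oscillator state x: `2 / (1 + exp(-2x)) - 1`,
#' which is algebraically `tanh(x)` and therefore bounded in (-1, 1).
#' @param x numeric oscillator state(s)
#' @return numeric in (-1, 1)
#' @export
cpg_output <- function(x) 2 / (1 + exp(-2 * x)) - 1

#' Steer joint commands toward a target
#'
#' Joints are partitioned into a left and a right group by the sign of their
#' body-frame x coordinate (on-axis joints are never modulated). The side the
#' target lies on is slowed by the factor `max(0, 1 - c * |bearing| / pi)`;
#' the other side is unchanged. Positive bearing means the target is to the
#' robot's right.
#'
#' @param commands numeric joint commands, one per joint (decode order)
#' @param bearing signed angle to the target in `(-pi, pi]`, positive to the
#'   right
#' @param b the `robot_body` (source of the joints' body-frame x coordinates)
#' @param c steering gain (default 1)
#' @return modulated commands
#' @export
steer <- function(commands, bearing, b, c = 1) {
  j <- body_joints(b)
  if (length(commands) != length(j))
    stop("one command per joint required")
  if (bearing == 0 || length(j) == 0) return(commands)
  xs <- b$modules$x[j]
  side <- if (bearing > 0) xs > 0 else xs < 0
  fac <- max(0, 1 - c * abs(bearing) / pi)
  commands[side] <- commands[side] * fac
  commands
}

#' Weight vector of a CPG network
#'
#' Flattens the network's expressed weights into one vector: the internal
#' weights followed by the couplings of each neighbour pair (i < j in decode
#' order). [set_network_weights()] is the inverse. This is the search space of
#' the lifetime learner.
#' @param n a `cpg_network`
#' @return numeric vector
#' @export
network_weights <- function(n) {
  if (n$n == 0) return(numeric(0))
  pairs <- which(upper.tri(n$neighbours) & n$neighbours, arr.ind = TRUE)
  c(n$w_internal, n$coupling[pairs])
}

#' @rdname network_weights
#' @param w numeric vector as produced by [network_weights()]
#' @return `set_network_weights`: the network with weights replaced
#' @export
set_network_weights <- function(n, w) {
  pairs <- which(upper.tri(n$neighbours) & n$neighbours, arr.ind = TRUE)
  if (length(w) != n$n + nrow(pairs)) stop("weight vector has wrong dimension")
  if (n$n > 0) n$w_internal <- w[seq_len(n$n)]
  if (nrow(pairs) > 0) {
    vals <- w[n$n + seq_len(nrow(pairs))]
    n$coupling[pairs] <- vals
    n$coupling[pairs[, c(2, 1), drop = FALSE]] <- -vals
  }
  n
}

#' Dump a network's state as JSON (debug aid)
#' @param n a `cpg_network`
#' @return JSON string with states, weights and couplings
#' @export
network_state_json <- function(n) {
  jsonlite::toJSON(list(x = n$x, y = n$y, w_internal = n$w_internal,
                        coupling = n$coupling), digits = NA)
}
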