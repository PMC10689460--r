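# Reversible Differential Evolution (RevDE) lifetime learner. From every
# sampled triplet (w_i, w_j, w_k) the mutation operator produces three
# candidates via an invertible linear map:
#   v1 = w_i + F (w_j - w_k)
#   v2 = w_j + F (w_k - v1)
#   v3 = w_k + F (v1 - v2)
# followed by binomial crossover against the corresponding triplet member.
# Selection keeps the best K of parents and offspring (elitist), so the
# best-so-far reward never decreases.

#' Learner configuration
#'
#' Defaults follow the study conditions: population size K = 10, scaling
#' factor F = 0.5, crossover rate CR = 0.9, 10 iterations, initial mutants
#' drawn by adding Gaussian noise (sd 0.5) to the inherited vector. At the
#' defaults one learning session costs K + 3K (iterations - 1) = 280
#' assessments.
#' @param K population size (>= 4 for triplet sampling; default 10)
#' @param F scaling factor (default 0.5)
#' @param CR crossover rate (default 0.9)
#' @param iterations number of iterations including the initial assessment
#'   round (default 10)
#' @param init_sd sd of the Gaussian noise that creates the initial mutants
#'   (default 0.5)
#' @return object of class `learner_config`
#' @export
learner_config <- function(K = 10, F = 0.5, CR = 0.9, iterations = 10,
                           init_sd = 0.5) {
  stopifnot(K >= 1, F > 0, CR > 0, CR <= 1, iterations >= 1)
  structure(list(K = K, F = F, CR = CR, iterations = iterations,
                 init_sd = init_sd), class = "learner_config")
}

#' Number of reward assessments one learning session costs
#' @param cfg a `learner_config`
#' @return `K + 3K (iterations - 1)`
#' @export
learner_assessments <- function(cfg) cfg$K + 3 * cfg$K * (cfg$iterations - 1)

#' Reversible differential mutation
#'
#' Produces three candidates from a triplet; the map (w_i, w_j, w_k) ->
#' (v1, v2, v3) is linear and invertible (the "reversible" in RevDE).
#' @param w_i,w_j,w_k numeric vectors of equal length
#' @param F scaling factor
#' @return list with `v1`, `v2`, `v3`
#' @export
revde_mutation <- function(w_i, w_j, w_k, F = 0.5) {
  if (length(w_i) != length(w_j) || length(w_j) != length(w_k))
    stop("triplet members must have equal dimension")
  v1 <- w_i + F * (w_j - w_k)
  v2 <- w_j + F * (w_k - v1)
  v3 <- w_k + F * (v1 - v2)
  list(v1 = v1, v2 = v2, v3 = v3)
}

#' Invert the reversible differential mutation
#'
#' Recovers the original triplet from the three candidates; inverse of
#' [revde_mutation()].
#' @param v1,v2,v3 numeric vectors produced by [revde_mutation()]
#' @param F scaling factor used in the forward map
#' @return list with `w_i`, `w_j`, `w_k`
#' @export
revde_mutation_inverse <- function(v1, v2, v3, F = 0.5) {
  # forward map per dimension: v = R w with
  #   R = [1, F, -F; -F, 1-F^2, F+F^2; F+F^2, -F+F^2+F^3, 1-2F^2-F^3]
  R <- matrix(c(
    1,        F,              -F,
    -F,       1 - F^2,        F + F^2,
    F + F^2,  -F + F^2 + F^3, 1 - 2 * F^2 - F^3
  ), nrow = 3, byrow = TRUE)
  V <- rbind(v1, v2, v3)
  W <- solve(R, V)
  list(w_i = W[1, ], w_j = W[2, ], w_k = W[3, ])
}

#' Binomial (uniform) DE crossover
#'
#' Samples a Bernoulli(CR) mask per dimension; masked dimensions come from the
#' mutant `v`, the rest from the parent `w`.
#' @param v mutant vector
#' @param w parent vector
#' @param CR crossover rate
#' @return trial vector
#' @export
de_crossover <- function(v, w, CR = 0.9) {
  if (length(v) != length(w)) stop("vectors must have equal dimension")
  m <- stats::runif(length(v)) < CR
  ifelse(m, v, w)
}

#' Initial learning population
#'
#' Element 1 is the inherited vector unchanged; the other K - 1 elements are
#' the inherited vector plus Gaussian noise.
#' @param inherited inherited weight vector
#' @param cfg a `learner_config`
#' @return list of K numeric vectors
#' @export
init_learning_population <- function(inherited, cfg = learner_config()) {
  pop <- vector("list", cfg$K)
  pop[[1]] <- inherited
  for (i in seq_len(cfg$K - 1) + 1)
    pop[[i]] <- inherited + stats::rnorm(length(inherited), 0, cfg$init_sd)
  pop
}

#' Run one RevDE learning session
#'
#' Iteration 1 assesses the K initial vectors. Each subsequent iteration draws
#' K random triplets (members distinct within a triplet), produces 3 candidates
#' per triplet via [revde_mutation()], crosses each candidate with its
#' corresponding triplet member ([de_crossover()]), assesses the 3K trials and
#' keeps the best K of parents and offspring.
#'
#' @param inherited inherited weight vector (the learner's starting point)
#' @param reward_fn function(weight vector) -> scalar reward
#' @param cfg a `learner_config`
#' @return list: `best` (best-ever vector), `best_reward`, `history`
#'   (data.frame iteration / best / mean, where `best` is best-so-far),
#'   `assessments` (total reward calls)
#' @export
revde_learn <- function(inherited, reward_fn, cfg = learner_config()) {
  pop <- init_learning_population(inherited, cfg)
  rewards <- vapply(pop, reward_fn, numeric(1))
  assessments <- cfg$K
  best_idx <- which.max(rewards)
  best <- pop[[best_idx]]
  best_reward <- rewards[best_idx]
  history <- data.frame(iteration = 1L, best = best_reward,
                        mean = mean(rewards))
  if (cfg$iterations > 1) for (it in 2:cfg$iterations) {
    cand <- vector("list", 3 * cfg$K)
    partner <- vector("list", 3 * cfg$K)
    for (t in seq_len(cfg$K)) {
      trip <- if (cfg$K >= 3) sample.int(cfg$K, 3) else
        sample(rep(seq_len(cfg$K), length.out = 3))
      v <- revde_mutation(pop[[trip[1]]], pop[[trip[2]]], pop[[trip[3]]], cfg$F)
      for (q in 1:3) {
        cand[[3 * (t - 1) + q]] <- v[[q]]
        partner[[3 * (t - 1) + q]] <- pop[[trip[q]]]
      }
    }
    trials <- lapply(seq_along(cand), function(i)
      de_crossover(cand[[i]], partner[[i]], cfg$CR))
    trial_rewards <- vapply(trials, reward_fn, numeric(1))
    assessments <- assessments + length(trials)
    # elitist selection over parents + offspring
    all_pop <- c(pop, trials)
    all_rew <- c(rewards, trial_rewards)
    keep <- order(all_rew, decreasing = TRUE)[seq_len(cfg$K)]
    pop <- all_pop[keep]
    rewards <- all_rew[keep]
    if (rewards[1] > best_reward) {
      best_reward <- rewards[1]
      best <- pop[[1]]
    }
    history <- rbind(history, data.frame(iteration = it, best = best_reward,
                                         mean = mean(rewards)))
  }
  list(best = best, best_reward = best_reward, history = history,
       assessments = assessments)
}

#' Learn the brain weights of one robot
#'
#' Wraps [revde_learn()] around the locomotion reward: the weight vector is
#' the robot's expressed CPG weights ([network_weights()]), the reward is the
#' task fitness of the network with those weights. Assessments are booked in
#' the ledger under the "learning" context.
#'
#' @param body a `robot_body`
#' @param network the robot's inherited `cpg_network`
#' @param backend a locomotion backend
#' @param task a `task_spec`
#' @param cfg a `learner_config`
#' @param ledger an [eval_ledger()] or NULL
#' @return as [revde_learn()], plus `network`: the network carrying the best
#'   learned weights
#' @export
learn_brain <- function(body, network, backend = surrogate_backend(),
                        task = task_spec(), cfg = learner_config(),
                        ledger = NULL) {
  reward_fn <- function(w) {
    nw <- set_network_weights(network, w)
    evaluate(body, nw, backend, task, ledger, context = "learning")$fitness
  }
  res <- revde_learn(network_weights(network), reward_fn, cfg)
  res$network <- set_network_weights(network, res$best)
  res
}
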