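# Integrated evolution + learning. Each generation, lambda children are made
# by binary-tournament parent selection, sexual body reproduction (NEAT
# crossover + mutation of the CPPN) and asexual brain reproduction (Gaussian
# mutation of the fittest parent's brain genome). Every newborn is evaluated
# before learning, learns with RevDE, is evaluated after learning, and — in
# Lamarckian mode only — has its learned weights written back into its brain
# genome. Survivors are the deterministic best mu - lambda of the old
# generation; selection fitness is the post-learning fitness.

#' Evolution configuration
#'
#' Defaults are the study conditions (mu = 50, lambda = 25, binary
#' tournaments, 30 generations, 20 repetitions); tests and the smoke campaign
#' scale them down.
#'
#' @param mu population size (default 50)
#' @param lambda offspring per generation (default 25)
#' @param tournament_size parent tournament size (default 2)
#' @param generations number of generations (default 30)
#' @param mode `"lamarckian"` (learned weights written back into the genome)
#'   or `"darwinian"` (genome keeps its birth weights)
#' @param repetitions independent repetitions in a campaign (default 20)
#' @param body_mutation body mutation rates, see [body_mutation_rates()]
#' @param body_crossover_p probability of body crossover (default 0.8)
#' @param brain_mutation_p per-entry brain mutation probability (default 0.8)
#' @param brain_mutation_sd brain mutation noise sd (default 0.5)
#' @param init_brain_sd sd of generation-0 brain genome entries (default 0.5)
#' @param learner a [learner_config()]
#' @param task a [task_spec()]
#' @param random_bodies if TRUE, every newborn's inherited body is replaced by
#'   a randomly generated one (the morphological-intelligence control
#'   experiment); the inherited brain is kept
#' @param max_modules non-core module cap for decoded bodies (default 10)
#' @return object of class `evo_config`
#' @export
evo_config <- function(mu = 50, lambda = 25, tournament_size = 2,
                       generations = 30, mode = c("lamarckian", "darwinian"),
                       repetitions = 20,
                       body_mutation = body_mutation_rates(),
                       body_crossover_p = 0.8,
                       brain_mutation_p = 0.8, brain_mutation_sd = 0.5,
                       init_brain_sd = 0.5,
                       learner = learner_config(), task = task_spec(),
                       random_bodies = FALSE, max_modules = 10L) {
  mode <- match.arg(mode)
  stopifnot(lambda <= mu, tournament_size >= 1, repetitions >= 1)
  structure(list(mu = mu, lambda = lambda, tournament_size = tournament_size,
                 generations = generations, mode = mode,
                 repetitions = repetitions, body_mutation = body_mutation,
                 body_crossover_p = body_crossover_p,
                 brain_mutation_p = brain_mutation_p,
                 brain_mutation_sd = brain_mutation_sd,
                 init_brain_sd = init_brain_sd, learner = learner, task = task,
                 random_bodies = random_bodies, max_modules = max_modules),
            class = "evo_config")
}

# -- individuals --------------------------------------------------------------

.new_individual <- function(id, body_genome, brain_genome, generation,
                            parent_ids = integer(0), max_modules = 10L) {
  body <- decode_body(body_genome, max_modules)
  list(id = id, body_genome = body_genome,
       brain_genome_birth = brain_genome,  # as inherited at birth
       brain_genome = brain_genome,        # current (Lamarckian write-back)
       body = body,
       fitness_before = NA_real_, fitness_after = NA_real_,
       learned_network = NULL, parent_ids = parent_ids,
       generation = generation)
}

# learn + evaluate one newborn in place; Lamarckian write-back if configured
.rear_individual <- function(ind, cfg, backend, ledger) {
  net <- develop_brain(ind$brain_genome, ind$body)
  ind$fitness_before <- evaluate(ind$body, net, backend, cfg$task, ledger,
                                 context = "pre_learning")$fitness
  lr <- learn_brain(ind$body, net, backend, cfg$task, cfg$learner, ledger)
  ind$learned_network <- lr$network
  ind$fitness_after <- evaluate(ind$body, lr$network, backend, cfg$task,
                                ledger, context = "evolution")$fitness
  if (cfg$mode == "lamarckian")
    ind$brain_genome <- encode_brain(lr$network, ind$body, ind$brain_genome)
  ind
}

#' Binary tournament selection
#'
#' Draws `size` individuals uniformly with replacement and returns the one
#' with the highest post-learning fitness; exact fitness ties are broken
#' uniformly at random among the drawn best.
#' @param pop list of individuals with evaluated `fitness_after`
#' @param size tournament size (default 2)
#' @return the selected individual
#' @export
tournament_select <- function(pop, size = 2) {
  if (length(pop) == 0) stop("empty population")
  idx <- sample.int(length(pop), size, replace = TRUE)
  fits <- vapply(pop[idx], function(i) i$fitness_after, numeric(1))
  winners <- idx[fits == max(fits)]
  pop[[if (length(winners) == 1) winners else sample(winners, 1)]]
}

#' Produce a child's genomes from two parents
#'
#' The body genome is sexual: NEAT crossover of the parents' CPPNs (probability
#' `body_crossover_p`, otherwise a clone of the fitter parent) followed by
#' mutation. The brain genome is asexual: the brain genome of the fittest
#' parent undergoes Gaussian mutation. In Lamarckian mode the source brain
#' genome is the parent's genome after learned-weight write-back; in Darwinian
#' mode it is the genome the parent was born with. Fitness ties are broken by
#' lower parent id.
#'
#' @param p1,p2 parent individuals (evaluated)
#' @param cfg an `evo_config`
#' @return list with `body_genome` and `brain_genome`
#' @export
reproduce <- function(p1, p2, cfg = evo_config()) {
  if (is.na(p1$fitness_after) || is.na(p2$fitness_after))
    stop("parents must be evaluated before reproduction")
  body <- crossover_body(p1$body_genome, p2$body_genome,
                         p1$fitness_after, p2$fitness_after,
                         cfg$body_crossover_p)
  body <- mutate_body(body, cfg$body_mutation)
  fittest <- if (p2$fitness_after > p1$fitness_after) p2
             else if (p1$fitness_after > p2$fitness_after) p1
             else if (p1$id <= p2$id) p1 else p2
  src <- switch(cfg$mode,
                lamarckian = fittest$brain_genome,
                darwinian  = fittest$brain_genome_birth)
  brain <- gaussian_mutate_brain(src, cfg$brain_mutation_p,
                                 cfg$brain_mutation_sd)
  other <- if (identical(fittest, p1)) p2 else p1
  # fittest (brain-donor) parent recorded first; lineage analyses rely on it
  list(body_genome = body, brain_genome = brain,
       parent_ids = c(fittest$id, other$id))
}

# deterministic survivor order: fitness desc, then older generation, then id
.survivor_order <- function(pop) {
  fits <- vapply(pop, function(i) i$fitness_after, numeric(1))
  gens <- vapply(pop, function(i) i$generation, numeric(1))
  ids  <- vapply(pop, function(i) i$id, numeric(1))
  order(-fits, gens, ids)
}

#' Advance the population by one generation
#'
#' Produces lambda children (each decoded, pre-evaluated, learned,
#' post-evaluated, and written back in Lamarckian mode), keeps the best
#' mu - lambda of the old generation as survivors, and returns their union.
#' @param pop list of mu evaluated individuals
#' @param cfg an `evo_config`
#' @param backend a locomotion backend
#' @param ledger an [eval_ledger()] or NULL
#' @param gen generation number assigned to the newborns
#' @param next_id first free individual id
#' @return list with `pop` (the new generation) and `newborns`
#' @export
next_generation <- function(pop, cfg, backend = surrogate_backend(),
                            ledger = NULL, gen = 1L,
                            next_id = max(vapply(pop, `[[`, numeric(1), "id")) + 1L) {
  newborns <- vector("list", cfg$lambda)
  for (i in seq_len(cfg$lambda)) {
    p1 <- tournament_select(pop, cfg$tournament_size)
    p2 <- tournament_select(pop, cfg$tournament_size)
    child <- reproduce(p1, p2, cfg)
    if (cfg$random_bodies)
      child$body_genome <- random_cppn()
    ind <- .new_individual(next_id, child$body_genome, child$brain_genome,
                           gen, child$parent_ids, cfg$max_modules)
    next_id <- next_id + 1L
    newborns[[i]] <- .rear_individual(ind, cfg, backend, ledger)
  }
  survivors <- pop[.survivor_order(pop)][seq_len(cfg$mu - cfg$lambda)]
  list(pop = c(survivors, newborns), newborns = newborns)
}

# per-generation statistics row
.gen_stats <- function(pop, newborns, gen, diversity_fn = diversity) {
  fits <- vapply(pop, function(i) i$fitness_after, numeric(1))
  nb_b <- vapply(newborns, function(i) i$fitness_before, numeric(1))
  nb_a <- vapply(newborns, function(i) i$fitness_after, numeric(1))
  data.frame(
    gen = gen,
    mean_fitness = mean(fits), max_fitness = max(fits),
    mean_newborn_before = mean(nb_b), max_newborn_before = max(nb_b),
    mean_newborn_after = mean(nb_a), max_newborn_after = max(nb_a),
    mean_learning_delta = mean(nb_a - nb_b),
    max_learning_delta = max(nb_a - nb_b),
    diversity = diversity_fn(pop)
  )
}

#' Run one evolutionary run
#'
#' Builds an initial population of mu random individuals (random CPPN bodies,
#' i.i.d. Gaussian brain genomes), rears them (pre-evaluation, learning,
#' post-evaluation, Lamarckian write-back as configured), then iterates
#' [next_generation()] for `cfg$generations` generations. Fully reproducible
#' from `seed`.
#'
#' @param cfg an `evo_config`
#' @param backend a locomotion backend
#' @param seed integer seed for the run
#' @return object of class `run_record`: `cfg`, `seed`, `mode`, `stats`
#'   (per-generation data.frame including diversity and mean parent-child
#'   tree-edit distance), `population` (final), `ledger` (counter snapshot),
#'   `accounting` (printed-convention and observed evaluation counts)
#' @export
run_evolution <- function(cfg = evo_config(), backend = surrogate_backend(),
                          seed = 1L) {
  set.seed(seed)
  ledger <- eval_ledger()
  archive <- new.env(parent = emptyenv())  # id -> body (for lineage TED)
  pop <- vector("list", cfg$mu)
  for (i in seq_len(cfg$mu)) {
    ind <- .new_individual(i, random_cppn(),
                           random_brain_genome(cfg$init_brain_sd), 0L,
                           max_modules = cfg$max_modules)
    pop[[i]] <- .rear_individual(ind, cfg, backend, ledger)
  }
  for (ind in pop) assign(as.character(ind$id), ind$body, envir = archive)
  # printed-accounting convention counts lambda evaluations at initialization
  stats <- .gen_stats(pop, pop, 0L)
  stats$mean_parent_child_ted <- NA_real_
  next_id <- cfg$mu + 1L
  if (cfg$generations > 0) for (gen in seq_len(cfg$generations)) {
    step <- next_generation(pop, cfg, backend, ledger, gen, next_id)
    pop <- step$pop
    for (ind in step$newborns)
      assign(as.character(ind$id), ind$body, envir = archive)
    next_id <- next_id + cfg$lambda
    row <- .gen_stats(pop, step$newborns, gen)
    row$mean_parent_child_ted <- mean(vapply(step$newborns, function(i) {
      fp <- .fittest_parent_id(i, pop, archive)
      parent_child_distance(i$body, get(as.character(fp), envir = archive))
    }, numeric(1)))
    stats <- rbind(stats, row)
  }
  accounting <- list(
    printed_evolution_evals = cfg$lambda * (1 + cfg$generations),
    observed_evolution_evals = ledger$evolution_evals,
    observed_pre_learning_evals = ledger$pre_learning_evals,
    observed_learning_assessments = ledger$learning_assessments,
    newborns = cfg$mu + cfg$lambda * cfg$generations,
    note = paste("printed convention counts lambda individuals at",
                 "initialization; observed counter counts all mu")
  )
  structure(list(cfg = cfg, seed = seed, mode = cfg$mode, stats = stats,
                 population = pop,
                 ledger = list(evolution_evals = ledger$evolution_evals,
                               learning_assessments = ledger$learning_assessments,
                               pre_learning_evals = ledger$pre_learning_evals,
                               simulated_seconds = ledger$simulated_seconds),
                 accounting = accounting),
            class = "run_record")
}

# id of the fittest parent of a newborn (recorded first by reproduce())
.fittest_parent_id <- function(ind, pop, archive) {
  if (length(ind$parent_ids) == 0) stop("individual has no recorded parents")
  ind$parent_ids[1]
}

#' @export
print.run_record <- function(x, ...) {
  last <- x$stats[nrow(x$stats), ]
  cat(sprintf(paste0("<run_record: %s, %d generations, final mean fitness ",
                     "%.4f, max %.4f>\n"),
              x$mode, max(x$stats$gen), last$mean_fitness, last$max_fitness))
  invisible(x)
}
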