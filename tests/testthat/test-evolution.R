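.mk_ind <- function(id, fit, gen = 0L) {
  ind <- lamevo:::.new_individual(id, fixture_cppn("plus"), brain_genome(0), gen)
  ind$fitness_before <- fit - 0.1
  ind$fitness_after <- fit
  ind
}

test_that("tournament selection returns the fittest of the drawn candidates", {
  one <- list(.mk_ind(1, 0.5))
  expect_identical(tournament_select(one, 2)$id, 1)
  expect_error(tournament_select(list()), "empty")
  # closed form: P(best wins a binary tournament with replacement) = (2n-1)/n^2
  pop <- lapply(1:4, function(i) .mk_ind(i, i / 10))
  n <- 4
  # exhaustive enumeration over all ordered draws
  wins <- 0
  for (i in 1:n) for (j in 1:n) if (max(i, j) == n) wins <- wins + 1
  expect_equal(wins / n^2, (2 * n - 1) / n^2)
  set.seed(10)
  picks <- replicate(4000, tournament_select(pop, 2)$id)
  expect_lt(abs(mean(picks == 4) - (2 * n - 1) / n^2), 0.03)
})

test_that("brain inheritance is Lamarckian or Darwinian as configured", {
  set.seed(11)
  cfg_l <- tiny_cfg("lamarckian", brain_mutation_p = 0)
  led <- eval_ledger()
  p1 <- lamevo:::.rear_individual(.mk_ind(1, 0), cfg_l, surrogate_backend(), led)
  p2 <- lamevo:::.rear_individual(.mk_ind(2, 0), cfg_l, surrogate_backend(), led)
  # after learning, the Lamarckian genome differs from the birth genome on the
  # expressed entries...
  expect_false(identical(unclass(p1$brain_genome),
                         unclass(p1$brain_genome_birth)))
  fit_p <- if (p1$fitness_after >= p2$fitness_after) p1 else p2
  child <- reproduce(p1, p2, cfg_l)
  # ...and with mutation disabled the child's brain genome equals the fittest
  # parent's post-learning genome exactly
  expect_identical(unclass(child$brain_genome), unclass(fit_p$brain_genome))
  expect_equal(child$parent_ids[1], fit_p$id)

  cfg_d <- tiny_cfg("darwinian", brain_mutation_p = 0)
  set.seed(11)
  q1 <- lamevo:::.rear_individual(.mk_ind(1, 0), cfg_d, surrogate_backend(), led)
  q2 <- lamevo:::.rear_individual(.mk_ind(2, 0), cfg_d, surrogate_backend(), led)
  # Darwinian: the genome never changes after birth
  expect_identical(unclass(q1$brain_genome), unclass(q1$brain_genome_birth))
  fit_q <- if (q1$fitness_after >= q2$fitness_after) q1 else q2
  child_d <- reproduce(q1, q2, cfg_d)
  expect_identical(unclass(child_d$brain_genome),
                   unclass(fit_q$brain_genome_birth))
  expect_error(reproduce(.mk_ind(1, NA), q2, cfg_d), "evaluated")
})

test_that("fitness ties between parents break by lower id", {
  cfg <- tiny_cfg("darwinian", brain_mutation_p = 0)
  set.seed(12)
  a <- .mk_ind(7, 0.5); b <- .mk_ind(3, 0.5)
  child <- reproduce(a, b, cfg)
  expect_equal(child$parent_ids[1], 3)
})

test_that("a generation keeps mu individuals: survivors plus newborns", {
  set.seed(13)
  cfg <- tiny_cfg("lamarckian")
  pop <- lapply(1:4, function(i) {
    lamevo:::.rear_individual(
      lamevo:::.new_individual(i, random_cppn(), random_brain_genome(), 0L),
      cfg, surrogate_backend(), NULL)
  })
  step <- next_generation(pop, cfg, surrogate_backend(), NULL, gen = 1L)
  expect_length(step$pop, 4)
  expect_length(step$newborns, 2)
  # survivors are the deterministic best mu - lambda of the old generation
  old_fits <- sort(vapply(pop, function(i) i$fitness_after, numeric(1)),
                   decreasing = TRUE)
  surv_fits <- vapply(step$pop[1:2], function(i) i$fitness_after, numeric(1))
  expect_equal(sort(surv_fits, decreasing = TRUE), old_fits[1:2])
  # every newborn carries both fitness records
  for (nb in step$newborns) {
    expect_false(is.na(nb$fitness_before))
    expect_false(is.na(nb$fitness_after))
  }
})

test_that("runs are reproducible and track the printed evaluation convention", {
  cfg <- tiny_cfg("darwinian")
  r1 <- run_evolution(cfg, seed = 5)
  r2 <- run_evolution(cfg, seed = 5)
  expect_identical(r1$stats, r2$stats)
  expect_equal(r1$accounting$printed_evolution_evals,
               cfg$lambda * (1 + cfg$generations))
  expect_equal(r1$ledger$evolution_evals, cfg$mu + cfg$lambda * cfg$generations)
  expect_equal(r1$ledger$learning_assessments,
               (cfg$mu + cfg$lambda * cfg$generations) *
                 learner_assessments(cfg$learner))
  # zero generations: only the initial population
  r0 <- run_evolution(tiny_cfg("darwinian", generations = 0), seed = 5)
  expect_equal(nrow(r0$stats), 1)
  expect_equal(r0$ledger$evolution_evals, 4)
})

test_that("max fitness never decreases across generations (elitist survival)", {
  for (mode in c("lamarckian", "darwinian")) {
    r <- run_evolution(tiny_cfg(mode, generations = 3), seed = 21)
    expect_true(all(diff(r$stats$max_fitness) >= 0))
  }
})

test_that("Darwinian genomes are frozen at birth; Lamarckian change exactly once", {
  r_d <- run_evolution(tiny_cfg("darwinian"), seed = 31)
  for (ind in r_d$population)
    expect_identical(unclass(ind$brain_genome), unclass(ind$brain_genome_birth))
  r_l <- run_evolution(tiny_cfg("lamarckian"), seed = 31)
  changed <- vapply(r_l$population, function(ind)
    !identical(unclass(ind$brain_genome), unclass(ind$brain_genome_birth)),
    logical(1))
  # write-back happens once per individual, right after learning; a core-only
  # body has no expressed entries, so allow unchanged tables for those only
  n_joints <- vapply(r_l$population, function(ind)
    length(body_joints(ind$body)), integer(1))
  expect_true(all(changed[n_joints > 0]))
})
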