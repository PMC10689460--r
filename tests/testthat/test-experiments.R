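test_that("the budget identities follow from the configuration in closed form", {
  cfg <- evo_config()   # study conditions
  br <- budget_report(cfg)
  expect_equal(br$assessments_per_robot, 280)
  expect_equal(br$evolution_evals_per_run, 775)
  expect_equal(br$campaign_total_evals, 434000)
  expect_equal(br$simulated_hours, 4822)
  # the closed forms hold for arbitrary configurations, not just defaults
  cfg2 <- evo_config(mu = 9, lambda = 3, generations = 4,
                     learner = learner_config(K = 5, iterations = 3))
  br2 <- budget_report(cfg2, systems = 1)
  expect_equal(br2$assessments_per_robot, 5 + 15 * 2)
  expect_equal(br2$evolution_evals_per_run, 3 * 5)
  expect_equal(br2$newborns_per_run, 9 + 3 * 4)
  expect_equal(br2$campaign_total_evals, 15 * 35)
})

test_that("ledger observation must match prediction or budget_report errors", {
  cfg <- tiny_cfg("darwinian")
  rec <- run_evolution(cfg, seed = 3)
  expect_silent(budget_report(cfg, observed = rec))
  broken <- rec
  broken$ledger$learning_assessments <- broken$ledger$learning_assessments + 1
  expect_error(budget_report(cfg, observed = broken), "accounting")
})

test_that("savings estimate reproduces the crossover arithmetic", {
  cfg <- evo_config()
  expect_equal(savings_estimate(14, cfg), 25 * 16 * 280 * 20)
  expect_equal(savings_estimate(14, cfg), 2240000)
  expect_equal(savings_estimate(cfg$generations, cfg), 0)
  cfg1 <- evo_config(repetitions = 1)
  expect_equal(savings_estimate(14, cfg1), 2240000 / 20)
})

test_that("campaigns run every mode x repetition cell reproducibly", {
  cfg <- tiny_cfg()
  spec <- campaign_spec(cfg, modes = c("lamarckian", "darwinian"),
                        repetitions = 2, seed = 100)
  cp <- run_campaign(spec)
  expect_length(cp$runs, 4)
  expect_equal(cp$manifest$mode_of_run,
               rep(c("lamarckian", "darwinian"), each = 2))
  expect_equal(length(unique(cp$manifest$seeds)), 4)  # distinct per-run seeds
  cp2 <- run_campaign(spec)
  expect_identical(cp$aggregate, cp2$aggregate)
  expect_identical(lapply(cp$runs, function(r) r$stats),
                   lapply(cp2$runs, function(r) r$stats))
})

test_that("confidence bands of constant data have zero width", {
  cfg <- tiny_cfg()
  spec <- campaign_spec(cfg, modes = "darwinian", repetitions = 2, seed = 7)
  cp <- run_campaign(spec)
  # duplicate one run: identical values per generation -> zero-width CI
  fake <- cp$runs
  fake[[2]] <- fake[[1]]
  agg <- aggregate_generations(fake)
  expect_equal(agg$mean_lo, agg$mean_hi)
  expect_equal(agg$mean_lo, agg$mean_fitness)
})

test_that("campaign outputs are written and reproducible on disk", {
  outdir <- tempfile("campaign")
  on.exit(unlink(outdir, recursive = TRUE))
  cfg <- tiny_cfg()
  spec <- campaign_spec(cfg, modes = "lamarckian", repetitions = 1, seed = 9,
                        outdir = outdir)
  run_campaign(spec)
  expect_true(file.exists(file.path(outdir, "manifest.json")))
  expect_true(file.exists(file.path(outdir, "aggregate.csv")))
  csv1 <- readLines(list.files(outdir, "run_", full.names = TRUE)[1])
  run_campaign(spec)
  csv2 <- readLines(list.files(outdir, "run_", full.names = TRUE)[1])
  expect_identical(csv1, csv2)
})

test_that("the random-body control severs the body lineage but keeps brains", {
  cfg <- tiny_cfg("darwinian")
  spec <- campaign_spec(cfg, modes = "darwinian", repetitions = 1, seed = 11)
  ctrl <- control_experiment(spec)
  expect_true(ctrl$runs[[1]]$cfg$random_bodies)
  # Darwinian control: genomes still frozen at birth
  for (ind in ctrl$runs[[1]]$population)
    expect_identical(unclass(ind$brain_genome), unclass(ind$brain_genome_birth))
  # determinism
  ctrl2 <- control_experiment(spec)
  expect_identical(ctrl$runs[[1]]$stats, ctrl2$runs[[1]]$stats)
  # mechanism: newborn bodies are independent of the parents' bodies --
  # parent-child TED should look like TED between unrelated random bodies
  set.seed(12)
  cfg_big <- tiny_cfg("darwinian", generations = 3)
  ctrl3 <- run_evolution({ c <- cfg_big; c$random_bodies <- TRUE; c },
                         seed = 13)
  pc <- ctrl3$stats$mean_parent_child_ted[-1]
  rnd <- replicate(30, tree_edit_distance(random_body(), random_body()))
  # permutation-style check at tiny scale: the control's parent-child
  # distances sit inside the random-pair distribution
  expect_gt(mean(pc), mean(rnd) - 2 * sd(rnd))
  expect_lt(mean(pc), mean(rnd) + 2 * sd(rnd))
})

test_that("mode comparison reports differences, Bonferroni level and correlation", {
  cfg <- tiny_cfg()
  spec <- campaign_spec(cfg, modes = c("lamarckian", "darwinian"),
                        repetitions = 2, seed = 50)
  cp <- run_campaign(spec)
  cmp <- compare_modes(cp, comparisons = 6)
  expect_equal(cmp$bonferroni_alpha, 0.05 / 6, tolerance = 1e-12)
  expect_equal(nrow(cmp$per_generation), cfg$generations + 1)
  expect_true(all(cmp$per_generation$p >= 0 & cmp$per_generation$p <= 1))
  # identical record sets: zero differences, p = 1
  same <- c(cp$runs[1:2], lapply(cp$runs[1:2], function(r) {
    r$mode <- "darwinian"; r
  }))
  cmp_same <- compare_modes(same)
  expect_true(all(cmp_same$per_generation$diff == 0))
  expect_true(all(cmp_same$per_generation$p == 1))
  expect_error(compare_modes(cp$runs[1:2]), "two modes")
})
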