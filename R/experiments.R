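# Campaign harness and evaluation-budget bookkeeping. All counts are
# recomputed in closed form from the configuration; budget_report() also
# cross-checks them against observed ledger counters.

#' Campaign specification
#'
#' @param cfg an [evo_config()] shared by all runs (mode is overridden per run)
#' @param modes inheritance modes to run (default both)
#' @param repetitions repetitions per mode (default `cfg$repetitions`)
#' @param seed base seed; run r of mode m uses `seed + (m_index - 1) *
#'   repetitions + (r - 1)`, so all per-run seeds are distinct
#' @param outdir optional directory for CSV/JSON outputs
#' @return object of class `campaign_spec`
#' @export
campaign_spec <- function(cfg = evo_config(),
                          modes = c("lamarckian", "darwinian"),
                          repetitions = cfg$repetitions, seed = 1L,
                          outdir = NULL) {
  stopifnot(repetitions >= 1, length(modes) >= 1)
  structure(list(cfg = cfg, modes = modes, repetitions = repetitions,
                 seed = seed, outdir = outdir), class = "campaign_spec")
}

#' Closed-form evaluation budget of a configuration
#'
#' Recomputes the bookkeeping identities from the configuration: assessments
#' per robot (`K + 3K (iterations - 1)`), evolution-level evaluations per run
#' in the printed convention (`lambda (1 + generations)`, which counts lambda
#' individuals at initialization), the observed convention
#' (`mu + lambda * generations` newborns, each evaluated once after
#' learning), the campaign totals over `systems` modes
#' (`per-run evaluations x assessments x systems`) and the simulated hours at
#' `evaluation duration` seconds per assessment. When a ledger or
#' `run_record` is supplied, predicted and observed counters are compared and
#' a mismatch raises an accounting error.
#'
#' @param cfg an `evo_config`
#' @param systems number of compared systems in the campaign total (default 2)
#' @param observed optional [eval_ledger()] or `run_record` to verify
#' @return list of class `budget_report` with the predicted counts (and
#'   `observed`, when supplied)
#' @export
budget_report <- function(cfg = evo_config(), systems = 2, observed = NULL) {
  per_robot <- learner_assessments(cfg$learner)
  printed_evals <- cfg$lambda * (1 + cfg$generations)
  newborns <- cfg$mu + cfg$lambda * cfg$generations
  campaign_total <- printed_evals * per_robot * systems
  sim_hours <- campaign_total * cfg$task$duration / 3600
  rep <- list(
    assessments_per_robot = per_robot,
    evolution_evals_per_run = printed_evals,
    newborns_per_run = newborns,
    observed_evolution_evals_per_run = newborns,
    campaign_total_evals = campaign_total,
    simulated_hours = round(sim_hours),
    simulated_hours_exact = sim_hours
  )
  if (!is.null(observed)) {
    led <- if (inherits(observed, "run_record")) observed$ledger else
      list(evolution_evals = observed$evolution_evals,
           learning_assessments = observed$learning_assessments,
           pre_learning_evals = observed$pre_learning_evals)
    expect <- list(evolution_evals = newborns,
                   learning_assessments = newborns * per_robot,
                   pre_learning_evals = newborns)
    for (f in names(expect)) {
      if (led[[f]] != expect[[f]])
        stop(sprintf("accounting error: %s observed %d, predicted %d",
                     f, led[[f]], expect[[f]]))
    }
    rep$observed <- led
  }
  class(rep) <- "budget_report"
  rep
}

#' @export
print.budget_report <- function(x, ...) {
  cat(sprintf(paste0("<budget_report: %d assessments/robot, %d evolution ",
                     "evaluations/run (printed convention; %d observed), ",
                     "%d campaign evaluations, %d simulated hours>\n"),
              x$assessments_per_robot, x$evolution_evals_per_run,
              x$observed_evolution_evals_per_run, x$campaign_total_evals,
              x$simulated_hours))
  invisible(x)
}

#' Evaluation savings when one system reaches the other's final quality early
#'
#' If the faster system matches the slower one's end-of-run quality at
#' generation `gen_equal`, the remaining `generations - gen_equal` generations
#' of offspring learning are no longer needed:
#' `lambda x (generations - gen_equal) x assessments-per-robot x repetitions`.
#' @param gen_equal generation at which quality crosses over
#' @param cfg an `evo_config`
#' @return evaluation count
#' @export
savings_estimate <- function(gen_equal, cfg = evo_config()) {
  stopifnot(gen_equal <= cfg$generations, gen_equal >= 0)
  cfg$lambda * (cfg$generations - gen_equal) *
    learner_assessments(cfg$learner) * cfg$repetitions
}

#' Run a full campaign
#'
#' Executes every (mode x repetition) run with distinct per-run seeds,
#' verifies the ledger of each run against the closed-form budget, and
#' aggregates per-generation statistics (mean and 95% t confidence interval
#' across repetitions). When `spec$outdir` is set, writes a JSON manifest and
#' per-generation CSVs.
#' @param spec a [campaign_spec()]
#' @param backend a locomotion backend
#' @return list of class `campaign_record`: `spec`, `runs` (list of
#'   `run_record`s), `aggregate` (data.frame), `manifest`
#' @export
run_campaign <- function(spec, backend = surrogate_backend()) {
  runs <- list()
  idx <- 0L
  for (mi in seq_along(spec$modes)) {
    for (r in seq_len(spec$repetitions)) {
      idx <- idx + 1L
      cfg <- spec$cfg
      cfg$mode <- spec$modes[mi]
      run_seed <- spec$seed + (mi - 1L) * spec$repetitions + (r - 1L)
      rec <- run_evolution(cfg, backend, seed = run_seed)
      budget_report(cfg, observed = rec)   # accounting check per run
      runs[[idx]] <- rec
    }
  }
  agg <- aggregate_generations(runs)
  manifest <- list(
    modes = spec$modes, repetitions = spec$repetitions, seed = spec$seed,
    seeds = vapply(runs, function(r) r$seed, numeric(1)),
    mode_of_run = vapply(runs, function(r) r$mode, character(1)),
    accounting = runs[[1]]$accounting,
    ledger_totals = list(
      evolution_evals = sum(vapply(runs, function(r) r$ledger$evolution_evals, numeric(1))),
      learning_assessments = sum(vapply(runs, function(r) r$ledger$learning_assessments, numeric(1))),
      simulated_seconds = sum(vapply(runs, function(r) r$ledger$simulated_seconds, numeric(1)))
    )
  )
  rec <- structure(list(spec = spec, runs = runs, aggregate = agg,
                        manifest = manifest), class = "campaign_record")
  if (!is.null(spec$outdir)) .write_campaign(rec, spec$outdir)
  rec
}

#' Aggregate per-generation statistics across runs
#'
#' Means and 95% confidence intervals (Sample Mean +/- t-value x Standard
#' Error) per mode and generation; the CI of constant data has zero width.
#' @param runs list of `run_record`s
#' @return data.frame with mode, gen, and mean/lo/hi columns for mean and max
#'   fitness
#' @export
aggregate_generations <- function(runs) {
  modes <- unique(vapply(runs, function(r) r$mode, character(1)))
  out <- NULL
  for (md in modes) {
    rs <- Filter(function(r) r$mode == md, runs)
    gens <- rs[[1]]$stats$gen
    for (g in gens) {
      vals_mean <- vapply(rs, function(r) r$stats$mean_fitness[r$stats$gen == g],
                          numeric(1))
      vals_max <- vapply(rs, function(r) r$stats$max_fitness[r$stats$gen == g],
                         numeric(1))
      ci <- function(v) {
        n <- length(v)
        if (n < 2 || stats::sd(v) == 0) return(c(mean(v), mean(v)))
        se <- stats::sd(v) / sqrt(n)
        tcrit <- stats::qt(0.975, n - 1)
        mean(v) + c(-1, 1) * tcrit * se
      }
      cm <- ci(vals_mean); cx <- ci(vals_max)
      out <- rbind(out, data.frame(
        mode = md, gen = g,
        mean_fitness = mean(vals_mean), mean_lo = cm[1], mean_hi = cm[2],
        max_fitness = mean(vals_max), max_lo = cx[1], max_hi = cx[2]))
    }
  }
  out
}

.write_campaign <- function(rec, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(rec$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(rec$aggregate, file.path(outdir, "aggregate.csv"),
                   row.names = FALSE)
  for (i in seq_along(rec$runs)) {
    r <- rec$runs[[i]]
    utils::write.csv(r$stats,
                     file.path(outdir, sprintf("run_%s_seed%d.csv", r$mode,
                                               r$seed)),
                     row.names = FALSE)
  }
  invisible(outdir)
}

#' Run the random-body control experiment
#'
#' Identical to [run_campaign()] except that every newborn's inherited body is
#' replaced by a randomly generated one before learning (the inherited brain
#' genome is kept; in Lamarckian mode learned weights are still written back).
#' @param spec a [campaign_spec()]
#' @param backend a locomotion backend
#' @return a `campaign_record`
#' @export
control_experiment <- function(spec, backend = surrogate_backend()) {
  spec$cfg$random_bodies <- TRUE
  run_campaign(spec, backend)
}

#' Compare inheritance modes
#'
#' Per-generation Welch t-tests on run-level mean fitness between two modes,
#' with Bonferroni correction over `comparisons` tests, plus the pooled
#' correlation between newborn fitness and parent-child tree-edit distance.
#' Constant, identical groups are reported as p = 1.
#' @param records a `campaign_record` (or list of `run_record`s) holding >= 2
#'   runs per mode
#' @param comparisons number of comparisons for the Bonferroni correction
#'   (default 6)
#' @param alpha family-wise significance level (default 0.05)
#' @return list: `per_generation` data.frame (gen, difference of means, p,
#'   significant), `bonferroni_alpha`, `fitness_ted_correlation` per mode
#' @export
compare_modes <- function(records, comparisons = 6, alpha = 0.05) {
  runs <- if (inherits(records, "campaign_record")) records$runs else records
  modes <- unique(vapply(runs, function(r) r$mode, character(1)))
  if (length(modes) != 2) stop("exactly two modes required")
  split_runs <- lapply(modes, function(md) Filter(function(r) r$mode == md, runs))
  if (any(vapply(split_runs, length, integer(1)) < 2))
    stop("at least two runs per mode required")
  gens <- split_runs[[1]][[1]]$stats$gen
  per_gen <- NULL
  thr <- alpha / comparisons
  for (g in gens) {
    v1 <- vapply(split_runs[[1]], function(r) r$stats$mean_fitness[r$stats$gen == g], numeric(1))
    v2 <- vapply(split_runs[[2]], function(r) r$stats$mean_fitness[r$stats$gen == g], numeric(1))
    p <- if (stats::sd(v1) == 0 && stats::sd(v2) == 0) {
      if (isTRUE(all.equal(mean(v1), mean(v2)))) 1 else 0
    } else stats::t.test(v1, v2)$p.value
    per_gen <- rbind(per_gen, data.frame(
      gen = g, diff = mean(v1) - mean(v2), p = p, significant = p < thr))
  }
  corr <- lapply(seq_along(modes), function(k) {
    fits <- unlist(lapply(split_runs[[k]], function(r)
      r$stats$mean_newborn_after[r$stats$gen > 0]))
    teds <- unlist(lapply(split_runs[[k]], function(r)
      r$stats$mean_parent_child_ted[r$stats$gen > 0]))
    if (length(fits) < 3 || stats::sd(fits) == 0 || stats::sd(teds) == 0)
      return(NA_real_)
    stats::cor(fits, teds)
  })
  names(corr) <- modes
  list(per_generation = per_gen, bonferroni_alpha = thr,
       fitness_ted_correlation = corr)
}
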