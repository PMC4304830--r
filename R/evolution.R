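#' Genetic-algorithm configuration
#'
#' Defaults follow the full-scale search setup: population 100, 100
#' generations, tournament size 5, crossover probability 0.5, mutation
#' probability 0.15, worst-half generational replacement, a two-stage
#' fitness-approximation evaluator (probe stage of `probe_samples` Monte
#' Carlo samples; candidates scoring below `approx_threshold` percent keep
#' the cheap probe estimate, others get a `full_samples` evaluation) and an
#' archive re-evaluation probability `reevaluate_prob` guarding against
#' accidentally poor stored scores.
#'
#' @param population_size,generations,tournament_size GA size controls.
#' @param crossover_prob probability a mating performs crossover (otherwise
#'   offspring are clones).
#' @param mutation_prob probability an offspring is mutated (single-entry
#'   mutation); under `mutation_mode = "per_entry"` the per-entry flip rate.
#' @param replacement_fraction fraction of the population (the worst
#'   individuals) replaced by offspring each generation.
#' @param approx_threshold percent robustness below which the probe estimate
#'   is kept as an approximation.
#' @param reevaluate_prob probability of re-evaluating a topology already in
#'   the archive (recommended 0.10-0.20).
#' @param probe_samples,full_samples Monte Carlo sample counts of the two
#'   evaluation stages (`probe_samples < full_samples`).
#' @param mutation_mode `"per_offspring"` (default: one uniformly chosen
#'   entry is changed with probability `mutation_prob`) or `"per_entry"`
#'   (every entry independently changed with rate `mutation_prob`).
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 100, generations = 100,
                      tournament_size = 5, crossover_prob = 0.5,
                      mutation_prob = 0.15, replacement_fraction = 0.5,
                      approx_threshold = 5, reevaluate_prob = 0.15,
                      probe_samples = 500, full_samples = 10000,
                      mutation_mode = c("per_offspring", "per_entry")) {
  mutation_mode <- match.arg(mutation_mode)
  stopifnot(population_size >= 2, generations >= 0, tournament_size >= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            replacement_fraction > 0, replacement_fraction <= 1,
            approx_threshold >= 0, reevaluate_prob >= 0,
            reevaluate_prob <= 1, probe_samples >= 1,
            probe_samples < full_samples)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 tournament_size = as.integer(tournament_size),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 replacement_fraction = replacement_fraction,
                 approx_threshold = approx_threshold,
                 reevaluate_prob = reevaluate_prob,
                 probe_samples = as.integer(probe_samples),
                 full_samples = as.integer(full_samples),
                 mutation_mode = mutation_mode),
            class = "ga_config")
}

#' Tournament selection
#'
#' Draws `size` members uniformly without replacement (with replacement when
#' the population is smaller than the tournament) and returns the entrant
#' with the highest fitness; ties are broken uniformly at random.
#'
#' @param population non-empty list of individuals, each a list with at
#'   least elements `topology` and `fitness`.
#' @param size tournament size.
#' @return The selected individual.
#' @export
tournament_select <- function(population, size = 5) {
  if (length(population) == 0) {
    stop("population must be non-empty", call. = FALSE)
  }
  idx <- sample.int(length(population), size,
                    replace = length(population) < size)
  fit <- vapply(population[idx], `[[`, numeric(1), "fitness")
  best <- which(fit == max(fit))
  if (length(best) > 1) best <- best[sample.int(length(best), 1)]
  population[[idx[best]]]
}

#' Matrix crossover of two topologies
#'
#' Chooses a horizontal (row) or vertical (column) orientation with equal
#' probability and a cut point uniformly in `1..N-1`; offspring 1 takes
#' parent 1's block before the cut and parent 2's block after, offspring 2
#' the complement. With `N = 1` there is no valid cut point and the
#' offspring are clones. Every offspring entry equals the corresponding
#' entry of one of its parents.
#'
#' @param parent1,parent2 [grn_topology()] objects of equal size.
#' @return A list of two offspring topologies.
#' @export
crossover_topologies <- function(parent1, parent2) {
  stopifnot(inherits(parent1, "grn_topology"),
            inherits(parent2, "grn_topology"),
            parent1$n_genes == parent2$n_genes)
  n <- parent1$n_genes
  if (n == 1) return(list(parent1, parent2))
  horizontal <- stats::runif(1) < 0.5
  cut <- sample.int(n - 1L, 1)
  m1 <- parent1$matrix
  m2 <- parent2$matrix
  o1 <- m1
  o2 <- m2
  if (horizontal) {
    rows <- seq_len(cut)
    o1[-rows, ] <- m2[-rows, ]
    o2[-rows, ] <- m1[-rows, ]
  } else {
    cols <- seq_len(cut)
    o1[, -cols] <- m2[, -cols]
    o2[, -cols] <- m1[, -cols]
  }
  list(grn_topology(o1, genes = parent1$genes),
       grn_topology(o2, genes = parent1$genes))
}

#' Mutate a topology matrix
#'
#' Under the default per-offspring mode, with probability `mutation_prob`
#' one matrix entry chosen uniformly is replaced by one of the other two
#' values of `{-1, 0, 1}` (chosen uniformly); otherwise the topology is
#' returned unchanged. Under `mode = "per_entry"` each entry is
#' independently changed with rate `mutation_prob`.
#'
#' @param topology a [grn_topology()].
#' @param mutation_prob application probability (or per-entry rate).
#' @param mode `"per_offspring"` or `"per_entry"`.
#' @return A (possibly unchanged) [grn_topology()].
#' @export
mutate_topology <- function(topology, mutation_prob = 0.15,
                            mode = c("per_offspring", "per_entry")) {
  stopifnot(inherits(topology, "grn_topology"))
  mode <- match.arg(mode)
  m <- topology$matrix
  flip <- function(v) {
    others <- setdiff(c(-1L, 0L, 1L), v)
    others[sample.int(2L, 1)]
  }
  if (mode == "per_offspring") {
    if (stats::runif(1) >= mutation_prob) return(topology)
    pos <- sample.int(length(m), 1)
    m[pos] <- flip(m[pos])
  } else {
    hits <- which(stats::runif(length(m)) < mutation_prob)
    for (pos in hits) m[pos] <- flip(m[pos])
  }
  grn_topology(m, genes = topology$genes)
}

#' Archive of evaluated topologies
#'
#' A memo table mapping the exact (label-sensitive) topology matrix to its
#' best-known robustness score and whether that score came from the probe
#' stage only. Stored scores are monotone: updates keep the maximum of the
#' old and new score. Lookup of an unseen topology reports absence.
#'
#' @return `new_archive()` returns an empty archive (an environment of class
#'   `grn_archive`).
#' @export
new_archive <- function() {
  structure(new.env(parent = emptyenv()), class = "grn_archive")
}

#' @rdname new_archive
#' @param archive a `grn_archive`.
#' @param topology a [grn_topology()].
#' @return `archive_lookup()` returns the stored record
#'   (`list(fitness, approximate, n_evaluations)`) or `NULL` if absent.
#' @export
archive_lookup <- function(archive, topology) {
  stopifnot(inherits(archive, "grn_archive"))
  key <- topology_key(topology)
  if (exists(key, envir = archive, inherits = FALSE)) {
    get(key, envir = archive, inherits = FALSE)
  } else {
    NULL
  }
}

#' @rdname new_archive
#' @param fitness robustness score to store.
#' @param approximate whether the score came from the probe stage only.
#' @return `archive_store()` returns the stored record invisibly; if the key
#'   already exists the maximum of old and new fitness is retained.
#' @export
archive_store <- function(archive, topology, fitness, approximate) {
  stopifnot(inherits(archive, "grn_archive"))
  key <- topology_key(topology)
  old <- if (exists(key, envir = archive, inherits = FALSE)) {
    get(key, envir = archive, inherits = FALSE)
  } else {
    NULL
  }
  rec <- if (is.null(old)) {
    list(fitness = fitness, approximate = approximate, n_evaluations = 1L,
         insert_order = length(ls(envir = archive)) + 1L)
  } else if (fitness > old$fitness) {
    list(fitness = fitness, approximate = approximate,
         n_evaluations = old$n_evaluations + 1L,
         insert_order = old$insert_order)
  } else {
    list(fitness = old$fitness, approximate = old$approximate,
         n_evaluations = old$n_evaluations + 1L,
         insert_order = old$insert_order)
  }
  assign(key, rec, envir = archive)
  invisible(rec)
}

#' @rdname new_archive
#' @return `archive_size()` returns the number of stored topologies.
#' @export
archive_size <- function(archive) {
  stopifnot(inherits(archive, "grn_archive"))
  length(ls(envir = archive))
}

#' @export
print.grn_archive <- function(x, ...) {
  cat(sprintf("topology archive: %d evaluated topologies\n",
              archive_size(x)))
  invisible(x)
}

#' Two-stage fitness approximation
#'
#' Stage 1 estimates robustness from `probe_samples` Monte Carlo samples.
#' If the probe estimate falls below `approx_threshold` percent the cheap
#' estimate is returned as an approximation (such low-fitness candidates
#' rarely survive selection, so a rough score suffices); otherwise a fresh
#' full evaluation with `full_samples` samples is performed.
#'
#' @inheritParams estimate_robustness
#' @param config a [ga_config()] supplying `probe_samples`, `full_samples`
#'   and `approx_threshold`.
#' @return A list with `score` (percent) and `approximate` (logical).
#' @export
approximate_fitness <- function(topology, behavior, coop,
                                ranges = parameter_ranges(),
                                config = ga_config()) {
  probe <- estimate_robustness(topology, behavior, coop, ranges,
                               n_samples = config$probe_samples)
  if (probe$score < config$approx_threshold) {
    return(list(score = probe$score, approximate = TRUE))
  }
  full <- estimate_robustness(topology, behavior, coop, ranges,
                              n_samples = config$full_samples)
  list(score = full$score, approximate = FALSE)
}

#' Archive-memoized fitness evaluation
#'
#' Unseen topologies are scored with the evaluator and stored. Topologies
#' already in the archive are re-evaluated with probability
#' `config$reevaluate_prob` -- storing the maximum of the old and new score,
#' so stored fitness only ever increases -- and otherwise returned from the
#' archive at zero simulation cost.
#'
#' @inheritParams approximate_fitness
#' @param archive a [new_archive()].
#' @param evaluator function `(topology, behavior, coop, ranges, config)`
#'   returning `list(score, approximate)`; defaults to
#'   [approximate_fitness()]. Injectable for testing/instrumentation.
#' @return A list with `score` and `approximate` (the archived values after
#'   any update).
#' @export
evaluate_with_archive <- function(topology, behavior, coop,
                                  ranges = parameter_ranges(),
                                  config = ga_config(), archive,
                                  evaluator = approximate_fitness) {
  stopifnot(inherits(archive, "grn_archive"))
  rec <- archive_lookup(archive, topology)
  if (is.null(rec)) {
    res <- evaluator(topology, behavior, coop, ranges, config)
    archive_store(archive, topology, res$score, res$approximate)
  } else if (stats::runif(1) < config$reevaluate_prob) {
    res <- evaluator(topology, behavior, coop, ranges, config)
    archive_store(archive, topology, res$score, res$approximate)
  }
  rec <- archive_lookup(archive, topology)
  list(score = rec$fitness, approximate = rec$approximate)
}

#' Evolve a robust topology
#'
#' Genetic algorithm over `{-1, 0, 1}^(N x N)` topology matrices. The
#' population is initialized with uniformly random matrices and evaluated
#' through the archive; each generation, parents are chosen by tournament
#' selection, matings apply crossover with probability
#' `config$crossover_prob` (else clone) and mutation with probability
#' `config$mutation_prob`, and the resulting offspring replace the worst
#' `replacement_fraction` of the population. Survivors keep their scores.
#' After the final generation the archive-best topology is re-scored with a
#' full (non-approximate) Monte Carlo evaluation and returned.
#'
#' @param behavior an [oscillation_spec()] or [bistability_spec()].
#' @param coop Hill coefficient.
#' @param n_genes network size `N`.
#' @param ranges a [parameter_ranges()].
#' @param config a [ga_config()].
#' @param evaluator see [evaluate_with_archive()].
#' @param verbose print per-generation progress.
#' @return A list with `best` (list `topology`, `fitness`, `approximate`),
#'   `history` (data frame: generation, best and mean population fitness,
#'   cumulative evaluations, archive size) and the `archive`.
#' @export
evolve_topology <- function(behavior, coop, n_genes,
                            ranges = parameter_ranges(),
                            config = ga_config(),
                            evaluator = approximate_fitness,
                            verbose = FALSE) {
  stopifnot(inherits(behavior, "behavior_spec"), n_genes >= 1)
  coop <- .check_coop(coop)
  archive <- new_archive()
  n_evals <- 0L
  eval_counted <- function(top) {
    n_evals <<- n_evals + 1L
    evaluate_with_archive(top, behavior, coop, ranges, config, archive,
                          evaluator)
  }

  population <- lapply(seq_len(config$population_size), function(i) {
    top <- random_topology(n_genes)
    res <- eval_counted(top)
    list(topology = top, fitness = res$score, approximate = res$approximate)
  })

  n_offspring <- max(2L, as.integer(round(config$population_size *
                                            config$replacement_fraction)))
  history <- data.frame(generation = integer(0), best = numeric(0),
                        mean = numeric(0), evaluations = integer(0),
                        archive_size = integer(0))
  record <- function(gen) {
    fit <- vapply(population, `[[`, numeric(1), "fitness")
    history[nrow(history) + 1L, ] <<- list(gen, max(fit), mean(fit),
                                           n_evals, archive_size(archive))
  }
  record(0L)

  for (gen in seq_len(config$generations)) {
    offspring <- list()
    while (length(offspring) < n_offspring) {
      p1 <- tournament_select(population, config$tournament_size)
      p2 <- tournament_select(population, config$tournament_size)
      if (stats::runif(1) < config$crossover_prob) {
        kids <- crossover_topologies(p1$topology, p2$topology)
      } else {
        kids <- list(p1$topology, p2$topology)
      }
      for (kid in kids) {
        if (length(offspring) >= n_offspring) break
        kid <- mutate_topology(kid, config$mutation_prob,
                               config$mutation_mode)
        res <- eval_counted(kid)
        offspring[[length(offspring) + 1L]] <-
          list(topology = kid, fitness = res$score,
               approximate = res$approximate)
      }
    }
    fit <- vapply(population, `[[`, numeric(1), "fitness")
    keep <- order(fit, decreasing = TRUE)[
      seq_len(config$population_size - n_offspring)]
    population <- c(population[keep], offspring)
    record(gen)
    if (verbose) {
      message(sprintf("generation %d: best %.3f, archive %d", gen,
                      max(vapply(population, `[[`, numeric(1), "fitness")),
                      archive_size(archive)))
    }
  }

  # archive-best, finalized with a full (non-approximate) evaluation;
  # ties broken by discovery order (first topology to reach the score)
  keys <- ls(envir = archive)
  recs <- lapply(keys, get, envir = archive, inherits = FALSE)
  fits <- vapply(recs, `[[`, numeric(1), "fitness")
  ord <- vapply(recs, `[[`, numeric(1), "insert_order")
  best_idx <- which(fits == max(fits))
  best_idx <- best_idx[which.min(ord[best_idx])]
  best_key <- keys[best_idx]
  best_matrix <- matrix(as.integer(strsplit(best_key, ",")[[1]]), n_genes,
                        n_genes, byrow = TRUE)
  best_top <- grn_topology(best_matrix)
  cfg_final <- config
  cfg_final$approx_threshold <- 0  # probe never falls below: force full stage
  final <- evaluator(best_top, behavior, coop, ranges, cfg_final)
  archive_store(archive, best_top, final$score, approximate = FALSE)

  list(best = list(topology = best_top, fitness = final$score,
                   approximate = isTRUE(final$approximate)),
       history = history, archive = archive)
}
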