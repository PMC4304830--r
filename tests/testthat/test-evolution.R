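# cheap deterministic evaluator for GA mechanics tests: fitness = I (number
# of interactions), counting calls so archive savings are observable
make_counting_evaluator <- function() {
  calls <- new.env()
  calls$n <- 0L
  ev <- function(topology, behavior, coop, ranges, config) {
    calls$n <- calls$n + 1L
    list(score = sum(topology$matrix != 0L), approximate = FALSE)
  }
  list(evaluator = ev, calls = calls)
}

test_that("tournament selection returns the combinatorially expected winner", {
  pop <- lapply(c(10, 90, 20, 30, 40, 50, 60, 70, 80, 15), function(f) {
    list(topology = NULL, fitness = f)
  })
  set.seed(10)
  wins <- replicate(10000, tournament_select(pop, 5)$fitness == 90)
  expected <- oracle_tournament_top_prob(10, 5)  # = 1/2
  expect_equal(mean(wins), expected, tolerance = 0.03)

  # population of one; tie rule uniform over entrants
  expect_equal(tournament_select(list(list(fitness = 3)))$fitness, 3)
  tied <- lapply(1:6, function(i) list(id = i, fitness = 1))
  set.seed(11)
  picks <- replicate(6000, tournament_select(tied, 3)$id)
  expect_gt(stats::chisq.test(table(picks))$p.value, 0.01)
  expect_error(tournament_select(list()), "non-empty")
})

test_that("crossover exchanges contiguous blocks between parents", {
  p1 <- grn_topology(matrix(1L, 2, 2))
  p2 <- grn_topology(matrix(-1L, 2, 2))
  set.seed(12)
  seen <- character(0)
  for (rep in 1:50) {
    kids <- crossover_topologies(p1, p2)
    m1 <- kids[[1]]$matrix
    m2 <- kids[[2]]$matrix
    # with N=2 the only cuts are row 1 / col 1; enumerate the 2 outcomes
    horiz1 <- rbind(c(1L, 1L), c(-1L, -1L))
    vert1 <- cbind(c(1L, 1L), c(-1L, -1L))
    expect_true(all(m1 == horiz1) || all(m1 == vert1))
    # offspring 2 is the complement
    expect_true(all(m2 == -m1))
    seen <- c(seen, if (all(m1 == horiz1)) "h" else "v")
  }
  expect_setequal(unique(seen), c("h", "v"))

  # identical parents breed identical offspring whatever the cut
  kids <- crossover_topologies(p1, grn_topology(matrix(1L, 2, 2)))
  expect_true(topologies_equal(kids[[1]], p1))
  expect_true(topologies_equal(kids[[2]], p1))

  # every entry of an offspring comes from one of its parents
  set.seed(13)
  a <- random_topology(4)
  b <- random_topology(4)
  for (rep in 1:20) {
    kids <- crossover_topologies(a, b)
    for (kid in kids) {
      from_parent <- kid$matrix == a$matrix | kid$matrix == b$matrix
      expect_true(all(from_parent))
    }
  }
})

test_that("mutation changes exactly one entry, uniformly placed", {
  top <- grn_topology(matrix(0L, 3, 3))
  expect_true(topologies_equal(mutate_topology(top, mutation_prob = 0),
                               top))
  set.seed(14)
  hits <- integer(0)
  for (rep in 1:6000) {
    mut <- mutate_topology(top, mutation_prob = 1)
    diffs <- which(mut$matrix != top$matrix)
    expect_length(diffs, 1)
    expect_true(mut$matrix[diffs] %in% c(-1L, 1L))
    hits <- c(hits, diffs)
  }
  expect_gt(stats::chisq.test(table(factor(hits, levels = 1:9)))$p.value,
            0.01)
})

test_that("archive retains the maximum score and memoizes evaluations", {
  arc <- new_archive()
  top <- library_topology("toggle_switch")
  expect_null(archive_lookup(arc, top))
  archive_store(arc, top, 50, approximate = FALSE)
  archive_store(arc, top, 43, approximate = TRUE)
  expect_equal(archive_lookup(arc, top)$fitness, 50)
  archive_store(arc, top, 55, approximate = FALSE)
  expect_equal(archive_lookup(arc, top)$fitness, 55)
  expect_equal(archive_size(arc), 1)

  # memoization: second call with reevaluate_prob = 0 costs zero evaluations
  ce <- make_counting_evaluator()
  cfg <- ga_config(population_size = 4, probe_samples = 10,
                   full_samples = 20, reevaluate_prob = 0)
  arc2 <- new_archive()
  r1 <- evaluate_with_archive(top, bistability_spec(), 2, config = cfg,
                              archive = arc2, evaluator = ce$evaluator)
  n_after_first <- ce$calls$n
  r2 <- evaluate_with_archive(top, bistability_spec(), 2, config = cfg,
                              archive = arc2, evaluator = ce$evaluator)
  expect_equal(ce$calls$n, n_after_first)
  expect_identical(r1$score, r2$score)

  # reevaluate_prob = 1 re-runs and keeps the maximum
  cfg1 <- ga_config(population_size = 4, probe_samples = 10,
                    full_samples = 20, reevaluate_prob = 1)
  noisy <- local({
    vals <- c(50, 43, 55)
    i <- 0
    function(topology, behavior, coop, ranges, config) {
      i <<- i + 1
      list(score = vals[i], approximate = FALSE)
    }
  })
  arc3 <- new_archive()
  s <- vapply(1:3, function(i) {
    evaluate_with_archive(top, bistability_spec(), 2, config = cfg1,
                          archive = arc3, evaluator = noisy)$score
  }, numeric(1))
  expect_equal(s, c(50, 50, 55))
})

test_that("approximate_fitness early-exits below the threshold", {
  cfg <- ga_config(probe_samples = 30, full_samples = 200,
                   approx_threshold = 10)
  empty <- grn_topology(matrix(0L, 2, 2))
  set.seed(15)
  res <- approximate_fitness(empty, oscillation_spec(), 2, config = cfg)
  expect_true(res$approximate)
  expect_equal(res$score, 0)

  # toggle bistability ~ 40-50% >= threshold: full evaluation
  set.seed(16)
  res2 <- approximate_fitness(library_topology("toggle_switch"),
                              bistability_spec(), 2, config = cfg)
  expect_false(res2$approximate)

  # threshold 0 disables approximation entirely
  cfg0 <- ga_config(probe_samples = 30, full_samples = 100,
                    approx_threshold = 0)
  set.seed(17)
  res3 <- approximate_fitness(empty, oscillation_spec(), 2, config = cfg0)
  expect_false(res3$approximate)
})

test_that("GA mechanics: constant population, monotone best, determinism", {
  ce <- make_counting_evaluator()
  cfg <- ga_config(population_size = 12, generations = 8,
                   probe_samples = 5, full_samples = 10,
                   reevaluate_prob = 0.15)
  set.seed(18)
  run <- evolve_topology(bistability_spec(), 2, n_genes = 3, config = cfg,
                         evaluator = ce$evaluator)
  # fitness = interaction count; optimum is the full matrix with I = 9
  expect_true(all(diff(run$history$best) >= 0))
  expect_equal(nrow(run$history), 9)  # generation 0..8
  expect_gte(min(run$history$mean), 0)
  expect_equal(run$best$fitness, sum(run$best$topology$matrix != 0L))
  expect_gte(run$best$fitness, 8)

  set.seed(18)
  ce2 <- make_counting_evaluator()
  run2 <- evolve_topology(bistability_spec(), 2, n_genes = 3, config = cfg,
                          evaluator = ce2$evaluator)
  expect_identical(run$history, run2$history)
  expect_true(topologies_equal(run$best$topology, run2$best$topology))
})

test_that("archive bounds full evaluations by the size of the search space", {
  # N = 2: 3^4 = 81 possible topologies; distinct evaluator calls cannot
  # exceed 81 plus re-evaluations, and the archive never exceeds 81 keys
  ce <- make_counting_evaluator()
  cfg <- ga_config(population_size = 20, generations = 10,
                   probe_samples = 5, full_samples = 10,
                   reevaluate_prob = 0)
  set.seed(19)
  run <- evolve_topology(oscillation_spec(), 2, n_genes = 2, config = cfg,
                         evaluator = ce$evaluator)
  expect_lte(archive_size(run$archive), 81)
  # with reevaluate_prob = 0, evaluator calls == distinct topologies seen
  # (+1 for the final full re-score of the best individual)
  expect_lte(ce$calls$n, 81)
})

test_that("scaled-down GA recovers the toggle switch for bistability", {
  cfg <- ga_config(population_size = 20, generations = 6,
                   probe_samples = 100, full_samples = 400,
                   approx_threshold = 5, reevaluate_prob = 0.15)
  toggle_key <- canonical_topology_key(library_topology("toggle_switch"))
  set.seed(20)
  run <- evolve_topology(bistability_spec(), 2, n_genes = 2, config = cfg)
  expect_identical(canonical_topology_key(run$best$topology), toggle_key)
  expect_gt(run$best$fitness, 20)
})
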