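# helper: wrap a matrix of concentrations as a trajectory object
as_traj <- function(times, conc, dt_out = 1) {
  structure(list(times = times, concentrations = as.matrix(conc),
                 ok = TRUE, dt_out = dt_out), class = "grn_trajectory")
}

test_that("peak detection: constants and monotone series have no peaks", {
  t <- 0:500
  expect_equal(nrow(detect_peaks(rep(5, 501), t)), 0)
  expect_equal(nrow(detect_peaks(seq(0, 50, length.out = 501), t)), 0)
})

test_that("peak detection counts and measures a synthetic sine", {
  t <- 300:2100
  y <- 50 + 40 * sin(2 * pi * t / 100)
  pk <- detect_peaks(y, t, prominence = 0.5)
  expect_equal(nrow(pk), 18)  # floor(1800 / 100)
  expect_true(all(abs(pk$height - 90) < 0.5))
  # amplitude = height minus mean adjacent inter-peak troughs = ~80
  expect_true(all(abs(pk$amplitude - 80) < 0.5))
  # ordered by time, one per period
  expect_true(all(diff(pk$time) > 95 & diff(pk$time) < 105))
})

test_that("oscillation score: constant trajectory scores zero", {
  t <- 0:2100
  tr <- as_traj(t, cbind(rep(100, 2101), rep(3, 2101)))
  out <- oscillation_score(tr)
  expect_false(out$satisfied)
  expect_equal(out$score, 0)
})

test_that("oscillation score saturates at SD_max for a large sustained sine", {
  t <- 0:2100
  spec <- oscillation_spec(sd_cap = 10)
  conc <- cbind(100 + 80 * sin(2 * pi * t / 150),
                100 + 80 * cos(2 * pi * t / 150))
  out <- oscillation_score(as_traj(t, conc), spec)
  expect_true(out$satisfied)
  expect_equal(out$score, 10, tolerance = 1e-6)
  expect_equal(unname(out$per_gene_scores), c(10, 10), tolerance = 1e-6)
})

test_that("damped oscillation is penalized below the threshold", {
  t <- 0:2100
  # amplitude halves every 300 min after the transient window
  env <- 80 * 2^(-(t - 300) / 300)
  y <- 100 + env * sin(2 * pi * t / 150)
  out <- oscillation_score(as_traj(t, cbind(y, y)))
  pk <- detect_peaks(y[t >= 300], t[t >= 300])
  # amplitudes decay monotonically, so PN = 0.1 and LC = last/first
  expect_true(all(diff(pk$amplitude) < 0))
  lc <- pk$amplitude[nrow(pk)] / pk$amplitude[1]
  expect_false(out$satisfied)
  expect_equal(out$score, 10 * lc * 0.1, tolerance = 1e-6)
  expect_lt(out$score, 5)
  expect_gt(out$score, 0)
})

test_that("oscillation score is invariant under gene relabeling", {
  t <- 0:2100
  conc <- cbind(100 + 30 * sin(2 * pi * t / 120),
                50 + 15 * sin(2 * pi * t / 90 + 1),
                200 + 60 * cos(2 * pi * t / 200))
  s1 <- oscillation_score(as_traj(t, conc))
  s2 <- oscillation_score(as_traj(t, conc[, c(3, 1, 2)]))
  expect_equal(s1$score, s2$score)
  expect_identical(s1$satisfied, s2$satisfied)
})

test_that("score never exceeds SD_max and satisfaction implies positivity", {
  t <- 0:2100
  set.seed(14)
  for (rep in 1:10) {
    amp <- runif(1, 0.5, 100)
    per <- runif(1, 40, 400)
    level <- runif(1, amp, amp + 200)
    y <- level + amp * sin(2 * pi * t / per)
    out <- oscillation_score(as_traj(t, cbind(y)))
    expect_lte(out$score, 10 + 1e-9)
    if (out$satisfied) expect_gt(out$score, 0)
  }
})

test_that("toggle switch with strong mutual repression is bistable", {
  top <- library_topology("toggle_switch")
  out <- bistability_satisfied(top, strong_toggle_params(), 2)
  expect_true(out$satisfied)
  expect_lte(out$max_fluctuation, 0.01)
})

test_that("bistability verdict is symmetric in the probe genes", {
  top <- library_topology("toggle_switch")
  set.seed(21)
  for (rep in 1:20) {
    p <- sample_parameters(top)
    v1 <- bistability_satisfied(top, p, 2)$satisfied
    # relabel the genes: swap rows/cols of the matrix and the rate vectors,
    # rebuilding the threshold vector in the swapped row-major order
    swapped <- grn_topology(top$matrix[c(2, 1), c(2, 1)])
    km <- matrix(0, 2, 2)
    km[t(top$matrix) != 0] <- p$thresholds
    km <- t(km)           # km[i, j] = threshold of edge j -> i
    km2 <- km[c(2, 1), c(2, 1)]
    th2 <- t(km2)[t(swapped$matrix) != 0]
    p2 <- kinetic_parameters(p$basal_rates[c(2, 1)],
                             p$degradation_rates[c(2, 1)], th2)
    v2 <- bistability_satisfied(swapped, p2, 2)$satisfied
    expect_identical(v1, v2)
  }
})

test_that("symmetric uncoupled genes fail the strict ordering condition", {
  top <- grn_topology(matrix(0L, 2, 2))
  p <- kinetic_parameters(c(50, 50), c(0.1, 0.1))
  out <- bistability_satisfied(top, p, 2)
  expect_false(out$satisfied)
})

test_that("a sustained oscillator cannot satisfy the bistability band", {
  top <- library_topology("repressilator")
  # asymmetric rates: a fully symmetric parameter set would stay on the
  # invariant diagonal manifold and never leave the unstable fixed point
  p <- kinetic_parameters(c(60, 55, 65), c(0.10, 0.09, 0.11),
                          thresholds = c(40, 35, 45))
  tr <- simulate_grn(top, p, 3, rep(1, 3), t_end = 2100)
  osc <- oscillation_score(tr)
  expect_true(osc$satisfied)
  bst <- bistability_satisfied(top, p, 3)
  expect_false(bst$satisfied)
  expect_gt(bst$max_fluctuation, 0.01)
})

test_that("quantitative deviation implements the satisfied/else-zero rule", {
  expect_equal(quantitative_deviation(10, 10, TRUE), 0)
  expect_equal(quantitative_deviation(10, 4, FALSE), 0)
  expect_equal(quantitative_deviation(10, 4, TRUE), 6)
})

test_that("behavior specs rebuild from flat config lists", {
  sp <- behavior_spec_from_config(list(behavior = "oscillation",
                                       sd_max = 25, peak_prominence = 1))
  expect_s3_class(sp, "oscillation_spec")
  expect_equal(sp$sd_max, 25)
  expect_equal(sp$satisfaction_threshold, 12.5)
  sp2 <- behavior_spec_from_config(list(behavior = "bistability",
                                        fluctuation_tolerance = 0.05))
  expect_s3_class(sp2, "bistability_spec")
  expect_equal(sp2$fluctuation_tolerance, 0.05)
  expect_error(behavior_spec_from_config(list(behavior = "chaos")),
               "oscillation")
})
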