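test_that("PRC of a null perturbation is zero at every phase", {
  top <- library_topology("delayed_negative_feedback_3")
  prc <- phase_response_curve(top, dnf_osc_params(), 3, pulse_nM = 0,
                              n_phases = 8)
  expect_equal(nrow(prc$curve), 8)
  expect_lt(max(abs(prc$curve$shift_rad)), 1e-4)
  expect_true(all(abs(prc$curve$shift_rad) <= pi))
})

test_that("PRC period matches the unperturbed inter-peak spacing", {
  top <- library_topology("delayed_negative_feedback_3")
  p <- dnf_osc_params()
  prc <- phase_response_curve(top, p, 3, pulse_nM = 5, n_phases = 4)
  spec <- oscillation_spec()
  tr <- simulate_grn(top, p, 3, rep(1, 3), spec$t_end)
  w <- tr$times >= spec$stabilization_skip
  pk <- detect_peaks(tr$concentrations[w, 1], tr$times[w])
  expect_equal(prc$period, mean(diff(pk$time)), tolerance = 0.01)
})

test_that("PRC shifts are converged in the settling horizon", {
  top <- library_topology("delayed_negative_feedback_3")
  p <- dnf_osc_params()
  a <- phase_response_curve(top, p, 3, pulse_nM = 10, n_phases = 6,
                            settle_periods = 20)
  b <- phase_response_curve(top, p, 3, pulse_nM = 10, n_phases = 6,
                            settle_periods = 40)
  expect_lt(max(abs(a$curve$shift_rad - b$curve$shift_rad)), 0.01)
})

test_that("higher cooperativity gives a flatter PRC on the same parameters", {
  top <- library_topology("delayed_negative_feedback_3")
  p <- dnf_osc_params()
  prc3 <- phase_response_curve(top, p, 3, pulse_nM = 10)
  prc4 <- phase_response_curve(top, p, 4, pulse_nM = 10)
  expect_lt(max(abs(prc4$curve$shift_rad)), max(abs(prc3$curve$shift_rad)))
})

test_that("PRC refuses a non-oscillating parameter set", {
  top <- library_topology("toggle_switch")
  expect_error(phase_response_curve(top, strong_toggle_params(), 2),
               "limit cycle")
})

test_that("PRC CSV export carries the documented columns", {
  top <- library_topology("delayed_negative_feedback_3")
  prc <- phase_response_curve(top, dnf_osc_params(), 3, pulse_nM = 5,
                              n_phases = 4)
  f <- tempfile(fileext = ".csv")
  write_prc_csv(prc, f)
  expect_identical(readLines(f, n = 1), "phase_rad,shift_rad")
  unlink(f)
})

test_that("comparison reports are sorted, complete and order-invariant", {
  tops <- list(repressilator = library_topology("repressilator"),
               delayed_nf = library_topology("delayed_negative_feedback_3"))
  set.seed(55)
  rep1 <- compare_topologies(tops, oscillation_spec(), c(4, 3),
                             n_samples = 120, n_repeats = 2)
  expect_equal(nrow(rep1), 4)
  expect_identical(rep1$topology, c("delayed_nf", "delayed_nf",
                                    "repressilator", "repressilator"))
  expect_identical(rep1$n, c(3L, 4L, 3L, 4L))
  expect_equal(rep1$I, rep(3L, 4))
  expect_equal(rep1$K, rep(1, 4))

  set.seed(55)
  rep2 <- compare_topologies(rev(tops), oscillation_spec(), c(3, 4),
                             n_samples = 120, n_repeats = 2)
  expect_identical(rep1$topology, rep2$topology)
  expect_identical(rep1$n, rep2$n)

  txt <- format_comparison(rep1)
  expect_match(txt, "repressilator")
  f <- tempfile(fileext = ".csv")
  write_comparison_csv(rep1, f)
  back <- utils::read.csv(f)
  expect_equal(back$robustness, rep1$robustness)
  unlink(f)
})

test_that("a single-cell comparison equals a direct verification call", {
  top <- list(toggle = library_topology("toggle_switch"))
  set.seed(66)
  rep1 <- compare_topologies(top, bistability_spec(), 2, n_samples = 150,
                             n_repeats = 2)
  set.seed(66)
  direct <- verify_robustness(library_topology("toggle_switch"),
                              bistability_spec(), 2, n_samples = 150,
                              n_repeats = 2)
  expect_equal(rep1$robustness, direct$score)
  expect_equal(rep1$sd, direct$replicate_sd)
})

test_that("command-line interface runs the cheap subcommands", {
  cli <- system.file("scripts", "grn-design.R", package = "grndesign")
  skip_if(cli == "", "CLI script not installed")
  rscript <- file.path(R.home("bin"), "Rscript")
  tsv <- tempfile(fileext = ".tsv")
  write_topology_tsv(library_topology("evolved_oscillator_4"), tsv)

  out_json <- tempfile(fileext = ".json")
  status <- system2(rscript, c(cli, "complexity", "--topology", tsv,
                               "--out", out_json))
  expect_equal(status, 0)
  res <- jsonlite::fromJSON(out_json)
  expect_equal(res$I, 5)
  expect_equal(round(res$c, 2), 0.31)

  out_csv <- tempfile(fileext = ".csv")
  status <- system2(rscript, c(cli, "simulate", "--topology", tsv,
                               "--n", "3", "--t-end", "50", "--seed", "4",
                               "--out", out_csv))
  expect_equal(status, 0)
  expect_identical(substr(readLines(out_csv, n = 1), 1, 8), "time_min")

  out_rob <- tempfile(fileext = ".json")
  status <- system2(rscript, c(cli, "robustness", "--topology", tsv,
                               "--behavior", "bistability", "--n", "2",
                               "--samples", "25", "--seed", "9",
                               "--out", out_rob))
  expect_equal(status, 0)
  rob <- jsonlite::fromJSON(out_rob)
  expect_true(all(c("score", "n_satisfied", "n_samples", "semantics",
                    "seed") %in% names(rob)))
  expect_equal(rob$n_samples, 25)

  # --seed makes reruns bit-identical
  out_rob2 <- tempfile(fileext = ".json")
  system2(rscript, c(cli, "robustness", "--topology", tsv,
                     "--behavior", "bistability", "--n", "2",
                     "--samples", "25", "--seed", "9", "--out", out_rob2))
  expect_identical(readLines(out_rob2), readLines(out_rob))
  unlink(c(tsv, out_json, out_csv, out_rob, out_rob2))
})
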