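#' Monte Carlo robustness of a topology
#'
#' Estimates topological robustness by drawing `n_samples` kinetic-parameter
#' sets independently and uniformly from their ranges (all perturbations
#' equiprobable) and evaluating the target behavior for each. Under Boolean
#' semantics the estimate is the percentage of parameter sets preserving the
#' behavior; under quantitative semantics it is the accumulated absolute
#' deviation `|f_a(0) - f_a(p)|` over behavior-preserving sets, with the
#' unperturbed reference `f_a(0)` taken as the topology's behavior score
#' under the midpoint parameter set (every parameter at its range midpoint).
#' Integrator failures count as behavior-not-satisfied. Sampling consumes R's
#' global RNG sequentially, so a fixed seed reproduces the estimate
#' bit-exactly; draw order per sample is `a_i` (genes in order), `b_i`, then
#' edge thresholds row-major.
#'
#' @param topology a [grn_topology()].
#' @param behavior an [oscillation_spec()] or [bistability_spec()].
#' @param coop Hill coefficient applied to every regulation.
#' @param ranges a [parameter_ranges()].
#' @param n_samples number of Monte Carlo perturbations (default 10000).
#' @param semantics `"boolean"` or `"quantitative"`.
#' @param dt_out,rtol,atol integration controls.
#' @return An object of class `robustness_estimate` with `score` (percent
#'   for Boolean, accumulated deviation for quantitative), `n_samples`,
#'   `n_satisfied`, `n_failed`, `semantics` and, for quantitative runs,
#'   `reference_score`.
#' @examples
#' \donttest{
#' set.seed(1)
#' estimate_robustness(library_topology("toggle_switch"),
#'                     bistability_spec(), coop = 2, n_samples = 200)
#' }
#' @export
estimate_robustness <- function(topology, behavior, coop,
                                ranges = parameter_ranges(),
                                n_samples = 10000,
                                semantics = c("boolean", "quantitative"),
                                dt_out = 1, rtol = 1e-6, atol = 1e-8) {
  stopifnot(inherits(topology, "grn_topology"),
            inherits(behavior, "behavior_spec"),
            inherits(ranges, "parameter_ranges"), n_samples >= 1)
  semantics <- match.arg(semantics)
  coop <- .check_coop(coop)

  ref <- 0
  if (semantics == "quantitative") {
    ref <- .reference_score(topology, behavior, coop, ranges, dt_out,
                            rtol, atol)
  }
  res <- .mc_robustness_cpp(topology$matrix, coop, ranges$basal_range,
                            ranges$degradation_range,
                            ranges$threshold_range, as.integer(n_samples),
                            behavior$behavior, behavior, ref, dt_out,
                            rtol, atol)
  score <- if (semantics == "boolean") {
    100 * res$n_satisfied / res$n_samples
  } else {
    res$sum_deviation
  }
  structure(list(score = score, n_samples = res$n_samples,
                 n_satisfied = res$n_satisfied, n_failed = res$n_failed,
                 semantics = semantics,
                 reference_score = if (semantics == "quantitative") ref,
                 behavior = behavior$behavior, coop = coop,
                 replicate_sd = NULL),
            class = "robustness_estimate")
}

# unperturbed reference f_a(0): behavior score at the midpoint parameter set
.reference_score <- function(topology, behavior, coop, ranges, dt_out,
                             rtol, atol) {
  mid <- midpoint_parameters(topology, ranges)
  if (inherits(behavior, "oscillation_spec")) {
    tr <- simulate_grn(topology, mid, coop,
                       rep(behavior$initial_concentration,
                           topology$n_genes),
                       behavior$t_end, dt_out, rtol, atol)
    oscillation_score(tr, behavior)$score
  } else {
    bistability_satisfied(topology, mid, coop, behavior, dt_out, rtol,
                          atol)$score
  }
}

#' Replicated robustness verification
#'
#' Repeats [estimate_robustness()] `n_repeats` times (fresh draws each
#' repeat, continuing the RNG stream) and reports the mean score with the
#' spread across repeats; the verification protocol used when comparing
#' topologies.
#'
#' @inheritParams estimate_robustness
#' @param n_samples samples per repeat (default 100000).
#' @param n_repeats number of repeats (default 10).
#' @return A `robustness_estimate` whose `score` is the mean across repeats,
#'   with `replicate_sd` and the per-repeat `replicate_scores`.
#' @export
verify_robustness <- function(topology, behavior, coop,
                              ranges = parameter_ranges(),
                              n_samples = 100000, n_repeats = 10,
                              semantics = c("boolean", "quantitative"),
                              dt_out = 1, rtol = 1e-6, atol = 1e-8) {
  stopifnot(n_repeats >= 1)
  semantics <- match.arg(semantics)
  reps <- lapply(seq_len(n_repeats), function(i) {
    estimate_robustness(topology, behavior, coop, ranges, n_samples,
                        semantics, dt_out, rtol, atol)
  })
  scores <- vapply(reps, `[[`, numeric(1), "score")
  out <- reps[[1]]
  out$score <- mean(scores)
  out$replicate_sd <- if (n_repeats > 1) stats::sd(scores) else NA_real_
  out$replicate_scores <- scores
  out$n_repeats <- n_repeats
  out$n_satisfied <- sum(vapply(reps, `[[`, numeric(1), "n_satisfied"))
  out$n_failed <- sum(vapply(reps, `[[`, numeric(1), "n_failed"))
  out$n_samples <- n_samples
  out
}

#' @export
print.robustness_estimate <- function(x, ...) {
  unit <- if (x$semantics == "boolean") "%" else " (accumulated deviation)"
  cat(sprintf("%s robustness (%s): %.4g%s over %d samples%s\n",
              x$behavior, x$semantics, x$score, unit, x$n_samples,
              if (!is.null(x$replicate_sd) && !is.na(x$replicate_sd)) {
                sprintf(" x %d repeats (SD %.3g)", x$n_repeats,
                        x$replicate_sd)
              } else ""))
  invisible(x)
}
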