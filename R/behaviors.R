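#' Oscillation behavior specification
#'
#' Protocol and scoring constants for detecting sustained oscillation. A
#' 2100-minute time series is generated from 1 nM initial concentration per
#' gene; the first 300 minutes are discarded as a stabilization transient.
#' Each gene's series is scored as `f_osc = min(SD, sd_max) * LC * PN`, where
#' `SD` is the standard deviation over the scoring window, `LC` compares the
#' amplitudes of the first and last detected peaks (1 for a perfect limit
#' cycle, 0 with fewer than two peaks) and `PN` penalizes damped oscillation.
#' The system satisfies the behavior when the average `f_osc` across genes
#' reaches `satisfaction_threshold` (= `sd_max / 2`) and every gene shows at
#' least two peaks.
#'
#' @param t_end simulation horizon, minutes.
#' @param stabilization_skip transient to drop before scoring, minutes.
#' @param initial_concentration per-gene initial value, nM.
#' @param sd_cap cap `SD_max` on the standard-deviation term, nM. The score
#'   of a perfect oscillation saturates at this value.
#' @param damping_penalty_factor multiplicative penalty `PN` applied when the
#'   peak-amplitude sequence decays monotonically by more than
#'   `damping_rel_drop` from first to last peak.
#' @param damping_rel_drop relative first-to-last amplitude drop treated as
#'   damping.
#' @param peak_prominence minimum peak prominence, nM (suppresses integrator
#'   ripple).
#' @param satisfaction_threshold score needed to count the behavior as
#'   preserved; defaults to `sd_cap / 2`.
#' @return An object of class `oscillation_spec`.
#' @export
oscillation_spec <- function(t_end = 2100, stabilization_skip = 300,
                             initial_concentration = 1, sd_cap = 10,
                             damping_penalty_factor = 0.1,
                             damping_rel_drop = 0.05,
                             peak_prominence = 0.5,
                             satisfaction_threshold = sd_cap / 2) {
  stopifnot(stabilization_skip >= 0, stabilization_skip < t_end,
            sd_cap > 0, satisfaction_threshold > 0,
            satisfaction_threshold <= sd_cap,
            damping_penalty_factor >= 0, damping_penalty_factor <= 1,
            peak_prominence >= 0)
  structure(list(behavior = "oscillation", t_end = t_end,
                 stabilization_skip = stabilization_skip,
                 initial_concentration = initial_concentration,
                 sd_max = sd_cap,
                 damping_penalty_factor = damping_penalty_factor,
                 damping_rel_drop = damping_rel_drop,
                 peak_prominence = peak_prominence,
                 satisfaction_threshold = satisfaction_threshold),
            class = c("oscillation_spec", "behavior_spec"))
}

#' Bistability behavior specification
#'
#' Protocol for the paired-initialization bistability test: two 600-minute
#' simulations, the first with `G0 = 100`, `G1 = 300` nM (all other genes
#' 200 nM), the second with `G0` and `G1` swapped. The system is bistable if
#' in both runs (i) `G0` and `G1` each fluctuate by at most
#' `fluctuation_tolerance` over the 400-600 min window and (ii) the gene
#' initialized higher settles strictly higher than the gene initialized
#' lower.
#'
#' @param t_end simulation horizon, minutes.
#' @param check_window length-2 window (minutes) over which fluctuation and
#'   the level ordering are assessed.
#' @param high_init,low_init,other_init initial concentrations, nM.
#' @param fluctuation_tolerance maximum allowed max-minus-min excursion of
#'   each probe gene over the window, nM.
#' @return An object of class `bistability_spec`.
#' @export
bistability_spec <- function(t_end = 600, check_window = c(400, 600),
                             high_init = 300, low_init = 100,
                             other_init = 200,
                             fluctuation_tolerance = 0.01) {
  stopifnot(length(check_window) == 2, check_window[1] >= 0,
            check_window[1] < check_window[2], check_window[2] <= t_end,
            high_init > low_init, fluctuation_tolerance > 0)
  structure(list(behavior = "bistability", t_end = t_end,
                 check_window = as.numeric(check_window),
                 high_init = high_init, low_init = low_init,
                 other_init = other_init,
                 fluctuation_tolerance = fluctuation_tolerance),
            class = c("bistability_spec", "behavior_spec"))
}

#' Build a behavior spec from a configuration list
#'
#' Accepts the flat key set used by the config files of the command-line
#' tools: `behavior` (`"oscillation"` or `"bistability"`) plus any of
#' `sd_max`, `damping_penalty_factor`, `peak_prominence`,
#' `fluctuation_tolerance`, `t_end`, `stabilization_skip`, `check_window`.
#'
#' @param config a named list (e.g. from a parsed YAML/JSON file).
#' @return An [oscillation_spec()] or [bistability_spec()].
#' @export
behavior_spec_from_config <- function(config) {
  behavior <- config$behavior
  if (is.null(behavior) ||
      !behavior %in% c("oscillation", "bistability")) {
    stop("config$behavior must be 'oscillation' or 'bistability'",
         call. = FALSE)
  }
  pick <- function(key, default) {
    if (!is.null(config[[key]])) config[[key]] else default
  }
  if (behavior == "oscillation") {
    oscillation_spec(
      t_end = pick("t_end", 2100),
      stabilization_skip = pick("stabilization_skip", 300),
      sd_cap = pick("sd_max", 10),
      damping_penalty_factor = pick("damping_penalty_factor", 0.1),
      peak_prominence = pick("peak_prominence", 0.5)
    )
  } else {
    bistability_spec(
      t_end = pick("t_end", 600),
      check_window = unlist(pick("check_window", c(400, 600))),
      fluctuation_tolerance = pick("fluctuation_tolerance", 0.01)
    )
  }
}

#' Detect peaks in a concentration series
#'
#' Strict local maxima filtered by prominence (height above the higher of
#' the two adjacent inter-peak minima), ordered by time. Each retained peak
#' also carries an amplitude: its height minus the mean of its adjacent
#' inter-peak troughs (edge peaks use their single inter-peak trough; a lone
#' peak falls back to the window minimum).
#'
#' @param series numeric concentration series.
#' @param times matching time grid (minutes).
#' @param prominence minimum prominence, nM.
#' @return A data frame with columns `time`, `height`, `amplitude` (zero
#'   rows when no peak qualifies).
#' @export
detect_peaks <- function(series, times, prominence = 0.5) {
  stopifnot(length(series) == length(times))
  res <- .detect_peaks_cpp(as.numeric(series), as.numeric(times),
                           prominence)
  data.frame(time = res$time, height = res$height,
             amplitude = res$amplitude)
}

#' Score a trajectory for sustained oscillation
#'
#' Applies the `f_osc = min(SD, SD_max) * LC * PN` score per gene over the
#' post-transient window and averages across genes (see
#' [oscillation_spec()]). Non-evaluable trajectories score 0 and are not
#' satisfied.
#'
#' @param trajectory a [simulate_grn()] result covering `[0, t_end]`.
#' @param spec an [oscillation_spec()].
#' @return A `behavior_outcome` list: `satisfied`, `score` (mean `f_osc`),
#'   `per_gene_scores`, `n_peaks` per gene and `all_oscillating` (whether
#'   every gene had at least two peaks).
#' @export
oscillation_score <- function(trajectory, spec = oscillation_spec()) {
  stopifnot(inherits(trajectory, "grn_trajectory"),
            inherits(spec, "oscillation_spec"))
  if (!isTRUE(trajectory$ok)) {
    return(structure(list(satisfied = FALSE, score = 0,
                          per_gene_scores = NULL, n_peaks = NULL,
                          all_oscillating = FALSE),
                     class = "behavior_outcome"))
  }
  if (max(trajectory$times) < spec$t_end - 1e-9) {
    stop("trajectory must cover [0, t_end] of the oscillation spec",
         call. = FALSE)
  }
  res <- .osc_score_cpp(trajectory$concentrations, trajectory$dt_out, spec)
  structure(list(satisfied = res$satisfied, score = res$score,
                 per_gene_scores = stats::setNames(
                   res$per_gene_scores, colnames(trajectory$concentrations)),
                 n_peaks = res$n_peaks,
                 all_oscillating = res$all_oscillating),
            class = "behavior_outcome")
}

#' Paired-initialization bistability test
#'
#' Runs the two swapped-initialization simulations described in
#' [bistability_spec()] and applies the fluctuation and ordering criteria to
#' probe genes `G0` and `G1` (the first two genes). Integrator failure in
#' either run yields `satisfied = FALSE`.
#'
#' @param topology a [grn_topology()] with at least two genes.
#' @param params a matching [kinetic_parameters()].
#' @param coop Hill coefficient.
#' @param spec a [bistability_spec()].
#' @param dt_out,rtol,atol integration controls (see [simulate_grn()]).
#' @return A `behavior_outcome` list: `satisfied`, `score` (1 if satisfied
#'   else 0) and `max_fluctuation` of the probe genes over the window.
#' @export
bistability_satisfied <- function(topology, params, coop,
                                  spec = bistability_spec(), dt_out = 1,
                                  rtol = 1e-6, atol = 1e-8) {
  stopifnot(inherits(topology, "grn_topology"),
            inherits(params, "kinetic_parameters"),
            inherits(spec, "bistability_spec"))
  if (topology$n_genes < 2) {
    stop("bistability requires at least two genes", call. = FALSE)
  }
  .check_params_topology(params, topology)
  coop <- .check_coop(coop)
  res <- .bistable_cpp(topology$matrix, params$basal_rates,
                       params$degradation_rates, params$thresholds, coop,
                       spec, dt_out, rtol, atol)
  structure(list(satisfied = res$satisfied,
                 score = as.numeric(res$satisfied),
                 max_fluctuation = res$max_fluctuation,
                 evaluable = res$evaluable),
            class = "behavior_outcome")
}

#' Quantitative behavior deviation
#'
#' The quantitative robustness semantics accumulates
#' `|f_a(0) - f_a(p)|` over perturbations that still satisfy the behavior
#' criterion, and 0 otherwise.
#'
#' @param reference_score unperturbed behavior score `f_a(0)` (>= 0).
#' @param perturbed_score perturbed behavior score `f_a(p)` (>= 0).
#' @param satisfied whether the perturbed system satisfies the criterion.
#' @return A nonnegative deviation.
#' @export
quantitative_deviation <- function(reference_score, perturbed_score,
                                   satisfied) {
  stopifnot(reference_score >= 0, perturbed_score >= 0)
  if (isTRUE(satisfied)) abs(reference_score - perturbed_score) else 0
}

#' @export
print.behavior_outcome <- function(x, ...) {
  cat(sprintf("behavior outcome: %s (score %.4g)\n",
              if (x$satisfied) "satisfied" else "not satisfied", x$score))
  invisible(x)
}
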