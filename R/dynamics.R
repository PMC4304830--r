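#' Hill-kinetics ODE right-hand side
#'
#' Evaluates the production/decay rate of every gene at a given state. Gene
#' `i` is produced at its basal rate `a_i` multiplied by one Hill factor per
#' regulator -- `K^n / (G_j^n + K^n)` for an inhibitor `j`,
#' `G_k^n / (G_k^n + Ka^n)` for an activator `k`, all regulators acting
#' independently -- and degraded linearly at rate `b_i G_i`. Empty products
#' equal 1, so an unregulated gene is produced at `a_i`. All Hill factors lie
#' in (0, 1\], hence production never exceeds `a_i` and trajectories started
#' nonnegative remain in `[0, max(a_i / b_i)]`.
#'
#' @param topology a [grn_topology()].
#' @param params a [kinetic_parameters()] matching the topology.
#' @param coop Hill coefficient `n >= 1`, applied uniformly to every
#'   regulation.
#' @param state numeric vector of `N` nonnegative concentrations (nM).
#' @return Numeric vector of `N` rates (nM/min).
#' @export
grn_derivative <- function(topology, params, coop, state) {
  stopifnot(inherits(topology, "grn_topology"),
            inherits(params, "kinetic_parameters"))
  .check_params_topology(params, topology)
  coop <- .check_coop(coop)
  state <- as.numeric(state)
  if (length(state) != topology$n_genes || any(!is.finite(state)) ||
      any(state < 0)) {
    stop("state must hold one finite nonnegative concentration per gene",
         call. = FALSE)
  }
  out <- .derivative_cpp(topology$matrix, params$basal_rates,
                         params$degradation_rates, params$thresholds,
                         coop, state)
  stats::setNames(out, topology$genes)
}

#' Simulate a GRN trajectory
#'
#' Integrates the Hill-kinetics ODE system with an adaptive explicit
#' Dormand-Prince 5(4) scheme (relative tolerance `1e-6`, absolute `1e-8` by
#' default) and samples the solution on a regular grid `0..t_end` with
#' spacing `dt_out`. Tiny negative integrator output is clipped to 0. If the
#' integrator fails (step-size underflow or non-finite state) the returned
#' trajectory is flagged non-evaluable (`ok = FALSE`, concentrations `NA`);
#' behavior detectors treat such trajectories as behavior-not-satisfied.
#'
#' @inheritParams grn_derivative
#' @param initial_state numeric vector of `N` nonnegative concentrations (nM).
#' @param t_end simulation horizon in minutes.
#' @param dt_out output grid spacing in minutes (default 1, the grid the
#'   behavior detectors operate on).
#' @param rtol,atol integrator tolerances.
#' @return An object of class `grn_trajectory` with elements `times`
#'   (minutes), `concentrations` (grid x genes matrix, nM) and `ok`.
#' @examples
#' top <- grn_topology(matrix(0L, 1, 1))
#' par <- kinetic_parameters(10, 0.1)
#' tr <- simulate_grn(top, par, coop = 2, initial_state = 0, t_end = 50)
#' tail(tr$concentrations, 1)  # approaches a/b = 100 nM
#' @export
simulate_grn <- function(topology, params, coop, initial_state,
                         t_end, dt_out = 1, rtol = 1e-6, atol = 1e-8) {
  stopifnot(inherits(topology, "grn_topology"),
            inherits(params, "kinetic_parameters"))
  .check_params_topology(params, topology)
  coop <- .check_coop(coop)
  initial_state <- as.numeric(initial_state)
  if (length(initial_state) == 1) {
    initial_state <- rep(initial_state, topology$n_genes)
  }
  if (length(initial_state) != topology$n_genes || any(initial_state < 0)) {
    stop("initial_state must hold one nonnegative concentration per gene",
         call. = FALSE)
  }
  if (t_end <= 0 || dt_out <= 0) {
    stop("t_end and dt_out must be positive", call. = FALSE)
  }
  res <- .simulate_cpp(topology$matrix, params$basal_rates,
                       params$degradation_rates, params$thresholds,
                       coop, initial_state, t_end, dt_out, rtol, atol)
  conc <- res$concentrations
  colnames(conc) <- topology$genes
  structure(list(times = res$times, concentrations = conc, ok = res$ok,
                 dt_out = dt_out),
            class = "grn_trajectory")
}

#' @export
print.grn_trajectory <- function(x, ...) {
  cat(sprintf("GRN trajectory: %d genes, %d time points over [0, %g] min%s\n",
              ncol(x$concentrations), length(x$times), max(x$times),
              if (x$ok) "" else " (non-evaluable: integrator failure)"))
  invisible(x)
}

#' Export a trajectory as CSV
#'
#' Writes a table with header `time_min,G0,G1,...`.
#'
#' @param trajectory a [simulate_grn()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "grn_trajectory"))
  df <- data.frame(time_min = trajectory$times,
                   trajectory$concentrations, check.names = FALSE)
  colnames(df) <- c("time_min", paste0("G", seq_len(
    ncol(trajectory$concentrations)) - 1L))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
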