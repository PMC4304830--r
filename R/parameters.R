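#' Kinetic-parameter sampling ranges
#'
#' Biologically feasible intervals from which the Monte Carlo perturbations
#' are drawn, one uniform draw per parameter. Defaults: basal transcription
#' rate a_i in \[10, 100\] nM/min, degradation rate b_i in \[0.02, 0.15\]
#' 1/min, and regulation half-saturation thresholds (Ki for inhibitory, Ka
#' for activatory edges) in \[10, 100\] nM.
#'
#' @param basal_range,degradation_range,threshold_range numeric length-2
#'   intervals `c(lower, upper)` with `0 < lower < upper`.
#' @return An object of class `parameter_ranges`.
#' @export
parameter_ranges <- function(basal_range = c(10, 100),
                             degradation_range = c(0.02, 0.15),
                             threshold_range = c(10, 100)) {
  chk <- function(r, what) {
    if (length(r) != 2 || !all(is.finite(r)) || r[1] <= 0 || r[1] >= r[2]) {
      stop(sprintf("%s must be c(lower, upper) with 0 < lower < upper", what),
           call. = FALSE)
    }
    as.numeric(r)
  }
  structure(list(basal_range = chk(basal_range, "basal_range"),
                 degradation_range = chk(degradation_range,
                                         "degradation_range"),
                 threshold_range = chk(threshold_range, "threshold_range")),
            class = "parameter_ranges")
}

#' Kinetic parameters for a topology
#'
#' One point of the perturbation space: per-gene basal transcription rates
#' `a_i` (nM/min), per-gene degradation rates `b_i` (1/min) and one
#' half-saturation threshold (nM) per nonzero edge of the topology matrix,
#' stored row-major over the matrix (so a `(topology, seed)` pair fully
#' determines a sampled parameter set). With the per-edge cooperativity
#' coefficients the model has `2 * (N + I)` kinetic parameters in total.
#'
#' @param basal_rates numeric vector of length `N`, strictly positive.
#' @param degradation_rates numeric vector of length `N`, strictly positive.
#' @param thresholds numeric vector of length `I` (row-major over nonzero
#'   matrix entries), strictly positive; may be length 0 if `I = 0`.
#' @return An object of class `kinetic_parameters`.
#' @export
kinetic_parameters <- function(basal_rates, degradation_rates,
                               thresholds = numeric(0)) {
  basal_rates <- as.numeric(basal_rates)
  degradation_rates <- as.numeric(degradation_rates)
  thresholds <- as.numeric(thresholds)
  if (length(basal_rates) != length(degradation_rates)) {
    stop("need one basal and one degradation rate per gene", call. = FALSE)
  }
  vals <- c(basal_rates, degradation_rates, thresholds)
  if (length(basal_rates) < 1 || !all(is.finite(vals)) || any(vals <= 0)) {
    stop("all kinetic parameters must be strictly positive", call. = FALSE)
  }
  structure(list(basal_rates = basal_rates,
                 degradation_rates = degradation_rates,
                 thresholds = thresholds),
            class = "kinetic_parameters")
}

.check_params_topology <- function(params, topology) {
  if (length(params$basal_rates) != topology$n_genes ||
      length(params$thresholds) != interaction_count(topology)) {
    stop("parameter dimensions do not match the topology (need N rates and ",
         "one threshold per interaction)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Sample a kinetic-parameter set uniformly
#'
#' Draws each parameter independently and uniformly from its range using R's
#' global RNG. Draw order is fixed: all `a_i` (genes in order), then all
#' `b_i`, then thresholds row-major over nonzero matrix entries, so a seed
#' plus a topology reproduces the set exactly.
#'
#' @param topology a [grn_topology()].
#' @param ranges a [parameter_ranges()].
#' @return A [kinetic_parameters()].
#' @export
sample_parameters <- function(topology, ranges = parameter_ranges()) {
  stopifnot(inherits(topology, "grn_topology"),
            inherits(ranges, "parameter_ranges"))
  N <- topology$n_genes
  I <- interaction_count(topology)
  kinetic_parameters(
    basal_rates = stats::runif(N, ranges$basal_range[1],
                               ranges$basal_range[2]),
    degradation_rates = stats::runif(N, ranges$degradation_range[1],
                                     ranges$degradation_range[2]),
    thresholds = if (I > 0) {
      stats::runif(I, ranges$threshold_range[1], ranges$threshold_range[2])
    } else numeric(0)
  )
}

#' Midpoint parameter set
#'
#' Every parameter at the midpoint of its range; used as the unperturbed
#' reference point for the quantitative robustness semantics.
#'
#' @inheritParams sample_parameters
#' @return A [kinetic_parameters()].
#' @export
midpoint_parameters <- function(topology, ranges = parameter_ranges()) {
  stopifnot(inherits(topology, "grn_topology"),
            inherits(ranges, "parameter_ranges"))
  N <- topology$n_genes
  I <- interaction_count(topology)
  kinetic_parameters(
    basal_rates = rep(mean(ranges$basal_range), N),
    degradation_rates = rep(mean(ranges$degradation_range), N),
    thresholds = rep(mean(ranges$threshold_range), I)[seq_len(I)]
  )
}

.check_coop <- function(n) {
  if (length(n) != 1 || !is.finite(n) || n < 1 || n != round(n)) {
    stop("cooperativity (Hill coefficient) must be a single integer >= 1",
         call. = FALSE)
  }
  as.integer(n)
}
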