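# Independent oracles, deliberately naive: an R-level transcription of the
# Hill-kinetics rate law and a fixed-step classical RK4 integrator. These are
# kept separate from the package's compiled implementation so the two routes
# can disagree.

# rate law written directly from the model definition
oracle_rhs <- function(topology, params, n, state) {
  M <- topology$matrix
  N <- nrow(M)
  K <- params$thresholds
  # thresholds are stored row-major over nonzero entries
  kmat <- matrix(NA_real_, N, N)
  idx <- 0L
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (M[i, j] != 0L) {
        idx <- idx + 1L
        kmat[i, j] <- K[idx]
      }
    }
  }
  rate <- numeric(N)
  for (i in seq_len(N)) {
    prod <- params$basal_rates[i]
    for (j in seq_len(N)) {
      if (M[i, j] == -1L) {
        prod <- prod * kmat[i, j]^n / (state[j]^n + kmat[i, j]^n)
      } else if (M[i, j] == 1L) {
        prod <- prod * state[j]^n / (state[j]^n + kmat[i, j]^n)
      }
    }
    rate[i] <- prod - params$degradation_rates[i] * state[i]
  }
  rate
}

# classical fixed-step 4th-order Runge-Kutta at step h, sampled every dt_out
oracle_rk4 <- function(topology, params, n, init, t_end, h = 0.01,
                       dt_out = 1) {
  steps_per_out <- round(dt_out / h)
  n_out <- floor(t_end / dt_out)
  y <- init
  out <- matrix(NA_real_, n_out + 1L, length(init))
  out[1L, ] <- pmax(y, 0)
  f <- function(s) oracle_rhs(topology, params, n, pmax(s, 0))
  for (g in seq_len(n_out)) {
    for (s in seq_len(steps_per_out)) {
      k1 <- f(y)
      k2 <- f(y + h / 2 * k1)
      k3 <- f(y + h / 2 * k2)
      k4 <- f(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[g + 1L, ] <- pmax(y, 0)
  }
  list(times = seq(0, n_out * dt_out, by = dt_out), concentrations = out)
}

# tournament-selection win probability for the top individual, by exhaustive
# enumeration of size-k subsets of 1..n when the top individual is unique
oracle_tournament_top_prob <- function(n, k) {
  choose(n - 1, k - 1) / choose(n, k)
}

# parameter set (drawn once from the uniform ranges) under which the 3-gene
# delayed negative feedback loop sustains oscillation at both n = 3 and n = 4
dnf_osc_params <- function() {
  kinetic_parameters(basal_rates = c(33.896, 43.491, 61.557),
                     degradation_rates = c(0.13807, 0.04622, 0.13679),
                     thresholds = c(95.021, 69.472, 66.62))
}

# parameter set known (verified in test-behaviors.R) to make the toggle
# switch strongly bistable: deep mutual repression, saturated auto-activation
strong_toggle_params <- function() {
  kinetic_parameters(basal_rates = c(100, 100),
                     degradation_rates = c(0.05, 0.05),
                     thresholds = c(30, 50, 50, 30))
}
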