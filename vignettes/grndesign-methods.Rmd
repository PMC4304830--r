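---
title: "Quantifying and evolving topological robustness of gene regulatory networks"
author: "grndesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and evolving topological robustness of gene regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grndesign)
```

## The problem

Synthetic gene circuits must keep working when their kinetic constants
drift: transcription rates, degradation rates and binding affinities vary
with temperature, growth phase, mutation and molecular noise. Much of that
tolerance is attributed not to fine-tuned constants but to the *wiring* of
the network. `grndesign` treats the wiring as the object of study: it
quantifies how much of the kinetic-parameter space preserves a target
dynamic behavior (the *topological robustness* of the wiring), and it
searches the space of wirings for the most robust one with a genetic
algorithm.

## Model

A network of $N$ genes is a signed adjacency matrix $M$ with
$M_{ij} \in \{+1, -1, 0\}$ (gene $j$ activates, inhibits, or ignores gene
$i$). Concentrations $G_i(t)$ (nM) follow Hill kinetics in which all
regulators act independently:

$$\frac{dG_i}{dt} \;=\; a_i
  \prod_{j \in \mathrm{inh}(i)} \frac{K_{ij}^{\,n}}{G_j^{\,n} + K_{ij}^{\,n}}
  \prod_{k \in \mathrm{act}(i)} \frac{G_k^{\,n}}{G_k^{\,n} + Ka_{ik}^{\,n}}
  \;-\; b_i\, G_i ,$$

with basal transcription rate $a_i$ (nM/min), first-order degradation $b_i$
(1/min), one half-saturation threshold (nM) per edge, and a single Hill
coefficient $n$ shared by every regulation (the cooperativity level; 2 =
low, 3 = medium, 4 = high). Empty products equal 1, so an unregulated gene
relaxes to $a_i/b_i$. Every Hill factor lies in $(0, 1]$, hence
trajectories started nonnegative remain inside
$[0, \max_i a_i/b_i]$ — the system cannot blow up, which is what makes an
explicit adaptive integrator a safe default. A network with $I$ edges has
$2(N + I)$ kinetic parameters.

Parameter perturbations are drawn independently and uniformly from
biologically feasible ranges: $a_i \in [10, 100]$, $b_i \in [0.02, 0.15]$,
thresholds $\in [10, 100]$. Uniformity on the linear scale is a deliberate
choice: the ranges are narrow enough (one decade) that a log-uniform
alternative changes robustness estimates materially, and the linear reading
is the plain one for "randomly sampled within the ranges". Draw order is
fixed (all $a_i$, then all $b_i$, then thresholds row-major over the
matrix), so a topology plus a seed reproduces a parameter set exactly.

## Robustness

Robustness of a wiring $G$ for behavior $a$ is the integral of a behavior
preservation score over the perturbation space with all perturbations
equiprobable, estimated by Monte Carlo:

$$R_a^G \;=\; \frac{100}{S}\sum_{i=1}^{S} D_a^G(p_i), \qquad
  D_a^G(p) = \mathbf{1}\{f_a(p)\ \text{satisfies}\ \rho\},$$

with $S = 10{,}000$ samples by default (Boolean semantics, reported as a
percentage). The quantitative semantics replaces the indicator with
$|f_a(0) - f_a(p)|$ for perturbations that still satisfy $\rho$, and 0
otherwise; it accumulates how far the behavior drifts rather than whether
it survives. The unperturbed reference point $f_a(0)$ of a *topology* is
not well defined (a topology has no distinguished parameter set), so the
package uses the behavior score at the midpoint of every parameter range;
absolute quantitative scores should therefore only be compared between
topologies evaluated under the same convention. Integration failures count
as behavior-not-satisfied, the conservative reading.

`verify_robustness()` repeats the estimator (default 10 × 100,000 samples)
and reports the mean and replicate spread; a Boolean estimate at sample
size $S$ is a binomial proportion with standard error
$100\sqrt{p(1-p)/S}$, about 0.5 points at $p = 0.5$, $S = 10^4$ — a useful
sanity check on any reported spread.

## Behavior detectors

**Oscillation.** A 2100-minute trajectory is generated from 1 nM per gene;
the first 300 minutes are discarded as transient. Each gene is scored as

$$f_{\mathrm{osc}} = \min(SD, SD_{\max}) \cdot LC \cdot PN$$

where $SD$ is the standard deviation of the post-transient series,
$LC \in [0,1]$ compares the amplitudes of the first and last detected
peaks (ratio of smaller to larger; 0 with fewer than two peaks) and $PN$
penalizes damped oscillation. The criterion is satisfied when the average
$f_{\mathrm{osc}}$ across genes reaches $SD_{\max}/2$ *and* every gene
shows at least two peaks ("the system oscillates if every gene
oscillates"). Design choices that the score construction leaves open, and
the defaults taken:

* $SD_{\max} = 10$ nM. Small relative to attainable concentrations
  ($a/b \in [67, 5000]$ nM), so the cap saturates for any oscillation of
  non-trivial amplitude and the criterion effectively asks "is there a
  sustained, non-damped oscillation", not "how large is it".
* Peaks are strict local maxima with prominence at least 0.5 nM (suppresses
  integrator ripple). A peak's amplitude is its height minus the mean of
  its adjacent inter-peak troughs; edge peaks use their single inter-peak
  trough. Computing edge amplitudes against the window boundary instead
  turns out to inflate the first amplitude whenever the window opens
  mid-rise, which breaks damping detection — hence the inter-peak rule.
* $PN = 0.1$ when the peak-amplitude sequence decays monotonically by more
  than 5% from first to last peak, else 1.

These constants shape absolute robustness percentages for *marginal*
oscillators; for the reference oscillators studied here the score is
saturated (an oscillating parameter set scores $\approx SD_{\max}$, a
non-oscillating one $\approx 0$), so the estimates are insensitive to the
exact values. The extreme case is the 2-gene amplified negative feedback
loop at $n = 2$, whose robustness is of order $10^{-2}$ percent and whose
estimate is dominated by borderline damped trajectories — absolute numbers
for that cell should not be over-interpreted under any constant choice.

**Bistability.** Two 600-minute simulations: first $G_0 = 100$,
$G_1 = 300$ nM (other genes 200 nM), then the same with $G_0$ and $G_1$
swapped. The system is bistable iff in *both* runs (i) $G_0$ and $G_1$
each vary by at most 0.01 nM (max minus min) over minutes 400–600 and (ii)
the gene initialized higher settles strictly higher (window means). The
paired-swap protocol is what rejects monostable systems: a system with a
single attractor favors the same gene in both runs and fails (ii) once.

The 0.01 nM band is strict relative to the degradation range: a genuinely
bistable system with $b$ near 0.02/min still drifts more than 0.01 nM over
minutes 400–600 (relaxation time $1/b = 50$ min, and initial gaps are
hundreds of nM), so roughly five percentage points of truly bistable
parameter sets fail condition (i) at the 600-minute horizon. This is a
property of the stated protocol, not of the integrator: the shortfall is
unchanged between relative tolerances $10^{-6}$ and $10^{-10}$, and
measuring "true" bistability at a 3000-minute horizon with
distinct-attractor checks recovers those points. The protocol is
implemented exactly as stated; the vignette records the effect so that
users comparing against published toggle-switch robustness figures know
where the systematic offset comes from.

## Numerical integration

The right-hand side and all hot loops are compiled (Rcpp). Trajectories are
integrated with an adaptive explicit Dormand–Prince 5(4) scheme, relative
tolerance $10^{-6}$, absolute tolerance $10^{-8}$, output on a regular
1-minute grid (the grid the detectors operate on; configurable). The
bounded-box property above means stiffness is mild across the entire
parameter space, so no implicit fallback is used: a step-size underflow or
non-finite state flags the trajectory non-evaluable and the sample counts
as behavior-not-satisfied (in practice this occurs in none of the $10^4$
draws for the reference topologies). Concentrations clipped at 0 guard the
odd-exponent Hill terms against tiny negative integrator output. The test
suite cross-checks the integrator against a fixed-step RK4 oracle at step
0.01 min (agreement better than 0.1 nM pointwise) and against
`deSolve::lsoda` on an oscillating repressilator.

A caution that the tests encode: a *perfectly symmetric* parameter set on a
symmetric topology (e.g. the repressilator with identical $a, b, K$) stays
on the invariant diagonal manifold $G_0 = G_1 = G_2$ forever and will not
oscillate from symmetric initial conditions, even when the fixed point is
unstable in the full space. Randomly sampled parameter sets break the
symmetry almost surely, so this matters only for hand-picked parameters.

## Evolutionary search

The genetic algorithm works directly on the matrices: population 100
random matrices over $\{-1,0,1\}^{N\times N}$, 100 generations, tournament
selection of size 5, one-cut row/column block crossover with probability
0.5 (offspring exchange complementary blocks), single-entry mutation with
probability 0.15 (a per-entry mode is available), and generational
replacement of the worst 50% by the offspring. The best individual can
never be replaced, so the recorded generation-best fitness is
non-decreasing.

Fitness is the Boolean robustness, made affordable by two devices:

* **Two-stage approximation.** A probe of 500 samples is evaluated first;
  if the probe estimate falls below `approx_threshold` (default 5%), it is
  kept as the (approximate) fitness — low-robustness candidates rarely
  survive selection, so a rough score suffices. Otherwise a fresh
  full-sample evaluation is performed. The probe's samples are not reused
  in the full stage; sharing them would save 5% of the cost at the price
  of correlated stages.
* **Archive.** Every evaluated matrix is memoized with its best-known
  score. A topology already in the archive is re-evaluated only with
  probability `reevaluate_prob` (default 0.15, recommended 0.10–0.20) —
  guarding against an accidentally poor score — and the archive always
  retains the maximum. Stored scores therefore never decrease. For small
  search spaces ($3^{N^2}$ matrices; 81 at $N = 2$) the archive bounds the
  number of expensive evaluations by the size of the space. Archive keys
  are exact matrices: relabelings of the same wiring are distinct entries,
  matching how the search itself treats them; permutation-invariant
  comparison (`canonical_topology_key()`) is available at the reporting
  level.

Only offspring are evaluated after initialization; survivors keep their
scores. The final result is the archive-best topology, re-scored with a
full non-approximate evaluation so that a lucky probe estimate is never
reported. Ties in archive-best fitness are broken by discovery order. The
tie-break matters only when the fitness landscape is entirely flat (as it
is for 2-gene oscillation at $n = 2$, where sustained oscillation is
vanishingly rare); a value-based tie-break would then deterministically
return the same matrix in every run and manufacture apparent convergence,
which is exactly what a convergence measurement must not do.

## Phase response curves

For an oscillating (topology, parameter set, $n$) system,
`phase_response_curve()` estimates the period from inter-peak spacing,
lets the system settle 20 periods onto the limit cycle, applies an
instantaneous additive pulse to one gene at 24 phases across the cycle
(default magnitude 10% of that gene's peak-to-trough amplitude), integrates
10 further periods and reads the asymptotic phase shift off the late peak
times, wrapped to $(-\pi, \pi]$ with advance positive. Peak times are
refined by quadratic interpolation on a 0.25-minute grid and the shift is
averaged over the last four peaks: relaxation-type waveforms have spiky
crests whose single-peak localization noise is of order 0.1 rad, an order
of magnitude above the converged signal differences. With these settings,
doubling the settling horizon moves no phase point by more than 0.01 rad,
and a zero-magnitude pulse yields shifts below $10^{-4}$ rad. When
comparing sensitivity across cooperativity levels, pass an explicit
`pulse_nM`: the default relative pulse scales with each system's own
amplitude and would confound the comparison.

## Problem sizes used in the checks

The packaged tests and the acceptance script reproduce reference figures
at 10,000 Monte Carlo samples per estimate (the published tables
additionally average 10 repeats of 100,000 samples; at these sample sizes
the binomial spread is a few tenths of a point, far inside the comparison
tolerances). The GA convergence checks run 5 seeds of a scaled-down
configuration (population 20, 10 generations, probe 200, full 2,000
samples) on the 2-gene problems, where the archive bound (81 topologies)
keeps runs fast; the bistability search converges to the mutual-repression
toggle switch in every seed, while the 2-gene oscillation search has no
usable fitness signal at $n = 2$ (see above) and its convergence fraction
is reported as measured.

## What the generator does and does not emulate

All inputs here are synthetic by construction: the "data" are ODE
trajectories of the stated model under uniformly sampled kinetics. Passing
checks demonstrate that the estimators and the search behave correctly
*under the model's assumptions* — deterministic dynamics, independent
regulation, shared cooperativity, uniform parameter uncertainty. They say
nothing about intrinsic molecular noise, transcription–translation delays,
gene-specific cooperativity, resource competition or extrinsic
fluctuations, none of which the model represents. Robustness rankings
between topologies have repeatedly proven more transferable than absolute
percentages; treat the percentages as model-relative quantities.

## Known limitations

* Absolute oscillation-robustness percentages depend on the scoring
  constants ($SD_{\max}$, damping rules) for marginal oscillators; rankings
  are stable.
* The bistability band (0.01 nM over minutes 400–600) systematically
  excludes slowly-relaxing bistable systems, as quantified above.
* The quantitative semantics needs a reference score; the midpoint
  convention makes scores comparable only within one convention.
* No delay, stochastic or multi-state dynamics; behaviors beyond
  oscillation and bistability require a new detector (`f_a`, $\rho$) but no
  changes elsewhere.
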