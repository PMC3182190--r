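---
title: "Methods: competing binary synapses, from lattice to mean field"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: competing binary synapses, from lattice to mean field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compsyn)
```

## The model and its assumptions

The package simulates a chain of binary synapses, each in a *strong* or
*weak* state, connected through binary threshold neurons. The plasticity
rule is competitive and anti-Hebbian in flavour: when a synapse is
selected for an update, its two flanking neurons fire independently —
with probability `alpha` when a neuron's other adjacent synapse is
strong, `beta` when it is weak; the candidate synapse itself is ignored
in both activations, since it is common to both neurons and drops out of
any comparison of their average activity. If the two
neighbouring synapses are of mixed type and only the strong-adjacent
neuron fires, the synaptic current is positively polarized and the
candidate is set to strong; if only the weak-adjacent neuron fires, it is
set to weak; in every other case (both or neither firing, or same-type
neighbours) nothing happens. Updates are idempotent on the winning type:
a potentiation event leaves an already strong synapse unchanged.

All of the package's dynamics derive from a single enumeration of the
2×2 table of joint neuron activations (`neighbor_outcome_probs()`). For
mixed neighbours this gives the per-update probabilities

* potentiation: `A = alpha (1 - beta)`,
* depression: `B = beta (1 - alpha)`,

and zero for same-type neighbours. We treat this enumeration — not any
transcribed algebra — as the source of truth; every closed form below is
derived from it and the test suite checks the two routes against each
other to `1e-12` over a parameter grid.

### Mean-field effective dynamics

The effective description assigns every synapse the same strong
probability `x` and neglects spatial correlations. Averaging the
enumeration over neighbour configurations drawn independently with
strong-probability `x` (mixed pairs carry weight `2 x (1 - x)`) gives

```
dx/dt = (1 - x) W_up(x) - x W_down(x),
W_up  = 2 x (1 - x) A,
W_down = 2 x (1 - x) B,
```

a cubic flow with unstable absorbing fixed points at 0 and 1 and a stable
interior fixed point

```
x* = A / (A + B),   tau = -1 / drift'(x*) = (A + B) / (2 A B).
```

`tau` is the exponential time constant for relaxation *to the end state
of whatever parameters are in force*; learning a signal is governed by
the signal-on parameters, forgetting by the default ones. Both `x*` and
`tau` respect the exact strong↔weak relabeling symmetry
`(alpha, beta, x) -> (beta, alpha, 1 - x)`.

```{r fixed-points}
p <- plasticity_params(0.8, 0.2)
c(x_star = stable_fixed_point(p),
  tau_symmetric = relaxation_time(plasticity_params(0.5, 0.5)))
```

### Signals and protocols

A signal of strength `s` shifts the parameters as
`(alpha + s, beta - s)`, conserving `alpha + beta`; admissibility requires
both shifted probabilities to stay strictly inside (0, 1), which is the
open interval returned by `allowed_signal_range()` and is widest (length
1) on the diagonal `alpha + beta = 1`. The three two-phase protocols are
encoded by `build_protocol()`: de-adaptation (`s`, then 0), downscaling
(`s`, then `s/2`) and reversal (`s`, then `-s`). Each phase runs until
*saturation*; for the reversal protocol the relearning time is measured
only from the moment the trajectory first crosses the default fixed-point
level (located by linear interpolation between integrator steps, removing
the O(`dt`) bias), mirroring the idea that the system must first forget
the original signal.

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `alpha`, `beta` | activation probabilities (strong-/weak-adjacent) | — | the only model parameters; open interval (0,1) with `1e-9` margins, since boundary values degenerate the dynamics |
| `tol` | saturation threshold, change of `x` per sweep | `1e-6` | small enough that measured times are tolerance-dominated only logarithmically (`t_sat` grows by `tau ln 2` per halving, a property the tests verify) |
| `dt` | Euler step, sweeps | `0.01` | relative rate bias is `dt / (2 tau) <= 0.13%` for `tau >= 4`, the minimum attainable |
| `max_time` | per-phase cap, sweeps | `1e5` | safety against non-convergent configurations |
| lattice `n` | chain length | `1e3`–`1e4` in examples | large enough that binomial noise (`~1/sqrt(n)`) is small next to the effects studied |
| map grids | diagonal `a`, signal `s` | 41×41 over `a ∈ [0.05, 0.95]`, `s` spanning the admissible band | resolves the maps' structure at interactive runtimes; the test suite uses 30×30 |

Time is measured in sweeps throughout: one unit equals one expected
update attempt per synapse, which makes lattice and mean-field clocks
directly comparable.

## The saturation criterion

Saturation is declared when the change of `x` per unit time falls below
`tol`. Two normalizations are offered (`saturation_config(normalize =)`):

* `"change"` (default): `|x(t+1) - x(t)| < tol`, the absolute change of
  the strong fraction;
* `"state"`: the change relative to `max(|x|, 1e-9)`.

The default was a genuine design decision. The relative-change variant
breaks the exact relabeling symmetry of the model: mirrored protocols
(e.g. reversal at a symmetric default) would measure different times for
mirror-image trajectories, with an excess of `tau * ln((1 - x*)/x*)`
coming purely from the measurement convention. The absolute criterion is
invariant under `x -> 1 - x`, so mirror-image protocols measure
mirror-image times, the reversal ratio at a symmetric default is 1, and
the phase maps obey `log_ratio(a, s) = log_ratio(1 - a, -s)` to solver
tolerance — properties the suite tests. The criterion is evaluated per
unit time, not per micro-step, so measured times are `dt`-independent to
first order.

```{r reversal-symmetry}
run_protocol(plasticity_params(0.5, 0.5), build_protocol("reversal", 0.2))$ratio
```

## Numeric versus analytic timescale ratios

For each protocol two ratios are reported. The *numeric* ratio divides
the measured saturation times of the two phases; each carries a
logarithmic factor `~ ln(d0 / (tol * tau))` in the initial displacement
`d0` on top of the exponential time constant. The *analytic* ratio is the
pure time-constant ratio `tau(end of phase 2) / tau(end of phase 1)`.
They are therefore not numerically equal, but they rank configurations
the same way; the test suite checks Spearman agreement ≥ 0.95 on a 30×30
de-adaptation map, and `compare_maps()` reports the comparison for any
pair of maps.

## What the lattice shows that mean field cannot

The stochastic chain (`run_sweeps()`, compiled kernel, R's RNG for seeded
reproducibility) uses random-sequential updates — uniform site choice
with replacement, fresh independent activation draws per update — and
periodic boundaries. Both choices are documented defaults rather than
claims: the update order is left open by the effective description
(which assumes uncorrelated outcomes anyway), and periodicity removes
edge effects, matching the translation-invariant mean-field picture.

Two facts about the chain are deliberately pinned by tests:

1. **Absorbing states.** All-strong and all-weak chains are invariant
   under any update sequence, and the interior state is metastable at
   finite `n`; runs flag absorption, and stationary estimates should
   exclude absorbed runs.
2. **Correlation shift.** The mean-field fixed point is *not* an unbiased
   predictor of the chain's stationary strong fraction. Updates copy a
   neighbouring synapse's type into the candidate, so adjacent synapses
   are positively correlated; mixed-neighbour pairs are rarer than the
   independence weight `2 x (1 - x)`, and the candidate's own state is
   correlated with its neighbours'. The net effect pulls the stationary
   fraction from `x*` toward 1/2, weakly for small `|alpha - beta|` and
   strongly near the corners (at `(0.8, 0.2)` the chain sits near 0.74
   against `x* ≈ 0.94`; the suite pins the gap at `(0.7, 0.3)` and the
   agreement at `(0.52, 0.48)`):

```{r lattice-gap}
p <- plasticity_params(0.7, 0.3)
est <- stationary_fraction(run_sweeps(init_lattice(1e4, 0.5, seed = 13), p, 500))
c(lattice = est$mean, mean_field = stable_fixed_point(p))
```

Consequently, passing mean-field tests says nothing quantitative about
the spatially resolved system at strong asymmetry; the effective level is
the right object for the protocol and phase-map analyses (which are
defined on it), while the chain is the right object for questions about
fluctuations, absorption and correlations. The chain emulates none of
the features of real neural tissue beyond the model's own scope: no
directed synapses, no membrane dynamics, no higher-dimensional or
heterogeneous connectivity, and signals act only at the effective level.

## Numerical choices and degenerate inputs

* **Integration** is explicit Euler with `dt = 0.01`; the compiled
  integrator consumes the exact cubic coefficients of the
  enumeration-built drift (recovered by interpolating the quadratic
  transition probabilities at 3 points — machine-exact for polynomials).
  An adaptive-solver cross-check (`deSolve::lsoda`) is part of the test
  suite. Steps that would leave `[0, 1]` abort with advice to reduce
  `dt`; boundary round-off is clamped.
* **Root finding** for `x*` brackets the drift's interior sign change in
  `(1e-9, 1 - 1e-9)` (`uniroot`, tol `1e-12`) and polishes with Newton
  steps on the exact cubic; stability `drift'(x*) < 0` is asserted.
* **Degenerate protocols** raise errors rather than returning silent
  NaNs: zero-shift signals (`s = 0`, learning time undefined), phases
  starting at their own fixed point (immediate saturation), inadmissible
  signals (message names the violated interval), and a never-reached
  default crossing in the reversal phase. Phase-map cells in any of these
  conditions are masked (`admissible = FALSE`).
* **Batch means.** `stationary_fraction()` uses ≥ 10 contiguous batches
  after burn-in; with autocorrelation times of order `tau` sweeps the
  standard error is mildly optimistic for short runs, which is why the
  tests that rely on it use generous multiples or absolute tolerances.

## Known limitations

* The mean-field level ignores correlations by construction; the chain
  quantifies (but the package does not correct) the resulting bias — a
  pair approximation is out of scope.
* Only piecewise-constant signals applied symmetrically to both
  parameters are supported.
* Measured saturation times depend logarithmically on `tol`; only ratios
  at a fixed `tol` are comparable across configurations.
* The `(0.5, 0.5)` chain is effectively unbiased (A = B) and its strong
  fraction performs a slow random walk; stationary estimates there are
  dominated by wandering, not by a restoring force, and tests avoid
  asserting tight agreement at that point.
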