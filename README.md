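# compsyn

Simulation and analysis of a network of **competing binary synapses**: a
one-dimensional chain of plastic synapses, each either *strong* or *weak*,
whose state updates are driven by competition between neighbouring
synapses, together with the mean-field effective dynamics of the
strong-synapse fraction, signal-driven adaptation protocols, and
learning-versus-forgetting phase maps.

The package is aimed at computational neuroscientists studying how
multiple synaptic timescales shape system-level learning, retention and
interference — in particular at the qualitative phenomenology of motor
adaptation paradigms (de-adaptation, downscaling, anterograde
interference).

## The model

Neurons are binary threshold units connected in a chain by undirected
binary synapses. When a synapse is considered for an update, each of its
two flanking neurons fires independently, with probability

- `alpha` if the neuron's *other* adjacent synapse is strong,
- `beta` if it is weak

(the shared candidate synapse is ignored). The update has an anti-Hebbian
flavour: if the neighbouring synapses are of mixed type and *only* the
strong-adjacent neuron fires, the current is positively polarized and the
candidate is potentiated (set to strong); if only the weak-adjacent neuron
fires, it is depressed; every other combination leaves it unchanged. For
mixed neighbours the per-update probabilities are therefore

```
P(potentiate) = A = alpha (1 - beta)
P(depress)    = B = beta (1 - alpha)
```

In the mean-field description every synapse is strong with probability
`x`, and

```
dx/dt = (1 - x) W_up(x) - x W_down(x),   W_up = 2 x (1 - x) A,  W_down = 2 x (1 - x) B
```

with one time unit equal to one update sweep. Besides the absorbing states
at 0 and 1 the flow has a stable interior fixed point and an exponential
relaxation time

```
x* = A / (A + B),        tau = (A + B) / (2 A B)
```

`tau` is the central quantity for learning and forgetting: it depends only
on the parameters of the *end* state of a phase. A signal `s` perturbs the
parameters as `(alpha, beta) -> (alpha + s, beta - s)`, shifting the fixed
point while preserving `alpha + beta`; protocols chain such phases and
measure the time each phase needs to saturate.

In the package, all of these quantities are built by enumerating the
neuron-activation outcomes (`neighbor_outcome_probs()`); the closed forms
above are derived from the enumeration and cross-checked against it in the
test suite. The stochastic chain (`init_lattice()`, `run_sweeps()`) is the
microscopic counterpart and exposes what mean field ignores: nearest-
neighbour correlations shift the chain's stationary strong fraction away
from `x*` as `|alpha - beta|` grows (see the methods vignette).

## Worked example

```r
library(compsyn)

p <- plasticity_params(0.8, 0.2)
stable_fixed_point(p)
#> [1] 0.9411765
relaxation_time(plasticity_params(0.5, 0.5))
#> [1] 4

res <- run_protocol(plasticity_params(0.2, 0.8),
                    build_protocol("deadaptation", 0.1))
glance(res)
#> # A tibble: 1 × 8
#>   kind             s alpha  beta t_learn t_second ratio analytic_ratio
#>   <chr>        <dbl> <dbl> <dbl>   <dbl>    <dbl> <dbl>          <dbl>
#> 1 deadaptation   0.1   0.2   0.8    68.3     106.  1.55           2.02
```

At `(alpha, beta) = (0.8, 0.2)` the stable state has 94% strong synapses.
The symmetric system relaxes with time constant 4 sweeps. In the
de-adaptation run the system starts at the fixed point of the default
parameters `(0.2, 0.8)`, learns a signal of strength 0.1 in `t_learn ≈ 68`
sweeps, and — with the signal removed — forgets back to the default state
in `t_second ≈ 106` sweeps: forgetting is 1.55× slower than learning
(`ratio`), while the pure time-constant ratio of the two end states is
2.02 (`analytic_ratio`; saturation times also carry logarithmic
distance-to-fixed-point factors, hence the difference).

`autoplot(res)` draws the phase-labelled trajectory;
`ratio_map()`/`compare_maps()` sweep the diagonal default and the signal
strength to produce the phase maps, and `rate_map()` the `1/tau`
landscape. A thin command-line wrapper is installed at `exec/compsyn`
(subcommands `simulate`, `lattice`, `protocol`, `phasemap`, `compare`).

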