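# tsnets

Network analysis of nonlinear time series: **tsnets** converts a scalar or
multichannel recording into a discrete state-space network and computes the
dynamical and information-theoretic measures defined on it. It is aimed at
researchers (e.g. in neuroscience or physiology) who want a time-resolved,
network-based picture of a signal's dynamics — the repertoire of states the
system visits, how predictably it moves between them, and how far from
equilibrium its flow through state space is — rather than a static
connectivity summary.

Three constructions are provided:

- **Recurrence networks (RN).** State vectors `X_i` (native multichannel
  samples or a delay embedding) become nodes; an undirected edge links
  `i, j` when `||X_i − X_j|| < ε` (Heaviside-thresholded recurrence plot as
  an adjacency matrix). Euclidean, Manhattan, Chebyshev, cosine and
  correlation metrics; Theiler window; weighted variant; threshold
  heuristics (fraction of max distance, exact target density via distance
  quantiles, `5σ` noise rule, minimal connectivity, maximal degree
  variance) and a full ε-sweep (the network filtration).
- **Visibility networks (VN/HVN).** Samples become nodes; `i, j` are linked
  when the chord between `(t_i, x_i)` and `(t_j, x_j)` clears every
  intermediate sample (natural variant), or when every intermediate value is
  strictly below `min(x_i, x_j)` (horizontal variant,
  `x_k < min(x_i, x_j)`). Degree series and degree-distribution entropy
  turn the raw signal into a discrete, information-ready sequence.
- **Ordinal partition networks (OPN).** A delay embedding
  `V_i = (x_i, x_{i+τ}, …, x_{i+(d−1)τ})` is discretized to rank words
  `S_i = φ(V_i)` (ascending ranks, Bandt–Pompe tie rule); nodes are the
  observed patterns and directed weighted edges carry
  `p_ij = P(S_{t+1} = j | S_t = i)`. On top of this sit permutation
  entropy, determinism/degeneracy
  (`det = (log₂N − ⟨H₂(W_i)⟩)/log₂N`,
  `deg = (log₂N − H₂(⟨W⟩))/log₂N`), per-pair transition asymmetry
  `|p_ij − p_ji|/(p_ij + p_ji)`, entropy production
  `Σ p_ij log(p_ij/p_ji)`, and constrained random-walk surrogate series
  that preserve the ordinal transition dynamics.

Shared utilities: sample entropy `S = −log(A/B)` from recurrence counts at
dimensions `m+1` and `m`, embedding-parameter selection (ACF first zero,
auto-mutual-information first minimum; degree-variance, permutation-entropy
first peak, and saturation criteria for `d`), scalar network summaries,
community detection with macro-state renormalization, a synthetic-signal
generator (sine, logistic map, Lorenz, Rössler, white/pink/AR(1) noise),
plain-text readers/writers (edge list, GraphML, adjacency CSV) and a CLI.

## Worked example

The nine-sample reference series embedded with `d = 3`, `τ = 2`:

```r
library(tsnets)
x <- c(0.1, 0.3, 1.2, 0.2, 0.8, 1.7, 1.3, 0.4, 0.2)
permutation_embed(x, dim = 3, lag = 2)
#> # A tibble: 5 × 2
#>    time pattern
#> 1     1 132
#> 2     2 213
#> 3     3 213
#> 4     4 132
#> 5     5 231
```

The first embedded vector is `(0.1, 1.2, 0.8)`: its smallest value sits
first and its largest second, so its rank word is `132`. Building the OPN
from the symbol sequence:

```r
net <- build_opn(permutation_embed(x, dim = 3, lag = 2))
tidy(net)
#> # A tibble: 4 × 4
#>   from  to    count probability
#> 1 132   213       1         0.5
#> 2 132   231       1         0.5
#> 3 213   132       1         0.5
#> 4 213   213       1         0.5
```

Node `132` was visited twice and moved once to `213` and once to `231`, so
each outgoing edge carries probability 0.5; `213` has a self-loop (it
repeated) with weight 0.5. The terminal pattern `231` is a node with a
visit but no outgoing edge. The symbol frequencies are (2/5, 2/5, 1/5), so
`permutation_entropy(...)` returns 1.0549 nats.

A full pipeline on a chaotic flow, with data-driven parameters:

```r
ro  <- generate_signal("rossler", n = 3000)           # x, y, z channels
lag <- select_lag(ro, "acf-first-zero", max_lag = 200, channel = "x")
#> 29  (quarter of the dominant orbital period, in samples)
d   <- select_dimension(ro, lag = lag, criterion = "degree-variance",
                        channel = "x")
#> 8
net <- build_opn(permutation_embed(ro, dim = d, lag = lag, channel = "x"))
determinism_degeneracy(net)
#> determinism 0.897, degeneracy 0.0456
```

High determinism with low degeneracy is the signature of a deterministic
but chaotic flow: the next ordinal state is nearly fixed by the current
one, yet distinct pasts rarely collapse onto a common future. The same
series as a recurrence network:

```r
cl <- delay_embed(ro, dim = 3, lag = lag, channel = "x")
eps <- select_epsilon(pairwise_distances(cl), "target-density", rho = 0.05)
rn  <- build_recurrence_network(cl, epsilon = eps, theiler = lag)
glance(rn)
#> 2942 nodes, 194867 edges, density 0.045, clustering 0.568, 1 component
```

All result objects support `tidy()` (edge list), `glance()` (scalar
summary) and `autoplot()`; see the methods vignette
(`vignettes/state-space-networks.Rmd`) for the model details, parameter
guidance, and numerical conventions.

## Command line

```sh
Rscript inst/scripts/tsnets.R opn --input series.csv --dim 3 --lag 2 --out opn.tsv
Rscript inst/scripts/tsnets.R synth --kind white --n 1000 --seed 1 --out noise.csv
```

Subcommands: `embed`, `rn`, `vg`, `hvg`, `opn`, `opn-surrogate`, `synth`,
`summarize`; all parameters are validated up front and echoed for
provenance, and runs are bit-reproducible given `--seed`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch against the installed package, the ordinal-pattern
labels of the first and last embedded vectors of the reference series and
the outgoing edge weight of the `132` node of its ordinal partition
network, and writes them as JSON.
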