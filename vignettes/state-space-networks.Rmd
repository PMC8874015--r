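---
title: "State-space networks from time series: models, parameters, conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-space networks from time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsnets)
```

tsnets turns a time series into one of three discrete state-space networks
and computes dynamical and information-theoretic measures on it. This
vignette is the package's account of the underlying models, the parameters
that matter, and the numerical conventions the implementation commits to.
Everything quantitative shown here is computed by the code at build time;
the test suite re-derives the same quantities against independent
brute-force oracles.

## 1. Delay embedding and ordinal patterns

A scalar series $x_1, \dots, x_n$ is embedded as
$V_i = (x_i, x_{i+\tau}, \dots, x_{i+(d-1)\tau})$, giving
$n - (d-1)\tau$ state vectors. `ordinal_pattern()` maps a vector to its
rank word: element $k$ receives rank
$1 + \#\{j : x_j < x_k\}$, with ties broken by the earlier index taking
the lower rank (the Bandt–Pompe convention). Real data has ties, so the
tie rule is part of the definition, not an afterthought: it makes the
symbolization total and deterministic, and it is what the horizontal
visibility and surrogate code assume. Rank words are rendered as
concatenated digits (`"132"`) for $d \le 9$ and dash-separated above
that.

```{r}
x <- c(0.1, 0.3, 1.2, 0.2, 0.8, 1.7, 1.3, 0.4, 0.2)
permutation_embed(x, dim = 3, lag = 2)$pattern
```

### Choosing the delay

`select_lag()` implements two standard heuristics.

* **ACF first zero** returns the first non-positive integer lag of the
  sample autocorrelation. One numerical subtlety: for an exactly
  quarter-periodic sinusoid the finite-sample ACF at $T/4$ is not zero
  but $O(1/n)$ *positive* (a boundary artifact of the non-circular sum),
  so the literal "first non-positive" rule lands one lag late. The
  implementation therefore takes, at a sign crossing, the integer whose
  ACF value is nearer zero — still an integer lag, no interpolation —
  which restores the analytic answer $T/4$.
* **AMI first minimum** returns the first interior local minimum of the
  binned auto-mutual information
  $I(x_t; x_{t+\ell})$, estimated by the plug-in estimator on an
  equal-width 2-D histogram (natural log). The default bin count is
  $\lceil\sqrt{n}\rceil$ capped at 64, the usual bias/variance
  compromise; it is overridable. A caution worth recording: for a
  *noise-free* periodic signal the AMI curve is high and nearly flat at
  every lag (the lagged value is a deterministic, two-branch function of
  the current one), so "first minimum" is only meaningful for signals
  with an observational-noise floor. The tests use a noisy sinusoid for
  exactly this reason.

Constant series are rejected explicitly (autocorrelation undefined); if no
lag qualifies up to `max_lag`, `max_lag` is returned with a warning.

### Choosing the dimension

`select_dimension()` scans a candidate range (default 3–8) at a fixed lag:

* `degree-variance`: the $d$ whose ordinal partition network maximizes the
  variance of total degree — the "richest" network between the saturated
  small-$d$ regime and the path-graph large-$d$ regime. Total degree
  (in + out, distinct edges) is used; ties go to the smallest $d$.
* `pe-first-peak`: first local maximum of permutation entropy across $d$.
* `min-unsaturated`: the smallest $d$ realizing fewer than $d!$ patterns,
  i.e. the first dimension that actually resolves structure. This is also
  the right criterion when two series must share one alphabet.

## 2. Recurrence networks

For state vectors $X_i$ (native multichannel rows, or a delay embedding),
the adjacency is $M_{ij} = \Theta(\varepsilon - \|X_i - X_j\|)$. Two
conventions are fixed so counts are reproducible: the inequality is
*strict* ($d < \varepsilon$), resolving the Heaviside-at-zero ambiguity,
and a Theiler window $w$ (default 0) removes pairs with $|i-j| \le w$,
suppressing the trivially sequential edges that appear once
$\varepsilon$ approaches the mean inter-point spacing. The weighted
variant stores the (strictly positive) distance on qualifying edges.

Metrics: Euclidean, Manhattan, Chebyshev, plus cosine and correlation
($1 - r$, range $[0, 2]$, monotone in dissimilarity) for high-dimensional
recordings where $L_p$ metrics lose contrast. Degenerate vectors (zero
vector under cosine, constant vector under correlation) are rejected with
the offending time index named.

Threshold heuristics in `select_epsilon()`: a fraction $p$ of the maximum
distance; an exact target edge density, implemented as the $\rho$-quantile
of the off-diagonal distances rather than an iterative search; $5\sigma$
for a known noise level $\sigma$; the smallest grid value that connects
the network; and the grid value maximizing degree variance.
`epsilon_sweep()` reports density, components, degree variance and global
clustering along an increasing grid — the network filtration obtained by
growing the recurrence threshold — and edge sets are nested along it by
construction.

**Sample entropy.** $S = -\log(A/B)$ where $B$ and $A$ are the recurrence
(template-match) counts at embedding dimensions $m$ and $m+1$ (Chebyshev,
delay 1, strict threshold, Theiler 0). Both dimensions count over the same
first $n - m$ templates, the standard estimator convention; the dimension-$m$
cloud would otherwise have one extra template and a constant series would
not return exactly 0. Zero counts raise an explicit "insufficient
recurrences" error carrying $A$ and $B$ rather than returning a silent
infinity.

## 3. Visibility networks

Natural visibility links $i < j$ when every intermediate sample lies
strictly below the chord between $(t_i, x_i)$ and $(t_j, x_j)$; the
horizontal variant requires $x_k < \min(x_i, x_j)$. Both inequalities are
strict, so equal-height intermediates block visibility and a constant
series yields a path graph deterministically. Adjacent samples are always
linked (the condition is vacuous), which guarantees connectivity of the
natural graph. Irregular sampling enters through explicit times; the
directed option (past → future) is off by default.

Construction: the natural graph uses a running-maximum-slope sweep — from
each origin $i$, $(i,j)$ is an edge iff the slope to $j$ strictly exceeds
every earlier slope from $i$ — which is $O(n^2)$ against the $O(n^3)$
definition; the horizontal graph uses the standard monotone-stack scan,
$O(n)$. The $O(n^3)$ and $O(n^2)$ literal transcriptions of the defining
conditions remain in the test suite as oracles.

`degree_series()` symbolizes the signal by node degree, and
`degree_entropy()` is the Shannon entropy of the empirical degree
distribution — a network-based entropy estimate that assumes neither
independence nor Gaussianity. For i.i.d. noise the horizontal graph's
degree distribution follows the closed form
$P(k) = \tfrac{1}{3}\left(\tfrac{2}{3}\right)^{k-2}$ regardless of the
marginal; the acceptance suite checks this at $n = 10^5$.

## 4. Ordinal partition networks

`build_opn()` counts consecutive pattern pairs: one node per observed
pattern, a directed edge per observed transition (self-loops retained —
repeated patterns are real dynamics), probabilities normalized per row
over *observed outgoing counts only*. The terminal symbol contributes a
node and a visit but no outgoing transition. This convention reproduces
the two 0.5-weight outgoing edges of the worked example above.

Measures, with $N$ the node count and $W_i$ node $i$'s outgoing
distribution (terminal-only nodes excluded from averages):

* **Determinism** $= (\log_2 N - \langle H_2(W_i)\rangle)/\log_2 N$: 1
  when every state has a unique successor, 0 when every row is uniform.
* **Degeneracy** $= (\log_2 N - H_2(\langle W\rangle))/\log_2 N$: how much
  distinct pasts funnel into common futures (1 when all rows are the same
  point mass). The effective-information decomposition is adopted because
  the two terms share the $\log_2 N$ normalization and bracket the
  predictability/information-loss trade-off.
* **Transition asymmetry** per unordered pair,
  $|p_{ij} - p_{ji}|/(p_{ij} + p_{ji})$, for pairs with positive total.
* **Entropy production** $\sum_{i,j} p_{ij}\log(p_{ij}/p_{ji})$ over
  $p_{ij} > 0$: zero under detailed balance. If some transition has no
  observed reverse the plug-in estimate diverges; the function returns
  `Inf` as an explicit irreversibility flag rather than silently dropping
  one-way terms (which would understate irreversibility). An optional
  pseudocount $\alpha > 0$ smooths all counts before normalization when a
  finite regularized value is wanted.

`renormalize_opn()` aggregates micro-states into community macro-states:
macro counts are summed micro counts (total transitions conserved
exactly), probabilities re-normalized per macro-node. Community detection
runs on symmetrized weights ($c_{ij} + c_{ji}$); directed modularity is
deferred. One backend note: greedy modularity can split modularity-*tied*
graphs (e.g. complete graphs) arbitrarily, so partitions that do not
strictly beat the trivial single community are collapsed to it.

## 5. Constrained-walk surrogates

`surrogate_series()` generates a synthetic series preserving the ordinal
transition dynamics: a walker moves over the OPN sampling successors
proportionally to edge probabilities, restricted to *overlap-consistent*
transitions — the successor's leading $d-1$ ranks must order-match the
predecessor's trailing $d-1$ ranks. Values are emitted so that every
window of the output realizes its walk pattern: the new sample is drawn
from the empirical values observed at the final window position of the
successor pattern, restricted to the bracket its rank demands (bracket
midpoint as fallback). Dead ends restart from a visit-frequency-weighted
node, with a message and a `restarts` attribute.

The honest scope of this construction: with $\tau = 1$ consecutive
windows genuinely share $d - 1$ samples, every observed transition is
overlap-consistent, and re-embedding the surrogate with the generating
$(d, \tau)$ reproduces the walk's pattern sequence *exactly* — so the
surrogate's empirical transition probabilities converge to the source
network's, which is what the acceptance suite verifies at length $10^4$.
With $\tau > 1$ consecutive windows share no samples: the
overlap-consistency rule is then a heuristic, and it can even forbid
transitions a real series exhibits (in the worked example at $\tau = 2$,
the observed 132 → 231 transition is not rank-compatible). Surrogates at
$\tau > 1$ therefore preserve the source alphabet and are reproducible,
but per-edge fidelity is only guaranteed at $\tau = 1$ — use lag-1
embeddings when the surrogate is the point of the analysis.

## 6. Synthetic reference signals

`generate_signal()` provides the regimes the constructions are meant to
distinguish: a sinusoid (periodic), the logistic map at $r = 3.5$
(period-4) vs $r = 4$ (chaotic), the Lorenz
($\sigma = 10, \rho = 28, \beta = 8/3$, $dt = 0.01$) and Rössler
($a = b = 0.2, c = 5.7$, $dt = 0.05$) flows, and white, $1/f$ (spectral
synthesis), and AR(1) noise. Flows use fixed-step RK4 — reproducibility
outweighs integration accuracy at fixture scale — and flows/maps discard
a 1000-step transient so output starts near the attractor; stochastic
kinds require a seed and identical spec + seed is bit-identical.

What a green test on these fixtures does establish: the constructions
separate periodic, chaotic and stochastic regimes in the directions the
theory predicts (single-pattern networks for monotone input, cycles for
periodic input, higher out-degree variance at the onset of chaos, the
exponential horizontal-visibility tail for noise). What it does not: that
any of this transfers to empirical recordings with nonstationarity,
artifacts, filtering, or line noise — none of which the generator
emulates. Parameter defaults were chosen once from the standard
literature values above and are not tuned to the tests.

## 7. Input/output and indexing

Readers sniff the delimiter, validate every cell (non-numeric cells are
reported with row and column), and either reject or, on request, drop
incomplete rows — dropping is legitimate for recurrence networks, which
need no regular sampling. Internally the package uses R's 1-based time
indices; written artifacts (edge lists, adjacency CSV) use 0-based time
indices for recurrence/visibility node ids and pattern labels for OPN
nodes. Edge weights are written with 12 significant digits, enough for
exact round trips at test scale. Betweenness uses stored distances as
lengths on weighted recurrence networks and $-\log p$ on OPNs, so
shortest paths mean most-probable routes.

## 8. Known limitations

* The natural-visibility sweep is $O(n^2)$ in R; very long series
  ($n \gg 10^5$) are better served by the horizontal variant ($O(n)$).
* Multivariate generalizations (multiplex visibility, joint/cross ordinal
  networks), line-based recurrence quantification (determinism via
  diagonal lines, laminarity), persistent homology summaries, and
  visibility-based transfer entropy are out of scope.
* Surrogate fidelity at $\tau > 1$ is heuristic, as analyzed in section 5.
* The plug-in auto-mutual information is biased upward at small samples;
  the default bin rule mitigates but does not remove this.
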