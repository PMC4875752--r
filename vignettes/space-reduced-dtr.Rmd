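---
title: "Space-reduced node mapping for dated tree reconciliation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Space-reduced node mapping for dated tree reconciliation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cophymap)
```

## The problem

Cophylogeny mapping reconciles a dependent (parasite) phylogeny with an
independent (host) phylogeny, given which extant host each extant parasite
inhabits. Four events explain any incongruence between the two trees:
**codivergence** (the parasite diverges with its host), **duplication** (the
parasite diverges on one host lineage), **host switch** (one child lineage
jumps to a contemporaneous, non-ancestral host lineage) and **loss** (a
parasite lineage tracks through a host divergence without diverging). With
penalties $C, D, W, L$ and an event census $(\alpha, \beta, \gamma, \delta)$,
a reconciliation costs

$$E = \alpha C + \beta D + \gamma W + \delta L,$$

and the goal is a minimum-cost, time-consistent map. Finding it over all
temporal orderings of host divergences is NP-hard; fixing a total order on
the host's internal nodes (a *dated* host) yields the polynomially solvable
**dated tree reconciliation problem (DTR)**, the problem this package
solves. A tanglegram here is the triple (dated host tree, parasite tree,
leaf association map $\varphi$), with each parasite leaf on exactly one host
leaf.

## The mapping-site table and why it is small

Node-mapping DTR solvers work from the parasite leaves up, storing for each
parasite node $p$ the candidate placements ("mapping sites") on host nodes
together with the minimum cost of embedding $p$'s subtree there. A dense
table has $(2n_p - 1)(2n_h - 1)$ cells; in practice most cells are never
needed. `solve_dtr()` stores an array of per-node lists instead, retaining
for each internal $p$:

1. **Inherited sites** — for each site $s$ of one child, a placement of $p$
   at $s$'s host with the other child reaching its own cheapest feasible
   site by a duplication descent or a host switch.
2. **Codivergence/duplication sites** — the cheapest such event at each
   common-ancestor host of a pair of child sites, thinned to the Pareto
   frontier under loss-priced descent: a candidate at $g$ is dropped when a
   kept candidate at a descendant host $g'$ satisfies
   $c' + L\,\mathrm{dist}(g, g') \le c$, because the deeper site then
   substitutes in every later use of $g$. The frontier — rather than a
   single cheapest site — is required for optimality: a site exactly *at*
   an ancestor $g$ cannot serve a parent codivergence at $g$, so a dearer
   site strictly below $g$ may be the only way to reach the optimum.
   In practice the frontier almost always has one or two members.
3. **The most recent host switch per direction** — among minimum-cost
   feasible switches the one with the latest take-off (ties: lowest landing
   node id). A take-off above the resident child's site costs one loss per
   edge climbed, so the winner usually coincides with an inherited site;
   it differs only when the switched child's site sits on a host lineage
   that ended before the resident edge began.

Lists keep at most one site (the cheapest) per host node. The per-level
list bound follows the additive recurrence $a_0 = 1$, $a_1 = 3$,
$a_i = 2a_{i-1} + 2$, whose closed form is $a_i = 5 \cdot 2^{i-1} - 2$
(`a_sites()`); combined with the host-node cap the budget is
$f(i) = \min(5 \cdot 2^{i-1} - 2,\; 2n_h - 1)$, saturating above the level
threshold $\lfloor \lg(n + 2) \rfloor - 1$ (`level_threshold()`). Summing
$f(i)$ against the expected number of parasite nodes per level $g(i)$ gives
the model space bounds evaluated by `space_bound()` — $O(n^{1.42})$ for
Yule-shaped trees and $O(n^{1.58})$ for Uniform-shaped ones, with expected
per-node list sizes $n^{0.42}$ and $n^{0.58}$ and expected running times
$n^{1.84}$ and $n^{2.17}$ (`expected_complexities()`).

## Event semantics and time consistency

The classification of a placement triple (parent at $h$, children at $h_1,
h_2$) is fixed in one place (`classify_event()`, shared verbatim by the
solver and both oracles):

* codivergence requires $h = \mathrm{lca}(h_1, h_2)$ with the children
  separated through different children of $h$; each side loses
  $\mathrm{dist} - 1$ host divergences;
* duplication covers both children at or below $h$ otherwise, losing the
  full edge distances. A separated configuration admits both explanations —
  a codivergence, or an independent duplication at $h$ followed by lineage
  sorting ($D + L(d_1 + d_2)$) — and the classifier reports the cheaper
  one (codivergence on ties, hence always codivergence when
  $C \le D + 2L$, as under the default scheme);
* a host switch keeps one child at or below $h$ and sends the other to a
  lineage incomparable with $h$. The switched lineage lands at the lowest
  ancestor-or-equal of its site whose host edge temporally coexists with
  the take-off edge above $h$ — the landing that minimises losses — and
  tracks down from there. Coexistence is strict open-interval overlap of
  edge rank intervals (`edges_coexist()`), with all leaves at rank $n$
  (extant taxa are contemporaneous) and a notional root stem opening at
  rank 0.

Because every switch is checked against `edges_coexist()`, reported maps
are time-consistent by construction. Exactly one optimal reconciliation is
reported; co-optima are not enumerated. Costs are compared with a fixed
tolerance of `1e-9`, so integer schemes behave exactly.

Two naive references guard the filters: `dtr_full_table()` (the dense DP)
and `dtr_brute_force()` (exhaustive assignment enumeration, guarded to 5
internal parasite nodes and 11 host nodes). The test suite checks three-way
agreement of the optima on hundreds of random tanglegrams under cost
schemes including free losses and effectively forbidden switches.

## Simulators and what they do (not) emulate

`sim_yule_tree()` grows a tree by bifurcating a uniformly chosen leaf until
$n$ leaves exist (equal-rates-Markov), dating internal nodes by birth order
— the natural total order of a pure-birth process. `sim_uniform_tree()`
samples uniformly over labeled topologies (PDA) by attaching leaf $k + 1$
to one of the $2k - 1$ edge slots (including a root stem); because PDA
defines shapes, not times, its dating is a uniformly random linear
extension of the ancestry order. Tip labels follow leaf creation order, so
labeled-topology statistics stay observable. `sim_tanglegram()` draws
independent, equal-sized host and parasite trees from one model and
associates leaves by a uniformly random bijection (sampling with
replacement via `fan_out = TRUE` for robustness tests). Replicate $k$ of a
batch uses an RNG stream derived deterministically from `(seed, k)`.

These generators bracket realistic tree shapes (Yule the balanced end, PDA
the unbalanced end) but do not simulate coevolution: host and parasite are
drawn independently, so passing tests say nothing about how well inferred
events recover a true joint history — only that optima, feasibility and
storage behave as claimed. Real association maps are also richer than a
bijection (failure to diverge, widespread taxa are out of scope, and a
parasite may never inhabit more than one host here).

Two facts about the level-profile model $g(i)$ matter when reading
results. It is exact at level 1 — Yule trees carry $n/3$ cherries in
expectation, PDA trees $n(n-1)/(2(2n-3)) \approx n/4$ — but for deeper
levels it is an asymptotic approximation: every 4-leaf tree has exactly one
level-2 node where the model predicts $8/9$, and at $n = 900$ the observed
Yule level-2 mean is near $0.20n$, not $2n/9 \approx 0.22n$. The simulators
implement the generative processes faithfully rather than the approximate
profile, so level-2 z-tests against the model fail by design; the space
bounds built from $g(i)$ remain valid upper envelopes in practice.

## The space-scaling experiment

`profile_space()` simulates tanglegrams on a log-spaced size grid
(`profile_sizes()`, default 25 sizes in $[10, 2500]$), solves each and
records retained mapping sites against dense-matrix cells. The package's
replication uses 20 replicates per size — enough for stable per-size
medians while keeping the whole experiment inside a few minutes on one
core. `fit_space_scaling()` reduces the profile to per-size medians and
fits $l(n) = a n^b$.

`power_law_fit()` offers two least-squares variants: `scale = "original"`
(Levenberg–Marquardt on the raw values, initialised from the log-log line;
the default, and what the replication uses) and `scale = "log"` (the
ordinary log-log regression). $R^2$ is always reported on the original
scale. The two disagree in a characteristic way on these profiles: the
raw-scale fit is dominated by the largest trees, where per-node lists start
saturating at the $2n_h - 1$ cap, while the log-log fit weights every
decade of $n$ equally — on Yule profiles it lands next to published
constants (about $5.3\,n^{1.23}$), on Uniform profiles it emphasises the
mid-range steepening and reports a higher exponent. Under either variant
both exponents sit below the $1.42$/$1.58$ model bounds, and the observed
medians sit below the evaluated bound sums — the bound over-counts, as
intended for a worst-case envelope.

## Tunable parameters

* **Event costs** `event_costs(codivergence = 0, duplication = 1,
  host_switch = 2, loss = 1)` — dimensionless penalties; the default is the
  classical scheme in which codivergence is free and switches are dearest
  (flagged as Jungle-style; the canonical Jungle values are not published,
  so the scheme is configurable). Infinite costs are allowed; if they make
  every map infeasible, `solve_dtr()` errors rather than reporting a
  non-optimum.
* **Dating** — explicit ranks (NEXUS `DATING` block, `name#rank` labels, or
  `apply_dating(tree, ranks)`); otherwise a canonical dating (by depth,
  then left-to-right) is synthesized, since any ancestry-respecting order
  is valid.
* **Generator settings** — `n` (taxa per tree), `model`
  (`"yule"`/`"uniform"`), `seed`, `fan_out`; sizes and replicates of
  `profile_space()`.

## Degenerate inputs and numerical choices

Trees must be rooted, strictly bifurcating, with at least two uniquely
labeled leaves; polytomies are rejected, not resolved. Branch lengths are
parsed and ignored (both tree models are shape models). Association maps
must be total and single-host; many parasites per host leaf are fine.
Power-law fits require at least three distinct sizes and positive values;
if the nonlinear refinement hits a degenerate surface (e.g. constant data)
the log-log solution is kept. Memory arithmetic uses binary units
(1 KB = 1024 B) and a 36-byte mapping-site record (28 bytes of members plus
two 32-bit header words); the sublinear layout uses the worst-case exponent
0.58 as printed rather than $\lg 3 - 1$.

## Known limitations

The package solves single-instance DTR; it does not search over host
datings (the NP-hard cophylogeny reconstruction problem), enumerate
co-optimal maps, or estimate event costs. No wall-clock benchmarking
against other solvers is included — runtime claims are hardware-bound and
out of scope; the oracle-equivalence and site-cap properties are the
correctness surface instead. The retained lists are not hard-capped: the
elevated switch sites and the codivergence/duplication frontier can, in
principle, push a list past the $2a_{i-1} + 2$ budget. Optimality was
preferred over truncation; across every fixed-seed suite in the package the
realized lists still respect $\min(5 \cdot 2^{i-1} - 2, 2n_h - 1)$.
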