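---
title: "Invariants, modules and reduction of metabolic Petri nets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Invariants, modules and reduction of metabolic Petri nets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petrinetr)
```

## The model

A place/transition Petri net represents a metabolic system as a directed
bipartite graph: passive vertices (places) are metabolites carrying
tokens, active vertices (transitions) are enzyme-catalysed reactions, and
integer arc weights are stoichiometric coefficients.  A marking
`m : P → ℕ₀` is a system state; a transition is enabled when each
pre-place holds at least the arc-weight tokens (and post-places have
capacity, though metabolic models normally leave capacities unbounded),
and firing moves tokens accordingly.  The incidence matrix
`C[p, t] = w(t→p) − w(p→t)` summarizes the net effect, so for a
firing-count vector `τ` the state change is `Δm = C τ` regardless of
ordering.  Read arcs (a metabolite consumed and reproduced by the same
reaction, e.g. a catalyst) are stored as two arcs; their incidence entry
is the net change, possibly zero, while the firing rule still demands the
tokens — this is why the package keeps the arc lists and not just `C`.

Throughout, stoichiometries are restricted to positive integers; rational
coefficients must be pre-scaled, which loses no generality and keeps
every computation exact.

## Minimal invariants by Fourier–Motzkin elimination

T-invariants (elementary flux modes) are the minimal, nontrivial,
nonnegative integer solutions of `C t = 0`; p-invariants solve the
transposed system.  *Minimal* means no other solution's support (set of
nonzero entries) is properly contained in theirs and the gcd of the
entries is one; the minimal solutions generate all others by nonnegative
integer combinations.

The solver is the classical tableau form of Fourier–Motzkin elimination:
each row pairs a candidate firing-count vector with its residual effect
on the not-yet-balanced metabolites (initially, the identity block next
to `Cᵀ`).  Eliminating one metabolite combines every positive-residual
row with every negative-residual row, scaling the pair by the two entries
divided by their gcd; contributing rows are dropped, the combined row is
divided by its content, and rows whose support strictly contains another
row's support are pruned immediately — pruning after every step, not only
at the end, is what keeps the tableau small on practice-shaped nets.
The elimination order follows the standard growth heuristic
(minimize `pos·neg − pos − neg` over the open columns, ties by input
order).  Numerical choices:

* Arithmetic is exact integer arithmetic carried in doubles (exact up to
  2⁵³) with gcd reduction at every combination; any tableau entry
  exceeding 2⁵⁰ aborts the run rather than risking silent rounding.  At
  the scale this package targets, entries stay tiny.
* The tableau has a configurable row cap (default 2 × 10⁵); exceeding it
  raises a structured `fm_tableau_explosion` error carrying the offending
  size, since the worst-case growth of the method is exponential.

On the built-in potato-tuber example (8 metabolites, 9 reactions) the
solver returns exactly two minimal t-invariants — the trivial reversible
isomerase pair and the sucrose-to-starch pathway with firing counts
15:15:15:0:13:2:28:15:28 — and a single p-invariant, the conserved
ADP/ATP pool:

```{r}
net <- potato_net()
t_invariants(net)
p_invariants(net)
```

## Coverage (CTI/CPI) and the Farkas dual

A model is *covered by t-invariants* (CTI) when every reaction occurs in
at least one invariant; an uncovered reaction cannot be balanced at
steady state and usually marks a missing reaction or a modelling error.
`cti_check()` reads coverage off the computed invariants.
`farkas_uncovered()` decides the same question through the dual system:
by the Lemma of Farkas a reaction is uncovered exactly when some
hyperplane normal `s` satisfies `Cᵀ s ≥ 0` with strict slack at that
reaction, i.e. `Cᵀ s − ν = 0` with `ν ≥ 0`.  The signed normal is split
`s = u − v`, `u, v ≥ 0`, so the same nonnegative Fourier–Motzkin engine
applies; reactions with `ν > 0` in some minimal solution form the
uncovered set, and solutions with `ν = 0` are precisely the p-invariants.
The two routes are checked against each other on seeded random nets in
the test suite.

## Steady-state modules

Given the t-invariants, the package derives four module families:

* **MCT-sets** group reactions with identical binary occurrence patterns
  across the invariants; each set is inside or disjoint from every
  support, so the sets partition the covered reactions into disjoint
  building blocks.  Reactions in no invariant are reported as a flagged
  extra group rather than being silently dropped or forced into a set —
  the cleanest of the options the definition leaves open.
* **Enzyme subsets** strengthen the criterion from equal zero patterns to
  proportional coefficient vectors (fixed flux ratios across all steady
  states).  Proportionality is tested by exact integer reduction of each
  coefficient vector to its primitive form, never by floating-point
  ratios; each subset reports its smallest integer flux ratio.  Every
  enzyme subset lies inside one MCT-set by construction.
* **T-clusters** allow overlap: invariants are clustered hierarchically
  under the Tanimoto support distance
  `d = 1 − |X∩Y| / |X∪Y|`.  UPGMA (average linkage, via `hclust`) is the
  default; neighbor joining (via `ape::nj`) is available, its unrooted
  tree cut by removing the longest branches until the tips fall into `k`
  components.  When `k` is not supplied it maximizes the average
  silhouette width over `k = 2 … min(10, n−1)`; members of singleton
  clusters contribute silhouette 0 by the usual convention, since the
  within-cluster mean distance is undefined for them.
* **Minimal cut sets** for an objective reaction are the inclusion-minimal
  hitting sets of the supports of the invariants containing it —
  knockouts that block every steady-state flux through the objective.
  They are enumerated exhaustively by increasing size with
  contains-a-smaller-cut pruning, which is entirely adequate at didactic
  scale; an instance guard (default 20 relevant invariants) aborts before
  the enumeration could blow up.  The objective itself is excluded from
  cut sets unless explicitly admitted.

```{r}
tis <- t_invariants(net)
mct_sets(tis)
enzyme_subsets(tis)
minimal_cut_sets(tis, "glycolysis")
```

## Communities and Q-modularity

Without the steady-state assumption, modules are communities: groups of
vertices densely connected inside and sparsely connected outside,
scored by Q-modularity.  For plain undirected unweighted graphs the
module-sum form `Q = Σ_c [l_c/m − (d_c/2m)²]` applies directly.  A
metabolic Petri net, however, is bipartite, directed and weighted, and
flattening it loses the flow direction.  The package therefore scores
partitions of the net itself with a directed-weighted configuration null
model:

`Q = (1/W) Σ_{i,j same module} [ w_ij − s_out(i) s_in(j) / W ]`

with `W` the total arc weight and `s_out`/`s_in` the weighted
out-/in-strengths, the null term running over all ordered same-module
vertex pairs.  This form was chosen (over a cross-type-restricted null)
because it makes `Q` of the single-module partition exactly zero and is
invariant under reversing every arc — two anchors the test suite asserts
exactly.  It is one admissible bipartite-directed generalization among
several; the scorer is isolated behind `modularity_bipartite()` so
alternatives can be plugged in without touching the optimizer.

Maximizing Q is NP-hard, so the package optimizes with a genetic
algorithm over module-label chromosomes: elitist selection (the best
chromosomes survive unchanged, making the best-so-far score
non-decreasing by construction), binary tournaments, one-point crossover
with label canonicalization, per-vertex mutation to an existing or fresh
label, and a few random immigrant chromosomes per generation to prevent
premature convergence.  Defaults (population 100, 500 generations,
mutation 0.02 per vertex, crossover 0.8, elite 2, stagnation stop after
100 flat generations) were chosen for desk-scale convergence and are all
exposed; the seed is mandatory, making every run reproducible.  On nets
small enough to enumerate all set partitions, the GA's optimum is checked
against the exhaustive maximum in the tests.

## CTI-preserving reduction

Because invariant computation can explode, the package reduces nets
before analysis using two local rules that provably preserve the CTI
property:

* **ITP** (invariant transition pair): a reversible reaction pair with
  exactly mirrored arcs.  The pair is removed and, when the forward
  reaction converts exactly one metabolite into one other 1:1 (the only
  case where the fusion is obviously sound), the two metabolites are
  fused into one place.  More general mirrored pairs are left in place
  with a warning rather than fused — keeping the CTI-conservation
  argument airtight was judged more valuable than maximal reduction.
* **CTP** (common transition pair): a place with exactly one producer
  (weight `a`) and one consumer (weight `b`) is contracted; the two
  reactions are replaced by one lumped reaction firing them `b/g` and
  `a/g` times (`g = gcd(a, b)`), which balances the removed place
  exactly.

Rules are applied ITP-first, then CTP, iterating to a fixpoint; the order
matters only for the trace bookkeeping, not for the CTI outcome, and is
the order in which the example network collapses naturally.  Every
application is recorded in a trace mapping reduced reactions to original
ones with multiplicities.  `lift_invariants()` replays the trace:
merged-reaction coefficients are distributed through the multipliers,
then each removed reversible pair is fired exactly as often as needed to
cancel the residual imbalance at its fused metabolites (the imbalance is
recomputed against the original incidence matrix, later fusions first),
and each removed pair additionally contributes its trivial two-reaction
invariant.  Lifted vectors are verified against `C t = 0` on the original
net — the lift is defined constructively and checked, rather than claimed
minimal; minimality is re-established by an explicit filter.

```{r}
red <- reduce_net(net)
red
t_invariants(red$net)
lift_invariants(red)
```

On the example network this removes four chain metabolites and the
isomerase pair, leaving three lumped reactions with a single invariant
that lifts back to the original pathway exactly.

## The random-net generator

Property tests run against `random_net()`, which emulates the structural
features the methods rely on: connected bipartite topology (grown from a
random spanning tree plus extra arcs), small integer stoichiometries
(uniform on `1:max_weight`), and reversible reaction pairs realized as
exact structural mirrors linked by metadata (40% of transitions in the
suite's property runs, echoing the prevalence of reversible reactions in
metabolic databases; weights 1–2 and nets of 2–6 places and 2–6
transitions keep the exhaustive oracles conclusive).  It does *not*
emulate scale-free degree distributions, currency-metabolite hubs, or
realistic pathway lengths — so passing property tests demonstrate
algebraic correctness of the solvers on small integer systems, not
performance or biological fidelity on genome-scale networks.  The
generator requires a seed and is fully deterministic given one.

Test problem sizes were chosen so the independent oracles stay exact:
bounded-coefficient enumeration for the invariant solver (the bound grows
adaptively with the largest computed coefficient so the enumeration is
always conclusive), Bell-number enumeration of all partitions for the GA,
and the naive adjacency double sum for unipartite Q.

## Degenerate inputs and tie-breaks

* A net with no arcs has an all-zero incidence matrix; every single
  transition is then a (unit) t-invariant.
* An all-zero metabolite column eliminates as a no-op; elimination-order
  ties go to input order, making tableau evolution fully deterministic.
* Two-invariant distance matrices cluster trivially; neighbor joining
  requires at least four invariants and says so.
* An objective reaction occurring in no invariant yields an empty cut-set
  list with status `"already blocked"`.
* Truncated reachability exploration (default cap 10⁶ states) sets a
  flag and logs a message instead of erroring: state-space explosion is
  an expected outcome, not a failure.

## Known limitations

* Fourier–Motzkin is exponential in the worst case; the row cap makes
  that an explicit, catchable error.  The faster nullspace/bit-pattern
  algorithms from the elementary-mode literature are out of scope.
* The bipartite-directed Q formula is one defensible choice, not the
  unique one; comparisons of absolute Q values across scorers are not
  meaningful.
* ITP fusion is deliberately restricted to 1:1 two-metabolite pairs.
* Colored, timed and stochastic extensions of Petri nets, symbolic
  state-space compression, and overlapping communities are out of scope.
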