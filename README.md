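# petrinetr

Petri-net analysis of metabolic networks: steady-state invariants,
functional-module detection, and CTI-preserving network reduction.

## The problem

A metabolic reaction system can be modelled as a place/transition Petri net:
metabolites are places, reactions (named after their enzymes) are
transitions, and integer arc weights carry the stoichiometry.  The incidence
matrix `C` (one row per place, one column per transition) holds the net
token change per firing, so a firing-count (Parikh) vector `τ` moves the
system state by `Δm = C τ`.

Two families of questions about such a net matter to modellers, and this
package answers both:

* **Steady-state structure.**  A *t-invariant* is a minimal, nontrivial,
  nonnegative integer solution of `C t = 0` — a set of reactions with fixed
  relative firing counts whose combined effect cancels, i.e. an elementary
  flux mode or basic steady-state pathway.  A *p-invariant* solves
  `Cᵀ p = 0` and names a conserved metabolite pool.  A model in which some
  reaction lies outside every t-invariant cannot balance that reaction at
  steady state — a strong hint of a modelling error — so the *covered by
  t-invariants* (CTI) property is a standard verification criterion.  On
  top of the invariants the package derives functional modules:
  **MCT-sets** (maximal sets of reactions occurring in exactly the same
  invariants), **enzyme subsets** (reactions with fixed flux ratios across
  all steady states), **t-clusters** (hierarchical clustering of invariants
  under the Tanimoto support distance, UPGMA or neighbor joining, with
  silhouette-guided cluster counts), and **minimal cut sets** (smallest
  knockout sets blocking all steady-state flux through an objective
  reaction).
* **Connectivity structure.**  Ignoring the steady state, vertices can be
  partitioned into communities scored by **Q-modularity**; the package
  scores both plain undirected graphs (`Q = Σ_c [l_c/m − (d_c/2m)²]`) and
  the bipartite directed weighted net itself (directed configuration null
  model), and optimizes the partition with a seeded genetic algorithm.

Computing all t-invariants is done by **Fourier–Motzkin elimination** over
the integers, the classical tableau algorithm: start from the transposed
incidence matrix beside an identity block and repeatedly combine
positive/negative row pairs to zero out one metabolite column at a time,
pruning non-minimal candidate rows after every step.  Because the tableau
can explode on large nets, the package also implements **CTI-preserving
reduction**: *common transition pairs* (a place with exactly one producer
and one consumer) are contracted into lumped reactions and *invariant
transition pairs* (reversible forward/backward reactions) are removed with
fusion of the interconverted metabolites.  Invariants computed on the
reduced net are lifted back to the original one through the recorded trace.

## Worked example

The built-in fixture is the sucrose-to-starch carbon metabolism of young
potato tubers: 8 metabolites, 9 reactions, among them the reversible
phosphoglucoisomerase pair and a glycolysis reaction converting fructose
6-phosphate plus 29 ADP into 29 ATP.

```r
library(petrinetr)
net <- potato_net()
t_invariants(net)
#> 2 minimal t-invariants over 9 transitions
#>   inv1: {PGI_f, PGI_b}
#>   inv2: {15 invertase, 15 hexokinase, 15 fructokinase, 13 PGI_b,
#>          2 glycolysis, 28 starch_synthase, 15 sucrose_input,
#>          28 starch_output}
```

`inv1` is the trivial invariant of the reversible isomerase: firing forward
then backward changes nothing.  `inv2` is the basic pathway of the network:
per 15 sucrose taken up and cleaved, 15 hexoses are phosphorylated on each
branch, 13 fructose 6-phosphate are isomerized backwards to glucose
6-phosphate, 2 enter glycolysis (regenerating 2 × 29 = 58 ATP), and 28
glucose 6-phosphate become starch.  Every reaction sits in at least one
invariant, so the model passes verification:

```r
cti_check(net)
#> t-invariant (CTI) coverage: complete (9 covered, 0 uncovered)
p_invariants(net)
#> 1 minimal p-invariant over 8 places
#>   inv1: {ADP, ATP}          # the conserved adenylate pool
mct_sets(t_invariants(net))
#> 3 MCT-sets
#>   1: {invertase, hexokinase, fructokinase, glycolysis,
#>       starch_synthase, sucrose_input, starch_output}  pattern 01
#>   2: {PGI_f}  pattern 10
#>   3: {PGI_b}  pattern 11
reduce_net(net)
#> network reduction: 4 CTP, 1 ITP, 3 reactions remain
#>   places 8 -> 3, transitions 9 -> 3
```

The reduction contracts the four chain metabolites (sucrose, glucose,
fructose, starch), removes the reversible pair while fusing the two hexose
phosphates, and leaves a 3-reaction net with a single t-invariant;
`lift_invariants()` expands it back to `inv2` above exactly.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/petrinetr.R demo --seed 1
Rscript inst/cli/petrinetr.R invariants --input inst/extdata/potato.rxn
```

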