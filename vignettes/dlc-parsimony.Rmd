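---
title: "Parsimony reconciliation in the duplication-loss-coalescence model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsimony reconciliation in the duplication-loss-coalescence model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlcrecon)
```

## The model

Phylogenetic reconciliation explains the incongruence between a gene tree
`G` and a species tree `S`, linked by a leaf map `Le` that sends each
sampled gene to the species it was found in, as a history of evolutionary
events.  The duplication-loss-coalescence (DLC) model adds explicit *loci*
to the classical duplication-loss picture, which lets it separate genuine
duplications from deep coalescence.  A reconciliation is a *labeled
coalescent tree* (LCT): a species map `M` sending every gene node to a
species node, a finite locus set, and a locus map sending every gene node
to a locus, subject to five constraints:

1. `M` extends `Le` on the gene leaves;
2. every node maps to an ancestor-or-self of its children's images;
3. gene leaves in the same species (paralogs) carry distinct loci;
4. every locus in the set is used by some gene node;
5. every locus except the root's is created exactly once (the root's is
   never created).

A non-root gene node whose locus differs from its parent's induces a
**duplication** on the branch above it.  A locus present at the top of a
species branch, or created inside it, but absent at its bottom induces a
**loss** on that branch.  With nonnegative per-event costs `cost_dup` and
`cost_loss` (deep coalescence is free in this model), the cost of an LCT
is `d * cost_dup + l * cost_loss`; the optimization problem asks for a
minimum-cost LCT and the decision problem whether cost at most `k` is
attainable.  Both are provably intractable — the package exists to make
the model, its event counting, and the constructions behind those
hardness results concrete and testable at desk scale.

## Implied speciation nodes

A single gene branch may span several species branches.  Before the locus
map is defined, degree-2 *implied speciation nodes* are inserted so that
every gene branch crosses one species branch at a time
(`add_implied_speciations()`).  Two readings in the procedure's statement
deserve a note, both recorded here as the package's interpretation:

* The first insertion condition ("the parent image of `M(g)` differs from
  `M(p(g))`") carries the implicit side condition `M(g) != M(p(g))`;
  taken literally it would fire even for a node mapped to the same
  species node as its parent and insert an unbounded chain.  The fixpoint
  the procedure is meant to reach — every non-root node satisfies
  `M(p(g)) == M(g)` or `M(p(g)) == p(M(g))` — pins down this reading.
* The procedure is stated for internal nodes, but loss counting through
  branch tops and bottoms needs terminal gene branches subdivided too
  (a locus must be seen to traverse every species branch on its way to a
  leaf).  The package therefore applies the conditions to every non-root
  node.

The fixpoint is canonical: for each original gene branch it equals the
per-edge subdivision of the species path it spans, with one extra node at
the parent's species node when the parent is not a speciation node.  The
implementation processes nodes in a configurable order and the test suite
checks order-invariance and idempotence against an independently coded
per-edge oracle.

## Duplication placements

Duplications depend only on the locus map, and locus maps are
interchangeable with *duplication placements*: edge sets containing, for
every paralogous leaf pair, an edge separating the pair.  Removing a
placement's `d` edges partitions the gene tree into `d + 1` components,
which become the loci (`locus_map_from_placement()`); conversely the
locus-change edges of a valid locus map form a placement of exactly the
duplication count (`placement_from_locus_map()`).  The package's scoring
pipeline follows the model's prescribed order: fix the species map, insert
implied speciation nodes, then define the locus map on the augmented tree.
Loci are opaque consecutive integers in preorder discovery order; only the
partition they induce is meaningful.

## Solvers

Minimizing duplications alone is minimum multicut on the gene tree with
the paralog pairs as terminal pairs — NP-hard, so the exact solvers are
deliberately combinatorial:

* `min_dup_exhaustive()` enumerates edge subsets in increasing size with
  chunked bitmask coverage tests; it is the brute-force reference.
* `min_dup_exact()` is a branch-and-bound: superset pairs and dominated
  edges are removed, branching picks the uncovered pair with fewest
  candidate edges, the lower bound is a greedy set of edge-disjoint
  uncovered paths, and the factor-2 approximation seeds the incumbent.
* `min_dup_approx()` is the classical primal-dual scheme for multicut on
  trees (process least common ancestors bottom-up, saturate path edges,
  reverse-delete), guaranteed within twice the optimum.  A
  polynomial-time approximation scheme for multicut in binary trees
  exists in the literature; the package intentionally ships the simpler
  factor-2 method, whose guarantee the tests verify against the exact
  solver, since nothing downstream needs the stronger scheme.

`solve_dlcop()` minimizes the full objective.  When `cost_loss == 0` the
optimum provably collapses to `cost_dup` times the minimum placement size
(losses are free, and any valid species map attains them), so the
branch-and-bound path is used.  Otherwise every valid species map is
enumerated (each internal node's image ranges over the species path
between its parent's image and its subtree's lca image) and, per map,
placements on the augmented tree are scored up to a size cap of the
paralog-pair count plus a configurable slack.  No optimum ever needs more
duplications than pairs when duplications cost anything; whether extra
duplications could ever pay for themselves purely through losses is not
settled by the model's description, so the cap is honest, configurable,
and recorded in the result's `meta`.  Guards on edge counts and map
counts are hard errors, never silent truncation.  Tie-breaks are
lexicographic over byte-ordered (radix-sorted) edge ids, so arg-mins are
reproducible across platforms and locales.

`solve_dlcdp()` answers the decision problem, short-circuiting as soon as
any placement within budget is found (the approximation is tried first).
Costs in all shipped constructions are integers; the comparison against
`k` uses a `1e-9` slack purely to absorb floating-point arithmetic on
user-supplied decimal costs.

## The decision-side construction

`build_np_instance()` compiles a 3-CNF formula (m variables, n clauses,
normalized so clauses have three distinct variables, tautologies are
dropped, and unused variables are compacted) into a decision instance
with duplication cost 1, loss cost 0, and budget `2n + m`:

* a *variable gadget* per variable: a root over a "true" and a "false"
  caterpillar, whose twin leaves `y_i`/`ybar_i` share a species leaf and
  therefore force one duplication per gadget, on one side or the other;
* a *clause gadget* per clause: three literal nodes whose `k` leaves
  share a species leaf, forcing two duplications among the three literal
  edges — the uncut literal is the one that must satisfy the clause,
  because its `k'` leaf is paired with an indexed leaf inside the
  corresponding variable gadget's chosen side;
* "arbitrary" shapes (the gadget backbone and the species tree) are
  deterministic left combs so instances are byte-reproducible, and
  species leaves are labeled `1..2mn+m+n` as plain integers.

`np_solution_from_valuation()` and `np_valuation_from_solution()`
implement the two constructive proof directions (true means a duplication
on the path from the gadget root to `y_i`); the test suite closes the
loop through the solver: a formula is satisfiable exactly when the
compiled instance admits `2n + m` duplications.

## The optimization-side construction

`build_apx_instance()` compiles a bounded-occurrence formula
(MAX3SAT(B)) into an optimization instance with duplication cost
`2Bn^2`, loss cost 1, and satisfiability budget
`b = (10B+2)n^3 + 121n^2`.  Thorn gadgets (caterpillars with a designated
end tip) wire losses to the Boolean structure: each literal occurrence
carries an `(n^2-1)`-thorn in its variable gadget that maps leaf-for-leaf
into an `n^2`-thorn hanging off the species trunk at that clause
position, whose end tip receives the clause gadget's `k''` leaf.  A
duplication separating the two sides prices `n^2` losses on that species
thorn's terminal edges; a satisfied clause leaves its chosen literal's
thorn loss-free (2n^2 per clause), an unsatisfied one pays in all three
(3n^2).  Losses on thorn root edges are bookkept with the trunk (they
emanate from trunk nodes and are covered by the trunk's `< 121n^2`
allowance), which is how `apx_loss_audit()` classifies them.

Points where the construction is silent and the package had to choose:

* The true/false duplication conventions of the two constructions are
  mirror images (decision side: duplication on the `beta` branch means
  true; optimization side: on the `bbar` branch).  Each compiler follows
  its own convention; they are easy to conflate.
* The gene occurrence thorn has `n^2 - 1` leaves but the species thorn
  `n^2`; indices `1..n^2-1` pair off and the species end tip receives
  only `k''`.
* `n >= 2` is required (an `(n^2-1)`-thorn is empty at `n = 1`; the
  construction is asymptotic in `n` anyway), and degenerate gadget shapes
  at occurrence counts 0 and 1, and at `m = 3n` (the shared thorn shrinks
  to a single leaf), are resolved in the natural way.
* The reference solution is defined only for satisfying valuations; the
  explicit `allow_unsatisfied` switch places the two clause duplications
  on the first two literal edges of an unsatisfied clause (the same
  replacement the well-behaving argument uses), so that wrong valuations
  can be audited.  The gap constant `alpha = epsilon / (20B + 4)` is kept
  symbolically via its denominator: `epsilon` is existential and the
  package makes no numeric claim about it.

## Generators and what the tests show

The generators (`random_tree`, `random_instance`, `random_cnf`,
`random_species_map`) are purely structural: uniform recursive splits for
tree shapes, a paralogy rate for how often a gene leaf joins an occupied
species leaf, and budget-balanced literal sampling for formulas.  They
seed their own PRNG from an explicit argument and are bit-stable.  They
do not emulate birth-death gene family evolution, coalescent locus
histories, branch lengths, or reconstruction error in real gene trees —
the constructions under test are combinatorial, so structural coverage is
the relevant notion of realism, and passing tests say nothing about
statistical performance on empirical gene families.

Problem sizes were chosen to keep the full suite in the minutes range on
one core: exhaustive soundness over all one- and two-clause formulas on
three variables plus 200 random formulas up to 5 variables and 4 clauses;
500 placement/locus round trips; 200 instances of at most 12 gene-tree
edges for the approximation factor (with the exact side re-verified by
exhaustive subsets); 200 random triples for the implied-speciation
fixpoint; and loss audits at `n = 2, 3`.

## Limitations

Coalescence events are never counted — the model prices them at zero and
the package follows suit, so `EventCount` carries duplications and losses
only.  Exact optimization is enumeration under guards and is meant for
instances of a few dozen gene-tree edges; the only large-instance tool is
the factor-2 approximation for the duplication-only objective.  Trees are
rooted and binary (except for the degree-2 nodes the augmentation
inserts), without branch lengths.
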