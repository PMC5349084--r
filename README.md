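# dlcrecon

Parsimony reconciliation under the duplication-loss-coalescence (DLC)
model, with the constructions that make its intractability concrete.

## What this is for

Given a rooted binary gene tree *G*, a species tree *S*, and a leaf map
*Le : L(G) → L(S)* saying which species each sampled gene came from, a
DLC reconciliation (a *labeled coalescent tree*, LCT) assigns every gene
node a species node and a locus.  A locus change along a gene branch is a
**duplication**; a locus present at the top of a species branch but gone
at its bottom is a **loss**; deep coalescence is unpriced.  The
maximum-parsimony problem minimizes

    cost = d · C_d + ℓ · C_ℓ

over all valid LCTs.  This problem is NP-hard even for duplications alone
(it is minimum multicut on the gene tree, with paralogous leaf pairs as
terminal pairs) and APX-hard once losses are priced.  `dlcrecon` is for
people who work on the algorithmics of this model: it scores
reconciliations event-by-event, solves desk-scale instances exactly,
approximates the duplication-only objective within factor 2, and —
centrally — compiles 3-CNF / MAX3SAT(B) formulas into the DLC instances
behind both hardness results, together with the constructive maps between
Boolean valuations and solutions, so every step of those arguments can be
executed and checked on real objects.

## Worked example

The single clause (x1 ∨ ¬x2 ∨ x3) compiles into a decision instance with
three variable gadgets, one clause gadget, and budget k = 2n + m = 5:

```r
library(dlcrecon)
ex <- np_example_single_clause()
ex$instance
#> DLC decision instance from a 3-CNF formula
#>   variables: 3  clauses: 1
#>   gene tree: 35 nodes; species tree: 19 nodes
#>   decision parameter k = 5

res <- min_dup_exact(ex$instance$recon)
res
#> DLC solver result (optimal)
#>   placement size: 5
#>   duplications: 5  losses: 17  cost: 5
#>   candidates explored: 9
```

Five duplications are necessary and sufficient: one per variable gadget
(the side it lands on *is* the truth value) and two in the clause gadget
(the uncut literal edge is the one whose literal satisfies the clause).
The cost is 5 because losses are free here (C_d = 1, C_ℓ = 0); the 17
losses are reported for transparency.  Reading the optimal placement back
as a valuation:

```r
np_valuation_from_solution(ex$instance, res$best_placement)
#> [1]  TRUE FALSE  TRUE
```

which indeed satisfies the clause, and the decision answers flip exactly
at the budget:

```r
solve_dlcdp(ex$instance$recon, 5)   # TRUE
solve_dlcdp(ex$instance$recon, 4)   # FALSE
```

The same loop runs from the shell:

```sh
dlc reduce --mode np --cnf clause.cnf --out bundle/
dlc solve --gene bundle/gene.nwk --species bundle/species.nwk \
    --leafmap bundle/leafmap.tsv --dup-cost 1 --loss-cost 0 --decision 5
# exit code 0 (yes)
```

The optimization-side compiler works the same way (`build_apx_instance`,
`apx_solution_from_valuation`, `apx_loss_audit`) and its loss audit
reproduces the construction's ledgers: 5n duplications, 2n² thorn losses
per satisfied clause, 3n² per unsatisfied one, trunk losses below 121n².

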