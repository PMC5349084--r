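Package: dlcrecon
Title: Parsimony Reconciliation and Hardness Gadgets for the
    Duplication-Loss-Coalescence Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring and optimizing gene-tree/species-tree
    reconciliations under the duplication-loss-coalescence (DLC) parsimony
    model.  Implements the labeled coalescent tree (LCT) representation with
    its validity constraints, implied speciation insertion, duplication and
    loss event counting, and the equivalence between locus maps and
    duplication placements.  Provides exact (branch-and-bound and exhaustive)
    and factor-2 approximate minimum-duplication solvers, desk-scale exact
    optimization and decision solvers, compilers from 3-CNF formulas to
    DLC decision and optimization instances via variable, clause, and thorn
    gadgets, constructive maps between Boolean valuations and
    reconciliation solutions, deterministic generators for random trees,
    instances, and formulas, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
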