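test_that("the single-clause instance has the published shape and budget", {
  ex <- np_example_single_clause()
  np <- ex$instance
  expect_identical(np$decision_k, 5L)
  expect_length(tree_leaves(np$recon$species_tree), 10L)   # 2mn + m + n
  gi <- np$gadget_index
  expect_setequal(unique(gi$gadget),
                  c("var_1", "var_2", "var_3", "clause_1", "backbone"))
  # clause gadget: delta over delta-prime and the three lambda nodes, each
  # lambda with two leaf children
  lam <- gi$node[gi$role == "lambda"]
  expect_length(lam, 3L)
  for (l in lam) {
    kids <- tree_children(np$recon$gene_tree, l)
    expect_length(kids, 2L)
    expect_true(all(vapply(kids, function(k) is_leaf(np$recon$gene_tree, k),
                           logical(1))))
  }
})

test_that("gadget and leaf-map bookkeeping matches the construction counts", {
  for (i in 1:10) {
    set.seed(i)
    cnf <- random_cnf(sample(3:5, 1L), sample(1:4, 1L), 13L, seed = 40L + i)
    np <- build_np_instance(cnf)
    m <- cnf$num_vars; n <- length(cnf$clauses)
    inst <- np$recon
    expect_identical(np$decision_k, 2L * n + m)
    expect_length(tree_leaves(inst$species_tree), 2L * m * n + m + n)
    # occupancy: m y-pairs and 3n k-prime/y duos share a leaf pairwise,
    # n k-triples share one leaf, and the remaining 2mn-3n gene leaves
    # sit alone on fresh leaves (so every species leaf is an image)
    shared <- table(inst$leaf_map)
    expect_identical(sum(shared == 2L), m + 3L * n)
    expect_identical(sum(shared == 3L), n)
    expect_identical(sum(shared == 1L), 2L * m * n - 3L * n)
    # gadget index is a bijection onto the gene nodes
    expect_setequal(np$gadget_index$node, inst$gene_tree$ids)
    expect_false(anyDuplicated(np$gadget_index$node) > 0L)
  }
})

test_that("satisfying valuations compile to valid placements of size 2n+m", {
  ex <- np_example_single_clause()
  np <- ex$instance
  v <- c(TRUE, TRUE, FALSE)
  D <- np_solution_from_valuation(np, v)
  expect_length(D, 5L)
  expect_true(is_duplication_placement(np$recon, D))
  expect_identical(np_valuation_from_solution(np, D), v)
  # unsatisfying valuation: the clause has no true literal
  expect_error(np_solution_from_valuation(np, c(FALSE, TRUE, FALSE)),
               "clause 1")

  for (i in 1:20) {
    cnf <- random_cnf(sample(3:5, 1L), sample(1:4, 1L), 13L, seed = 60L + i)
    np2 <- build_np_instance(cnf)
    sat <- cnf_satisfiable(cnf)
    if (!sat$satisfiable) next
    D2 <- np_solution_from_valuation(np2, sat$valuation)
    expect_length(D2, np2$decision_k)
    expect_true(is_duplication_placement(np2$recon, D2))
    expect_identical(np_valuation_from_solution(np2, D2), sat$valuation)
  }
})

test_that("variable gadgets force one side and clause gadgets force two edges", {
  ex <- np_example_single_clause()
  np <- ex$instance
  tr <- np$recon$gene_tree
  # any valid placement separates y_i from its barred twin inside gadget i
  D <- np_solution_from_valuation(np, c(TRUE, FALSE, TRUE))
  for (i in 1:3) {
    pe <- path_edges(tr, paste0("y_", i), paste0("ybar_", i))
    expect_true(any(D %in% pe))
  }
  # a malformed placement with duplications on both sides of a gadget
  D_bad <- c(D, "bbar_1")
  expect_error(np_valuation_from_solution(np, D_bad), "both sides")
})

test_that("a solver-found optimal placement satisfies the formula", {
  ex <- np_example_single_clause()
  np <- ex$instance
  res <- min_dup_exact(np$recon)
  expect_length(res$best_placement, 5L)
  val <- np_valuation_from_solution(np, res$best_placement)
  expect_true(eval_cnf(np$formula, val))
})
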