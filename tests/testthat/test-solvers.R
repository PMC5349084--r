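test_that("paralog pair count is the sum of per-species binomials", {
  inst0 <- random_instance(4L, 6L, 0, seed = 1L)
  expect_length(paralog_pairs(inst0), 0L)
  g <- parse_newick("((a,b)u,c)r;")
  s <- parse_newick("(A,B)rs;")
  inst3 <- recon_instance(g, s, c(a = "A", b = "A", c = "A"))
  expect_length(paralog_pairs(inst3), 3L)
  for (i in 1:20) {
    inst <- random_instance(sample(3:9, 1L), sample(2:6, 1L), 0.5,
                            seed = 100L + i)
    want <- sum(choose(table(inst$leaf_map), 2L))
    expect_length(paralog_pairs(inst), want)
  }
})

test_that("exact minimum duplications match the exhaustive-subset oracle", {
  inst0 <- random_instance(4L, 6L, 0, seed = 2L)
  expect_length(min_dup_exact(inst0)$best_placement, 0L)
  for (i in 1:40) {
    inst <- random_instance(sample(3:7, 1L), sample(2:5, 1L), 0.5,
                            seed = 200L + i)   # <= 12 gene edges
    res <- min_dup_exact(inst)
    expect_true(res$optimal)
    expect_true(is_duplication_placement(inst, res$best_placement))
    expect_identical(length(res$best_placement), oracle_min_multicut(inst))
    bf <- min_dup_exhaustive(inst)
    expect_identical(length(bf$best_placement), length(res$best_placement))
  }
})

test_that("single paralog pair needs exactly one cut on its path", {
  g <- parse_newick("((a,b)u,c)r;")
  s <- parse_newick("(A,B)rs;")
  inst <- recon_instance(g, s, c(a = "A", b = "B", c = "A"))
  res <- min_dup_exact(inst)
  expect_length(res$best_placement, 1L)
  expect_true(res$best_placement %in% path_edges(g, "a", "c"))
})

test_that("size guard errors point to the approximation", {
  inst <- random_instance(30L, 10L, 0.5, seed = 3L)
  expect_error(min_dup_exact(inst, max_edges = 10L), "min_dup_approx")
})

test_that("the primal-dual approximation is valid and within factor 2", {
  for (i in 1:60) {
    inst <- random_instance(sample(3:7, 1L), sample(2:5, 1L), 0.6,
                            seed = 300L + i)
    ap <- min_dup_approx(inst)
    expect_false(ap$optimal)
    expect_true(is_duplication_placement(inst, ap$best_placement))
    ex <- min_dup_exact(inst)
    expect_lte(length(ap$best_placement), 2L * length(ex$best_placement))
  }
})

test_that("minimum duplications ignore the species tree", {
  for (i in 1:10) {
    inst <- random_instance(5L, 4L, 0.5, seed = 400L + i)
    other <- random_tree(6L, seed = 500L + i, prefix = "s")
    le2 <- inst$leaf_map
    le2[] <- tree_leaves(other)[as.integer(factor(inst$leaf_map))]
    inst2 <- recon_instance(inst$gene_tree, other, le2)
    expect_identical(length(min_dup_exact(inst)$best_placement),
                     length(min_dup_exact(inst2)$best_placement))
  }
})

test_that("species-map enumeration is exactly the constraint-filtered set", {
  # cherry on one species leaf: internal image ranges over that leaf's
  # ancestors, so depth+1 maps
  g <- parse_newick("(a,b)r;")
  s <- parse_newick("((A,B)x,C)rs;")
  inst <- recon_instance(g, s, c(a = "A", b = "A"))
  maps <- enumerate_species_maps(inst)
  expect_length(maps, 3L)
  for (m in maps) {
    expect_identical(nrow(dlcrecon:::check_species_map(inst, m)), 0L)
  }
  # brute-force count over all |V(S)|^|I(G)| assignments
  for (i in 1:10) {
    inst2 <- random_instance(sample(2:4, 1L), sample(2:3, 1L), 0.5,
                             seed = 600L + i)
    maps2 <- enumerate_species_maps(inst2)
    expect_false(any(duplicated(vapply(maps2, paste, "", collapse = "|"))))
    gt <- inst2$gene_tree; st <- inst2$species_tree
    internals <- tree_internal(gt)
    grid <- expand.grid(rep(list(st$ids), length(internals)),
                        stringsAsFactors = FALSE)
    brute <- 0L
    for (r in seq_len(nrow(grid))) {
      m <- stats::setNames(as.character(unlist(grid[r, ])), internals)
      m[tree_leaves(gt)] <- inst2$leaf_map[tree_leaves(gt)]
      ok <- nrow(dlcrecon:::check_species_map(inst2, m)) == 0L
      if (ok) brute <- brute + 1L
    }
    expect_identical(length(maps2), brute)
  }
})

test_that("optimization collapses to minimum multicut when losses are free", {
  for (i in 1:10) {
    inst <- random_instance(sample(3:6, 1L), sample(2:4, 1L), 0.5,
                            seed = 700L + i, cost_dup = 1, cost_loss = 0)
    r <- solve_dlcop(inst)
    expect_identical(r$events$cost,
                     as.numeric(length(min_dup_exact(inst)$best_placement)))
  }
  # single-leaf gene tree: zero cost
  g1 <- parse_newick("a;")
  s <- parse_newick("(A,B)rs;")
  inst1 <- recon_instance(g1, s, c(a = "A"), 1, 1)
  expect_identical(solve_dlcop(inst1)$events$cost, 0)
})

test_that("optimal cost is monotone in each event cost", {
  for (i in 1:5) {
    inst <- random_instance(4L, 3L, 0.5, seed = 800L + i, cost_dup = 1,
                            cost_loss = 1)
    base <- solve_dlcop(inst)$events$cost
    up_d <- inst; up_d$cost_dup <- 2
    up_l <- inst; up_l$cost_loss <- 2
    expect_gte(solve_dlcop(up_d)$events$cost, base)
    expect_gte(solve_dlcop(up_l)$events$cost, base)
  }
})

test_that("solver results are internally consistent", {
  for (i in 1:5) {
    inst <- random_instance(4L, 3L, 0.6, seed = 900L + i, cost_dup = 2,
                            cost_loss = 1)
    r <- solve_dlcop(inst)
    expect_true(is_duplication_placement(inst, r$best_placement))
    ev <- reconciliation_cost(inst, r$best_lct)
    expect_identical(ev$cost, r$events$cost)
    expect_identical(nrow(validate_lct(inst, r$best_lct)), 0L)
    # decision at the optimum is yes; one unit less (integer costs) is no
    expect_true(solve_dlcdp(inst, r$events$cost))
    if (r$events$cost >= 1) {
      expect_false(solve_dlcdp(inst, r$events$cost - 1))
    }
  }
})

test_that("the non-terminal search switch is rejected when losses cost", {
  inst <- random_instance(4L, 3L, 0.5, seed = 42L, cost_dup = 1, cost_loss = 1)
  expect_error(solve_dlcop(inst, leaf_dup_free = TRUE), "cost_loss")
  # non-sibling paralogs: pushing duplications off terminal edges is free
  g <- parse_newick("((a,b)u,c)r;")
  s <- parse_newick("(A,B)rs;")
  inst0 <- recon_instance(g, s, c(a = "A", b = "B", c = "A"))
  r1 <- solve_dlcop(inst0)
  r2 <- solve_dlcop(inst0, leaf_dup_free = TRUE)
  expect_identical(r1$events$cost, r2$events$cost)
  # sibling paralogs are separable only by terminal edges
  sib <- recon_instance(g, s, c(a = "A", b = "A", c = "B"))
  expect_error(solve_dlcop(sib, leaf_dup_free = TRUE), "terminal")
})
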