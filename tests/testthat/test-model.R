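cherry_instance <- function(cost_dup = 1, cost_loss = 0) {
  g <- parse_newick("((g1,g2)u,g3)r;")
  s <- parse_newick("((A,B)x,C)rs;")
  recon_instance(g, s, c(g1 = "A", g2 = "A", g3 = "C"), cost_dup, cost_loss)
}

test_that("instance construction validates maps and costs", {
  g <- parse_newick("(a,b)r;")
  s <- parse_newick("(A,B)rs;")
  expect_error(recon_instance(g, s, c(a = "A")), "not total")
  expect_error(recon_instance(g, s, c(a = "A", b = "Z")), "not species leaves")
  expect_error(recon_instance(g, s, c(a = "A", b = "B"), cost_dup = -1), "nonnegative")
  inst <- recon_instance(g, s, c(a = "A", b = "B"))
  expect_s3_class(inst, "dlc_instance")
})

test_that("validate_lct flags exactly the violated constraint", {
  inst <- cherry_instance()
  # constant locus map, lca species map: valid
  lct <- make_lct(inst, placement = c("g2"))
  expect_identical(nrow(validate_lct(inst, lct)), 0L)

  # constraint 3: the two paralogs on one locus
  bad <- make_lct(inst, placement = character(0))
  v <- validate_lct(inst, bad)
  expect_identical(unique(v$constraint), 3L)
  expect_match(v$witness, "g1")

  # constraint 5: hand-built locus map with a locus created twice
  lct2 <- make_lct(inst, placement = c("g2"))
  lm <- lct2$locus_map
  lm[] <- 1L
  lm[c("g1", "g2")] <- 2L   # locus 2 created at both g1 and g2
  lct2$locus_map <- lm
  lct2$locus_set <- 1:2
  v2 <- validate_lct(inst, lct2)
  expect_true(5L %in% v2$constraint)

  # constraint 4: an unused locus in the set
  lct3 <- make_lct(inst, placement = c("g2"))
  lct3$locus_set <- c(lct3$locus_set, 99L)
  expect_true(4L %in% validate_lct(inst, lct3)$constraint)
})

test_that("implied speciation inserts the canonical subdivision", {
  g <- parse_newick("(a,b)r;")
  s <- parse_newick("((A,B)x,C)rs;")
  # every gene node on one species node: identity
  m0 <- c(a = "A", b = "A", r = "A")
  aug0 <- add_implied_speciations(g, s, m0)
  expect_identical(aug0$tree$ids, g$ids)

  # gene edge spanning a 2-edge species path: exactly one insertion
  m1 <- c(a = "A", b = "C", r = "rs")
  aug1 <- add_implied_speciations(g, s, m1)
  expect_length(aug1$tree$ids, 4L)
  ins <- setdiff(aug1$tree$ids, g$ids)
  expect_identical(unname(aug1$species_map[ins]), "x")
})

test_that("implied speciation is idempotent and order/oracle-consistent", {
  for (i in 1:30) {
    inst <- random_instance(sample(3:8, 1L), sample(2:6, 1L), 0.4,
                            seed = 5000L + i)
    sm <- random_species_map(inst, seed = 6000L + i)
    aug <- add_implied_speciations(inst$gene_tree, inst$species_tree, sm)
    # oracle: canonical per-edge subdivision
    want <- oracle_subdivision_signature(inst$gene_tree, inst$species_tree, sm)
    got <- augmented_signature(inst$gene_tree, aug)
    expect_identical(got[names(want)], want)
    # order invariance (signature level)
    set.seed(i)
    aug2 <- add_implied_speciations(inst$gene_tree, inst$species_tree, sm,
                                    node_order = sample(inst$gene_tree$ids))
    expect_identical(augmented_signature(inst$gene_tree, aug2)[names(want)], want)
    # idempotence
    aug3 <- add_implied_speciations(aug$tree, inst$species_tree, aug$species_map)
    expect_length(aug3$tree$ids, length(aug$tree$ids))
  }
})

test_that("nodes/bottoms/tops follow their definitions", {
  inst <- cherry_instance()
  m <- lca_species_map(inst)
  aug <- add_implied_speciations(inst$gene_tree, inst$species_tree, m)
  sm <- aug$species_map
  # species leaf with two mapped gene leaves
  expect_setequal(nodes_of(sm, aug$tree, "A"), c("u", "g1", "g2"))
  expect_setequal(bottoms_of(sm, aug$tree, "A"), c("g1", "g2"))
  # empty species node
  expect_length(nodes_of(sm, aug$tree, "B"), 0L)
  expect_length(bottoms_of(sm, aug$tree, "B"), 0L)
  # tops(s) == bottoms(p(s)); tops at the root is empty
  expect_length(tops_of(sm, aug$tree, inst$species_tree, "rs"), 0L)
  for (i in 1:10) {
    inst2 <- random_instance(4L, 4L, 0.3, seed = 6500L + i)
    sm2 <- random_species_map(inst2, seed = 6600L + i)
    aug2 <- add_implied_speciations(inst2$gene_tree, inst2$species_tree, sm2)
    for (s2 in tree_edges(inst2$species_tree)) {
      expect_setequal(
        tops_of(aug2$species_map, aug2$tree, inst2$species_tree, s2),
        bottoms_of(aug2$species_map, aug2$tree,
                   tree_parent(inst2$species_tree, s2)))
    }
  }
})

test_that("duplication counting depends only on the locus map", {
  g <- parse_newick("((a,b)u,c)r;")
  const <- stats::setNames(rep(1L, 5L), g$ids)
  expect_identical(count_duplications(g, const), 0L)
  allswitch <- stats::setNames(c(1L, 2L, 3L, 4L, 5L), g$ids)
  expect_identical(count_duplications(g, allswitch), 4L)
  expect_error(count_duplications(g, const[-1L]), "not total")
})

test_that("loss counting matches the definitional oracle on valid LCTs", {
  # single locus everywhere, every species edge on a gene path: zero losses
  g <- parse_newick("(a,b)r;")
  s <- parse_newick("(A,B)rs;")
  inst <- recon_instance(g, s, c(a = "A", b = "B"), 1, 1)
  sc <- dlc_score(inst)
  expect_identical(sc$events$losses, 0L)

  # single-leaf gene tree: no events at all
  g1 <- parse_newick("a;")
  inst1 <- recon_instance(g1, s, c(a = "A"), 1, 1)
  sc1 <- dlc_score(inst1)
  expect_identical(sc1$events$duplications, 0L)

  for (i in 1:60) {
    inst2 <- random_instance(sample(3:7, 1L), sample(2:5, 1L), 0.5,
                             seed = 7000L + i)
    lct <- random_valid_lct(inst2, seed = 7100L + i)
    expect_identical(count_losses(inst2, lct),
                     oracle_count_losses(inst2, lct))
  }
})

test_that("cost is linear in the event counts", {
  inst <- cherry_instance(cost_dup = 2, cost_loss = 3)
  lct <- make_lct(inst, placement = c("g2"))
  ev <- reconciliation_cost(inst, lct)
  expect_identical(ev$cost, 2 * ev$duplications + 3 * ev$losses)
  # weight collapse
  inst10 <- cherry_instance(1, 0); inst01 <- cherry_instance(0, 1)
  ev10 <- reconciliation_cost(inst10, make_lct(inst10, placement = "g2"))
  ev01 <- reconciliation_cost(inst01, make_lct(inst01, placement = "g2"))
  expect_identical(ev10$cost, as.numeric(ev10$duplications))
  expect_identical(ev01$cost, as.numeric(ev01$losses))
})

test_that("locus maps and duplication placements are interchangeable", {
  g <- parse_newick("((a,b)u,c)r;")
  # empty placement: one locus, zero duplications
  loc0 <- locus_map_from_placement(g, character(0))
  expect_identical(loc0$locus_set, 1L)
  expect_identical(count_duplications(g, loc0$locus_map), 0L)
  # one switch on e(u)
  loc1 <- locus_map_from_placement(g, "u")
  expect_identical(placement_from_locus_map(g, loc1$locus_map), "u")
  expect_error(locus_map_from_placement(g, "zz"), "not in tree")

  for (i in 1:60) {
    tr <- random_tree(sample(3:20, 1L), seed = 8000L + i)
    set.seed(i)
    k <- sample(0:min(5L, length(tree_edges(tr))), 1L)
    D <- sort(sample(tree_edges(tr), k))
    loc <- locus_map_from_placement(tr, D)
    expect_length(loc$locus_set, k + 1L)
    expect_identical(count_duplications(tr, loc$locus_map), as.integer(k))
    expect_identical(placement_from_locus_map(tr, loc$locus_map),
                     lex_sort(D))
  }
})

test_that("placement validity is the pairwise separation condition", {
  g <- parse_newick("((a,b)u,c)r;")
  s <- parse_newick("((A,B)x,C)rs;")
  no_paralogs <- recon_instance(g, s, c(a = "A", b = "B", c = "C"))
  expect_true(is_duplication_placement(no_paralogs, character(0)))
  paralogs <- recon_instance(g, s, c(a = "A", b = "A", c = "B"))
  expect_false(is_duplication_placement(paralogs, character(0)))
  expect_true(is_duplication_placement(paralogs, "a"))

  for (i in 1:30) {
    inst <- random_instance(sample(3:7, 1L), sample(2:5, 1L), 0.5,
                            seed = 9000L + i)
    set.seed(i)
    D <- sample(tree_edges(inst$gene_tree),
                sample(0:3, 1L))
    want <- all(vapply(paralog_pairs(inst), function(pr) {
      any(vapply(D, function(e) separates(inst$gene_tree, e, pr[1L], pr[2L]),
                 logical(1)))
    }, logical(1)))
    expect_identical(is_duplication_placement(inst, D), want)
  }
})

test_that("map files round-trip and reject malformed input", {
  path <- withr::local_tempfile()
  m <- c(a = "A", b = "B")
  write_tsv_map(m, path)
  expect_identical(read_tsv_map(path), m)
  writeLines(c("# comment", "a\tA", "broken line"), path)
  expect_error(read_tsv_map(path), "malformed")
})
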