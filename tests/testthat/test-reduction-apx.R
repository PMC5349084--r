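apx_fixture <- function() {
  build_apx_instance(normalize_cnf(list(c(1L, -2L, 3L), c(2L, 3L, -4L))))
}

test_that("thorn gadgets are caterpillars with a deepest end tip", {
  th2 <- build_thorn(2L)
  expect_length(th2$ids, 3L)
  expect_error(build_thorn(1L), ">= 2")
  for (l in c(2L, 3L, 7L)) {
    th <- build_thorn(l)
    expect_length(tree_internal(th), l - 1L)
    expect_length(tree_leaves(th), l)
    tip <- attr(th, "end_tip")
    expect_identical(max(th$depth_i), th$depth_i[th$index[[tip]]])
    expect_identical(unname(th$depth_i[th$index[[tip]]]), l - 1L)
  }
})

test_that("the optimization instance matches the construction's counts", {
  apx <- apx_fixture()
  n <- apx$n; m <- apx$m
  st <- apx$recon$species_tree
  # trunk size 1 + 2m + 2n + 3n, and the tree is binary
  trunk <- grep("^(rho_|sig|tau_)", st$ids, value = TRUE)
  expect_length(trunk, 1L + 2L * m + 2L * n + 3L * n)
  expect_true(all(lengths(st$children_i) %in% c(0L, 2L)))
  expect_true(all(lengths(apx$recon$gene_tree$children_i) %in% c(0L, 2L)))
  # species leaves: r_0..r_2m, s_j, s'_j, 3n thorns of n^2 leaves, plus the
  # balancing leaf under the last trunk node
  expect_length(tree_leaves(st),
                (2L * m + 1L) + 2L * n + 3L * n * n^2 + 1L)
  # one (n^2-1)-thorn per literal occurrence in the gene tree
  expect_length(apx$occ_thorns, 3L * n)
  for (th in apx$occ_thorns) expect_length(th$leaves, n^2 - 1L)
  # the shared thorn under g1 has 3n - m + 1 leaves
  expect_length(apx$g1_thorn$leaves, 3L * n - m + 1L)
  expect_identical(apx$recon$cost_dup, 2 * apx$B * n^2)
  expect_identical(apx$budget_b, (10 * apx$B + 2) * n^3 + 121 * n^2)
  expect_error(build_apx_instance(normalize_cnf(list(c(1L, 2L, 3L)))), "n >= 2")
  expect_error(build_apx_instance(apx$formula, B = 1L), "violated")
})

test_that("reference solutions use exactly 5n duplications and round-trip", {
  apx <- apx_fixture()
  n <- apx$n
  v <- c(TRUE, TRUE, FALSE, FALSE)
  expect_true(eval_cnf(apx$formula, v))
  sol <- apx_solution_from_valuation(apx, v)
  expect_length(sol$placement, 5L * n)
  expect_true(is_duplication_placement(apx$recon, sol$placement))
  expect_true(apx_is_well_behaved(apx, sol$placement))
  expect_identical(apx_valuation_from_solution(apx, sol$placement), v)
  expect_error(apx_solution_from_valuation(apx, c(FALSE, TRUE, FALSE, FALSE)),
               "clause")
})

test_that("well-behavedness rejects structural deviations", {
  apx <- apx_fixture()
  sol <- apx_solution_from_valuation(apx, c(TRUE, TRUE, FALSE, FALSE))
  expect_false(apx_is_well_behaved(apx, character(0)))
  # two duplications in one variable gadget
  twisted <- c(setdiff(sol$placement, "bbar_1"), "beta_1", "bbar_1")
  expect_false(apx_is_well_behaved(apx, twisted))
  # right count, wrong edge inside the variable gadget
  moved <- c(setdiff(sol$placement, "bbar_1"), "y_1")
  expect_false(apx_is_well_behaved(apx, moved))
  expect_error(apx_valuation_from_solution(apx, moved), "not well-behaved")
})

test_that("thorn losses audit 2n^2 per satisfied and 3n^2 per unsatisfied clause", {
  apx <- apx_fixture()
  n <- apx$n
  v <- c(TRUE, TRUE, FALSE, FALSE)
  sol <- apx_solution_from_valuation(apx, v)
  aud <- apx_loss_audit(apx, sol$species_map, sol$placement)
  expect_identical(aud$events$duplications, 5L * n)
  expect_equal(aud$thorn_losses_by_clause, rep(2 * n^2, n))
  expect_lt(aud$trunk_losses, 121 * n^2)
  expect_true(aud$within_budget)

  # deliberately wrong valuation: clause 1 unsatisfied, clause 2 satisfied
  w <- c(FALSE, TRUE, FALSE, FALSE)
  expect_identical(clause_values(apx$formula, w), c(FALSE, TRUE))
  solw <- apx_solution_from_valuation(apx, w, allow_unsatisfied = TRUE)
  audw <- apx_loss_audit(apx, solw$species_map, solw$placement)
  expect_equal(audw$thorn_losses_by_clause, c(3 * n^2, 2 * n^2))
})
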