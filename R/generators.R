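# Deterministic generators for random trees, reconciliation instances,
# species maps, and 3-CNF formulas, plus the worked single-clause decision
# example.  Every generator seeds its own PRNG explicitly from the `seed`
# argument, so identical arguments give bit-identical output.

rtree_build <- function(n_leaves, b, prefix, counter) {
  # recursive uniform random split; returns root id
  grow <- function(n) {
    if (n == 1L) {
      counter$leaf <- counter$leaf + 1L
      return(b$add(paste0(prefix, counter$leaf)))
    }
    left <- if (n == 2L) 1L else sample.int(n - 1L, 1L)
    counter$int <- counter$int + 1L
    me <- paste0("i", counter$int, "_", prefix)
    lroot <- grow(left)
    rroot <- grow(n - left)
    b$children[[me]] <- c(lroot, rroot)
    b$seen <- c(b$seen, me)
    me
  }
  grow(n_leaves)
}

#' Generate a random rooted binary tree
#'
#' Shapes arise from recursive uniform splits of the leaf count; leaves are
#' labeled `<prefix>1..<prefix>n` in left-to-right order.
#'
#' @param n_leaves number of leaves (>= 1).
#' @param seed integer PRNG seed; same seed, same tree.
#' @param prefix leaf label prefix.
#' @return a `dlc_tree`.
#' @export
random_tree <- function(n_leaves, seed, prefix = "L") {
  if (n_leaves < 1L) stop("n_leaves must be >= 1")
  set.seed(seed)
  b <- tree_builder()
  counter <- new.env(parent = emptyenv()); counter$leaf <- 0L; counter$int <- 0L
  root <- rtree_build(n_leaves, b, prefix, counter)
  tree_from_children(b$children, root)
}

#' Generate a random reconciliation instance
#'
#' Gene and species tree shapes are drawn independently; each gene leaf
#' joins the species leaf of an already-placed gene leaf with probability
#' `paralogy_rate` (creating paralogs) and otherwise takes a fresh unused
#' species leaf.  When no unused species leaf remains, the leaf joins an
#' existing group regardless of the rate; with `paralogy_rate = 0` that
#' situation is a configuration error.
#'
#' @param n_gene_leaves,n_species_leaves leaf counts (>= 1).
#' @param paralogy_rate probability in `[0, 1]` of joining an existing
#'   species-leaf group.
#' @param seed integer PRNG seed.
#' @param cost_dup,cost_loss event costs of the instance.
#' @return a `dlc_instance`.
#' @export
random_instance <- function(n_gene_leaves, n_species_leaves, paralogy_rate,
                            seed, cost_dup = 1, cost_loss = 0) {
  if (n_gene_leaves < 1L || n_species_leaves < 1L) stop("leaf counts must be >= 1")
  if (paralogy_rate < 0 || paralogy_rate > 1) stop("paralogy_rate must be in [0, 1]")
  if (paralogy_rate == 0 && n_gene_leaves > n_species_leaves) {
    stop("paralogy_rate 0 is impossible with more gene than species leaves")
  }
  set.seed(seed)
  b <- tree_builder()
  counter <- new.env(parent = emptyenv()); counter$leaf <- 0L; counter$int <- 0L
  groot <- rtree_build(n_gene_leaves, b, "g", counter)
  gene <- tree_from_children(b$children, groot)
  b2 <- tree_builder()
  counter2 <- new.env(parent = emptyenv()); counter2$leaf <- 0L; counter2$int <- 0L
  sroot <- rtree_build(n_species_leaves, b2, "s", counter2)
  species <- tree_from_children(b2$children, sroot)
  sp <- tree_leaves(species)
  unused <- sp
  used <- character(0)
  le <- character(0)
  for (g in tree_leaves(gene)) {
    join <- length(used) > 0L &&
      (stats::runif(1) < paralogy_rate || length(unused) == 0L)
    if (join) {
      tgt <- used[sample.int(length(used), 1L)]
    } else {
      pick <- sample.int(length(unused), 1L)
      tgt <- unused[pick]
      unused <- unused[-pick]
      used <- c(used, tgt)
    }
    le[g] <- tgt
  }
  recon_instance(gene, species, le, cost_dup = cost_dup, cost_loss = cost_loss)
}

#' Sample a random valid species map
#'
#' Draws each internal node's image uniformly from the species path between
#' its parent's image and the lca of its descendant leaves' images
#' (top-down), so the ancestry constraints always hold.
#'
#' @param instance a `dlc_instance`.
#' @param seed integer PRNG seed.
#' @return named character vector over the gene nodes.
#' @export
random_species_map <- function(instance, seed) {
  set.seed(seed)
  g <- instance$gene_tree; s <- instance$species_tree
  lca_img <- lca_species_map(instance)
  m <- character(length(g$ids)); names(m) <- g$ids
  for (i in seq_along(g$ids)) {   # preorder: parents first
    id <- g$ids[i]
    if (length(g$children_i[[i]]) == 0L) {
      m[id] <- instance$leaf_map[[id]]
      next
    }
    pa <- g$parent_i[i]
    top <- if (is.na(pa)) tree_root(s) else m[[g$ids[pa]]]
    choices <- character(0)
    j <- s$index[[lca_img[[id]]]]
    repeat {
      choices <- c(choices, s$ids[j])
      if (s$ids[j] == top) break
      j <- s$parent_i[j]
    }
    m[id] <- choices[sample.int(length(choices), 1L)]
  }
  m
}

#' Generate a random bounded-occurrence 3-CNF formula
#'
#' Each clause draws the 3 variables with the largest remaining occurrence
#' budgets (ties randomized) and random polarities; with `3n <= m * B` this
#' never strands the generator.  The result is normalized, so variables
#' that end up unused are compacted away.
#'
#' @param m number of variables (>= 3).
#' @param n number of clauses (>= 1).
#' @param B per-variable occurrence bound; `3n <= m * B` required.
#' @param seed integer PRNG seed.
#' @return a `dlc_cnf`.
#' @export
random_cnf <- function(m, n, B, seed) {
  if (m < 3L) stop("need at least 3 variables")
  if (n < 1L) stop("need at least 1 clause")
  if (3L * n > m * B) {
    stop("infeasible: 3n = ", 3L * n, " literal slots exceed m*B = ", m * B)
  }
  set.seed(seed)
  budget <- rep(B, m)
  clauses <- vector("list", n)
  for (j in seq_len(n)) {
    pick <- order(budget + stats::runif(m), decreasing = TRUE)[1:3]
    budget[pick] <- budget[pick] - 1L
    signs <- sample(c(-1L, 1L), 3L, replace = TRUE)
    clauses[[j]] <- as.integer(sort(pick) * signs)
  }
  suppressWarnings(normalize_cnf(clauses))
}

#' The worked single-clause decision example
#'
#' The decision instance built from the one-clause formula
#' (x1 v !x2 v x3): three variable gadgets, one clause gadget, a species
#' tree with 10 leaves, and decision parameter 5 (one duplication per
#' variable gadget plus two in the clause gadget).
#'
#' @return list(formula = `dlc_cnf`, instance = `dlc_np_instance`).
#' @export
np_example_single_clause <- function() {
  cnf <- normalize_cnf(list(c(1L, -2L, 3L)))
  list(formula = cnf, instance = build_np_instance(cnf))
}
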