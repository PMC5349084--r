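# Independent oracles used by the tests.  Each one re-derives a quantity
# from first principles (root paths, exhaustive subsets, per-edge
# subdivision, direct set comprehension) without touching the code path it
# checks.

# ids on the path from the root down to `id`, inclusive
oracle_root_path <- function(tree, id) {
  out <- character(0)
  i <- tree$index[[id]]
  repeat {
    out <- c(tree$ids[i], out)
    if (is.na(tree$parent_i[i])) break
    i <- tree$parent_i[i]
  }
  out
}

# lca by intersecting root paths and taking the deepest common node
oracle_lca <- function(tree, u, v) {
  pu <- oracle_root_path(tree, u)
  pv <- oracle_root_path(tree, v)
  common <- intersect(pu, pv)
  common[length(common)]
}

# the edges separating u and v are exactly the symmetric difference of the
# two root-path edge sets (an edge = its child, so drop the root)
oracle_separating_edges <- function(tree, u, v) {
  eu <- setdiff(oracle_root_path(tree, u), tree_root(tree))
  ev <- setdiff(oracle_root_path(tree, v), tree_root(tree))
  sort(union(setdiff(eu, ev), setdiff(ev, eu)))
}

# exhaustive-subset minimum multicut, plain combn loop over all edges
oracle_min_multicut <- function(instance) {
  tree <- instance$gene_tree
  pairs <- paralog_pairs(instance)
  if (length(pairs) == 0L) return(0L)
  paths <- lapply(pairs, function(pr) path_edges(tree, pr[1L], pr[2L]))
  edges <- tree_edges(tree)
  for (size in 0:length(edges)) {
    if (size == 0L) next
    cmb <- utils::combn(edges, size)
    for (k in seq_len(ncol(cmb))) {
      D <- cmb[, k]
      if (all(vapply(paths, function(p) any(D %in% p), logical(1)))) {
        return(size)
      }
    }
  }
  stop("unreachable: cutting all edges always works")
}

# canonical per-edge subdivision: for each original non-root gene node g,
# the species images of the nodes to insert between p(g) and g, top first.
# Chain = strict path interior from M(p(g)) to M(g), preceded by M(p(g))
# itself when p(g) is a non-speciation node (some child keeps its image).
oracle_subdivision_signature <- function(gene_tree, species_tree, species_map) {
  sig <- list()
  for (g in tree_edges(gene_tree)) {
    p <- tree_parent(gene_tree, g)
    mp <- species_map[[p]]; mg <- species_map[[g]]
    interior <- character(0)
    if (mp != mg) {
      walk <- oracle_root_path(species_tree, mg)
      i0 <- match(mp, walk)
      stopifnot(!is.na(i0))
      interior <- walk[seq_along(walk) > i0 & seq_along(walk) < length(walk)]
      sibs <- tree_children(gene_tree, p)
      non_spec <- any(species_map[sibs] == mp)
      if (non_spec) interior <- c(mp, interior)
    }
    sig[[g]] <- interior
  }
  sig
}

# the same signature read off an augmented tree: species images of the
# inserted nodes between each original node and its original parent
augmented_signature <- function(gene_tree, aug) {
  orig <- gene_tree$ids
  sig <- list()
  for (g in tree_edges(gene_tree)) {
    chain <- character(0)
    cur <- tree_parent(aug$tree, g)
    while (!cur %in% orig) {
      chain <- c(aug$species_map[[cur]], chain)
      cur <- tree_parent(aug$tree, cur)
    }
    sig[[g]] <- chain
  }
  sig
}

# loss count by direct evaluation of the event definition: for every
# non-root species node s, the loci at loci(tops(s) U nodes(s)) missing
# from loci(bottoms(s)); written as a literal set comprehension
oracle_count_losses <- function(instance, lct) {
  tr <- lct$tree; sm <- lct$species_map; lm <- lct$locus_map
  s <- instance$species_tree
  nodes_s <- function(x) names(sm)[sm == x]
  bottoms_s <- function(x) {
    Filter(function(g) {
      ch <- tree_children(tr, g)
      length(ch) == 0L || !any(sm[ch] == x)
    }, nodes_s(x))
  }
  total <- 0L
  for (x in setdiff(s$ids, tree_root(s))) {
    tops <- bottoms_s(tree_parent(s, x))
    present <- unique(as.character(lm[c(tops, nodes_s(x))]))
    below <- unique(as.character(lm[bottoms_s(x)]))
    total <- total + length(setdiff(present, below))
  }
  total
}

# valid LCT generator: random species map plus a placement that separates
# all paralogs (exact solver solution) extended by random extra edges
random_valid_lct <- function(instance, seed, extra = 2L) {
  sm <- random_species_map(instance, seed)
  base <- min_dup_exact(instance)$best_placement
  aug <- add_implied_speciations(instance$gene_tree, instance$species_tree, sm)
  set.seed(seed + 1L)
  pool <- setdiff(tree_edges(aug$tree), base)
  add <- if (length(pool) > 0L && extra > 0L) {
    sample(pool, min(extra, length(pool)))
  } else character(0)
  D <- union(base, add)
  loc <- locus_map_from_placement(aug$tree, D)
  list(tree = aug$tree, species_map = aug$species_map,
       locus_set = loc$locus_set, locus_map = loc$locus_map,
       placement = D)
}

# all normalized single clauses over exactly the variables 1..3, every
# polarity combination, literals in ascending variable order
all_clauses_m3 <- function() {
  out <- list()
  for (s1 in c(1L, -1L)) for (s2 in c(1L, -1L)) for (s3 in c(1L, -1L)) {
    out[[length(out) + 1L]] <- c(s1 * 1L, s2 * 2L, s3 * 3L)
  }
  out
}
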