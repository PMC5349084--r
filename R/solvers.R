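# Minimum-duplication (multicut) solvers and desk-scale exact optimization
# of the full duplication+loss objective.
#
# Minimizing duplications alone is exactly minimum multicut on the gene
# tree with the paralogous leaf pairs as terminal pairs, which is NP-hard;
# the exact solvers here are branch-and-bound / exhaustive and intended for
# desk-scale instances, with a classical primal-dual factor-2
# approximation for anything larger.

# pair paths as integer index vectors over a fixed edge universe
pair_path_index <- function(instance) {
  tree <- instance$gene_tree
  pairs <- paralog_pairs(instance)
  paths <- lapply(pairs, function(pr) lex_sort(path_edges(tree, pr[1L], pr[2L])))
  edges <- lex_sort(unique(unlist(paths)))
  eidx <- stats::setNames(seq_along(edges), edges)
  list(pairs = pairs,
       paths = lapply(paths, function(p) unname(eidx[p])),
       edges = edges)
}

# remove pairs whose path is a superset of another pair's path (hitting the
# subset hits the superset), keeping first occurrence of identical paths
reduce_pairs <- function(paths) {
  n <- length(paths)
  if (n == 0L) return(integer(0))
  keys <- vapply(paths, function(p) paste(p, collapse = ","), "")
  keep <- !duplicated(keys)
  ord <- order(lengths(paths))
  for (a in seq_len(n)) {
    i <- ord[a]
    if (!keep[i]) next
    for (b in seq_len(n)) {
      j <- ord[b]
      if (i == j || !keep[j] || length(paths[[j]]) <= length(paths[[i]])) next
      if (all(paths[[i]] %in% paths[[j]])) keep[j] <- FALSE
    }
  }
  which(keep)
}

# drop edges whose covered-pair set is contained in another edge's set
dominant_edges <- function(paths, n_edges) {
  cover <- vector("list", n_edges)
  for (k in seq_along(paths)) {
    for (e in paths[[k]]) cover[[e]] <- c(cover[[e]], k)
  }
  keep <- rep(TRUE, n_edges)
  nonzero <- which(lengths(cover) > 0L)
  for (a in nonzero) {
    if (!keep[a]) next
    for (b in nonzero) {
      if (a == b || !keep[a]) next
      covb <- cover[[b]]; cova <- cover[[a]]
      if (length(cova) < length(covb) && all(cova %in% covb)) {
        keep[a] <- FALSE
      } else if (length(cova) == length(covb) && a > b && all(cova %in% covb)) {
        keep[a] <- FALSE
      }
    }
  }
  keep[-nonzero] <- FALSE
  if (length(nonzero) == 0L) keep[] <- FALSE
  keep
}

# greedy lower bound: maximal set of pairwise edge-disjoint uncovered paths
disjoint_path_bound <- function(paths, alive) {
  used <- integer(0)
  lb <- 0L
  for (k in order(lengths(paths))) {
    if (!alive[k]) next
    p <- paths[[k]]
    if (!any(p %in% used)) {
      lb <- lb + 1L
      used <- c(used, p)
    }
  }
  lb
}

# branch-and-bound core over reduced paths; returns list(size, edges,
# explored) where edges are indices into the edge universe, or NULL when
# nothing at most `limit` exists.
bnb_multicut <- function(paths, n_edges, upper = NULL, limit = Inf) {
  keep_pairs <- reduce_pairs(paths)
  paths <- paths[keep_pairs]
  edge_ok <- dominant_edges(paths, n_edges)
  paths <- lapply(paths, function(p) p[edge_ok[p]])
  cover <- vector("list", n_edges)
  for (k in seq_along(paths)) for (e in paths[[k]]) cover[[e]] <- c(cover[[e]], k)

  env <- new.env(parent = emptyenv())
  env$best_size <- if (is.null(upper)) length(paths) + 1L else length(upper) + 1L
  env$best <- NULL
  env$explored <- 0L
  cap <- min(env$best_size, if (is.finite(limit)) limit + 1L else Inf)
  env$best_size <- cap

  recurse <- function(chosen, alive) {
    env$explored <- env$explored + 1L
    live <- which(alive)
    if (length(live) == 0L) {
      if (length(chosen) < env$best_size) {
        env$best_size <- length(chosen)
        env$best <- chosen
      }
      return(invisible(NULL))
    }
    lb <- disjoint_path_bound(paths, alive)
    if (length(chosen) + lb >= env$best_size) return(invisible(NULL))
    # fail-first: branch on the uncovered pair with fewest candidate edges
    k <- live[which.min(lengths(paths)[live])]
    for (e in paths[[k]]) {
      alive2 <- alive
      alive2[cover[[e]]] <- FALSE
      recurse(c(chosen, e), alive2)
      if (env$best_size <= 0L) break
    }
    invisible(NULL)
  }
  recurse(integer(0), rep(TRUE, length(paths)))
  if (is.null(env$best) && !is.null(upper) && length(upper) < cap) {
    # the initial upper bound itself was optimal within the cap
    return(list(size = length(upper), edges = upper, explored = env$explored))
  }
  if (is.null(env$best)) return(NULL)
  list(size = env$best_size, edges = env$best, explored = env$explored)
}

solver_result <- function(instance, placement, optimal, explored,
                          species_map = NULL, lct = NULL, meta = list()) {
  if (is.null(lct)) lct <- make_lct(instance, species_map, placement)
  structure(
    list(best_lct = lct, best_placement = lex_sort(placement),
         events = reconciliation_cost(instance, lct),
         optimal = isTRUE(optimal), explored = explored, meta = meta),
    class = "dlc_solver_result")
}

#' @export
print.dlc_solver_result <- function(x, ...) {
  cat("DLC solver result (", if (x$optimal) "optimal" else "not proven optimal",
      ")\n", sep = "")
  cat("  placement size:", length(x$best_placement), "\n")
  cat("  duplications:", x$events$duplications,
      " losses:", x$events$losses, " cost:", format(x$events$cost), "\n")
  cat("  candidates explored:", x$explored, "\n")
  invisible(x)
}

#' Exact minimum duplication placement (branch and bound)
#'
#' Finds a minimum-cardinality duplication placement: the smallest edge set
#' separating every paralogous leaf pair (minimum multicut on the gene
#' tree).  Uses superset-pair and dominated-edge reduction, an
#' edge-disjoint-path lower bound, and the factor-2 approximation as the
#' initial incumbent.  The result depends only on the gene tree and leaf
#' map, never on the species tree.
#'
#' @param instance a `dlc_instance`.
#' @param max_edges guard on the gene-tree edge count (an error beyond it
#'   points to [min_dup_approx()]); override for larger desk-scale runs.
#' @return a `dlc_solver_result` with the `optimal` flag set.
#' @export
min_dup_exact <- function(instance, max_edges = 40L) {
  n_edges <- length(tree_edges(instance$gene_tree))
  if (n_edges > max_edges) {
    stop("gene tree has ", n_edges, " edges (> max_edges = ", max_edges,
         "); raise max_edges or use min_dup_approx()")
  }
  pp <- pair_path_index(instance)
  if (length(pp$pairs) == 0L) {
    return(solver_result(instance, character(0), TRUE, 0L))
  }
  ub <- min_dup_approx(instance)
  ub_idx <- stats::setNames(seq_along(pp$edges), pp$edges)[ub$best_placement]
  res <- bnb_multicut(pp$paths, length(pp$edges), upper = unname(ub_idx))
  solver_result(instance, pp$edges[res$edges], TRUE, res$explored)
}

#' Exhaustive minimum duplication placement
#'
#' Brute-force reference solver: enumerates subsets of the gene-tree edges
#' in increasing size (lexicographic within a size) and returns the first
#' valid duplication placement found.  Edges lying on no paralog-pair path
#' are skipped, since they cannot separate anything.
#'
#' @param instance a `dlc_instance`.
#' @param max_size optional cap on the placement size searched.
#' @return a `dlc_solver_result` with the `optimal` flag set, or an error
#'   if no placement within `max_size` exists.
#' @export
min_dup_exhaustive <- function(instance, max_size = NULL) {
  pp <- pair_path_index(instance)
  n_pairs <- length(pp$pairs)
  if (n_pairs == 0L) return(solver_result(instance, character(0), TRUE, 0L))
  if (is.null(max_size)) max_size <- n_pairs
  # chunked bitmasks (30 bits per integer) over pairs, per edge
  n_chunk <- (n_pairs + 29L) %/% 30L
  masks <- matrix(0L, nrow = n_chunk, ncol = length(pp$edges))
  for (k in seq_len(n_pairs)) {
    ch <- (k - 1L) %/% 30L + 1L
    bit <- bitwShiftL(1L, (k - 1L) %% 30L)
    for (e in pp$paths[[k]]) masks[ch, e] <- bitwOr(masks[ch, e], bit)
  }
  full <- vapply(seq_len(n_chunk), function(ch) {
    k <- min(30L, n_pairs - (ch - 1L) * 30L)
    Reduce(bitwOr, lapply(seq_len(k) - 1L, function(b) bitwShiftL(1L, b)), 0L)
  }, integer(1))
  n_e <- length(pp$edges)
  env <- new.env(parent = emptyenv())
  env$explored <- 0L
  found <- NULL
  dfs <- function(start, left, acc, chosen) {
    if (!is.null(found)) return(invisible(NULL))
    env$explored <- env$explored + 1L
    if (all(acc == full)) {
      found <<- chosen
      return(invisible(NULL))
    }
    if (left == 0L || start > n_e) return(invisible(NULL))
    for (e in start:n_e) {
      if (!is.null(found)) break
      dfs(e + 1L, left - 1L,
          bitwOr(acc, masks[, e]), c(chosen, e))
    }
    invisible(NULL)
  }
  for (s in 0:max_size) {
    dfs(1L, s, rep(0L, n_chunk), integer(0))
    if (!is.null(found)) break
  }
  if (is.null(found)) {
    stop("no duplication placement of size <= ", max_size, " exists")
  }
  solver_result(instance, pp$edges[found], TRUE, env$explored)
}

#' Factor-2 approximate minimum duplication placement
#'
#' The classical primal-dual scheme for multicut on trees: process least
#' common ancestors bottom-up, saturating edges on still-connected pair
#' paths, then reverse-delete redundant edges.  Output is always a valid
#' duplication placement of size at most twice the optimum.
#'
#' @param instance a `dlc_instance`.
#' @return a `dlc_solver_result` with the `optimal` flag unset.
#' @export
min_dup_approx <- function(instance) {
  tree <- instance$gene_tree
  pp <- pair_path_index(instance)
  if (length(pp$pairs) == 0L) {
    return(solver_result(instance, character(0), FALSE, 0L))
  }
  lca_depth <- vapply(pp$pairs, function(pr) {
    tree$depth_i[tree$index[[lca(tree, pr[1L], pr[2L])]]]
  }, integer(1))
  ord <- order(-lca_depth, vapply(pp$pairs, paste, "", collapse = ","),
               method = "radix")
  slack <- rep(1, length(pp$edges))
  chosen <- integer(0)
  for (k in ord) {
    p <- pp$paths[[k]]
    if (any(slack[p] == 0)) next   # already disconnected
    delta <- min(slack[p])
    slack[p] <- slack[p] - delta
    newly <- p[slack[p] == 0]
    chosen <- c(chosen, newly[order(newly)])
  }
  # reverse delete
  hit <- lapply(pp$paths, function(p) p)
  for (i in rev(seq_along(chosen))) {
    trial <- chosen[-i]
    if (all(vapply(hit, function(p) any(trial %in% p), logical(1)))) {
      chosen <- trial
    }
  }
  solver_result(instance, pp$edges[chosen], FALSE, length(pp$pairs))
}

# number of species maps satisfying the ancestry constraints (DP)
count_species_maps <- function(instance) {
  g <- instance$gene_tree; s <- instance$species_tree
  lca_img <- lca_species_map(instance)
  # cnt[[i]][s_id]: number of completions of the subtree at gene node i
  # given image s_id
  cnt <- vector("list", length(g$ids))
  for (i in rev(seq_along(g$ids))) {
    ch <- g$children_i[[i]]
    top <- lca_img[[g$ids[i]]]
    # allowed images: ancestors-or-self of the subtree lca image
    allowed <- character(0)
    j <- s$index[[top]]
    repeat {
      allowed <- c(allowed, s$ids[j])
      if (is.na(s$parent_i[j])) break
      j <- s$parent_i[j]
    }
    v <- stats::setNames(numeric(length(allowed)), allowed)
    for (a in allowed) {
      prod <- 1
      for (c2 in ch) {
        sub <- cnt[[c2]]
        ok <- names(sub)[vapply(names(sub), function(x) is_ancestor(s, a, x),
                                logical(1))]
        prod <- prod * sum(sub[ok])
      }
      v[a] <- prod
    }
    if (length(ch) == 0L) v[] <- 0
    if (length(ch) == 0L) v[top] <- 1   # leaves are pinned to their image
    cnt[[i]] <- v
  }
  sum(cnt[[g$root_i]])
}

#' Enumerate valid species maps
#'
#' Yields every map satisfying the leaf-extension and child-ancestry
#' constraints exactly once: each internal node's image ranges over the
#' species path between its parent's image and the lca of its descendant
#' leaves' images.
#'
#' @param instance a `dlc_instance`.
#' @param max_maps guard: error when the count exceeds it.
#' @return list of named character vectors.
#' @export
enumerate_species_maps <- function(instance, max_maps = 100000) {
  total <- count_species_maps(instance)
  if (total > max_maps) {
    stop("instance admits ", format(total), " species maps (> max_maps = ",
         max_maps, "); raise the guard only for desk-scale instances")
  }
  g <- instance$gene_tree; s <- instance$species_tree
  lca_img <- lca_species_map(instance)
  # path in species tree from `from` down to `to` (inclusive), top first
  span <- function(from, to) {
    out <- character(0)
    j <- s$index[[to]]
    repeat {
      out <- c(s$ids[j], out)
      if (s$ids[j] == from) break
      j <- s$parent_i[j]
      if (is.na(j)) stop("internal error: span outside tree")
    }
    out
  }
  maps <- list(stats::setNames(character(0), character(0)))
  assign_node <- function(i, maps) {
    id <- g$ids[i]
    ch <- g$children_i[[i]]
    out <- list()
    for (m in maps) {
      pa <- g$parent_i[i]
      top <- if (is.na(pa)) tree_root(s) else m[[g$ids[pa]]]
      choices <- if (length(ch) == 0L) lca_img[[id]] else span(top, lca_img[[id]])
      for (cho in choices) {
        m2 <- m
        m2[id] <- cho
        out[[length(out) + 1L]] <- m2
      }
    }
    out
  }
  for (i in seq_along(g$ids)) maps <- assign_node(i, maps)   # preorder
  maps
}

#' Exact DLC parsimony optimization
#'
#' Minimizes duplications * cost_dup + losses * cost_loss over all LCTs.
#' When losses are free the optimum collapses to cost_dup times the
#' minimum duplication placement (any valid species map attains it) and
#' the branch-and-bound solver is used.  Otherwise every valid species map
#' is enumerated; for each, the gene tree is augmented with implied
#' speciation nodes and all duplication placements up to the paralog-pair
#' count plus `slack` extra edges are scored.  The placement-size cap is
#' recorded in the result's `meta` for auditability.
#'
#' @param instance a `dlc_instance`.
#' @param max_edges guard on gene-tree edges.
#' @param max_maps guard on the species-map count (general path only).
#' @param slack extra placement size allowed beyond the paralog-pair count
#'   (general path only).
#' @param leaf_dup_free if `TRUE`, search only placements avoiding terminal
#'   edges (duplications on such edges can always be pushed up one level
#'   without changing the optimum when losses are free); rejected when
#'   cost_loss > 0.
#' @return a `dlc_solver_result`.
#' @export
solve_dlcop <- function(instance, max_edges = 40L, max_maps = 20000,
                        slack = 1L, leaf_dup_free = FALSE) {
  if (leaf_dup_free && instance$cost_loss > 0) {
    stop("leaf_dup_free is only sound when cost_loss == 0")
  }
  if (instance$cost_loss == 0) {
    res <- if (leaf_dup_free) {
      min_dup_exact_nonterminal(instance, max_edges)
    } else {
      min_dup_exact(instance, max_edges = max_edges)
    }
    res$meta <- c(res$meta, list(path = "loss-free collapse"))
    return(res)
  }
  n_edges <- length(tree_edges(instance$gene_tree))
  if (n_edges > max_edges) {
    stop("gene tree has ", n_edges, " edges (> max_edges = ", max_edges, ")")
  }
  maps <- enumerate_species_maps(instance, max_maps = max_maps)
  pairs <- paralog_pairs(instance)
  cap <- length(pairs) + as.integer(slack)
  best <- NULL
  explored <- 0L
  for (m in maps) {
    aug <- add_implied_speciations(instance$gene_tree, instance$species_tree, m)
    edges <- lex_sort(tree_edges(aug$tree))
    paths <- lapply(pairs, function(pr) path_edges(aug$tree, pr[1L], pr[2L]))
    for (sz in 0:min(cap, length(edges))) {
      subsets <- if (sz == 0L) list(character(0)) else {
        cmb <- utils::combn(edges, sz)
        lapply(seq_len(ncol(cmb)), function(k) cmb[, k])
      }
      for (D in subsets) {
        if (!all(vapply(paths, function(p) sz > 0L && any(D %in% p) ||
                          length(p) == 0L, logical(1)))) next
        explored <- explored + 1L
        loc <- locus_map_from_placement(aug$tree, D)
        lct <- list(tree = aug$tree, species_map = aug$species_map,
                    locus_set = loc$locus_set, locus_map = loc$locus_map)
        ev <- reconciliation_cost(instance, lct)
        if (is.null(best) || ev$cost < best$events$cost) {
          best <- list(lct = lct, placement = D, events = ev)
        }
      }
    }
  }
  if (is.null(best)) stop("no valid LCT found within the placement cap")
  res <- solver_result(instance, best$placement, TRUE, explored,
                       lct = best$lct,
                       meta = list(path = "full enumeration",
                                   placement_cap = cap,
                                   species_maps = length(maps)))
  res
}

# exact multicut restricted to non-terminal edges (search-space reduction)
min_dup_exact_nonterminal <- function(instance, max_edges = 40L) {
  n_edges <- length(tree_edges(instance$gene_tree))
  if (n_edges > max_edges) {
    stop("gene tree has ", n_edges, " edges (> max_edges = ", max_edges, ")")
  }
  tree <- instance$gene_tree
  pp <- pair_path_index(instance)
  if (length(pp$pairs) == 0L) {
    return(solver_result(instance, character(0), TRUE, 0L))
  }
  terminal <- tree_leaves(tree)
  keep <- !(pp$edges %in% terminal)
  paths <- lapply(pp$paths, function(p) p[keep[p]])
  if (any(lengths(paths) == 0L)) {
    stop("a paralog pair is separable only by terminal edges; ",
         "disable leaf_dup_free")
  }
  res <- bnb_multicut(paths, length(pp$edges))
  solver_result(instance, pp$edges[res$edges], TRUE, res$explored,
                meta = list(path = "non-terminal edges only"))
}

#' DLC parsimony decision problem
#'
#' Does an LCT of cost at most `k` exist?  When losses are free this is a
#' bounded multicut search that short-circuits as soon as a placement
#' within budget is found (the factor-2 approximation is tried first);
#' otherwise the optimizer's cost is compared against `k`.
#'
#' @param instance a `dlc_instance`.
#' @param k nonnegative cost budget.
#' @param ... passed to [solve_dlcop()] on the general path.
#' @return logical scalar.
#' @export
solve_dlcdp <- function(instance, k, ...) {
  stopifnot(is.numeric(k), k >= 0)
  if (instance$cost_loss == 0) {
    if (instance$cost_dup == 0) return(TRUE)
    budget <- floor((k + 1e-9) / instance$cost_dup)
    ub <- min_dup_approx(instance)
    if (length(ub$best_placement) <= budget) return(TRUE)
    pp <- pair_path_index(instance)
    res <- bnb_multicut(pp$paths, length(pp$edges), limit = budget)
    return(!is.null(res) && res$size <= budget)
  }
  res <- solve_dlcop(instance, ...)
  res$events$cost <= k + 1e-9
}
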