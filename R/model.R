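# The DLC reconciliation model: reconciliation instances, labeled
# coalescent trees (LCTs), implied speciation insertion, event counting,
# and the locus-map/duplication-placement equivalence.
#
# Maps are named character vectors: names are gene node ids, values are
# species node ids (species/leaf maps) or locus labels (locus maps).  An
# LCT is a list(tree, species_map, locus_set, locus_map) where `tree` is
# the implied-speciation-augmented gene tree.

#' Build a reconciliation instance
#'
#' Bundles a gene tree, a species tree, the leaf map associating each gene
#' leaf with the species in which it is found, and nonnegative event costs
#' for duplications and losses.  Deep coalescence carries no cost in this
#' model, so only these two costs appear.
#'
#' @param gene_tree,species_tree rooted binary `dlc_tree`s.
#' @param leaf_map named character vector mapping every gene leaf id to a
#'   species leaf id; need not be one-to-one nor onto.  Gene leaves sharing
#'   an image are paralogs.
#' @param cost_dup,cost_loss nonnegative per-event costs.
#' @return an object of class `dlc_instance`.
#' @export
recon_instance <- function(gene_tree, species_tree, leaf_map,
                           cost_dup = 1, cost_loss = 0) {
  stopifnot(inherits(gene_tree, "dlc_tree"), inherits(species_tree, "dlc_tree"))
  gl <- tree_leaves(gene_tree)
  sl <- tree_leaves(species_tree)
  missing <- setdiff(gl, names(leaf_map))
  if (length(missing) > 0L) {
    stop("leaf map is not total on the gene leaves; missing: ",
         paste(lex_sort(missing), collapse = ", "))
  }
  extra <- setdiff(names(leaf_map), gl)
  if (length(extra) > 0L) {
    stop("leaf map names are not gene leaves: ", paste(lex_sort(extra), collapse = ", "))
  }
  bad <- setdiff(unname(leaf_map), sl)
  if (length(bad) > 0L) {
    stop("leaf map images are not species leaves: ", paste(lex_sort(bad), collapse = ", "))
  }
  if (!is.numeric(cost_dup) || !is.numeric(cost_loss) ||
      cost_dup < 0 || cost_loss < 0) {
    stop("event costs must be nonnegative numbers")
  }
  structure(
    list(gene_tree = gene_tree, species_tree = species_tree,
         leaf_map = leaf_map[gl], cost_dup = cost_dup, cost_loss = cost_loss),
    class = "dlc_instance")
}

#' @export
print.dlc_instance <- function(x, ...) {
  cat("DLC reconciliation instance\n")
  cat("  gene tree:    ", length(tree_leaves(x$gene_tree)), "leaves\n")
  cat("  species tree: ", length(tree_leaves(x$species_tree)), "leaves\n")
  cat("  paralogous leaf pairs:", length(paralog_pairs(x)), "\n")
  cat("  costs: duplication", x$cost_dup, "/ loss", x$cost_loss, "\n")
  invisible(x)
}

#' The least-common-ancestor species map
#'
#' The most parsimonious species map for constraints on ancestry: each gene
#' leaf maps to its leaf-map image and each internal node to the lca of its
#' children's images.  Always satisfies the species-map constraints (the
#' leaf-map extension and child-ancestry conditions).
#'
#' @param instance a `dlc_instance`.
#' @return named character vector over all gene-tree nodes.
#' @export
lca_species_map <- function(instance) {
  g <- instance$gene_tree; s <- instance$species_tree
  m <- character(length(g$ids)); names(m) <- g$ids
  for (i in rev(seq_along(g$ids))) {   # postorder via reverse preorder
    id <- g$ids[i]
    ch <- g$children_i[[i]]
    if (length(ch) == 0L) {
      m[id] <- instance$leaf_map[[id]]
    } else {
      img <- m[g$ids[ch[1L]]]
      for (c2 in ch[-1L]) img <- lca(s, img, m[g$ids[c2]])
      m[id] <- img
    }
  }
  m
}

# constraints 1-2 violations of a species map; data.frame(constraint, witness)
check_species_map <- function(instance, species_map, tree = instance$gene_tree) {
  viol <- list()
  missing <- setdiff(tree$ids, names(species_map))
  if (length(missing) > 0L) {
    stop("species map is not total; missing nodes: ",
         paste(lex_sort(missing), collapse = ", "))
  }
  s <- instance$species_tree
  smv <- unname(species_map[tree$ids])
  lv <- tree_leaves(tree)
  bad1 <- lv[smv[tree$index[lv]] != unname(instance$leaf_map[lv])]
  for (lf in bad1) {
    viol[[length(viol) + 1L]] <- data.frame(
      constraint = 1L, witness = lf, stringsAsFactors = FALSE)
  }
  for (i in seq_along(tree$ids)) {
    for (ci in tree$children_i[[i]]) {
      if (smv[i] != smv[ci] && !is_ancestor(s, smv[i], smv[ci])) {
        viol[[length(viol) + 1L]] <- data.frame(
          constraint = 2L, witness = paste0(tree$ids[i], "->", tree$ids[ci]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(viol) == 0L) {
    data.frame(constraint = integer(0), witness = character(0), stringsAsFactors = FALSE)
  } else do.call(rbind, viol)
}

#' Insert implied speciation nodes
#'
#' A gene branch may span several species branches under a species map;
#' degree-2 "implied speciation" nodes are inserted so that, at the
#' fixpoint, every non-root gene node g satisfies either M(p(g)) = M(g) or
#' M(p(g)) = p(M(g)), and every node mapped strictly below a non-speciation
#' parent is buffered by a node at the parent's species node.  The result
#' is independent of the processing order (the fixpoint is the canonical
#' per-edge subdivision); `node_order` only affects the generated ids of
#' inserted nodes.
#'
#' @param gene_tree a `dlc_tree` (binary).
#' @param species_tree a `dlc_tree`.
#' @param species_map named character vector on all gene nodes, satisfying
#'   the ancestry constraints.
#' @param node_order optional permutation of the gene node ids dictating the
#'   processing order (defaults to preorder).
#' @return list with `tree` (augmented `dlc_tree`, possibly containing
#'   one-child nodes) and `species_map` extended to the inserted nodes.
#' @export
add_implied_speciations <- function(gene_tree, species_tree, species_map,
                                    node_order = NULL) {
  missing <- setdiff(gene_tree$ids, names(species_map))
  if (length(missing) > 0L) {
    stop("species map is not total; missing nodes: ",
         paste(lex_sort(missing), collapse = ", "))
  }
  if (is.null(node_order)) node_order <- gene_tree$ids
  stopifnot(setequal(node_order, gene_tree$ids))

  P <- new.env(parent = emptyenv())   # parent id
  C <- new.env(parent = emptyenv())   # ordered children ids
  M <- new.env(parent = emptyenv())   # species image
  for (i in seq_along(gene_tree$ids)) {
    id <- gene_tree$ids[i]
    pa <- gene_tree$parent_i[i]
    assign(id, if (is.na(pa)) NA_character_ else gene_tree$ids[pa], envir = P)
    assign(id, gene_tree$ids[gene_tree$children_i[[i]]], envir = C)
    assign(id, species_map[[id]], envir = M)
  }
  nextlab <- auto_label_pool(gene_tree$ids)
  s_parent <- function(s) tree_parent(species_tree, s)
  is_speciation <- function(id) {
    ms <- get(id, envir = M)
    ch <- get(id, envir = C)
    length(ch) > 0L && all(vapply(ch, function(x) get(x, envir = M), "") != ms)
  }
  insert_above <- function(g, s_img) {
    h <- nextlab()
    pa <- get(g, envir = P)
    sib <- get(pa, envir = C)
    sib[sib == g] <- h
    assign(pa, sib, envir = C)
    assign(h, pa, envir = P)
    assign(h, g, envir = C)
    assign(g, h, envir = P)
    assign(h, s_img, envir = M)
    h
  }
  root <- tree_root(gene_tree)
  for (g in node_order) {
    if (g == root) next
    # condition (1): while the branch above spans >= 2 species branches,
    # insert a node one species level up and continue from it
    cur <- g
    repeat {
      mg <- get(cur, envir = M); mp <- get(get(cur, envir = P), envir = M)
      if (mg == mp) break
      pm <- s_parent(mg)
      if (identical(pm, mp)) break
      cur <- insert_above(cur, pm)
    }
    # condition (2): the chain top maps strictly below a non-speciation parent
    mg <- get(cur, envir = M); pa <- get(cur, envir = P)
    if (mg != get(pa, envir = M) && !is_speciation(pa)) {
      insert_above(cur, s_parent(mg))
    }
  }
  children <- as.list(C)
  children <- children[lengths(children) > 0L]
  tr <- tree_from_children(children, root = root, binary = FALSE)
  m2 <- vapply(tr$ids, function(id) get(id, envir = M), "")
  names(m2) <- tr$ids
  list(tree = tr, species_map = m2)
}

#' Gene nodes attached to a species node
#'
#' `nodes_of` returns the gene nodes mapped to species node `s`;
#' `bottoms_of` the subset whose children are all mapped strictly below `s`
#' (including leaves); `tops_of(s)` equals `bottoms_of(p(s))`, the loci
#' entering the branch above `s` (empty for the species root, which has no
#' branch above it).
#'
#' @param species_map named character vector over the (augmented) gene tree.
#' @param gene_tree the tree the map lives on.
#' @param species_tree the species tree (only needed by `tops_of`).
#' @param s a species node id.
#' @return character vector of gene node ids.
#' @export
nodes_of <- function(species_map, gene_tree, s) {
  names(species_map)[species_map == s]
}

#' @rdname nodes_of
#' @export
bottoms_of <- function(species_map, gene_tree, s) {
  nod <- nodes_of(species_map, gene_tree, s)
  keep <- vapply(nod, function(g) {
    ch <- tree_children(gene_tree, g)
    length(ch) == 0L || all(species_map[ch] != s)
  }, logical(1))
  nod[keep]
}

#' @rdname nodes_of
#' @export
tops_of <- function(species_map, gene_tree, species_tree, s) {
  p <- tree_parent(species_tree, s)
  if (is.na(p)) return(character(0))
  bottoms_of(species_map, gene_tree, p)
}

#' Count duplication events of a locus map
#'
#' A non-root gene node whose locus differs from its parent's induces a
#' duplication on the edge above it.  Depends only on the locus map, never
#' on the species map.
#'
#' @param gene_tree the (possibly augmented) gene tree.
#' @param locus_map named vector, total on the tree's nodes.
#' @return nonnegative integer.
#' @export
count_duplications <- function(gene_tree, locus_map) {
  missing <- setdiff(gene_tree$ids, names(locus_map))
  if (length(missing) > 0L) {
    stop("locus map is not total; missing nodes: ",
         paste(lex_sort(missing), collapse = ", "))
  }
  lmv <- unname(locus_map[gene_tree$ids])
  non_root <- which(!is.na(gene_tree$parent_i))
  sum(lmv[non_root] != lmv[gene_tree$parent_i[non_root]])
}

#' Assemble an LCT from a species map and a duplication placement
#'
#' The public scoring pipeline: the species map is fixed first, implied
#' speciation nodes are inserted, and only then is the locus map defined on
#' the augmented tree (here from a duplication placement via the
#' locus/placement equivalence).
#'
#' @param instance a `dlc_instance`.
#' @param species_map named character vector on the original gene tree;
#'   defaults to the lca map.
#' @param placement character vector of gene-tree edge (child) ids.
#' @return an LCT: list(tree, species_map, locus_set, locus_map).
#' @export
make_lct <- function(instance, species_map = NULL, placement = character(0)) {
  if (is.null(species_map)) species_map <- lca_species_map(instance)
  viol <- check_species_map(instance, species_map)
  if (nrow(viol) > 0L) {
    stop("invalid species map; first violation: constraint ", viol$constraint[1L],
         " at ", viol$witness[1L])
  }
  aug <- add_implied_speciations(instance$gene_tree, instance$species_tree,
                                 species_map)
  loc <- locus_map_from_placement(aug$tree, placement)
  list(tree = aug$tree, species_map = aug$species_map,
       locus_set = loc$locus_set, locus_map = loc$locus_map)
}

#' Validate an LCT against the five model constraints
#'
#' The constraints: (1) the species map extends the leaf map; (2) each node
#' maps to an ancestor-or-self of its children's images; (3) paralogous
#' leaves carry distinct loci; (4) every locus in the locus set is used;
#' (5) every locus except the root's has exactly one creation node, and the
#' root's has none.
#'
#' @param instance a `dlc_instance`.
#' @param lct list(tree, species_map, locus_set, locus_map) on the
#'   augmented gene tree.
#' @return a data.frame with columns `constraint` (1-5) and `witness`
#'   (offending node ids / loci); zero rows iff the LCT is valid.
#' @export
validate_lct <- function(instance, lct) {
  tr <- lct$tree
  missing <- setdiff(tr$ids, names(lct$locus_map))
  if (length(missing) > 0L) {
    stop("locus map is not total; missing nodes: ",
         paste(lex_sort(missing), collapse = ", "))
  }
  viol <- check_species_map(instance, lct$species_map, tree = tr)
  res <- list(viol)
  lm <- lct$locus_map
  # constraint 3: paralogous leaves on distinct loci
  by_sp <- split(names(instance$leaf_map), unname(instance$leaf_map))
  for (grp in by_sp) {
    if (length(grp) < 2L) next
    loci <- lm[grp]
    if (anyDuplicated(loci)) {
      dup <- grp[loci %in% loci[duplicated(loci)]]
      res[[length(res) + 1L]] <- data.frame(
        constraint = 3L, witness = paste(lex_sort(dup), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  # constraint 4: every locus used
  unused <- setdiff(as.character(lct$locus_set), as.character(unname(lm)))
  if (length(unused) > 0L) {
    res[[length(res) + 1L]] <- data.frame(
      constraint = 4L, witness = unused, stringsAsFactors = FALSE)
  }
  # constraint 5: creation-node counts
  root <- tree_root(tr)
  lmv <- unname(lm[tr$ids])
  non_root_i <- which(!is.na(tr$parent_i))
  created <- tr$ids[non_root_i[lmv[non_root_i] != lmv[tr$parent_i[non_root_i]]]]
  ncreate <- table(factor(as.character(lm[created]),
                          levels = as.character(lct$locus_set)))
  for (l in names(ncreate)) {
    want <- if (l == as.character(lm[[root]])) 0L else 1L
    if (ncreate[[l]] != want) {
      res[[length(res) + 1L]] <- data.frame(
        constraint = 5L, witness = paste0("locus ", l, " created ",
                                          ncreate[[l]], "x"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Count loss events of an LCT
#'
#' A locus induces a loss on a species branch when it is present at the top
#' of the branch or on a node inside it, but absent from the branch bottom.
#' `loss_events` returns one row per (species branch, locus) loss;
#' `count_losses` their number.
#'
#' @param instance a `dlc_instance`.
#' @param lct a valid LCT (see [validate_lct()]).
#' @return `count_losses`: nonnegative integer. `loss_events`: data.frame
#'   with columns `species` (the branch's child node) and `locus`.
#' @export
loss_events <- function(instance, lct) {
  viol <- validate_lct(instance, lct)
  if (nrow(viol) > 0L) {
    stop("invalid LCT; first violation: constraint ", viol$constraint[1L],
         " (", viol$witness[1L], ")")
  }
  tr <- lct$tree; sm <- lct$species_map; lm <- lct$locus_map
  s <- instance$species_tree
  # per-gene-node bottom flag: leaf, or no child mapped to the same species
  smv <- unname(sm[tr$ids])
  is_bottom <- vapply(seq_along(tr$ids), function(i) {
    ch <- tr$children_i[[i]]
    length(ch) == 0L || all(smv[ch] != smv[i])
  }, logical(1))
  nodes_by_sp <- split(names(sm), unname(sm))
  bottoms_by_sp <- split(tr$ids[is_bottom], unname(sm[tr$ids[is_bottom]]))
  loci_at <- function(gset) unique(as.character(lm[gset]))
  out <- list()
  for (i in seq_along(s$ids)) {
    sid <- s$ids[i]
    pa <- s$parent_i[i]
    if (is.na(pa)) next
    tops <- bottoms_by_sp[[s$ids[pa]]]
    nod <- nodes_by_sp[[sid]]
    bot <- bottoms_by_sp[[sid]]
    lost <- setdiff(loci_at(c(tops, nod)), loci_at(bot))
    if (length(lost) > 0L) {
      out[[length(out) + 1L]] <- data.frame(
        species = sid, locus = lex_sort(lost), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(species = character(0), locus = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' @rdname loss_events
#' @export
count_losses <- function(instance, lct) nrow(loss_events(instance, lct))

#' Reconciliation cost of an LCT
#'
#' @param instance a `dlc_instance` carrying the per-event costs.
#' @param lct a valid LCT.
#' @return an object of class `dlc_events`: list(duplications, losses,
#'   cost) with cost = d * cost_dup + l * cost_loss.
#' @export
reconciliation_cost <- function(instance, lct) {
  d <- count_duplications(lct$tree, lct$locus_map)
  l <- count_losses(instance, lct)
  structure(list(duplications = as.integer(d), losses = as.integer(l),
                 cost = d * instance$cost_dup + l * instance$cost_loss),
            class = "dlc_events")
}

#' @export
print.dlc_events <- function(x, ...) {
  cat("duplications\t", x$duplications, "\n", sep = "")
  cat("losses\t", x$losses, "\n", sep = "")
  cat("cost\t", format(x$cost), "\n", sep = "")
  invisible(x)
}

#' Duplication placement from a locus map
#'
#' The set of edges (child ids) on which the locus changes; its size equals
#' the number of duplication events induced by the locus map.
#'
#' @param gene_tree the tree the locus map lives on.
#' @param locus_map named vector, total.
#' @return character vector of edge (child) ids, lexicographically sorted.
#' @export
placement_from_locus_map <- function(gene_tree, locus_map) {
  missing <- setdiff(gene_tree$ids, names(locus_map))
  if (length(missing) > 0L) {
    stop("locus map is not total; missing nodes: ",
         paste(lex_sort(missing), collapse = ", "))
  }
  non_root <- gene_tree$ids[!is.na(gene_tree$parent_i)]
  lex_sort(non_root[vapply(non_root, function(g) {
    locus_map[[g]] != locus_map[[tree_parent(gene_tree, g)]]
  }, logical(1))])
}

#' Locus map from a duplication placement
#'
#' Removing the placement's edges partitions the tree into |D| + 1
#' components; each component becomes one locus (consecutive integers in
#' preorder discovery order; locus identity matters only up to bijection).
#' The resulting map induces exactly |D| duplications and satisfies the
#' locus-set and single-creation constraints by construction.
#'
#' @param gene_tree the (possibly augmented) gene tree.
#' @param placement character vector of edge (child) ids; must be distinct
#'   edges of the tree.
#' @return list(locus_set, locus_map): integer loci 1..|D|+1 and a named
#'   integer vector over all nodes.
#' @export
locus_map_from_placement <- function(gene_tree, placement) {
  placement <- unique(placement)
  idx <- gene_tree$index[placement]
  if (anyNA(idx)) {
    stop("placement edges not in tree: ",
         paste(placement[is.na(idx)], collapse = ", "))
  }
  if (any(idx == gene_tree$root_i)) {
    stop("the root does not identify an edge")
  }
  cut <- logical(length(gene_tree$ids))
  cut[idx] <- TRUE
  loc <- integer(length(gene_tree$ids))
  counter <- 0L
  for (i in seq_along(gene_tree$ids)) {   # preorder
    pa <- gene_tree$parent_i[i]
    if (is.na(pa) || cut[i]) {
      counter <- counter + 1L
      loc[i] <- counter
    } else {
      loc[i] <- loc[pa]
    }
  }
  names(loc) <- gene_tree$ids
  list(locus_set = seq_len(counter), locus_map = loc)
}

#' Test whether an edge set is a duplication placement
#'
#' `TRUE` iff every paralogous pair of gene leaves (equal leaf-map image)
#' is separated by some member edge.
#'
#' @param instance a `dlc_instance`.
#' @param placement character vector of edge (child) ids.
#' @param tree tree on which to interpret the edges (defaults to the
#'   instance's gene tree; pass the augmented tree for augmented
#'   placements).
#' @return logical scalar.
#' @export
is_duplication_placement <- function(instance, placement,
                                     tree = instance$gene_tree) {
  for (pr in paralog_pairs(instance)) {
    if (!any(placement %in% path_edges(tree, pr[1L], pr[2L]))) return(FALSE)
  }
  TRUE
}

#' Score a reconciliation
#'
#' End-to-end scoring entry point: fixes the species map, inserts implied
#' speciation nodes, derives the locus map from the duplication placement,
#' validates, and counts events.
#'
#' @inheritParams make_lct
#' @return list(events = `dlc_events`, lct = the assembled LCT).
#' @export
dlc_score <- function(instance, species_map = NULL, placement = character(0)) {
  lct <- make_lct(instance, species_map, placement)
  list(events = reconciliation_cost(instance, lct), lct = lct)
}

#' All paralogous gene-leaf pairs
#'
#' Every unordered pair of distinct gene leaves sharing a leaf-map image,
#' each once, deterministically ordered.
#'
#' @param instance a `dlc_instance`.
#' @return list of length-2 character vectors.
#' @export
paralog_pairs <- function(instance) {
  by_sp <- split(names(instance$leaf_map), unname(instance$leaf_map))
  out <- list()
  for (s in lex_sort(names(by_sp))) {
    grp <- lex_sort(by_sp[[s]])
    if (length(grp) < 2L) next
    cmb <- utils::combn(grp, 2L)
    for (k in seq_len(ncol(cmb))) out[[length(out) + 1L]] <- cmb[, k]
  }
  out
}

#' Read or write a two-column tab-separated map file
#'
#' Format: `node_id<TAB>image_id`, one row per node, `#` comments and blank
#' lines allowed.
#'
#' @param path file path.
#' @param map named character vector (for writing).
#' @return `read_tsv_map`: named character vector.
#' @export
read_tsv_map <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(stats::setNames(character(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L) {
    stop("malformed map line ", bad[1L], ": expected 'id<TAB>image'")
  }
  keys <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(keys)) {
    stop("duplicate map keys: ", paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  stats::setNames(vapply(parts, `[[`, "", 2L), keys)
}

#' @rdname read_tsv_map
#' @export
write_tsv_map <- function(map, path) {
  writeLines(paste(names(map), unname(as.character(map)), sep = "\t"), path)
  invisible(path)
}
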