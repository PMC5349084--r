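# Rooted trees with string node ids.  Edges are identified everywhere by
# their child node (the edge e(v) = (p(v), v)), so a "placement" or an edge
# argument is just a child id.  Input trees must be binary; trees augmented
# with implied speciation nodes may contain one-child nodes.

#' Construct a rooted tree from a children table
#'
#' Low-level constructor used by the parsers, generators, and gadget
#' builders.  Nodes are stored in preorder; child order is preserved and is
#' semantically irrelevant to all costs, but makes output deterministic.
#'
#' @param children named list; `children[[id]]` is a character vector of the
#'   ids of the (ordered) children of `id`.  Leaves may be omitted.
#' @param root id of the root node.
#' @param binary if `TRUE` (the default), every node must have exactly 0 or
#'   2 children; augmented trees pass `FALSE` to allow degree-2 nodes.
#' @return an object of class `dlc_tree` with fields `ids` (preorder),
#'   `index` (id to position), `parent_i`, `children_i`, `depth_i`,
#'   `root_i`.
#' @export
tree_from_children <- function(children, root, binary = TRUE) {
  stopifnot(is.character(root), length(root) == 1L)
  all_ids <- unique(c(root, names(children), unlist(children, use.names = FALSE)))
  if (anyDuplicated(all_ids)) {
    stop("duplicate node ids: ", paste(all_ids[duplicated(all_ids)], collapse = ", "))
  }
  # iterative preorder
  n_guess <- length(all_ids)
  ids <- character(n_guess)
  parent <- character(n_guess)
  depth <- integer(n_guess)
  stack_id <- root
  stack_par <- NA_character_
  stack_dep <- 0L
  k <- 0L
  while (length(stack_id) > 0L) {
    id <- stack_id[1L]; pa <- stack_par[1L]; de <- stack_dep[1L]
    stack_id <- stack_id[-1L]; stack_par <- stack_par[-1L]; stack_dep <- stack_dep[-1L]
    k <- k + 1L
    ids[k] <- id; parent[k] <- pa; depth[k] <- de
    ch <- children[[id]]
    if (length(ch) > 0L) {
      stack_id <- c(ch, stack_id)
      stack_par <- c(rep(id, length(ch)), stack_par)
      stack_dep <- c(rep(de + 1L, length(ch)), stack_dep)
    }
  }
  if (k != n_guess) {
    stop("tree is not connected: ", n_guess - k, " node(s) unreachable from root")
  }
  ids <- ids[seq_len(k)]
  index <- stats::setNames(seq_len(k), ids)
  parent_i <- ifelse(is.na(parent[seq_len(k)]), NA_integer_, index[parent[seq_len(k)]])
  children_i <- lapply(ids, function(id) {
    ch <- children[[id]]
    if (is.null(ch)) integer(0) else unname(index[ch])
  })
  nch <- lengths(children_i)
  if (binary && any(nch == 1L)) {
    bad <- ids[nch == 1L][1L]
    stop("non-binary tree: node '", bad, "' has 1 child")
  }
  if (any(nch > 2L)) {
    bad <- ids[nch > 2L][1L]
    stop("non-binary tree: node '", bad, "' has ", nch[index[bad]], " children")
  }
  structure(
    list(ids = ids, index = index, parent_i = parent_i,
         children_i = children_i, depth_i = depth[seq_len(k)],
         root_i = unname(index[root])),
    class = "dlc_tree")
}

#' @export
print.dlc_tree <- function(x, ...) {
  cat("rooted tree: ", length(x$ids), " nodes (", sum(lengths(x$children_i) == 0L),
      " leaves), root '", x$ids[x$root_i], "'\n", sep = "")
  invisible(x)
}

node_pos <- function(tree, id) {
  i <- tree$index[id]
  if (anyNA(i)) {
    stop("unknown node id(s): ", paste(id[is.na(i)], collapse = ", "))
  }
  unname(i)
}

#' Tree accessors
#'
#' `tree_root`, `tree_leaves`, `tree_internal`, and `tree_edges` return node
#' ids; `tree_edges` returns the non-root node ids, i.e. the edges e(v)
#' identified by their child. `tree_children` and `tree_parent` look up one
#' node.
#'
#' @param tree a `dlc_tree`.
#' @param id a node id (for `tree_children`/`tree_parent`).
#' @return character vector of node ids (`tree_parent` returns `NA` for the
#'   root).
#' @export
tree_leaves <- function(tree) tree$ids[lengths(tree$children_i) == 0L]

#' @rdname tree_leaves
#' @export
tree_internal <- function(tree) tree$ids[lengths(tree$children_i) > 0L]

#' @rdname tree_leaves
#' @export
tree_root <- function(tree) tree$ids[tree$root_i]

#' @rdname tree_leaves
#' @export
tree_edges <- function(tree) tree$ids[-tree$root_i]

#' @rdname tree_leaves
#' @export
tree_children <- function(tree, id) tree$ids[tree$children_i[[node_pos(tree, id)]]]

#' @rdname tree_leaves
#' @export
tree_parent <- function(tree, id) {
  p <- tree$parent_i[node_pos(tree, id)]
  if (is.na(p)) NA_character_ else tree$ids[p]
}

#' @rdname tree_leaves
#' @export
is_leaf <- function(tree, id) lengths(tree$children_i[node_pos(tree, id)]) == 0L

#' Least common ancestor
#'
#' The deepest node that is an ancestor-or-self of both `u` and `v` under
#' the root-to-leaf partial order.
#'
#' @param tree a `dlc_tree`.
#' @param u,v node ids.
#' @return the id of the least common ancestor.
#' @export
lca <- function(tree, u, v) {
  i <- node_pos(tree, u); j <- node_pos(tree, v)
  while (tree$depth_i[i] > tree$depth_i[j]) i <- tree$parent_i[i]
  while (tree$depth_i[j] > tree$depth_i[i]) j <- tree$parent_i[j]
  while (i != j) { i <- tree$parent_i[i]; j <- tree$parent_i[j] }
  tree$ids[i]
}

#' Ancestor test
#'
#' `TRUE` iff `u` lies on the path from the root to `v` (reflexive:
#' every node is an ancestor-or-self of itself).
#'
#' @inheritParams lca
#' @return logical scalar.
#' @export
is_ancestor <- function(tree, u, v) {
  i <- node_pos(tree, u); j <- node_pos(tree, v)
  while (tree$depth_i[j] > tree$depth_i[i]) j <- tree$parent_i[j]
  i == j
}

#' Edges on the path between two nodes
#'
#' Returns the child-ids of the edges on the unique tree path between `u`
#' and `v`: the edges from `lca(u, v)` down to `u` plus those down to `v`.
#'
#' @inheritParams lca
#' @return character vector of edge (child node) ids; empty when `u == v`.
#' @export
path_edges <- function(tree, u, v) {
  i <- node_pos(tree, u); j <- node_pos(tree, v)
  up_i <- integer(0); up_j <- integer(0)
  while (tree$depth_i[i] > tree$depth_i[j]) { up_i <- c(up_i, i); i <- tree$parent_i[i] }
  while (tree$depth_i[j] > tree$depth_i[i]) { up_j <- c(up_j, j); j <- tree$parent_i[j] }
  while (i != j) {
    up_i <- c(up_i, i); i <- tree$parent_i[i]
    up_j <- c(up_j, j); j <- tree$parent_i[j]
  }
  tree$ids[c(up_i, up_j)]
}

#' Edge separation predicate
#'
#' An edge separates `u` and `v` when it lies on the path from `lca(u, v)`
#' to `u` or on the path from `lca(u, v)` to `v`.
#'
#' @param tree a `dlc_tree`.
#' @param edge an edge, identified by its child node id.
#' @param u,v node ids.
#' @return logical scalar.
#' @export
separates <- function(tree, edge, u, v) {
  x <- node_pos(tree, edge)
  if (is.na(tree$parent_i[x])) stop("the root '", edge, "' does not identify an edge")
  edge %in% path_edges(tree, u, v)
}

auto_label_pool <- function(taken) {
  counter <- 0L
  taken <- as.environment(stats::setNames(as.list(rep(TRUE, length(taken))), taken))
  function() {
    repeat {
      cand <- paste0("n", counter)
      counter <<- counter + 1L
      if (!exists(cand, envir = taken, inherits = FALSE)) {
        assign(cand, TRUE, envir = taken)
        return(cand)
      }
    }
  }
}

#' Parse a newick string into a rooted binary tree
#'
#' One tree per string, trailing semicolon mandatory.  Internal nodes
#' without labels receive deterministic generated labels (`n0`, `n1`, ... in
#' preorder); generated ids therefore reserve the pattern `n<digits>`, and a
#' warning is raised if user labels of that shape coexist with unlabeled
#' nodes.  Branch lengths are not supported and non-binary nodes are
#' rejected.
#'
#' @param text a newick string (or a length-1 character file content).
#' @return a `dlc_tree`.
#' @export
parse_newick <- function(text) {
  txt <- trimws(paste(text, collapse = ""))
  if (!nzchar(txt)) stop("newick parse error at position 1: empty input")
  # pre-scan so malformed input errors can name a position
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (pos in seq_along(chars)) {
    if (chars[pos] == "(") depth <- depth + 1L
    if (chars[pos] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("newick parse error at position ", pos, ": unbalanced ')'")
    }
  }
  if (depth != 0L) stop("newick parse error at position ", nchar(txt),
                        ": ", depth, " unclosed '('")
  if (chars[length(chars)] != ";") {
    stop("newick parse error at position ", nchar(txt), ": missing terminal ';'")
  }
  if (!grepl("[(]", txt)) {
    # single-node tree, e.g. "a;"
    lab <- sub(";$", "", txt)
    if (!nzchar(lab)) stop("newick parse error at position 1: unlabeled single node")
    return(tree_from_children(list(), root = lab))
  }
  ph <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop("newick parse error: ", conditionMessage(e)))
  if (is.null(ph)) stop("newick parse error: unreadable tree")
  ntip <- length(ph$tip.label)
  nlab <- ph$node.label
  if (is.null(nlab)) nlab <- rep("", ph$Nnode)
  nlab[is.na(nlab)] <- ""
  labs <- c(ph$tip.label, nlab)
  given <- labs[nzchar(labs)]
  if (anyDuplicated(given)) {
    stop("duplicate node labels: ", paste(unique(given[duplicated(given)]), collapse = ", "))
  }
  if (any(!nzchar(labs)) && any(grepl("^n[0-9]+$", given))) {
    warning("labels matching the reserved generated-id pattern n<digits> ",
            "coexist with unlabeled nodes: ",
            paste(given[grepl("^n[0-9]+$", given)], collapse = ", "))
  }
  nextlab <- auto_label_pool(given)
  # walk edges in cladewise (preorder) order assigning generated labels
  root_num <- ntip + 1L
  if (!nzchar(labs[root_num])) labs[root_num] <- nextlab()
  for (r in seq_len(nrow(ph$edge))) {
    child <- ph$edge[r, 2L]
    if (!nzchar(labs[child])) labs[child] <- nextlab()
  }
  children <- list()
  for (r in seq_len(nrow(ph$edge))) {
    pa <- labs[ph$edge[r, 1L]]
    children[[pa]] <- c(children[[pa]], labs[ph$edge[r, 2L]])
  }
  tree_from_children(children, root = labs[root_num])
}

write_clade <- function(tree, i) {
  ch <- tree$children_i[[i]]
  if (length(ch) == 0L) return(tree$ids[i])
  paste0("(", paste(vapply(ch, function(j) write_clade(tree, j), character(1)),
                    collapse = ","), ")", tree$ids[i])
}

#' Serialize a tree to newick
#'
#' Internal node labels are always written; no branch lengths.  Round-trips
#' with [parse_newick()].
#'
#' @param tree a `dlc_tree`.
#' @param file optional path; when given, the string is also written there.
#' @return the newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  s <- paste0(write_clade(tree, tree$root_i), ";")
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

# locale-independent sort used for every lexicographic tie-break
lex_sort <- function(x) {
  if (length(x) == 0L) return(character(0))
  sort(x, method = "radix")
}
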