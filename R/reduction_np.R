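# Compiler from 3-CNF formulas to DLC decision instances, and the
# constructive maps between valuations and duplication placements used in
# the correctness argument.  Duplication cost 1, loss cost 0, decision
# parameter 2n + m (m variables, n clauses).

# -- small mutable tree builder ---------------------------------------------

tree_builder <- function() {
  b <- new.env(parent = emptyenv())
  b$children <- list()
  b$seen <- character(0)
  b$add <- function(id, parent = NULL) {
    if (id %in% b$seen) stop("duplicate node id in construction: ", id)
    b$seen <- c(b$seen, id)
    if (!is.null(parent)) b$children[[parent]] <- c(b$children[[parent]], id)
    id
  }
  b
}

# deterministic left-comb over pre-built subtree roots; spine ids get
# `prefix`; returns the comb root id
comb_over <- function(b, roots, prefix) {
  k <- length(roots)
  if (k == 1L) return(roots[1L])
  spine <- paste0(prefix, seq_len(k - 1L))
  for (i in seq_len(k - 1L)) {
    b$children[[spine[i]]] <- c(b$children[[spine[i]]], roots[i])
    if (i < k - 1L) {
      b$children[[spine[i]]] <- c(b$children[[spine[i]]], spine[i + 1L])
    } else {
      b$children[[spine[i]]] <- c(b$children[[spine[i]]], roots[k])
    }
  }
  b$seen <- c(b$seen, spine)
  spine[1L]
}

gi_row <- function(node, gadget, role, i = NA, j = NA, h = NA, idx = NA) {
  data.frame(node = node, gadget = gadget, role = role,
             i = i, j = j, h = h, idx = idx, stringsAsFactors = FALSE)
}

#' Compile a 3-CNF formula into a DLC decision instance
#'
#' Builds the gene tree from one variable gadget per variable (a root
#' alpha_i over a true and a false caterpillar carrying leaves y_i,
#' y_{i,1..n} and their barred twins) and one clause gadget per clause
#' (delta_j over delta'_j and the three literal nodes lambda_{h,j}, each
#' with leaf children k_{h,j}, k'_{h,j}), assembled on a deterministic
#' left-comb backbone; the species tree is a left comb with 2mn + m + n
#' leaves labeled `1..2mn+m+n`.  The leaf map ties each variable gadget's
#' y_i / barred-y_i pair to one shared species leaf, each clause's three
#' k-leaves to another, and each k'_{h,j} to the y_{i,j} of the literal it
#' represents; all remaining gene leaves get fresh unshared species
#' leaves.  Costs are duplication 1 / loss 0 and the decision parameter is
#' 2n + m.
#'
#' @param cnf a normalized `dlc_cnf` (see [normalize_cnf()]).
#' @return an object of class `dlc_np_instance`: list(recon, decision_k,
#'   formula, gadget_index) where `gadget_index` maps every gene node to
#'   its gadget and role.
#' @export
build_np_instance <- function(cnf) {
  stopifnot(inherits(cnf, "dlc_cnf"))
  m <- cnf$num_vars
  n <- length(cnf$clauses)
  b <- tree_builder()
  gi <- list()

  var_side <- function(i, barred) {
    tag <- if (barred) "bar" else ""
    beta <- if (barred) paste0("bbar_", i) else paste0("beta_", i)
    y0 <- paste0("y", tag, "_", i)
    yk <- paste0("y", tag, "_", i, "_", seq_len(n))
    b$add(y0, beta)
    if (n == 1L) {
      b$add(yk[1L], beta)
    } else {
      chain <- if (barred) paste0("bbar_", i, "_", seq_len(n - 1L))
               else paste0("beta_", i, "_", seq_len(n - 1L))
      b$add(chain[1L], beta)
      for (k in seq_len(n - 1L)) {
        b$add(yk[k], chain[k])
        if (k < n - 1L) b$add(chain[k + 1L], chain[k]) else b$add(yk[n], chain[k])
      }
      for (k in seq_len(n - 1L)) {
        gi[[length(gi) + 1L]] <<- gi_row(chain[k], paste0("var_", i),
                                         if (barred) "bbar_chain" else "beta_chain",
                                         i = i, idx = k)
      }
    }
    gi[[length(gi) + 1L]] <<- gi_row(y0, paste0("var_", i),
                                     if (barred) "ybar" else "y", i = i)
    for (k in seq_len(n)) {
      gi[[length(gi) + 1L]] <<- gi_row(yk[k], paste0("var_", i),
                                       if (barred) "ybar_k" else "y_k",
                                       i = i, idx = k)
    }
  }

  var_roots <- character(m)
  for (i in seq_len(m)) {
    a <- paste0("alpha_", i)
    var_roots[i] <- b$add(a)
    b$add(paste0("beta_", i), a)
    b$add(paste0("bbar_", i), a)
    gi[[length(gi) + 1L]] <- gi_row(a, paste0("var_", i), "alpha", i = i)
    gi[[length(gi) + 1L]] <- gi_row(paste0("beta_", i), paste0("var_", i),
                                    "beta", i = i)
    gi[[length(gi) + 1L]] <- gi_row(paste0("bbar_", i), paste0("var_", i),
                                    "bbar", i = i)
    var_side(i, FALSE)
    var_side(i, TRUE)
  }
  cl_roots <- character(n)
  for (j in seq_len(n)) {
    d <- paste0("delta_", j)
    dp <- paste0("deltap_", j)
    cl_roots[j] <- b$add(d)
    b$add(dp, d)
    gi[[length(gi) + 1L]] <- gi_row(d, paste0("clause_", j), "delta", j = j)
    gi[[length(gi) + 1L]] <- gi_row(dp, paste0("clause_", j), "deltap", j = j)
    for (h in 1:3) {
      lam <- paste0("lam_", h, "_", j)
      b$add(lam, if (h <= 2L) dp else d)
      b$add(paste0("k_", h, "_", j), lam)
      b$add(paste0("kp_", h, "_", j), lam)
      gi[[length(gi) + 1L]] <- gi_row(lam, paste0("clause_", j), "lambda",
                                      j = j, h = h)
      gi[[length(gi) + 1L]] <- gi_row(paste0("k_", h, "_", j),
                                      paste0("clause_", j), "k", j = j, h = h)
      gi[[length(gi) + 1L]] <- gi_row(paste0("kp_", h, "_", j),
                                      paste0("clause_", j), "kprime", j = j, h = h)
    }
  }
  root <- comb_over(b, c(var_roots, cl_roots), "bb_")
  gene <- tree_from_children(b$children, root)
  for (sp in grep("^bb_", gene$ids, value = TRUE)) {
    gi[[length(gi) + 1L]] <- gi_row(sp, "backbone", "backbone")
  }

  n_sp <- 2L * m * n + m + n
  sb <- tree_builder()
  sp_leaves <- as.character(seq_len(n_sp))
  for (lf in sp_leaves) sb$add(lf)
  sp_root <- comb_over(sb, sp_leaves, "sv_")
  species <- tree_from_children(sb$children, sp_root)

  le <- character(0)
  for (i in seq_len(m)) {
    le[paste0("y_", i)] <- as.character(i)
    le[paste0("ybar_", i)] <- as.character(i)
  }
  for (j in seq_len(n)) for (h in 1:3) {
    le[paste0("k_", h, "_", j)] <- as.character(m + j)
  }
  for (r in seq_len(nrow(cnf$occ))) {
    o <- cnf$occ[r, ]
    target <- as.character(m + n + 3L * (o$j - 1L) + o$h)
    yk <- paste0(if (o$positive) "y_" else "ybar_", o$var, "_", o$j)
    le[paste0("kp_", o$h, "_", o$j)] <- target
    le[yk] <- target
  }
  rest <- setdiff(tree_leaves(gene), names(le))   # preorder order
  fresh <- as.character(seq.int(m + 4L * n + 1L, length.out = length(rest)))
  stopifnot(length(rest) == 2L * m * n - 3L * n,
            as.integer(fresh[length(fresh)]) == n_sp || length(rest) == 0L)
  le[rest] <- fresh
  inst <- recon_instance(gene, species, le, cost_dup = 1, cost_loss = 0)
  structure(
    list(recon = inst, decision_k = 2L * n + m, formula = cnf,
         gadget_index = do.call(rbind, gi)),
    class = "dlc_np_instance")
}

#' @export
print.dlc_np_instance <- function(x, ...) {
  cat("DLC decision instance from a 3-CNF formula\n")
  cat("  variables:", x$formula$num_vars, " clauses:", length(x$formula$clauses), "\n")
  cat("  gene tree:", length(x$recon$gene_tree$ids), "nodes; species tree:",
      length(x$recon$species_tree$ids), "nodes\n")
  cat("  decision parameter k =", x$decision_k, "\n")
  invisible(x)
}

#' Duplication placement from a satisfying valuation
#'
#' The constructive direction of the reduction: one duplication on the true
#' branch e(beta_i) of each variable set true (the false branch
#' e(bar-beta_i) otherwise), and for each clause, duplications on the two
#' lambda edges NOT corresponding to its chosen satisfying literal (the
#' lowest-index one).  Always has size 2n + m; it is a valid duplication
#' placement exactly when the valuation satisfies the formula.
#'
#' @param np a `dlc_np_instance`.
#' @param valuation logical vector over the formula's variables.
#' @return character vector of gene-tree edge (child) ids.
#' @export
np_solution_from_valuation <- function(np, valuation) {
  cnf <- np$formula
  stopifnot(length(valuation) == cnf$num_vars)
  d <- character(0)
  for (i in seq_len(cnf$num_vars)) {
    d <- c(d, if (valuation[i]) paste0("beta_", i) else paste0("bbar_", i))
  }
  for (j in seq_along(cnf$clauses)) {
    cl <- cnf$clauses[[j]]
    sat <- which(ifelse(cl > 0L, valuation[abs(cl)], !valuation[abs(cl)]))
    if (length(sat) == 0L) {
      stop("valuation does not satisfy clause ", j,
           "; no 2-edge choice exists for its gadget")
    }
    hstar <- sat[1L]
    d <- c(d, paste0("lam_", setdiff(1:3, hstar), "_", j))
  }
  lex_sort(d)
}

#' Valuation extracted from a duplication placement
#'
#' The converse direction: variable i is set true when the placement holds
#' a duplication on the path from alpha_i to y_i, false when on the path
#' from alpha_i to the barred y_i.  For a valid placement within the
#' decision budget the result satisfies the formula; a gadget with
#' duplications on both sides, or neither, signals a malformed placement.
#'
#' @param np a `dlc_np_instance`.
#' @param placement character vector of gene-tree edge (child) ids.
#' @return logical vector over the variables.
#' @export
np_valuation_from_solution <- function(np, placement) {
  cnf <- np$formula
  tr <- np$recon$gene_tree
  val <- logical(cnf$num_vars)
  for (i in seq_len(cnf$num_vars)) {
    true_path <- path_edges(tr, paste0("alpha_", i), paste0("y_", i))
    false_path <- path_edges(tr, paste0("alpha_", i), paste0("ybar_", i))
    on_t <- any(placement %in% true_path)
    on_f <- any(placement %in% false_path)
    if (on_t == on_f) {
      stop("variable gadget ", i, " has duplications on ",
           if (on_t) "both sides" else "neither side",
           "; not a tight solution")
    }
    val[i] <- on_t
  }
  val
}
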