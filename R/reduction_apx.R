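# Compiler from MAX3SAT(B) formulas to DLC optimization instances with
# nonzero loss cost, plus the constructive solution built from a
# valuation, the well-behavedness test, the converse extraction, and a
# per-clause loss audit.  Event costs: duplication 2Bn^2, loss 1,
# coalescence 0; the satisfiability budget is b = (10B+2)n^3 + 121n^2.

# attach an l-thorn (caterpillar with a designated end tip) to `parent`;
# spine node ids are root_id, <prefix>u2, ..., leaves <prefix>t1..tl.
add_thorn <- function(b, parent, root_id, prefix, l) {
  if (l < 1L) stop("thorn size must be >= 1")
  if (l == 1L) {
    b$add(root_id, parent)
    return(list(root = root_id, leaves = root_id, end_tip = root_id,
                spine = character(0)))
  }
  spine <- c(root_id, paste0(prefix, "u", seq.int(2L, l - 1L))[seq_len(max(0L, l - 2L))])
  leaves <- paste0(prefix, "t", seq_len(l))
  b$add(root_id, parent)
  for (i in seq_len(l - 1L)) {
    b$add(leaves[i], spine[i])
    if (i < l - 1L) b$add(spine[i + 1L], spine[i]) else b$add(leaves[l], spine[i])
  }
  list(root = root_id, leaves = leaves, end_tip = leaves[l], spine = spine)
}

#' Build a free-standing thorn gadget
#'
#' An l-thorn is a caterpillar with l leaves t1..tl hanging off a spine
#' u1..u(l-1); the deepest leaf tl is the designated end tip.
#'
#' @param l number of leaves, at least 2.
#' @param prefix id prefix for the generated nodes.
#' @return a `dlc_tree` with attributes `end_tip` and `leaves`.
#' @export
build_thorn <- function(l, prefix = "th_") {
  if (l < 2L) stop("thorn size must be >= 2")
  b <- tree_builder()
  th <- add_thorn(b, NULL, paste0(prefix, "u1"), prefix, l)
  tr <- tree_from_children(b$children, th$root)
  attr(tr, "end_tip") <- th$end_tip
  attr(tr, "leaves") <- th$leaves
  tr
}

#' Compile a MAX3SAT(B) formula into a DLC optimization instance
#'
#' The gene tree hangs a (3n-m+1)-thorn (all leaves mapped to one shared
#' species leaf) and a comb of n clause gadgets followed by m variable
#' gadgets under the root.  Clause gadgets carry, per literal, leaves
#' k_{h,j}, k'_{h,j} and k''_{h,j}; variable gadgets carry one
#' (n^2-1)-thorn per literal occurrence.  The species tree is a long trunk
#' (rho_0..rho_2m, sigma_j/sigma'_j per clause, tau_{h,j} per literal) with
#' one n^2-thorn per literal position; each gene occurrence thorn maps
#' leaf-for-leaf into the species thorn of the clause position where the
#' occurrence appears, and k''_{h,j} maps to that thorn's end tip.  Event
#' costs are duplication 2Bn^2 and loss 1.
#'
#' Requires at least 2 clauses (the occurrence thorns are (n^2-1)-thorns
#' and the construction is asymptotic in n).
#'
#' @param cnf a normalized `dlc_cnf`.
#' @param B occurrence bound; defaults to the maximum number of
#'   appearances of any variable, and it is an error to pass a smaller
#'   value.
#' @return an object of class `dlc_apx_instance`: list(recon, budget_b,
#'   B, n, m, alpha_denominator, formula, gadget_index).  The gap constant
#'   alpha = epsilon / (20B+4) is kept symbolically via its denominator
#'   (epsilon is existential and never given a numeric value).
#' @export
build_apx_instance <- function(cnf, B = NULL) {
  stopifnot(inherits(cnf, "dlc_cnf"))
  m <- cnf$num_vars
  n <- length(cnf$clauses)
  if (n < 2L) stop("the optimization reduction needs n >= 2 clauses")
  if (m > 3L * n) stop("internal error: normalized formula with m > 3n")
  occ_tot <- cnf$pos_count + cnf$neg_count
  B_actual <- max(occ_tot)
  if (is.null(B)) B <- B_actual
  if (B < B_actual) {
    stop("occurrence bound B = ", B, " violated: a variable appears ",
         B_actual, " times")
  }
  tl <- n^2 - 1L       # gene occurrence thorn size
  b <- tree_builder()
  gi <- list()
  # clause gadgets
  cl_roots <- character(n)
  for (j in seq_len(n)) {
    d <- paste0("delta_", j); dp <- paste0("deltap_", j)
    cl_roots[j] <- b$add(d); b$add(dp, d)
    gad <- paste0("clause_", j)
    gi[[length(gi) + 1L]] <- gi_row(d, gad, "delta", j = j)
    gi[[length(gi) + 1L]] <- gi_row(dp, gad, "deltap", j = j)
    for (h in 1:3) {
      lam <- paste0("lam_", h, "_", j); lamp <- paste0("lamp_", h, "_", j)
      b$add(lam, if (h <= 2L) dp else d)
      b$add(paste0("k_", h, "_", j), lam)
      b$add(lamp, lam)
      b$add(paste0("kp_", h, "_", j), lamp)
      b$add(paste0("kpp_", h, "_", j), lamp)
      gi[[length(gi) + 1L]] <- gi_row(lam, gad, "lambda", j = j, h = h)
      gi[[length(gi) + 1L]] <- gi_row(lamp, gad, "lambdap", j = j, h = h)
      gi[[length(gi) + 1L]] <- gi_row(paste0("k_", h, "_", j), gad, "k", j = j, h = h)
      gi[[length(gi) + 1L]] <- gi_row(paste0("kp_", h, "_", j), gad, "kprime", j = j, h = h)
      gi[[length(gi) + 1L]] <- gi_row(paste0("kpp_", h, "_", j), gad, "kdblprime", j = j, h = h)
    }
  }
  # variable gadgets, one occurrence thorn per literal appearance
  var_roots <- character(m)
  occ_thorns <- list()   # key "i_pos_q" -> thorn info
  var_side <- function(i, barred) {
    Bi <- if (barred) cnf$neg_count[i] else cnf$pos_count[i]
    gad <- paste0("var_", i)
    beta <- if (barred) paste0("bbar_", i) else paste0("beta_", i)
    betap <- if (barred) paste0("bbarp_", i) else paste0("betap_", i)
    y0 <- paste0(if (barred) "ybar_" else "y_", i)
    yp <- paste0(if (barred) "ybarp_" else "yp_", i)
    gi[[length(gi) + 1L]] <<- gi_row(beta, gad, if (barred) "bbar" else "beta", i = i)
    gi[[length(gi) + 1L]] <<- gi_row(y0, gad, if (barred) "ybar" else "y", i = i)
    gi[[length(gi) + 1L]] <<- gi_row(yp, gad, if (barred) "ybarp" else "yp", i = i)
    b$add(y0, beta)
    if (Bi == 0L) {
      b$add(yp, beta)
      return(invisible(NULL))
    }
    b$add(betap, beta)
    gi[[length(gi) + 1L]] <<- gi_row(betap, gad, if (barred) "bbarp" else "betap", i = i)
    b$add(yp, betap)
    mk_thorn <- function(q, parent) {
      pre <- paste0(if (barred) "vthb_" else "vth_", i, "_", q, "_")
      th <- add_thorn(b, parent, paste0(pre, "u1"), pre, tl)
      occ_thorns[[paste0(i, "_", !barred, "_", q)]] <<- th
      for (nd in c(th$spine, th$leaves)) {
        gi[[length(gi) + 1L]] <<- gi_row(nd, gad, "occ_thorn", i = i, idx = q)
      }
      th
    }
    if (Bi == 1L) {
      mk_thorn(1L, betap)
    } else {
      chain <- paste0(if (barred) "vbbar_" else "vbeta_", i, "_", seq_len(Bi - 1L))
      b$add(chain[1L], betap)
      for (q in seq_len(Bi - 1L)) {
        gi[[length(gi) + 1L]] <<- gi_row(chain[q], gad,
                                         if (barred) "bbar_chain" else "beta_chain",
                                         i = i, idx = q)
        if (q < Bi - 1L) {
          mk_thorn(q, chain[q])
          b$add(chain[q + 1L], chain[q])
        } else {
          mk_thorn(q, chain[q])
          mk_thorn(Bi, chain[q])
        }
      }
    }
    invisible(NULL)
  }
  for (i in seq_len(m)) {
    a <- paste0("alpha_", i)
    var_roots[i] <- b$add(a)
    b$add(paste0("beta_", i), a)
    b$add(paste0("bbar_", i), a)
    gi[[length(gi) + 1L]] <- gi_row(a, paste0("var_", i), "alpha", i = i)
    var_side(i, FALSE)
    var_side(i, TRUE)
  }
  # gene tree: g0 over the shared-species thorn (g1) and the gadget comb (g2)
  l1 <- 3L * n - m + 1L
  b$add("g0")
  g1 <- add_thorn(b, "g0", "g1", "g1_", l1)
  inner <- comb_over(b, c(cl_roots, var_roots), "bb_")
  if (length(cl_roots) + length(var_roots) == 1L) {
    stop("internal error: comb needs >= 2 gadgets")
  }
  # name the comb root g2 by inserting it above
  b$children[["g2"]] <- b$children[[inner]]
  b$children[[inner]] <- NULL
  b$seen <- setdiff(c(b$seen, "g2"), inner)
  # rename references to `inner` (it was a spine node bb_1 or a gadget root)
  for (nm in names(b$children)) {
    b$children[[nm]][b$children[[nm]] == inner] <- "g2"
  }
  # careful: if inner was a gadget root (single gadget), its own children
  # moved under g2 and gadget ids broke -- excluded by the >= 2 guard above.
  b$children[["g0"]] <- c(b$children[["g0"]], "g2")
  gene <- tree_from_children(b$children, "g0")
  for (nd in c(g1$spine, if (l1 > 1L) g1$leaves else "g1")) {
    gi[[length(gi) + 1L]] <- gi_row(nd, "g1thorn", "g1thorn")
  }
  for (nd in c("g0", "g2", grep("^bb_", gene$ids, value = TRUE))) {
    gi[[length(gi) + 1L]] <- gi_row(nd, "backbone", "backbone")
  }

  # species tree: trunk + side leaves + one n^2-thorn per literal position
  sb <- tree_builder()
  trunk <- c("rho_0", paste0("rho_", seq_len(2L * m)),
             as.vector(rbind(paste0("sig_", seq_len(n)), paste0("sigp_", seq_len(n)))),
             unlist(lapply(seq_len(n), function(j) paste0("tau_", 1:3, "_", j))))
  side <- c("r_0", paste0("r_", seq_len(2L * m)),
            as.vector(rbind(paste0("s_", seq_len(n)), paste0("sp_", seq_len(n)))),
            rep(NA_character_, 3L * n))
  sb$add(trunk[1L])
  sp_thorns <- list()
  for (t in seq_along(trunk)) {
    nd <- trunk[t]
    if (is.na(side[t])) {
      hj <- sub("^tau_", "", nd)
      pre <- paste0("sth_", hj, "_")
      sp_thorns[[hj]] <- add_thorn(sb, nd, paste0(pre, "u1"), pre, n^2)
    } else {
      sb$add(side[t], nd)
    }
    if (t < length(trunk)) sb$add(trunk[t + 1L], nd) else sb$add("xtra", nd)
  }
  species <- tree_from_children(sb$children, "rho_0")

  # leaf map
  le <- character(0)
  for (i in seq_len(m)) {
    le[paste0(c("y_", "ybar_"), i)] <- paste0("r_", 2L * i - 1L)
    le[paste0(c("yp_", "ybarp_"), i)] <- paste0("r_", 2L * i)
  }
  for (j in seq_len(n)) {
    le[paste0("k_", 1:3, "_", j)] <- paste0("s_", j)
    le[paste0("kp_", 1:3, "_", j)] <- paste0("sp_", j)
  }
  le[if (l1 > 1L) g1$leaves else "g1"] <- "r_0"
  for (r in seq_len(nrow(cnf$occ))) {
    o <- cnf$occ[r, ]
    gth <- occ_thorns[[paste0(o$var, "_", o$positive, "_", o$q)]]
    sth <- sp_thorns[[paste0(o$h, "_", o$j)]]
    le[gth$leaves] <- sth$leaves[seq_len(tl)]
    le[paste0("kpp_", o$h, "_", o$j)] <- sth$end_tip
  }
  cost_dup <- 2 * B * n^2
  inst <- recon_instance(gene, species, le, cost_dup = cost_dup, cost_loss = 1)
  structure(
    list(recon = inst, budget_b = (10 * B + 2) * n^3 + 121 * n^2,
         B = as.integer(B), n = n, m = m,
         alpha_denominator = 20L * B + 4L,
         formula = cnf, gadget_index = do.call(rbind, gi),
         g1_thorn = g1, occ_thorns = occ_thorns, sp_thorns = sp_thorns),
    class = "dlc_apx_instance")
}

#' @export
print.dlc_apx_instance <- function(x, ...) {
  cat("DLC optimization instance from a MAX3SAT(B) formula\n")
  cat("  variables:", x$m, " clauses:", x$n, " B:", x$B, "\n")
  cat("  gene tree:", length(x$recon$gene_tree$ids), "nodes; species tree:",
      length(x$recon$species_tree$ids), "nodes\n")
  cat("  costs: duplication", x$recon$cost_dup, "/ loss 1;  budget b =",
      x$budget_b, "\n")
  invisible(x)
}

#' Construct the reference solution from a valuation
#'
#' The species map sends every internal gene node to the species root
#' except the shared-leaf thorn under g1, which sits on the species leaf
#' r_0.  One duplication is placed per variable gadget (on the FALSE
#' branch e(beta_i) when x_i is false and on e(bar-beta_i) when true --
#' note this is the mirror image of the decision-instance convention), two
#' per clause gadget on the lambda edges away from the chosen satisfying
#' literal, and 3n-m on the g1-thorn's terminal edges, for exactly 5n
#' duplications in total.
#'
#' @param apx a `dlc_apx_instance`.
#' @param valuation logical vector over the variables.
#' @param allow_unsatisfied by default an unsatisfied clause is an error
#'   (no satisfying literal can be chosen); when `TRUE` such a clause gets
#'   duplications on e(lambda_1), e(lambda_2), which keeps the placement
#'   valid and well-behaved and is what the loss audit of wrong valuations
#'   uses.
#' @return list(species_map, placement).
#' @export
apx_solution_from_valuation <- function(apx, valuation, allow_unsatisfied = FALSE) {
  cnf <- apx$formula
  stopifnot(length(valuation) == cnf$num_vars)
  inst <- apx$recon
  g <- inst$gene_tree
  sm <- stats::setNames(rep("rho_0", length(g$ids)), g$ids)
  in_g1 <- apx$gadget_index$node[apx$gadget_index$gadget == "g1thorn"]
  sm[in_g1] <- "r_0"
  lv <- tree_leaves(g)
  sm[lv] <- inst$leaf_map[lv]
  d <- character(0)
  for (i in seq_len(cnf$num_vars)) {
    d <- c(d, if (valuation[i]) paste0("bbar_", i) else paste0("beta_", i))
  }
  for (j in seq_along(cnf$clauses)) {
    cl <- cnf$clauses[[j]]
    sat <- which(ifelse(cl > 0L, valuation[abs(cl)], !valuation[abs(cl)]))
    if (length(sat) == 0L) {
      if (!allow_unsatisfied) {
        stop("valuation does not satisfy clause ", j)
      }
      hstar <- 3L
    } else hstar <- sat[1L]
    d <- c(d, paste0("lam_", setdiff(1:3, hstar), "_", j))
  }
  l1 <- 3L * apx$n - apx$m + 1L
  if (l1 > 1L) {
    d <- c(d, paste0("g1_t", seq_len(l1 - 1L)))
  }
  list(species_map = sm, placement = lex_sort(d))
}

#' Test well-behavedness of a placement
#'
#' A solution of the optimization instance is well-behaved when it uses
#' exactly 5n duplications: one per variable gadget sitting on e(beta_i)
#' or e(bar-beta_i), exactly two inside each clause gadget, and 3n-m
#' inside the shared-leaf thorn -- and it must be a valid duplication
#' placement.  All optimal solutions are well-behaved.
#'
#' @param apx a `dlc_apx_instance`.
#' @param placement character vector of gene-tree edge (child) ids.
#' @return logical scalar.
#' @export
apx_is_well_behaved <- function(apx, placement) {
  n <- apx$n; m <- apx$m
  if (length(unique(placement)) != 5L * n) return(FALSE)
  placement <- unique(placement)
  gi <- apx$gadget_index
  gadget_of <- stats::setNames(gi$gadget, gi$node)
  gg <- gadget_of[placement]
  if (anyNA(gg)) return(FALSE)
  for (i in seq_len(m)) {
    inside <- placement[gg == paste0("var_", i)]
    if (length(inside) != 1L ||
        !inside %in% paste0(c("beta_", "bbar_"), i)) return(FALSE)
  }
  for (j in seq_len(n)) {
    if (sum(gg == paste0("clause_", j)) != 2L) return(FALSE)
  }
  if (sum(gg == "g1thorn") != 3L * n - m) return(FALSE)
  is_duplication_placement(apx$recon, placement)
}

#' Valuation extracted from a well-behaved placement
#'
#' A duplication on e(beta_i) reads as x_i = false and one on
#' e(bar-beta_i) as x_i = true (the optimization-side convention).
#'
#' @param apx a `dlc_apx_instance`.
#' @param placement a well-behaved placement (precondition; error
#'   otherwise).
#' @return logical vector over the variables.
#' @export
apx_valuation_from_solution <- function(apx, placement) {
  if (!apx_is_well_behaved(apx, placement)) {
    stop("placement is not well-behaved; extraction is undefined")
  }
  vapply(seq_len(apx$m), function(i) paste0("bbar_", i) %in% placement,
         logical(1))
}

#' Audit duplications and losses of an optimization-instance solution
#'
#' Scores (species map, placement) through the full pipeline and splits
#' the losses into the species-tree occurrence thorns (attributed to their
#' clause) and the trunk (everything else).  Under the reference solution
#' each satisfied clause contributes 2n^2 thorn losses (the chosen
#' literal's thorn contributes none) and each unsatisfied clause 3n^2.
#'
#' @param apx a `dlc_apx_instance`.
#' @param species_map,placement a solution, e.g. from
#'   [apx_solution_from_valuation()].
#' @return list(events, thorn_losses_by_clause (length-n integer),
#'   trunk_losses, within_budget).
#' @export
apx_loss_audit <- function(apx, species_map, placement) {
  sc <- dlc_score(apx$recon, species_map, placement)
  ev <- loss_events(apx$recon, sc$lct)
  # the thorn ROOT edge emanates from a trunk node, so losses there belong
  # to the trunk budget; thorn losses are those on edges strictly inside
  inside <- grepl("^sth_", ev$species) & !grepl("_u1$", ev$species)
  clause_of <- ifelse(inside,
                      sub("^sth_[0-9]+_([0-9]+)_.*$", "\\1", ev$species),
                      NA_character_)
  thorn <- integer(apx$n)
  for (j in seq_len(apx$n)) thorn[j] <- sum(clause_of == as.character(j), na.rm = TRUE)
  trunk <- sum(is.na(clause_of))
  list(events = sc$events,
       thorn_losses_by_clause = thorn,
       trunk_losses = trunk,
       within_budget = sc$events$cost < apx$budget_b)
}
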