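# 3-CNF formulas with per-variable occurrence accounting.  Clauses are
# ordered and the literals within a clause are ordered, so "the h-th
# literal of clause j" and "the q-th occurrence of a literal" are well
# defined; both reduction compilers rely on this addressing.

#' Construct a 3-CNF formula
#'
#' A clause is a length-3 integer vector of signed variable indices
#' (`c(1, -2, 3)` is x1 v !x2 v x3).  Each clause must mention three
#' distinct variables; use [normalize_cnf()] for raw clause lists.
#'
#' @param clauses list of length-3 signed integer vectors.
#' @param num_vars number of variables; defaults to the largest index used.
#' @return an object of class `dlc_cnf` with fields `num_vars`, `clauses`,
#'   `occ` (a data.frame with one row per literal occurrence: clause `j`,
#'   position `h`, variable `var`, `positive`, and occurrence number `q`
#'   advancing in clause order separately for each literal), and
#'   `pos_count`/`neg_count` per-variable occurrence counts.
#' @export
new_cnf <- function(clauses, num_vars = NULL) {
  if (length(clauses) == 0L) stop("empty formula")
  clauses <- lapply(clauses, as.integer)
  for (j in seq_along(clauses)) {
    cl <- clauses[[j]]
    if (length(cl) != 3L || any(cl == 0L)) {
      stop("clause ", j, " must have exactly 3 nonzero literals")
    }
    if (anyDuplicated(abs(cl))) {
      stop("clause ", j, " mentions a variable twice")
    }
  }
  used <- sort(unique(abs(unlist(clauses))))
  if (is.null(num_vars)) num_vars <- max(used)
  if (max(used) > num_vars) stop("literal exceeds num_vars")
  occ <- data.frame(
    j = rep(seq_along(clauses), each = 3L),
    h = rep(1:3, times = length(clauses)),
    var = abs(unlist(clauses)),
    positive = unlist(clauses) > 0L)
  occ$q <- stats::ave(seq_len(nrow(occ)),
                      occ$var, occ$positive, FUN = seq_along)
  pos <- integer(num_vars); neg <- integer(num_vars)
  tab_p <- table(factor(occ$var[occ$positive], levels = seq_len(num_vars)))
  tab_n <- table(factor(occ$var[!occ$positive], levels = seq_len(num_vars)))
  structure(
    list(num_vars = as.integer(num_vars), clauses = clauses, occ = occ,
         pos_count = as.integer(tab_p), neg_count = as.integer(tab_n)),
    class = "dlc_cnf")
}

#' @export
print.dlc_cnf <- function(x, ...) {
  cat("3-CNF formula:", x$num_vars, "variables,", length(x$clauses),
      "clauses, max occurrences", max(x$pos_count + x$neg_count), "\n")
  invisible(x)
}

#' Normalize raw 3-CNF clauses
#'
#' Duplicate literals within a clause are deduplicated (a clause left with
#' fewer than 3 literals is a format error); tautological clauses
#' containing a literal and its negation are trivially satisfied and are
#' dropped with a warning; variables left unused are dropped and the
#' remaining indices compacted.
#'
#' @param clauses list of signed integer vectors.
#' @return a `dlc_cnf`.
#' @export
normalize_cnf <- function(clauses) {
  out <- list()
  for (j in seq_along(clauses)) {
    cl <- unique(as.integer(clauses[[j]]))
    if (any(cl == 0L)) stop("clause ", j, ": literal 0 is not allowed")
    if (anyDuplicated(abs(cl))) {
      warning("clause ", j, " contains a literal and its negation; dropped ",
              "(trivially satisfied)")
      next
    }
    if (length(cl) != 3L) {
      stop("clause ", j, " has ", length(cl),
           " distinct literals after deduplication (need 3)")
    }
    out[[length(out) + 1L]] <- cl
  }
  if (length(out) == 0L) stop("empty formula after normalization")
  used <- sort(unique(abs(unlist(out))))
  remap <- stats::setNames(seq_along(used), used)
  out <- lapply(out, function(cl) {
    as.integer(sign(cl) * remap[as.character(abs(cl))])
  })
  new_cnf(out, num_vars = length(used))
}

#' Read / write DIMACS CNF
#'
#' `parse_dimacs` accepts the standard format (`c` comment lines, a
#' `p cnf <vars> <clauses>` header, zero-terminated clauses) restricted to
#' 3-literal clauses, and normalizes the result (see [normalize_cnf()]).
#'
#' @param text character vector of lines, or a single string.
#' @param cnf a `dlc_cnf` (for writing).
#' @param path output file (for writing).
#' @return `parse_dimacs`: a `dlc_cnf`.
#' @export
parse_dimacs <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "c")]
  hdr <- grep("^p\\s+cnf\\s", lines)
  if (length(hdr) != 1L) stop("DIMACS format error: need one 'p cnf' header")
  body <- paste(lines[-seq_len(hdr)], collapse = " ")
  toks <- suppressWarnings(as.integer(strsplit(trimws(body), "\\s+")[[1]]))
  if (anyNA(toks)) stop("DIMACS format error: non-integer token in clause body")
  clauses <- list()
  cur <- integer(0)
  for (t in toks) {
    if (t == 0L) {
      clauses[[length(clauses) + 1L]] <- cur
      cur <- integer(0)
    } else cur <- c(cur, t)
  }
  if (length(cur) > 0L) stop("DIMACS format error: last clause not 0-terminated")
  normalize_cnf(clauses)
}

#' @rdname parse_dimacs
#' @export
write_dimacs <- function(cnf, path = NULL) {
  lines <- c(paste("p cnf", cnf$num_vars, length(cnf$clauses)),
             vapply(cnf$clauses, function(cl) paste(c(cl, 0L), collapse = " "), ""))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Evaluate and decide satisfiability by truth table
#'
#' `eval_cnf` evaluates a valuation (logical vector indexed by variable);
#' `cnf_satisfiable` enumerates all 2^m valuations (a deliberate brute
#' force usable as an independent oracle for small formulas).
#'
#' @param cnf a `dlc_cnf`.
#' @param valuation logical vector of length `num_vars`.
#' @param max_vars guard for the truth-table enumeration.
#' @return `eval_cnf`: logical (all clauses satisfied).  `clause_values`:
#'   logical per clause.  `cnf_satisfiable`: list(satisfiable, valuation)
#'   where `valuation` is the first satisfying assignment in binary
#'   counting order, or `NULL`.
#' @export
clause_values <- function(cnf, valuation) {
  stopifnot(length(valuation) == cnf$num_vars, !anyNA(valuation))
  vapply(cnf$clauses, function(cl) {
    any(ifelse(cl > 0L, valuation[abs(cl)], !valuation[abs(cl)]))
  }, logical(1))
}

#' @rdname clause_values
#' @export
eval_cnf <- function(cnf, valuation) all(clause_values(cnf, valuation))

#' @rdname clause_values
#' @export
cnf_satisfiable <- function(cnf, max_vars = 20L) {
  m <- cnf$num_vars
  if (m > max_vars) stop("truth table guard: ", m, " variables > ", max_vars)
  for (code in 0:(2^m - 1)) {
    val <- as.logical(bitwAnd(bitwShiftR(code, seq_len(m) - 1L), 1L))
    if (eval_cnf(cnf, val)) {
      return(list(satisfiable = TRUE, valuation = val))
    }
  }
  list(satisfiable = FALSE, valuation = NULL)
}
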