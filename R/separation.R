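#' Interactome separation score between two gene sets
#'
#' Compares the shortest-path structure of two gene sets on the
#' interactome. With unweighted hop distances \eqn{d(\cdot,\cdot)}:
#' \deqn{d_{AA} = \mathrm{mean}_{a \in A} \min_{a' \in A \setminus \{a\}}
#'   d(a, a')}
#' and likewise \eqn{d_{BB}};
#' \deqn{d_{AB} = \mathrm{mean over all } |A| + |B| \mathrm{ nodes of the
#'   distance to the nearest node of the other set}}
#' (a gene shared by both sets contributes 0); and
#' \deqn{s_{AB} = d_{AB} - (d_{AA} + d_{BB}) / 2.}
#' A positive \eqn{s_{AB}} indicates the two sets occupy topologically
#' separated interactome neighborhoods; identical sets give
#' \eqn{s_{AB} = -d_{AA} < 0}. Node pairs with no connecting path are
#' excluded from the means and counted; if every cross-set term is
#' unreachable, \eqn{s_{AB}} is reported as undefined (`NA`), never as a
#' number.
#'
#' @param set_a,set_b Character vectors of gene symbols; each must map at
#'   least two genes onto the interactome.
#' @param interactome An igraph interactome (confidence scores are used
#'   only at load time; distances are unweighted).
#' @return An object of class `separation_result`: list with `s_ab`,
#'   `d_aa`, `d_bb`, `d_ab`, `n_unmapped` (per set), `n_unreachable`
#'   (per set, cross-set terms with no path), and the mapped set sizes.
#' @export
separation_score <- function(set_a, set_b, interactome) {
  nm <- igraph::V(interactome)$name
  a <- sort(intersect(unique(set_a), nm))
  b <- sort(intersect(unique(set_b), nm))
  n_unmapped <- c(a = length(unique(set_a)) - length(a),
                  b = length(unique(set_b)) - length(b))
  if (length(a) < 2L)
    stop("input error: set A maps fewer than 2 genes onto the interactome",
         call. = FALSE)
  if (length(b) < 2L)
    stop("input error: set B maps fewer than 2 genes onto the interactome",
         call. = FALSE)
  all_nodes <- union(a, b)
  dm <- igraph::distances(interactome, v = all_nodes, to = all_nodes,
                          weights = NA)
  nearest <- function(from, to, exclude_self = FALSE) {
    vapply(from, function(u) {
      tt <- if (exclude_self) setdiff(to, u) else to
      if (!length(tt)) return(Inf)
      min(dm[u, tt])
    }, 1)
  }
  within_mean <- function(s) {
    v <- nearest(s, s, exclude_self = TRUE)
    fin <- is.finite(v)
    list(mean = if (any(fin)) mean(v[fin]) else NA_real_,
         n_unreachable_within = sum(!fin))
  }
  waa <- within_mean(a); wbb <- within_mean(b)
  va <- nearest(a, b); vb <- nearest(b, a)
  fin_a <- is.finite(va); fin_b <- is.finite(vb)
  cross <- c(va[fin_a], vb[fin_b])
  d_ab <- if (length(cross)) mean(cross) else NA_real_
  s_ab <- if (!is.na(d_ab) && !is.na(waa$mean) && !is.na(wbb$mean))
    d_ab - (waa$mean + wbb$mean) / 2 else NA_real_
  structure(list(s_ab = s_ab, d_aa = waa$mean, d_bb = wbb$mean, d_ab = d_ab,
                 n_mapped = c(a = length(a), b = length(b)),
                 n_unmapped = n_unmapped,
                 n_unreachable = c(a = sum(!fin_a), b = sum(!fin_b)),
                 n_unreachable_within = c(a = waa$n_unreachable_within,
                                          b = wbb$n_unreachable_within)),
            class = "separation_result")
}

#' @export
print.separation_result <- function(x, ...) {
  cat("separation_result\n")
  cat("  d_AA =", format(x$d_aa), " d_BB =", format(x$d_bb),
      " d_AB =", format(x$d_ab), "\n")
  if (is.na(x$s_ab))
    cat("  s_AB undefined (all cross-set pairs unreachable)\n")
  else
    cat("  s_AB =", format(x$s_ab),
        if (x$s_ab > 0) "(sets topologically separated)"
        else "(sets overlap in the interactome)", "\n")
  invisible(x)
}

#' @export
as.list.separation_result <- function(x, ...) unclass(x)

#' Hypergeometric over-representation test for a gene set
#'
#' One-sided upper-tail hypergeometric test of the overlap between a query
#' gene set and a reference set within a universe: the probability of
#' drawing at least the observed overlap when sampling `|query|` genes
#' without replacement from the universe.
#'
#' @param query,reference Character vectors of genes, both subsets of
#'   `universe`.
#' @param universe Character vector: the gene universe.
#' @return A p-value in (0, 1].
#' @export
overrepresentation_test <- function(query, reference, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L)
    stop("input error: empty universe", call. = FALSE)
  query <- unique(query); reference <- unique(reference)
  if (!all(query %in% universe) || !all(reference %in% universe))
    stop("input error: query and reference must be subsets of the universe",
         call. = FALSE)
  k <- length(intersect(query, reference))
  stats::phyper(k - 1, length(reference),
                length(universe) - length(reference), length(query),
                lower.tail = FALSE)
}
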