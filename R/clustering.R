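#' Jaccard distance between two patient networks
#'
#' Distance is computed on node sets (gene symbols) by default:
#' \eqn{1 - |V_1 \cap V_2| / |V_1 \cup V_2|}. Nodes are the biological
#' payload of a patient network, and the downstream unique-gene analysis is
#' node-based; an edge-set variant is available via `on = "edges"`.
#'
#' @param g1,g2 `sample_network` objects (or igraphs / character vectors of
#'   node names).
#' @param on `"nodes"` (default) or `"edges"`.
#' @return A distance in \[0, 1\]. Two empty networks give 1 with a warning.
#' @export
jaccard_distance <- function(g1, g2, on = c("nodes", "edges")) {
  on <- match.arg(on)
  elems <- function(g) {
    if (is.character(g)) {
      if (on == "edges")
        stop("input error: edge Jaccard needs graph input", call. = FALSE)
      return(unique(g))
    }
    gr <- if (inherits(g, "igraph")) g else g$graph
    if (on == "nodes") igraph::V(gr)$name
    else {
      e <- igraph::ends(gr, igraph::E(gr))
      paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]), sep = "|")
    }
  }
  a <- elems(g1); b <- elems(g2)
  u <- length(union(a, b))
  if (u == 0L) {
    warning("both networks empty; Jaccard distance set to 1")
    return(1)
  }
  1 - length(intersect(a, b)) / u
}

#' Pairwise Jaccard distance matrix over patient networks
#'
#' @param networks Named list of `sample_network` objects (names are sample
#'   ids; unnamed lists use each network's `sample_id`).
#' @param on Passed to [jaccard_distance()].
#' @return Symmetric matrix with zero diagonal, rows/columns ordered by
#'   sample id.
#' @export
network_distance_matrix <- function(networks, on = "nodes") {
  if (is.null(names(networks)) || any(!nzchar(names(networks))))
    names(networks) <- vapply(networks, function(x) x$sample_id, "")
  ids <- sort(names(networks))
  networks <- networks[ids]
  node_sets <- lapply(networks, network_nodes)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    dij <- if (on == "nodes") {
      a <- node_sets[[i]]; b <- node_sets[[j]]
      u <- length(union(a, b))
      if (u == 0L) 1 else 1 - length(intersect(a, b)) / u
    } else jaccard_distance(networks[[i]], networks[[j]], on = on)
    d[i, j] <- d[j, i] <- dij
  }
  d
}

#' UPGMA hierarchical clustering with deterministic tie-breaking
#'
#' Agglomerative average-linkage clustering: at each step the two clusters
#' at minimal distance are merged at a height equal to that distance, and
#' the distance from the merged cluster to any other is the size-weighted
#' arithmetic mean of all cross-pair leaf distances. Ties are broken by the
#' lexicographically smallest (then second-smallest) cluster label, where a
#' cluster's label is its smallest member id — so dendrograms are exactly
#' reproducible.
#'
#' @param d Symmetric distance matrix with labeled rows/columns (or a
#'   [stats::dist]). At least two samples; `NA`/`NaN` entries are an error.
#' @return An object of class `ppin_dendrogram`: list with `hclust` (a
#'   valid [stats::hclust] object), `labels`, and `members` (per internal
#'   node, the member leaf labels, in merge order).
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d))
  n <- nrow(d)
  if (n < 2L) stop("input error: need at least 2 samples", call. = FALSE)
  if (anyNA(d)) stop("input error: NA/NaN distances", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12 || any(diag(d) != 0))
    stop("input error: distance matrix must be symmetric with zero diagonal",
         call. = FALSE)
  labs <- rownames(d)
  if (is.null(labs)) labs <- sprintf("S%03d", seq_len(n))
  ord <- order(labs)
  d <- d[ord, ord, drop = FALSE]
  labs <- labs[ord]

  active <- seq_len(n)
  size <- rep(1L, n)
  id <- -seq_len(n)                 # hclust convention: leaves negative
  label <- labs                     # smallest member id per cluster
  members <- lapply(labs, identity)
  D <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  node_members <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(active)
    sub <- D[active, active, drop = FALSE]
    mn <- min(sub[upper.tri(sub)])
    ties <- which(sub == mn & upper.tri(sub), arr.ind = TRUE)
    best_i <- best_j <- 0L; best_key <- NULL
    for (t in seq_len(nrow(ties))) {
      ii <- ties[t, 1L]; jj <- ties[t, 2L]
      l1 <- label[active[ii]]; l2 <- label[active[jj]]
      key <- c(min(l1, l2), max(l1, l2))
      if (is.null(best_key) ||
          key[1L] < best_key[1L] ||
          (key[1L] == best_key[1L] && key[2L] < best_key[2L])) {
        best_key <- key; best_i <- ii; best_j <- jj
      }
    }
    a <- active[best_i]; b <- active[best_j]
    if (label[b] < label[a]) { tmp <- a; a <- b; b <- tmp }
    merge[step, ] <- c(id[a], id[b])
    height[step] <- D[a, b]
    node_members[[step]] <- sort(c(members[[a]], members[[b]]))
    newsize <- size[a] + size[b]
    for (o in setdiff(active, c(a, b)))
      D[a, o] <- D[o, a] <- (size[a] * D[a, o] + size[b] * D[b, o]) / newsize
    size[a] <- newsize
    id[a] <- step
    label[a] <- min(label[a], label[b])
    members[[a]] <- node_members[[step]]
    active <- setdiff(active, b)
  }
  hc <- structure(list(merge = merge, height = height,
                       order = hclust_order(merge, n),
                       labels = labs, method = "average",
                       call = match.call(), dist.method = "jaccard"),
                  class = "hclust")
  structure(list(hclust = hc, labels = labs, members = node_members),
            class = "ppin_dendrogram")
}

# leaf ordering for plotting: left-to-right traversal of the merge tree
hclust_order <- function(merge, n) {
  rec <- function(node) {
    if (node < 0L) return(-node)
    c(rec(merge[node, 1L]), rec(merge[node, 2L]))
  }
  rec(n - 1L)
}

#' @export
print.ppin_dendrogram <- function(x, ...) {
  cat("ppin_dendrogram: ", length(x$labels), " leaves, root height ",
      format(max(x$hclust$height)), "\n", sep = "")
  invisible(x)
}

#' @export
as.hclust.ppin_dendrogram <- function(x, ...) x$hclust

#' Cophenetic distances of a dendrogram
#' @param dend A `ppin_dendrogram`.
#' @return A [stats::dist] of cophenetic (merge-height) distances.
#' @export
cophenetic_distances <- function(dend) {
  stats::cophenetic(dend$hclust)
}

#' Serialize a dendrogram as a Newick string
#'
#' Branch lengths are parent height minus child height (leaves sit at
#' height zero), so leaf-to-leaf path lengths equal twice the cophenetic
#' half-distance structure of the UPGMA tree.
#'
#' @param dend A `ppin_dendrogram`.
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string (terminated by `;`).
#' @export
newick <- function(dend, digits = 10L) {
  hc <- dend$hclust
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  rec <- function(node, parent_h) {
    if (node < 0L)
      return(paste0(hc$labels[-node], ":", fmt(parent_h)))
    h <- hc$height[node]
    paste0("(", rec(hc$merge[node, 1L], h), ",",
           rec(hc$merge[node, 2L], h), "):", fmt(parent_h - h))
  }
  root <- nrow(hc$merge)
  h <- hc$height[root]
  paste0("(", rec(hc$merge[root, 1L], h), ",",
         rec(hc$merge[root, 2L], h), ");")
}

#' Test dendrogram clusters for case/control enrichment
#'
#' Every internal node with at least `min_size` member samples is tested
#' with a two-sided 2x2 Fisher exact test comparing its members'
#' case/control composition against the non-members'. Nodes with
#' (optionally Bonferroni-corrected) p below `alpha` are significant; among
#' nested significant nodes the maximal (closest-to-root) ones are flagged
#' as headline clusters.
#'
#' @param dend A `ppin_dendrogram` whose leaves are sample ids.
#' @param phenotypes Phenotype data frame labeling every leaf.
#' @param min_size Minimum member count for a node to be tested (default 3).
#' @param alpha Significance level (default 0.05).
#' @param correction `"none"` (default; raw p as reported) or
#'   `"bonferroni"` across tested nodes.
#' @return An object of class `ppin_clusters`: data frame with one row per
#'   tested node (`node`, `size`, `n_cases`, `n_controls`, `p_value`,
#'   `dominance`, `significant`, `maximal`) and attribute `members` (list
#'   of member sample ids per node).
#' @export
significant_clusters <- function(dend, phenotypes, min_size = 3L,
                                 alpha = 0.05,
                                 correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  st <- phenotypes$status[match(dend$labels, phenotypes$sample_id)]
  if (anyNA(st))
    stop("input error: unlabeled leaf/leaves: ",
         paste(dend$labels[is.na(st)], collapse = ", "), call. = FALSE)
  tot_case <- sum(st == "case"); tot_ctrl <- sum(st == "control")
  nodes <- which(vapply(dend$members, length, 1L) >= min_size)
  if (length(nodes) == 0L) {
    res <- data.frame(node = integer(0), size = integer(0),
                      n_cases = integer(0), n_controls = integer(0),
                      p_value = numeric(0), dominance = character(0),
                      significant = logical(0), maximal = logical(0),
                      stringsAsFactors = FALSE)
    attr(res, "members") <- list()
    class(res) <- c("ppin_clusters", "data.frame")
    return(res)
  }
  res <- data.frame(node = nodes, size = NA_integer_,
                    n_cases = NA_integer_, n_controls = NA_integer_,
                    p_value = NA_real_, dominance = NA_character_,
                    stringsAsFactors = FALSE)
  for (r in seq_along(nodes)) {
    mem <- dend$members[[nodes[r]]]
    inn <- dend$labels %in% mem
    a <- sum(st == "case" & inn); b <- sum(st == "control" & inn)
    res$size[r] <- length(mem)
    res$n_cases[r] <- a; res$n_controls[r] <- b
    res$p_value[r] <- fisher_exact_2x2(a, b, tot_case - a, tot_ctrl - b)
    prop_in <- a / (a + b)
    prop_all <- tot_case / (tot_case + tot_ctrl)
    res$dominance[r] <- if (prop_in > prop_all) "case"
      else if (prop_in < prop_all) "control" else "neither"
  }
  p_adj <- if (correction == "bonferroni")
    pmin(1, res$p_value * nrow(res)) else res$p_value
  res$significant <- p_adj < alpha
  # maximal = significant with no significant strict ancestor
  anc_sig <- vapply(seq_along(nodes), function(r) {
    mem <- dend$members[[nodes[r]]]
    any(res$significant & res$size > res$size[r] &
          vapply(res$node, function(nn)
            all(mem %in% dend$members[[nn]]), TRUE) &
          res$node != nodes[r])
  }, TRUE)
  res$maximal <- res$significant & !anc_sig
  attr(res, "members") <- dend$members[nodes]
  attr(res, "alpha") <- alpha
  attr(res, "correction") <- correction
  class(res) <- c("ppin_clusters", "data.frame")
  res
}

#' Build the layered network of a cluster
#'
#' Union of the member patients' networks: each node and edge carries a
#' `support` count (how many member networks contain it); a node's role is
#' `"seed"` if it is a seed in any member network and `"imputed"` if it is
#' imputed-only.
#'
#' @param members Character vector of member sample ids (or a single row of
#'   a `ppin_clusters` result via its `members` attribute).
#' @param networks Named list of `sample_network` objects covering the
#'   members.
#' @return An object of class `layered_network`: list with `graph` (igraph
#'   with vertex attributes `support`, `role` and edge attribute `support`)
#'   and `n_members`.
#' @export
build_layered_network <- function(members, networks) {
  if (is.null(names(networks)))
    names(networks) <- vapply(networks, function(x) x$sample_id, "")
  missing <- setdiff(members, names(networks))
  if (length(missing))
    stop("input error: missing member network(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  nets <- networks[members]
  node_support <- list(); node_seed <- list(); edge_support <- list()
  for (nw in nets) {
    nm <- igraph::V(nw$graph)$name
    role <- igraph::V(nw$graph)$role
    for (i in seq_along(nm)) {
      node_support[[nm[i]]] <- (node_support[[nm[i]]] %||% 0L) + 1L
      node_seed[[nm[i]]] <- (node_seed[[nm[i]]] %||% FALSE) ||
        role[i] == "seed"
    }
    if (igraph::ecount(nw$graph)) {
      e <- igraph::ends(nw$graph, igraph::E(nw$graph))
      ek <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]), sep = "|")
      for (k in ek)
        edge_support[[k]] <- (edge_support[[k]] %||% 0L) + 1L
    }
  }
  vnames <- sort(names(node_support))
  ek <- sort(names(edge_support))
  epairs <- if (length(ek)) do.call(rbind, strsplit(ek, "|", fixed = TRUE))
    else matrix(character(0), 0L, 2L)
  g <- igraph::graph_from_data_frame(
    data.frame(from = epairs[, 1L], to = epairs[, 2L],
               support = as.integer(unlist(edge_support[ek], use.names = FALSE)),
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = vnames))
  igraph::V(g)$support <- as.integer(unlist(node_support[vnames],
                                            use.names = FALSE))
  igraph::V(g)$role <- ifelse(unlist(node_seed[vnames], use.names = FALSE),
                              "seed", "imputed")
  structure(list(graph = g, n_members = length(members)),
            class = "layered_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.layered_network <- function(x, ...) {
  cat("layered_network over ", x$n_members, " member networks: ",
      igraph::vcount(x$graph), " nodes, ", igraph::ecount(x$graph),
      " edges\n", sep = "")
  invisible(x)
}

#' Genes unique to each of two layered networks
#'
#' Node-set differences in both directions, each gene annotated with its
#' role in its own layer (`"seed"` = seed in at least one member network,
#' `"imputed"` = imputed-only).
#'
#' @param layer_a,layer_b `layered_network` objects.
#' @return List with data frames `a_only` and `b_only` (`gene`, `role`,
#'   alphabetical by gene).
#' @export
unique_genes <- function(layer_a, layer_b) {
  va <- igraph::V(layer_a$graph)$name
  vb <- igraph::V(layer_b$graph)$name
  mk <- function(g, layer) {
    role <- igraph::V(layer$graph)$role[match(g, igraph::V(layer$graph)$name)]
    o <- order(g)
    data.frame(gene = g[o], role = role[o], stringsAsFactors = FALSE)
  }
  list(a_only = mk(setdiff(va, vb), layer_a),
       b_only = mk(setdiff(vb, va), layer_b))
}
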