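#' Load a STRING-style interactome edge list
#'
#' Reads a whitespace- or tab-separated edge list (`protein1 protein2
#' combined_score`, optional header), optionally maps external identifiers
#' to gene symbols through a two-column alias table, drops self-loops and
#' edges below the confidence threshold, and deduplicates undirected edges
#' (keeping the maximum score when duplicates disagree).
#'
#' @param path Edge-list file.
#' @param confidence_threshold Minimum combined score retained (default 400,
#'   STRING's "medium confidence"). Edges with score strictly below the
#'   threshold are dropped.
#' @param aliases Optional data frame or two-column TSV path mapping
#'   `external_id` to `symbol`; unmapped identifiers keep their own name.
#' @return An undirected simple [igraph::igraph] with integer edge attribute
#'   `score` and graph attribute `confidence_threshold`.
#' @export
load_interactome <- function(path, confidence_threshold = 400,
                             aliases = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(parts)
  start <- 1L
  if (length(parts) && suppressWarnings(is.na(as.numeric(parts[[1L]][3L]))))
    start <- 2L  # header row
  if (length(parts) >= start) {
    idx <- seq.int(start, length(parts))
    nonthree <- idx[nf[idx] != 3L]
    if (length(nonthree))
      stop("parse error at line ", nonthree[1L],
           ": expected 'protein1 protein2 score'", call. = FALSE)
    m <- matrix(unlist(parts[idx]), ncol = 3L, byrow = TRUE)
    score <- suppressWarnings(as.numeric(m[, 3L]))
    if (anyNA(score))
      stop("parse error at line ", idx[which(is.na(score))[1L]],
           ": non-numeric score", call. = FALSE)
    from <- m[, 1L]; to <- m[, 2L]
  } else {
    from <- to <- character(0); score <- numeric(0)
  }
  if (!is.null(aliases)) {
    if (is.character(aliases))
      aliases <- utils::read.table(aliases, header = FALSE, sep = "\t",
                                   col.names = c("external_id", "symbol"),
                                   stringsAsFactors = FALSE)
    map <- function(x) {
      i <- match(x, aliases[[1L]])
      ifelse(is.na(i), x, aliases[[2L]][i])
    }
    from <- map(from); to <- map(to)
  }
  keep <- from != to & score >= confidence_threshold
  edges <- data.frame(from = from[keep], to = to[keep],
                      score = as.integer(round(score[keep])),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = list(score = "max"))
  igraph::graph_attr(g, "confidence_threshold") <-
    as.integer(confidence_threshold)
  g
}

#' Write an interactome as a STRING-style edge list
#'
#' @param interactome An igraph with edge attribute `score`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_interactome <- function(interactome, path) {
  el <- igraph::as_edgelist(interactome)
  out <- data.frame(protein1 = el[, 1L], protein2 = el[, 2L],
                    combined_score = igraph::E(interactome)$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build one patient's PPI network from seed genes
#'
#' Expands a patient's seed genes on the interactome using paths of length
#' at most two: the network contains the mapped seeds plus every
#' \emph{imputed} protein adjacent to at least two distinct seeds (a single
#' intermediary connecting two seed proteins). Edges are the interactome's
#' seed-seed edges and seed-imputed edges; imputed-imputed edges are
#' excluded by default since they lie on no seed-seed path of length <= 2.
#' The network is then restricted to its largest connected component (ties
#' broken by more seed nodes, then by the lexicographically smallest node
#' set). Seed genes absent from the interactome are dropped and recorded.
#'
#' @param seeds Character vector of seed genes, or a data frame with a
#'   `gene` column (as from [select_seed_genes()]).
#' @param interactome An igraph interactome.
#' @param sample_id Optional sample identifier stored on the result.
#' @param keep_imputed_edges Retain imputed-imputed edges (default FALSE).
#' @param largest_component Restrict to the largest connected component
#'   (default TRUE).
#' @return An object of class `sample_network`: list with `sample_id`,
#'   `graph` (igraph with vertex attribute `role` = `"seed"`/`"imputed"`),
#'   `seeds_mapped`, and `seeds_dropped`.
#' @export
build_sample_network <- function(seeds, interactome, sample_id = NA_character_,
                                 keep_imputed_edges = FALSE,
                                 largest_component = TRUE) {
  if (is.data.frame(seeds)) {
    if (is.na(sample_id) && !is.null(attr(seeds, "sample_id")))
      sample_id <- attr(seeds, "sample_id")
    seeds <- seeds$gene
  }
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0L)
    stop("input error: empty seed set", call. = FALSE)
  nm <- igraph::V(interactome)$name
  mapped <- intersect(seeds, nm)
  dropped <- setdiff(seeds, nm)
  if (length(mapped) == 0L)
    stop("empty-network error: no seed gene maps to the interactome",
         call. = FALSE)
  nb <- igraph::adjacent_vertices(interactome, mapped)
  cnt <- table(unlist(lapply(nb, as.integer)))
  cand <- nm[as.integer(names(cnt))[cnt >= 2L]]
  imputed <- setdiff(cand, mapped)
  nodes <- c(mapped, imputed)
  sub <- igraph::induced_subgraph(interactome, nodes)
  role <- ifelse(igraph::V(sub)$name %in% mapped, "seed", "imputed")
  igraph::V(sub)$role <- role
  if (!keep_imputed_edges) {
    ends <- igraph::ends(sub, igraph::E(sub))
    imp <- igraph::V(sub)$name[igraph::V(sub)$role == "imputed"]
    both_imp <- ends[, 1L] %in% imp & ends[, 2L] %in% imp
    sub <- igraph::delete_edges(sub, which(both_imp))
  }
  if (largest_component && igraph::vcount(sub) > 0L) {
    comp <- igraph::components(sub)
    sizes <- comp$csize
    best <- which(sizes == max(sizes))
    if (length(best) > 1L) {
      nseed <- vapply(best, function(ci)
        sum(igraph::V(sub)$role[comp$membership == ci] == "seed"), 1L)
      best <- best[nseed == max(nseed)]
      if (length(best) > 1L) {
        keysets <- vapply(best, function(ci)
          paste(sort(igraph::V(sub)$name[comp$membership == ci]),
                collapse = ","), "")
        best <- best[order(keysets)][1L]
      } else best <- best[1L]
    }
    sub <- igraph::induced_subgraph(sub, which(comp$membership == best))
  }
  structure(list(sample_id = sample_id, graph = sub,
                 seeds_mapped = mapped, seeds_dropped = dropped),
            class = "sample_network")
}

#' @export
print.sample_network <- function(x, ...) {
  r <- igraph::V(x$graph)$role
  cat("sample_network", if (!is.na(x$sample_id)) paste0("[", x$sample_id, "]"),
      ": ", sum(r == "seed"), " seed + ", sum(r == "imputed"),
      " imputed nodes, ", igraph::ecount(x$graph), " edges\n", sep = "")
  invisible(x)
}

#' Node names of a sample network
#' @param network A `sample_network` or `layered_network`.
#' @return Character vector of gene symbols.
#' @export
network_nodes <- function(network) {
  g <- if (inherits(network, "igraph")) network else network$graph
  igraph::V(g)$name
}

#' Write a network as GraphML
#'
#' Serializes a sample or layered network with its `role` (and, for layered
#' networks, `support`) attributes.
#'
#' @param network A `sample_network` or `layered_network`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  g <- if (inherits(network, "igraph")) network else network$graph
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
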