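# ---------------------------------------------------------------------------
# Interaction-network construction, Markov clustering, cluster ranking,
# betweenness centrality
# ---------------------------------------------------------------------------

#' Build a thresholded interaction graph
#'
#' Keeps edges whose association score is at least `threshold` (boundary
#' inclusive; 0.4 is the conventional medium-stringency cutoff) and whose
#' endpoints both belong to the node universe — typically the
#' significantly up- or down-regulated proteins. Universe nodes without a
#' retained edge stay in the graph as isolated vertices and are reported.
#'
#' @param edges an [edge_table()].
#' @param universe character vector of node symbols (case-insensitive).
#' @param threshold minimum association score in `[0, 1]`.
#' @return object of class `interaction_graph`: list with `graph` (an
#'   undirected weighted igraph), `threshold`, `isolated`.
#' @export
build_graph <- function(edges, universe, threshold = 0.4) {
  stopifnot(inherits(edges, "edge_table"))
  if (length(universe) == 0) stop("node universe is empty")
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0,1]")
  universe <- sort(unique(toupper(universe)))
  e <- as.data.frame(edges)
  e <- e[e$score >= threshold & e$node_a %in% universe &
           e$node_b %in% universe, , drop = FALSE]
  # collapse duplicate undirected pairs, keeping the maximum score
  if (nrow(e) > 0) {
    key <- ifelse(e$node_a < e$node_b,
                  paste(e$node_a, e$node_b), paste(e$node_b, e$node_a))
    ord <- order(key, -e$score)
    e <- e[ord, , drop = FALSE]
    e <- e[!duplicated(key[ord]), , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(e[c("node_a", "node_b", "score")],
                                     directed = FALSE,
                                     vertices = data.frame(name = universe))
  igraph::E(g)$weight <- igraph::E(g)$score
  isolated <- universe[igraph::degree(g)[universe] == 0]
  if (length(isolated) == length(universe) && nrow(e) == 0)
    warning("no edge connects the universe: graph is fully isolated")
  structure(list(graph = g, threshold = threshold, isolated = isolated),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("interaction_graph: %d nodes, %d edges (score >= %.2f), %d isolated\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$threshold, length(x$isolated)))
  invisible(x)
}

#' Markov clustering (MCL) of an interaction graph
#'
#' The literal flow-simulation algorithm on the dense column-stochastic
#' matrix: the weighted adjacency gets a self-loop per node equal to its
#' maximum incident edge weight (1 for isolated nodes), columns are
#' normalized, then expansion (matrix squaring) alternates with inflation
#' (entrywise power and re-normalization), pruning entries below `prune`
#' for numerical hygiene, until the largest entry change drops below `tol`
#' or `max_iter` is reached (the latter returns the partial result with a
#' warning). Clusters are the connected components of the attractor
#' structure: attractor rows sharing support belong to one cluster and
#' every node joins the cluster of its strongest attractor (ties broken by
#' node-name order).
#'
#' @param ig an `interaction_graph` from [build_graph()].
#' @param inflation entrywise-power parameter, must exceed 1; larger
#'   values give finer clusters. 1.9 is the conventional setting here.
#' @param prune entries below this are zeroed after each inflation.
#' @param tol convergence tolerance on the max absolute entry change.
#' @param max_iter iteration cap.
#' @return object of class `cluster_set`: list with `membership` (named
#'   integer vector, cluster ids 1..k in decreasing size order),
#'   `clusters` (list of member vectors), `sizes`, `size_rank`,
#'   `n_iter`, `converged`, and `colsum_dev` (max deviation of column
#'   sums from 1 observed after any inflation step).
#' @export
mcl_cluster <- function(ig, inflation = 1.9, prune = 1e-5, tol = 1e-6,
                        max_iter = 100) {
  stopifnot(inherits(ig, "interaction_graph"))
  if (inflation <= 1) stop("inflation must exceed 1 (no contraction otherwise)")
  g <- ig$graph
  n <- igraph::vcount(g)
  if (n == 0) stop("graph is empty")
  nodes <- igraph::V(g)$name
  A <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  A <- as.matrix(A)[nodes, nodes, drop = FALSE]
  max_inc <- apply(A, 2, max)
  diag(A) <- ifelse(max_inc > 0, max_inc, 1)
  M <- sweep(A, 2, colSums(A), `/`)
  converged <- FALSE
  it <- 0L
  colsum_dev <- 0
  while (it < max_iter) {
    it <- it + 1L
    M_new <- M %*% M                       # expansion
    M_new <- M_new ^ inflation             # inflation
    M_new <- sweep(M_new, 2, colSums(M_new), `/`)
    M_new[M_new < prune] <- 0              # pruning
    cs <- colSums(M_new)
    if (any(cs == 0)) stop("pruning removed a whole column; lower `prune`")
    M_new <- sweep(M_new, 2, cs, `/`)
    colsum_dev <- max(colsum_dev, max(abs(colSums(M_new) - 1)))
    delta <- max(abs(M_new - M))
    M <- M_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL hit max_iter without converging; returning partial result")

  attractors <- which(diag(M) > 0)
  if (length(attractors) == 0) attractors <- seq_len(n)  # degenerate safety
  # union attractors that support a common node
  comp <- seq_along(attractors)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (j in seq_len(n)) {
    sup <- which(M[attractors, j] > 0)
    if (length(sup) > 1) {
      r <- find(sup[1])
      for (s in sup[-1]) comp[find(s)] <- r
    }
  }
  roots <- vapply(seq_along(attractors), find, integer(1))
  # assign each node to its strongest attractor (ties: first in node order)
  memb_raw <- integer(n)
  for (j in seq_len(n)) {
    w <- M[attractors, j]
    if (max(w) <= 0) { memb_raw[j] <- NA_integer_; next }
    memb_raw[j] <- roots[which.max(w)]
  }
  # unattracted nodes (only possible on a non-converged partial result)
  if (anyNA(memb_raw)) {
    for (j in which(is.na(memb_raw)))
      memb_raw[j] <- roots[which.max(M[attractors, j] + 0) ]
  }
  # relabel clusters 1..k by decreasing size, ties by smallest member name
  ids <- unique(memb_raw)
  members <- lapply(ids, function(id) sort(nodes[memb_raw == id]))
  sizes <- lengths(members)
  ord <- order(-sizes, vapply(members, `[`, character(1), 1L))
  members <- members[ord]
  membership <- setNames(integer(n), nodes)
  for (k in seq_along(members)) membership[members[[k]]] <- k
  structure(list(membership = membership, clusters = members,
                 sizes = lengths(members),
                 size_rank = seq_along(members),
                 n_iter = it, converged = converged,
                 colsum_dev = colsum_dev),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters over %d nodes (sizes %s)\n",
              length(x$clusters), length(x$membership),
              paste(head(x$sizes, 10), collapse = ", ")))
  invisible(x)
}

#' Rank clusters by population
#'
#' Orders clusters by size (descending); ties are broken by total internal
#' edge weight (descending), then by the lexicographically smallest
#' member, so the ordering is deterministic. The conventional report shows
#' the 8 most populated subnetworks.
#'
#' @param cs a `cluster_set` from [mcl_cluster()].
#' @param ig the `interaction_graph` the clustering was computed on.
#' @param top_k how many clusters to return.
#' @return data.frame with columns rank, size, internal_weight, members
#'   (semicolon-joined) plus attribute `clusters` (list of member
#'   vectors in rank order).
#' @export
rank_clusters <- function(cs, ig, top_k = 8) {
  stopifnot(inherits(cs, "cluster_set"), inherits(ig, "interaction_graph"))
  g <- ig$graph
  iw <- vapply(cs$clusters, function(m) {
    sub <- igraph::induced_subgraph(g, m)
    if (igraph::ecount(sub) == 0) 0 else sum(igraph::E(sub)$weight)
  }, numeric(1))
  first <- vapply(cs$clusters, `[`, character(1), 1L)
  ord <- order(-cs$sizes, -iw, first)
  if (top_k < length(ord)) {
    sel <- ord[seq_len(top_k)]
  } else {
    if (top_k > length(ord))
      message("only ", length(ord), " cluster(s) available; returning all")
    sel <- ord
  }
  out <- data.frame(rank = seq_along(sel),
                    size = cs$sizes[sel],
                    internal_weight = iw[sel],
                    members = vapply(cs$clusters[sel], paste,
                                     character(1), collapse = ";"),
                    stringsAsFactors = FALSE)
  attr(out, "clusters") <- cs$clusters[sel]
  out
}

#' Betweenness centrality of graph nodes
#'
#' Shortest-path betweenness on the unweighted topology (association
#' scores threshold the graph but do not weight the paths), normalized by
#' `(n-1)(n-2)/2` within each connected component so values lie in
#' `[0, 1]`; nodes in components of fewer than 3 nodes score 0.
#'
#' @param ig an `interaction_graph`.
#' @return named numeric vector of centralities in `[0, 1]`.
#' @export
node_betweenness <- function(ig) {
  stopifnot(inherits(ig, "interaction_graph"))
  g <- ig$graph
  raw <- igraph::betweenness(g, directed = FALSE, weights = NA,
                             normalized = FALSE)
  comp <- igraph::components(g)
  sizes <- comp$csize[comp$membership]
  norm <- (sizes - 1) * (sizes - 2) / 2
  out <- ifelse(norm > 0, raw / norm, 0)
  setNames(as.numeric(out), igraph::V(g)$name)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions (up to renaming), around 0 for independent
#' ones. Used to score planted-module recovery.
#'
#' @param a,b label vectors of equal length (names ignored; order pairs
#'   the items).
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

#' Export an interaction graph to GraphML
#'
#' @param ig an `interaction_graph`.
#' @param path output path.
#' @export
write_graphml <- function(ig, path) {
  stopifnot(inherits(ig, "interaction_graph"))
  igraph::write_graph(ig$graph, path, format = "graphml")
  invisible(path)
}
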