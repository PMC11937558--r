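# Median-threshold binary social networks and degree / betweenness /
# closeness centrality.
#
# Centrality conventions (chosen to be consistent with reported group
# tables): degree is the raw number of direct ties; betweenness is
# unnormalized shortest-path betweenness on the unweighted graph with each
# unordered pair counted once and fractional credit split equally among all
# shortest paths; closeness is the unnormalized reciprocal of the summed
# shortest-path lengths to the nodes reachable from a node (so a hub
# directly tied to its whole 6-node component scores 1/5 = 0.2), and an
# isolated node scores 0 in all three.

#' Mean dyadic distance matrix
#'
#' Arithmetic mean of every dyad's retained samples, aggregated over the
#' whole observation period, as a symmetric animal x animal matrix.
#'
#' @param series_list named list of [distance_series()].
#' @param roster character vector of animal ids (matrix order, >= 3).
#' @return symmetric numeric matrix (cm) with zero diagonal; dyads with no
#'   retained samples are `NA` and flagged with a warning.
#' @export
mean_distance_matrix <- function(series_list, roster) {
  stop_if(length(roster) < 3, "need at least 3 animals for a network")
  m <- matrix(NA_real_, length(roster), length(roster),
              dimnames = list(roster, roster))
  diag(m) <- 0
  for (s in series_list) {
    i <- match(s$dyad[1], roster); j <- match(s$dyad[2], roster)
    if (is.na(i) || is.na(j)) next
    if (!length(s$d)) next
    m[i, j] <- m[j, i] <- mean(s$d)
  }
  miss <- which(is.na(m) & upper.tri(m), arr.ind = TRUE)
  if (nrow(miss)) {
    warning(sprintf("%d dyad(s) have no retained samples", nrow(miss)))
  }
  m
}

#' Binarize a distance matrix at the median threshold
#'
#' The threshold is the median of the upper-triangle (each dyad once)
#' off-diagonal entries; an edge connects a dyad iff its mean distance is
#' strictly below the threshold, so entries equal to the median produce no
#' edge and an all-equal matrix yields an empty graph.
#'
#' @param m symmetric distance matrix (cm), `NA` dyads allowed (no edge).
#' @return list with `adjacency` (binary symmetric matrix, zero diagonal)
#'   and `threshold_cm`.
#' @export
binarize_network <- function(m) {
  stop_if(!isSymmetric(unname(m)), "distance matrix must be symmetric")
  vals <- m[upper.tri(m)]
  thr <- stats::median(vals, na.rm = TRUE)
  adj <- (m < thr) * 1
  adj[is.na(adj)] <- 0
  diag(adj) <- 0
  if (all(adj == 0)) warning("empty graph: no distance below the median threshold")
  list(adjacency = adj, threshold_cm = thr)
}

# BFS from source s on adjacency list; returns distances, shortest-path
# counts sigma, and predecessor lists (Brandes' bookkeeping).
.bfs_paths <- function(adj_list, n, s) {
  dist <- rep(Inf, n); sigma <- numeric(n); preds <- vector("list", n)
  dist[s] <- 0; sigma[s] <- 1
  queue <- s; order_out <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order_out <- c(order_out, v)
    for (w in adj_list[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
      if (dist[w] == dist[v] + 1) {
        sigma[w] <- sigma[w] + sigma[v]
        preds[[w]] <- c(preds[[w]], v)
      }
    }
  }
  list(dist = dist, sigma = sigma, preds = preds, order = order_out)
}

#' Degree, betweenness and closeness centrality
#'
#' Computes the three centralities on a binary undirected graph using the
#' conventions documented above (unnormalized; pairs counted once; closeness
#' restricted to the reachable component; isolated nodes score 0).
#'
#' @param adjacency binary symmetric matrix with zero diagonal.
#' @return data.frame: node, degree, betweenness, closeness.
#' @export
graph_centralities <- function(adjacency) {
  stop_if(!isSymmetric(unname(adjacency)), "adjacency must be symmetric")
  stop_if(any(adjacency != 0 & adjacency != 1), "adjacency must be binary")
  n <- nrow(adjacency)
  nodes <- rownames(adjacency) %||% as.character(seq_len(n))
  adj_list <- lapply(seq_len(n), function(i) which(adjacency[i, ] == 1))
  degree <- vapply(adj_list, length, 0L)
  btw <- numeric(n); clo <- numeric(n)
  for (s in seq_len(n)) {
    b <- .bfs_paths(adj_list, n, s)
    reach <- which(is.finite(b$dist))
    reach <- setdiff(reach, s)
    clo[s] <- if (length(reach)) 1 / sum(b$dist[reach]) else 0
    # Brandes dependency accumulation (counts each ordered pair once; the
    # undirected result is halved below)
    delta <- numeric(n)
    for (w in rev(b$order)) {
      for (v in b$preds[[w]]) {
        delta[v] <- delta[v] + b$sigma[v] / b$sigma[w] * (1 + delta[w])
      }
      if (w != s) btw[w] <- btw[w] + delta[w]
    }
  }
  btw <- btw / 2
  data.frame(node = nodes, degree = as.integer(degree), betweenness = btw,
             closeness = clo, stringsAsFactors = FALSE)
}

#' Build the social network of one condition
#'
#' Mean-distance matrix -> median-threshold binary adjacency -> centralities.
#'
#' @param series_list named list of [distance_series()].
#' @param roster character vector of animal ids.
#' @return object of class `social_network`: list with `mean_distance`,
#'   `threshold_cm`, `adjacency`, `centralities`, `roster`.
#' @export
build_social_network <- function(series_list, roster) {
  m <- mean_distance_matrix(series_list, roster)
  bn <- binarize_network(m)
  cent <- graph_centralities(bn$adjacency)
  structure(list(mean_distance = m, threshold_cm = bn$threshold_cm,
                 adjacency = bn$adjacency, centralities = cent,
                 roster = roster), class = "social_network")
}

#' @export
print.social_network <- function(x, ...) {
  cat(sprintf("<social_network: %d nodes, %d edges, threshold %.1f cm>\n",
              length(x$roster), sum(x$adjacency) / 2, x$threshold_cm))
  invisible(x)
}

#' Export a social network as GraphML and an edge-list CSV
#'
#' Node attributes carry the three centralities; the edge attribute
#' `mean_distance_cm` carries the dyad's mean distance (the edge weight
#' used for reporting).
#'
#' @param network a `social_network` from [build_social_network()].
#' @param graphml_path output GraphML path (skipped if `NULL`).
#' @param edges_path output edge-list CSV path (skipped if `NULL`).
#' @return the igraph object, invisibly.
#' @export
export_graph <- function(network, graphml_path = NULL, edges_path = NULL) {
  g <- igraph::graph_from_adjacency_matrix(network$adjacency,
                                           mode = "undirected")
  cent <- network$centralities
  igraph::V(g)$degree <- cent$degree
  igraph::V(g)$betweenness <- cent$betweenness
  igraph::V(g)$closeness <- cent$closeness
  el <- igraph::as_edgelist(g)
  w <- if (nrow(el)) network$mean_distance[el] else numeric(0)
  igraph::E(g)$mean_distance_cm <- w
  if (!is.null(graphml_path)) {
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  if (!is.null(edges_path)) {
    df <- data.frame(from = el[, 1], to = el[, 2], mean_distance_cm = w)
    utils::write.csv(df, edges_path, row.names = FALSE)
  }
  invisible(g)
}
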