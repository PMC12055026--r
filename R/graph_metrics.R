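#' Threshold an MSN into an undirected weighted graph
#'
#' Keeps the top `density` fraction of positive off-diagonal edges by weight
#' (proportional thresholding of the upper triangle), preserving the weights.
#' A disconnected result triggers a warning and is flagged; path-length
#' computation then falls back to the largest connected component.
#'
#' @param msn symmetric MSN matrix, zero diagonal.
#' @param density fraction of possible edges kept, in (0, 1). Default 0.10,
#'   mirroring the gradient sparsification.
#' @return list: `graph` (igraph, weighted), `connected` flag.
#' @export
threshold_graph <- function(msn, density = 0.10) {
  check_square_symmetric(msn, "msn")
  stop_if(density <= 0 || density >= 1, "`density` must lie in (0, 1)")
  n <- nrow(msn)
  ut <- which(upper.tri(msn), arr.ind = TRUE)
  w <- msn[ut]
  pos <- w > 0
  stop_if(!any(pos), "no positive off-diagonal entries: empty graph")
  m_keep <- max(1L, floor(density * nrow(ut)))
  m_keep <- min(m_keep, sum(pos))
  keep <- order(w, decreasing = TRUE)[seq_len(m_keep)]
  adj <- matrix(0, n, n, dimnames = dimnames(msn))
  adj[ut[keep, , drop = FALSE]] <- w[keep]
  adj <- adj + base::t(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  connected <- igraph::is_connected(g)
  if (!connected) {
    warning("thresholded graph is disconnected; path length will use the largest component",
            call. = FALSE)
  }
  list(graph = g, connected = connected)
}

#' Network-mean weighted clustering coefficient
#'
#' Onnela's weighted clustering: per node, the sum of geometric means of
#' max-normalized triangle weights over the number of possible triangles
#' `k(k-1)`, averaged over nodes (nodes with degree < 2 contribute 0). With
#' all weights equal this reduces exactly to the binary clustering
#' coefficient. Measures network segregation.
#'
#' @param graph result of [threshold_graph()] or an igraph object with a
#'   `weight` edge attribute (unweighted graphs are treated as unit weights).
#' @return scalar in \[0, 1\].
#' @export
clustering_coefficient <- function(graph) {
  g <- as_weighted_igraph(graph)
  n <- igraph::vcount(g)
  stop_if(n < 3, "need at least 3 nodes")
  w <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight", sparse = TRUE))
  mx <- max(w)
  if (mx == 0) return(0)
  w13 <- (w / mx)^(1 / 3)
  cycles <- diag(w13 %*% w13 %*% w13)      # 2 x sum of triangle geometric means
  k <- rowSums(w > 0)
  ci <- ifelse(k >= 2, cycles / (k * (k - 1)), 0)
  mean(ci)
}

#' Characteristic path length
#'
#' Mean shortest-path distance over ordered node pairs, with edge length
#' `1 / weight` (strong similarity = short distance), the standard weighted
#' convention. On a disconnected graph the mean is taken over the largest
#' connected component, with a warning. Measures network integration.
#'
#' @inheritParams clustering_coefficient
#' @return positive scalar.
#' @export
characteristic_path_length <- function(graph) {
  g <- as_weighted_igraph(graph)
  stop_if(igraph::vcount(g) < 2, "need at least 2 nodes")
  if (!igraph::is_connected(g)) {
    warning("graph disconnected: using the largest component", call. = FALSE)
    comp <- igraph::components(g)
    g <- igraph::induced_subgraph(g, which(comp$membership ==
                                             which.max(comp$csize)))
    stop_if(igraph::vcount(g) < 2, "largest component has a single node")
  }
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  mean(d[base::row(d) != base::col(d)])
}

as_weighted_igraph <- function(graph) {
  if (is.list(graph) && !igraph::is_igraph(graph) && !is.null(graph$graph)) {
    graph <- graph$graph
  }
  stop_if(!igraph::is_igraph(graph), "`graph` must be an igraph object")
  if (!"weight" %in% igraph::edge_attr_names(graph)) {
    igraph::E(graph)$weight <- 1
  }
  stop_if(any(igraph::E(graph)$weight <= 0), "edge weights must be positive")
  graph
}

#' Per-subject MSN topology metrics
#'
#' Convenience wrapper computing both topology metrics from each subject's
#' MSN at a common threshold density.
#'
#' @param msns list of MSN matrices.
#' @param density proportional threshold density.
#' @return data.frame: subject_id, clustering, path_length.
#' @export
topology_metrics <- function(msns, density = 0.10) {
  rows <- lapply(seq_along(msns), function(i) {
    tg <- threshold_graph(msns[[i]], density)
    data.frame(subject_id = names(msns)[i] %||% sprintf("sub-%03d", i),
               clustering = clustering_coefficient(tg),
               path_length = characteristic_path_length(tg),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Correlate a topology metric with a global gradient metric
#'
#' Pearson correlation (two-sided p) between a per-subject topology metric
#' and a per-subject global gradient metric within one group — e.g. path
#' length against the first-gradient explained ratio in the patient group.
#'
#' @param topology numeric vector (one value per subject).
#' @param gradient_metric numeric vector, same subjects.
#' @param subset optional logical/integer index restricting to a group.
#' @return list with `r` and `p`.
#' @export
topology_gradient_correlation <- function(topology, gradient_metric,
                                          subset = NULL) {
  if (!is.null(subset)) {
    topology <- topology[subset]
    gradient_metric <- gradient_metric[subset]
  }
  stop_if(length(topology) != length(gradient_metric),
          "metric vectors must be the same length")
  stop_if(length(topology) < 3, "need at least 3 subjects")
  ct <- cor.test(topology, gradient_metric)
  list(r = unname(ct$estimate), p = ct$p.value)
}
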