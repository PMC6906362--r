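# The sixteen node-level structural metrics.
#
# Topology metrics are computed on the unweighted skeleton (clique and
# triangle counts are inherently unweighted and no edge-inclusion weight
# threshold is imposed); edge_weight reports the co-occurrence proportions
# themselves.
# Three metrics are edge-valued (edge_betweenness_centrality, edge_load,
# edge_weight); they are returned per edge by default, with a per-node
# incident mean available. Disconnected graphs: distance-based metrics sum
# over reachable pairs only; degree-0 nodes score 0 where the textbook
# definition divides by the degree.

#' The sixteen supported metric names
#' @export
METRICS16 <- c("average_neighbor_degree", "degree_centrality",
               "closeness_centrality", "betweenness_centrality",
               "edge_betweenness_centrality", "number_of_cliques",
               "node_clique_number", "triangles", "clustering",
               "all_pairs_node_connectivity", "closeness_vitality",
               "square_clustering", "edge_load", "effective_size",
               "constraint", "edge_weight")

EDGE_METRICS <- c("edge_betweenness_centrality", "edge_load", "edge_weight")

adjacency_of <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    A[cbind(net$edges$from, net$edges$to)] <- 1L
    A[cbind(net$edges$to, net$edges$from)] <- 1L
  }
  A
}

edge_key <- function(from, to) {
  paste(pmin(from, to), pmax(from, to), sep = "|")
}

# local node connectivity between a specific pair, networkx-style: for
# adjacent nodes the direct edge contributes one internally disjoint path on
# top of the connectivity of the graph without that edge
local_node_connectivity <- function(g, u, v) {
  if (igraph::are_adjacent(g, u, v)) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(u, v)))
    1L + igraph::vertex_disjoint_paths(g2, source = u, target = v)
  } else {
    igraph::vertex_disjoint_paths(g, source = u, target = v)
  }
}

wiener_index <- function(g, weighted = FALSE) {
  w <- if (weighted) igraph::E(g)$weight else NA
  d <- igraph::distances(g, weights = w)
  sum(d[upper.tri(d)][is.finite(d[upper.tri(d)])])
}

square_clustering_one <- function(A, v) {
  nb <- which(A[v, ] == 1L)
  if (length(nb) < 2L) return(0)
  num <- 0; den <- 0
  for (ui in seq_along(nb)[-length(nb)]) {
    for (wi in (ui + 1L):length(nb)) {
      u <- nb[ui]; w <- nb[wi]
      common <- sum(A[u, ] == 1L & A[w, ] == 1L) -
        (A[u, v] & A[w, v])  # exclude v itself
      q <- common
      theta <- A[u, w]
      deg_u <- sum(A[u, ]); deg_w <- sum(A[w, ])
      a <- (deg_u - (1 + q + theta)) + (deg_w - (1 + q + theta))
      num <- num + q
      den <- den + q + a
    }
  }
  if (den == 0) 0 else num / den
}

# Goh load centrality on edges: each node, as a target of every source,
# receives one unit which flows back along shortest-path predecessors, split
# equally at each node; edge load is the total flow carried
edge_load_values <- function(net) {
  A <- adjacency_of(net)
  n <- nrow(A)
  nodes <- net$nodes
  load <- stats::setNames(numeric(nrow(net$edges)),
                          edge_key(net$edges$from, net$edges$to))
  if (n == 0 || nrow(net$edges) == 0) return(load)
  nbrs <- lapply(seq_len(n), function(i) which(A[i, ] == 1L))
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n); dist[s] <- 0L
    order_ <- integer(0); frontier <- s
    while (length(frontier)) {
      order_ <- c(order_, frontier)
      nxt <- integer(0)
      for (v in frontier) {
        for (w in nbrs[[v]]) if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          nxt <- c(nxt, w)
        }
      }
      frontier <- unique(nxt)
    }
    b <- rep(1, n); b[s] <- 0
    for (v in rev(order_)) {
      if (v == s) next
      preds <- nbrs[[v]][!is.na(dist[nbrs[[v]]]) & dist[nbrs[[v]]] == dist[v] - 1L]
      share <- b[v] / length(preds)
      for (p in preds) {
        b[p] <- b[p] + share
        load[edge_key(nodes[p], nodes[v])] <-
          load[edge_key(nodes[p], nodes[v])] + share
      }
    }
  }
  load
}

burt_p_matrix <- function(A) {
  deg <- rowSums(A)
  P <- A / ifelse(deg == 0, 1, deg)
  P
}

#' Compute one structural metric on a co-occurrence network
#'
#' @param net a `cooccurrence_network`.
#' @param metric one of [METRICS16].
#' @param aggregate for edge-valued metrics: `"edge"` (default, one value
#'   per edge) or `"node_mean"` (mean over each node's incident edges,
#'   0 for isolated nodes).
#' @param closeness_variant `"normalized"` (default; Wasserman-Faust
#'   component-scaled, in `[0, 1]`) or `"distance_sum"` (the total
#'   shortest-path distance to reachable nodes — an unnormalized variant on
#'   the scale of large published values).
#' @param vitality_weighted treat co-occurrence weights as distances in
#'   `closeness_vitality` (default `FALSE`: proportions-as-distances invert
#'   the metric's meaning and can turn it negative).
#' @return data.frame of class `metric_distribution` with columns `element`
#'   (node id or `a|b` edge key) and `value`; attributes `metric`,
#'   `outcome`.
#' @export
compute_metric <- function(net, metric, aggregate = c("edge", "node_mean"),
                           closeness_variant = c("normalized",
                                                 "distance_sum"),
                           vitality_weighted = FALSE) {
  stopifnot(inherits(net, "cooccurrence_network"))
  if (!metric %in% METRICS16) stop("unknown metric name: ", metric)
  aggregate <- match.arg(aggregate)
  closeness_variant <- match.arg(closeness_variant)
  g <- as_igraph(net)
  A <- adjacency_of(net)
  n <- length(net$nodes)
  deg <- rowSums(A)
  ekeys <- edge_key(net$edges$from, net$edges$to)

  node_result <- function(values) {
    structure(data.frame(element = net$nodes, value = unname(values),
                         stringsAsFactors = FALSE),
              metric = metric, outcome = net$outcome,
              class = c("metric_distribution", "data.frame"))
  }
  edge_result <- function(values) {
    if (aggregate == "node_mean") {
      v <- vapply(net$nodes, function(nd) {
        inc <- net$edges$from == nd | net$edges$to == nd
        if (!any(inc)) 0 else mean(values[inc])
      }, numeric(1))
      return(node_result(v))
    }
    structure(data.frame(element = ekeys, value = unname(values),
                         stringsAsFactors = FALSE),
              metric = metric, outcome = net$outcome,
              class = c("metric_distribution", "data.frame"))
  }

  switch(metric,
    average_neighbor_degree = {
      s <- as.vector(A %*% deg)
      node_result(ifelse(deg == 0, 0, s / deg))
    },
    degree_centrality = node_result(if (n > 1) deg / (n - 1) else deg * 0),
    closeness_centrality = {
      d <- igraph::distances(g, weights = NA)
      vals <- vapply(seq_len(n), function(i) {
        fin <- is.finite(d[i, ]) & seq_len(n) != i
        r <- sum(fin)
        if (r == 0) return(0)
        sd_ <- sum(d[i, fin])
        if (closeness_variant == "distance_sum") sd_
        else (r / (n - 1)) * (r / sd_)
      }, numeric(1))
      node_result(vals)
    },
    betweenness_centrality = {
      b <- igraph::betweenness(g, directed = FALSE, weights = NA,
                               normalized = n > 2)
      node_result(b[net$nodes])
    },
    edge_betweenness_centrality = {
      if (nrow(net$edges) == 0) return(edge_result(numeric(0)))
      eb <- igraph::edge_betweenness(g, directed = FALSE, weights = NA)
      # match the conventional pair normalization 2 / (n (n - 1))
      edge_result(eb * 2 / (n * (n - 1)))
    },
    number_of_cliques = {
      cl <- igraph::max_cliques(g, min = 1)
      cnt <- stats::setNames(numeric(n), net$nodes)
      for (c_ in cl) {
        nm <- igraph::V(g)$name[as.integer(c_)]
        cnt[nm] <- cnt[nm] + 1
      }
      node_result(cnt)
    },
    node_clique_number = {
      cl <- igraph::max_cliques(g, min = 1)
      best <- stats::setNames(numeric(n), net$nodes)
      for (c_ in cl) {
        nm <- igraph::V(g)$name[as.integer(c_)]
        best[nm] <- pmax(best[nm], length(c_))
      }
      node_result(best)
    },
    triangles = {
      tr <- igraph::count_triangles(g)
      node_result(stats::setNames(tr, igraph::V(g)$name)[net$nodes])
    },
    clustering = {
      cc <- igraph::transitivity(g, type = "localundirected",
                                 isolates = "zero")
      node_result(stats::setNames(cc, igraph::V(g)$name)[net$nodes])
    },
    all_pairs_node_connectivity = {
      if (n < 2) return(node_result(rep(0, n)))
      K <- matrix(0, n, n)
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          k <- local_node_connectivity(g, net$nodes[i], net$nodes[j])
          K[i, j] <- k; K[j, i] <- k
        }
      }
      node_result(rowSums(K) / (n - 1))
    },
    closeness_vitality = {
      # Wiener-index loss on node removal, unweighted skeleton by default:
      # co-occurrence weights are proportions, and using them as distances
      # makes removals *shorten* the index (negative vitality), which the
      # non-negative BEST comparison cannot accept; unreachable pairs are
      # excluded from the sums
      w_all <- wiener_index(g, weighted = vitality_weighted)
      vals <- vapply(net$nodes, function(nd) {
        w_all - wiener_index(igraph::delete_vertices(g, nd),
                             weighted = vitality_weighted)
      }, numeric(1))
      node_result(vals)
    },
    square_clustering = {
      node_result(vapply(seq_len(n), function(v) square_clustering_one(A, v),
                         numeric(1)))
    },
    edge_load = edge_result(unname(edge_load_values(net)[ekeys])),
    effective_size = {
      P <- burt_p_matrix(A)
      vals <- vapply(seq_len(n), function(i) {
        nb <- which(A[i, ] == 1L)
        if (length(nb) == 0) return(0)
        # Burt redundancy: 1 - sum_q p_iq m_jq, m normalized to j's max tie
        sum(vapply(nb, function(j) {
          m_j <- A[j, ] / max(A[j, ])
          1 - sum(P[i, ] * m_j * (seq_len(n) != i) * (seq_len(n) != j))
        }, numeric(1)))
      }, numeric(1))
      node_result(vals)
    },
    constraint = {
      P <- burt_p_matrix(A)
      vals <- vapply(seq_len(n), function(i) {
        nb <- which(A[i, ] == 1L)
        if (length(nb) == 0) return(0)
        sum(vapply(nb, function(j) {
          ind <- sum(P[i, ] * P[, j] * (seq_len(n) != i) * (seq_len(n) != j))
          (P[i, j] + ind)^2
        }, numeric(1)))
      }, numeric(1))
      node_result(vals)
    },
    edge_weight = edge_result(net$edges$weight)
  )
}

#' Compute all sixteen metrics for one network
#'
#' @param net a `cooccurrence_network`.
#' @param ... passed to [compute_metric()].
#' @return Named list of `metric_distribution` data.frames.
#' @export
compute_all_metrics <- function(net, ...) {
  stats::setNames(lapply(METRICS16, function(m) compute_metric(net, m, ...)),
                  METRICS16)
}

#' Write metric distributions as long-format CSV
#'
#' @param metrics named list (per outcome) of [compute_all_metrics()]
#'   results, e.g. `list(IMPV = ..., MC = ...)`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_distributions <- function(metrics, path) {
  rows <- list()
  for (outc in names(metrics)) {
    for (m in names(metrics[[outc]])) {
      md <- metrics[[outc]][[m]]
      rows[[length(rows) + 1L]] <- data.frame(
        network = outc, metric = m, element = md$element, value = md$value,
        stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
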