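# Brute-force graph oracles, independent of igraph and of the package's
# metric code: Floyd-Warshall distances, exhaustive subset enumeration for
# cliques and vertex cuts, explicit shortest-path enumeration for the
# betweenness family. Intended for graphs of <= 8 nodes.

o_graph <- function(A, weights = NULL) {
  stopifnot(isSymmetric(unname(A)), all(diag(A) == 0))
  list(A = A, n = nrow(A), names = rownames(A), weights = weights)
}

# random small network in the package's container plus the oracle's view
random_small_net <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("n%d", seq_len(n))
  A <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p) A[i, j] <- A[j, i] <- 1L
  }
  idx <- which(upper.tri(A) & A == 1L, arr.ind = TRUE)
  w <- round(runif(nrow(idx), 0.05, 0.95), 3)
  net <- structure(list(outcome = "IMPV", nodes = nodes,
                        edges = data.frame(from = nodes[idx[, 1]],
                                           to = nodes[idx[, 2]],
                                           count = rep(1L, nrow(idx)),
                                           weight = w,
                                           stringsAsFactors = FALSE),
                        group_size = 1L),
                   class = "cooccurrence_network")
  list(net = net, A = A)
}

o_dist <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  d[A == 1L] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# all shortest paths between s and t as lists of node indices
o_shortest_paths <- function(A, d, s, t) {
  if (!is.finite(d[s, t])) return(list())
  if (s == t) return(list(s))
  grow <- function(path) {
    v <- path[length(path)]
    if (v == t) return(list(path))
    nxt <- which(A[v, ] == 1L & d[, t] == d[v, t] - 1)
    unlist(lapply(nxt, function(w) grow(c(path, w))), recursive = FALSE)
  }
  grow(s)
}

o_avg_neighbor_degree <- function(A) {
  deg <- rowSums(A)
  vapply(seq_len(nrow(A)), function(v) {
    nb <- which(A[v, ] == 1L)
    if (!length(nb)) 0 else mean(deg[nb])
  }, numeric(1))
}

o_degree_centrality <- function(A) rowSums(A) / (nrow(A) - 1)

o_closeness <- function(A, variant = "normalized") {
  d <- o_dist(A)
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    dv <- d[v, -v]
    fin <- is.finite(dv)
    r <- sum(fin)
    if (r == 0) return(0)
    if (variant == "distance_sum") sum(dv[fin])
    else (r / (n - 1)) * (r / sum(dv[fin]))
  }, numeric(1))
}

o_betweenness <- function(A) {
  n <- nrow(A)
  d <- o_dist(A)
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- o_shortest_paths(A, d, s, t)
    if (!length(paths)) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      through <- sum(vapply(paths, function(p) v %in% p, logical(1)))
      b[v] <- b[v] + through / length(paths)
    }
  }
  if (n > 2) b / ((n - 1) * (n - 2) / 2) else b
}

o_edge_betweenness <- function(A, edges) {
  n <- nrow(A)
  d <- o_dist(A)
  eb <- numeric(nrow(edges))
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- o_shortest_paths(A, d, s, t)
    if (!length(paths)) next
    for (e in seq_len(nrow(edges))) {
      i <- match(edges$from[e], rownames(A))
      j <- match(edges$to[e], rownames(A))
      uses <- sum(vapply(paths, function(p) {
        any(p[-length(p)] == i & p[-1] == j) ||
          any(p[-length(p)] == j & p[-1] == i)
      }, logical(1)))
      eb[e] <- eb[e] + uses / length(paths)
    }
  }
  eb * 2 / (n * (n - 1))
}

o_maximal_cliques <- function(A) {
  n <- nrow(A)
  subsets <- lapply(seq_len(2^n - 1), function(m) which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0))
  is_clique <- vapply(subsets, function(s) {
    if (length(s) < 2) return(TRUE)
    all(A[s, s][upper.tri(A[s, s])] == 1L)
  }, logical(1))
  cl <- subsets[is_clique]
  keep <- vapply(seq_along(cl), function(i) {
    !any(vapply(seq_along(cl), function(j) {
      j != i && length(cl[[i]]) < length(cl[[j]]) && all(cl[[i]] %in% cl[[j]])
    }, logical(1)))
  }, logical(1))
  cl[keep]
}

o_number_of_cliques <- function(A) {
  cl <- o_maximal_cliques(A)
  vapply(seq_len(nrow(A)), function(v)
    sum(vapply(cl, function(s) v %in% s, logical(1))), numeric(1))
}

o_node_clique_number <- function(A) {
  cl <- o_maximal_cliques(A)
  vapply(seq_len(nrow(A)), function(v) {
    sizes <- lengths(cl)[vapply(cl, function(s) v %in% s, logical(1))]
    if (!length(sizes)) 0 else max(sizes)
  }, numeric(1))
}

o_triangles <- function(A) {
  n <- nrow(A)
  t <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1L)
    if (length(nb) >= 2) {
      t[i] <- sum(A[nb, nb][upper.tri(A[nb, nb])])
    }
  }
  t
}

o_clustering <- function(A) {
  deg <- rowSums(A)
  tr <- o_triangles(A)
  ifelse(deg < 2, 0, tr / (deg * (deg - 1) / 2))
}

o_reachable <- function(A, s, excluded) {
  n <- nrow(A)
  seen <- rep(FALSE, n)
  seen[excluded] <- NA  # marked unusable
  stack <- s
  seen[s] <- TRUE
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    for (w in which(A[v, ] == 1L)) {
      if (!is.na(seen[w]) && !seen[w]) {
        seen[w] <- TRUE
        stack <- c(stack, w)
      }
    }
  }
  which(!is.na(seen) & seen)
}

# minimum vertex cut separating non-adjacent s, t by subset enumeration
o_min_vertex_cut <- function(A, s, t) {
  n <- nrow(A)
  others <- setdiff(seq_len(n), c(s, t))
  for (size in 0:length(others)) {
    subs <- if (size == 0) list(integer(0)) else
      utils::combn(others, size, simplify = FALSE)
    for (S in subs) {
      if (!(t %in% o_reachable(A, s, S))) return(size)
    }
  }
  length(others)
}

o_local_connectivity <- function(A, s, t) {
  if (A[s, t] == 1L) {
    A2 <- A
    A2[s, t] <- A2[t, s] <- 0L
    1 + o_min_vertex_cut(A2, s, t)
  } else {
    o_min_vertex_cut(A, s, t)
  }
}

o_apnc <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    mean(vapply(setdiff(seq_len(n), v), function(u)
      o_local_connectivity(A, v, u), numeric(1)))
  }, numeric(1))
}

o_wiener <- function(A) {
  d <- o_dist(A)
  ut <- d[upper.tri(d)]
  sum(ut[is.finite(ut)])
}

o_closeness_vitality <- function(A) {
  w <- o_wiener(A)
  vapply(seq_len(nrow(A)), function(v)
    w - o_wiener(A[-v, -v, drop = FALSE]), numeric(1))
}

o_square_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] == 1L)
    if (length(nb) < 2) return(0)
    num <- 0; den <- 0
    pairs <- utils::combn(nb, 2, simplify = FALSE)
    for (p in pairs) {
      u <- p[1]; w <- p[2]
      q <- length(setdiff(which(A[u, ] == 1L & A[w, ] == 1L), v))
      theta <- A[u, w]
      a <- (sum(A[u, ]) - (1 + q + theta)) + (sum(A[w, ]) - (1 + q + theta))
      num <- num + q
      den <- den + q + a
    }
    if (den == 0) 0 else num / den
  }, numeric(1))
}

# per-target recursive flow splitting; summed over all (source, target)
# ordered pairs this equals the cumulative load accumulation
o_edge_load <- function(A, edges) {
  n <- nrow(A)
  d <- o_dist(A)
  key <- function(i, j) paste(sort(c(i, j)), collapse = "-")
  load <- stats::setNames(
    numeric(nrow(edges)),
    vapply(seq_len(nrow(edges)), function(e)
      key(match(edges$from[e], rownames(A)),
          match(edges$to[e], rownames(A))), character(1)))
  push <- function(s, v, amount) {
    if (v == s) return()
    preds <- which(A[v, ] == 1L & d[s, ] == d[s, v] - 1)
    share <- amount / length(preds)
    for (p in preds) {
      load[key(p, v)] <<- load[key(p, v)] + share
      push(s, p, share)
    }
  }
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (t != s && is.finite(d[s, t])) push(s, t, 1)
  }
  load
}

o_effective_size <- function(A) {
  vapply(seq_len(nrow(A)), function(v) {
    nb <- which(A[v, ] == 1L)
    k <- length(nb)
    if (k == 0) return(0)
    ties <- sum(A[nb, nb][upper.tri(A[nb, nb, drop = FALSE])])
    k - 2 * ties / k
  }, numeric(1))
}

o_constraint <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  p <- function(i, j) if (deg[i] == 0) 0 else A[i, j] / deg[i]
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1L)
    if (!length(nb)) return(0)
    sum(vapply(nb, function(j) {
      ind <- sum(vapply(setdiff(seq_len(n), c(i, j)), function(q)
        p(i, q) * p(q, j), numeric(1)))
      (p(i, j) + ind)^2
    }, numeric(1)))
  }, numeric(1))
}

# oracle dispatch returning values aligned with compute_metric output order
oracle_metric <- function(metric, A, net) {
  switch(metric,
    average_neighbor_degree = o_avg_neighbor_degree(A),
    degree_centrality = o_degree_centrality(A),
    closeness_centrality = o_closeness(A),
    betweenness_centrality = o_betweenness(A),
    edge_betweenness_centrality = o_edge_betweenness(A, net$edges),
    number_of_cliques = o_number_of_cliques(A),
    node_clique_number = o_node_clique_number(A),
    triangles = o_triangles(A),
    clustering = o_clustering(A),
    all_pairs_node_connectivity = o_apnc(A),
    closeness_vitality = o_closeness_vitality(A),
    square_clustering = o_square_clustering(A),
    edge_load = unname(o_edge_load(A, net$edges)),
    effective_size = o_effective_size(A),
    constraint = o_constraint(A),
    edge_weight = net$edges$weight)
}
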