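# Network construction and the sixteen structural metrics.

# wrap an explicit edge list as a network container
net_from_edges <- function(nodes, from, to, weight = NULL) {
  w <- if (is.null(weight)) rep(1, length(from)) else weight
  structure(list(outcome = "IMPV", nodes = nodes,
                 edges = data.frame(from = from, to = to,
                                    count = rep(1L, length(from)),
                                    weight = w, stringsAsFactors = FALSE),
                 group_size = 1L),
            class = "cooccurrence_network")
}

metric_values <- function(net, m, ...) compute_metric(net, m, ...)$value

test_that("shared characteristics require expression in both groups", {
  catalog <- characteristic_catalog(c("A", "B", "C"),
                                    source = rep("child", 3))
  sets <- list(c("A", "B"), "A",      # IMPV
               c("A", "C"), "C")      # MC: B absent, C absent in IMPV
  coh <- fixture_cohort(sets, groups = c("IMPV", "IMPV", "MC", "MC"),
                        catalog = catalog)
  expect_equal(shared_characteristics(coh), "A")
})

test_that("edge weights are within-group co-occurrence proportions", {
  catalog <- characteristic_catalog(c("A", "B", "C"),
                                    source = rep("child", 3))
  sets <- list(c("A", "B"), c("A", "B", "C"), c("A", "C"), "B",  # IMPV n=4
               c("A", "B"), "C")                                  # MC n=2
  coh <- fixture_cohort(sets, groups = c(rep("IMPV", 4), rep("MC", 2)),
                        catalog = catalog)
  net <- build_network(coh, "IMPV", shared = c("A", "B", "C"))
  expect_equal(net$group_size, 4)
  key <- paste(net$edges$from, net$edges$to)
  w <- setNames(net$edges$weight, key)
  expect_equal(unname(w["A B"]), 0.5)
  expect_equal(unname(w["A C"]), 0.5)
  expect_equal(unname(w["B C"]), 0.25)
  # a child with a single characteristic contributes no edge: B's marginal
  # is 3/4 but no (B, *) weight reaches it
  expect_true(all(net$edges$weight <= 0.5))
  # edge_weight metric returns exactly the build weights
  expect_equal(metric_values(net, "edge_weight"), net$edges$weight)
})

test_that("closed forms hold on K5, P3 and the star K1,4", {
  k5 <- net_from_edges(LETTERS[1:5],
                       from = c("A","A","A","A","B","B","B","C","C","D"),
                       to   = c("B","C","D","E","C","D","E","D","E","E"))
  expect_equal(metric_values(k5, "triangles"), rep(choose(4, 2), 5))
  expect_equal(metric_values(k5, "clustering"), rep(1, 5))
  expect_equal(metric_values(k5, "degree_centrality"), rep(1, 5))
  expect_equal(metric_values(k5, "number_of_cliques"), rep(1, 5))
  expect_equal(metric_values(k5, "node_clique_number"), rep(5, 5))

  p3 <- net_from_edges(c("A", "B", "C"), from = c("A", "B"),
                       to = c("B", "C"))
  v <- setNames(metric_values(p3, "degree_centrality"), p3$nodes)
  expect_equal(unname(v["B"]), 1)
  expect_equal(metric_values(p3, "clustering"), rep(0, 3))
  expect_equal(metric_values(p3, "triangles"), rep(0, 3))
  expect_equal(setNames(metric_values(p3, "betweenness_centrality"),
                        p3$nodes)[["B"]], 1)

  star <- net_from_edges(c("hub", paste0("s", 1:4)),
                         from = rep("hub", 4), to = paste0("s", 1:4))
  ncn <- setNames(metric_values(star, "node_clique_number"), star$nodes)
  ncl <- setNames(metric_values(star, "number_of_cliques"), star$nodes)
  expect_equal(unname(ncn["hub"]), 2)
  expect_equal(unname(ncl["hub"]), 4)
  expect_equal(unname(ncl["s1"]), 1)
})

test_that("all sixteen metrics match the brute-force oracle (spot sample)", {
  # broader 50-graph sweep runs in the acceptance suite
  cases <- list(c(5, 0.5, 1), c(6, 0.4, 2), c(7, 0.7, 3),
                c(8, 0.3, 4),   # sparse: usually disconnected
                c(6, 0.15, 5),  # very sparse with isolated nodes
                c(8, 0.9, 6))   # dense
  for (cs in cases) {
    r <- random_small_net(cs[1], cs[2], seed = 100 + cs[3])
    for (m in METRICS16) {
      got <- compute_metric(r$net, m)$value
      want <- oracle_metric(m, r$A, r$net)
      expect_equal(got, unname(want), tolerance = 1e-9,
                   label = sprintf("%s on graph %d", m, cs[3]))
    }
  }
})

test_that("metric distributions are invariant under node relabeling", {
  r <- random_small_net(7, 0.5, seed = 321)
  relab <- setNames(sprintf("z%d", 7:1), r$net$nodes)
  net2 <- r$net
  net2$nodes <- unname(relab[r$net$nodes])
  net2$edges$from <- unname(relab[r$net$edges$from])
  net2$edges$to <- unname(relab[r$net$edges$to])
  for (m in setdiff(METRICS16, EDGE_METRICS <- c("edge_betweenness_centrality",
                                                 "edge_load", "edge_weight"))) {
    v1 <- setNames(compute_metric(r$net, m)$value, relab[r$net$nodes])
    v2 <- setNames(compute_metric(net2, m)$value, net2$nodes)
    expect_equal(v2[names(v1)], v1, tolerance = 1e-9, label = m)
  }
})

test_that("triangle totals are divisible by three", {
  for (s in 1:5) {
    r <- random_small_net(8, 0.45, seed = 500 + s)
    expect_equal(sum(metric_values(r$net, "triangles")) %% 3, 0)
  }
})

test_that("edge metrics can be aggregated to per-node incident means", {
  r <- random_small_net(6, 0.6, seed = 77)
  per_edge <- compute_metric(r$net, "edge_weight")
  per_node <- compute_metric(r$net, "edge_weight", aggregate = "node_mean")
  expect_equal(nrow(per_edge), nrow(r$net$edges))
  expect_equal(nrow(per_node), length(r$net$nodes))
  nd <- r$net$nodes[1]
  inc <- r$net$edges$from == nd | r$net$edges$to == nd
  expect_equal(per_node$value[1], mean(r$net$edges$weight[inc]))
})

test_that("closeness variants and weighted vitality are available", {
  r <- random_small_net(6, 0.6, seed = 88)
  norm <- metric_values(r$net, "closeness_centrality")
  expect_true(all(norm >= 0 & norm <= 1))
  dsum <- metric_values(r$net, "closeness_centrality",
                        closeness_variant = "distance_sum")
  expect_equal(dsum, o_closeness(r$A, "distance_sum"))
  wv <- metric_values(r$net, "closeness_vitality", vitality_weighted = TRUE)
  expect_equal(length(wv), 6)
  expect_error(compute_metric(r$net, "not_a_metric"), "unknown metric")
})

test_that("network exports round-trip through TSV and GraphML", {
  g <- generate_cohort(small_scenario(seed = 12L))
  coh <- g$cohort
  net <- build_network(coh, "MC")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, graphml_path = gml, tsv_path = tsv)
  back <- read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(back$weight, net$edges$weight)
  gg <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(gg), length(net$nodes))
  expect_equal(igraph::gsize(gg), nrow(net$edges))
})
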