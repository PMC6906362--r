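# Per-outcome co-occurrence networks.
#
# Nodes are the characteristics expressed in BOTH outcome groups (a
# characteristic seen in only one group is treated as infrequent rather than
# group-exclusive, and would bias the comparison); an edge joins two
# characteristics that co-occur within at least one child of the group, and
# carries the proportion of the group's children expressing both.

#' Characteristics expressed in both outcome groups
#'
#' @param x a labeled `cohort` with both groups nonempty.
#' @return Character vector of catalog ids (catalog order preserved)
#'   expressed by at least one child in IMPV and at least one in MC.
#' @export
shared_characteristics <- function(x) {
  stopifnot(inherits(x, "cohort"))
  if (is.null(x$outcome)) pc_error("pc_unlabeled_error", "cohort is unlabeled")
  impv <- x$characteristics[group_ids(x, "IMPV"), , drop = FALSE]
  mc <- x$characteristics[group_ids(x, "MC"), , drop = FALSE]
  if (nrow(impv) == 0L || nrow(mc) == 0L) {
    pc_error("pc_validation_error", "both outcome groups must be nonempty")
  }
  x$catalog$id[colSums(impv) > 0 & colSums(mc) > 0]
}

#' Build one outcome group's co-occurrence network
#'
#' @param x a labeled `cohort`.
#' @param outcome `"IMPV"` or `"MC"`.
#' @param shared node set, normally [shared_characteristics()] output.
#' @return Object of class `cooccurrence_network`: `outcome`, `nodes`,
#'   `edges` (data.frame `from`, `to`, `count`, `weight` with
#'   `weight = count / group_size`), `group_size`. Isolated nodes are
#'   retained.
#' @export
build_network <- function(x, outcome, shared = shared_characteristics(x)) {
  stopifnot(inherits(x, "cohort"), length(shared) > 0)
  outcome <- match.arg(outcome, c("IMPV", "MC"))
  X <- x$characteristics[group_ids(x, outcome), shared, drop = FALSE]
  gsz <- nrow(X)
  co <- crossprod(X)  # co-occurrence counts, diagonal = marginal counts
  idx <- which(upper.tri(co) & co > 0, arr.ind = TRUE)
  edges <- data.frame(from = shared[idx[, 1]], to = shared[idx[, 2]],
                      count = co[idx], weight = co[idx] / gsz,
                      stringsAsFactors = FALSE)
  structure(list(outcome = outcome, nodes = shared, edges = edges,
                 group_size = gsz),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("%s co-occurrence network: %d nodes, %d edges (group n = %d)\n",
              x$outcome, length(x$nodes), nrow(x$edges), x$group_size))
  invisible(x)
}

#' Convert a co-occurrence network to igraph
#'
#' @param net a `cooccurrence_network`.
#' @return Undirected igraph graph with a `weight` edge attribute and all
#'   (including isolated) nodes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  igraph::graph_from_data_frame(net$edges[c("from", "to", "weight")],
                                directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Export a network as GraphML and/or weighted edge-list TSV
#'
#' @param net a `cooccurrence_network`.
#' @param graphml_path destination GraphML path (`NULL` to skip).
#' @param tsv_path destination TSV path (`NULL` to skip).
#' @return `net`, invisibly.
#' @export
export_network <- function(net, graphml_path = NULL, tsv_path = NULL) {
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(net), graphml_path, format = "graphml")
  }
  if (!is.null(tsv_path)) {
    utils::write.table(net$edges, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(net)
}
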