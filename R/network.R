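#' Contact networks
#'
#' A contact network is an undirected simple graph on `N` labelled nodes:
#' hosts are nodes, edges are potential transmission routes. Networks are
#' represented as [igraph][igraph::igraph-package] graphs whose vertices
#' carry a permanent integer label in the vertex attribute `name`, so that
#' subgraphs (e.g. the largest connected component) retain the original
#' node ids.
#'
#' @param n_nodes number of nodes.
#' @param edges optional two-column integer matrix of edges (node labels).
#' @return an undirected simple igraph graph with integer `name` labels.
#' @export
contact_network <- function(n_nodes, edges = NULL) {
  stopifnot(n_nodes >= 0)
  g <- igraph::make_empty_graph(n = n_nodes, directed = FALSE)
  igraph::V(g)$name <- as.character(seq_len(n_nodes))
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.matrix(edges)
    g <- igraph::add_edges(g, as.character(t(edges)))
  }
  validate_network(g)
  g
}

#' Validate the simple-graph invariants of a contact network
#'
#' Checks that the graph is undirected, has no self-loops, no duplicated
#' edges, and carries node labels.
#'
#' @param net a contact network.
#' @return `net`, invisibly; errors if an invariant fails.
#' @export
validate_network <- function(net) {
  if (igraph::is_directed(net))
    stop("contact network must be undirected")
  if (igraph::any_loop(net))
    stop("contact network must not contain self-loops")
  if (igraph::any_multiple(net))
    stop("contact network must not contain duplicate edges")
  if (is.null(igraph::V(net)$name))
    stop("contact network must carry node labels in V(net)$name")
  invisible(net)
}

#' Node labels of a contact network
#'
#' @param net a contact network.
#' @return integer vector of node ids.
#' @export
node_ids <- function(net) as.integer(igraph::V(net)$name)

#' Sample a Bernoulli (Erdos-Renyi) random network
#'
#' Each of the `N(N-1)/2` possible edges is present independently with
#' probability `p`. Sampling draws the edge count
#' `|Y| ~ Binomial(N(N-1)/2, p)` and then `|Y|` distinct unordered pairs
#' uniformly at random.
#'
#' @param n_nodes number of nodes `N` (at least 2). The study's Bernoulli
#'   arm uses `N = 500`.
#' @param edge_prob edge probability `p` in `[0, 1]`; the study uses
#'   `p = 7/N = 0.014`.
#' @return a contact network.
#' @examples
#' set.seed(1)
#' g <- sample_bernoulli(500, 0.014)
#' igraph::ecount(g)
#' @export
sample_bernoulli <- function(n_nodes, edge_prob) {
  if (!is.numeric(edge_prob) || length(edge_prob) != 1 ||
      is.na(edge_prob) || edge_prob < 0 || edge_prob > 1)
    stop("edge_prob must be a probability in [0, 1]")
  if (n_nodes < 2)
    stop("n_nodes must be at least 2")
  m <- stats::rbinom(1L, n_nodes * (n_nodes - 1L) / 2L, edge_prob)
  g <- igraph::sample_gnm(n_nodes, m, directed = FALSE)
  igraph::V(g)$name <- as.character(seq_len(n_nodes))
  g
}

#' Sample node degrees from a truncated power law
#'
#' Degrees are i.i.d. with `P(d = k)` proportional to `k^-alpha` on
#' `k = 1, ..., max_degree`. Support starts at 1 (an isolated node can
#' never join the giant component) and is truncated at `max_degree`
#' because `alpha < 2` gives a divergent mean otherwise; the default
#' cutoff `n_nodes - 1` is the largest degree a simple graph admits.
#' If the sampled degree total is odd (stub pairing needs an even total),
#' one node is chosen uniformly and its degree redrawn until the total
#' is even.
#'
#' @param n_nodes number of degrees to draw. The study's power-law arm
#'   uses `N = 600`.
#' @param exponent power-law exponent `alpha > 0`; the study uses 1.8.
#' @param max_degree largest admissible degree (default `n_nodes - 1`).
#' @return integer vector of degrees with an even sum.
#' @export
sample_power_law_degrees <- function(n_nodes, exponent,
                                     max_degree = n_nodes - 1L) {
  if (!is.numeric(exponent) || exponent <= 0)
    stop("exponent must be positive")
  if (max_degree < 1 || max_degree > n_nodes - 1L)
    stop("max_degree must lie in [1, n_nodes - 1]")
  k <- seq_len(max_degree)
  w <- k^(-exponent)
  d <- sample.int(max_degree, n_nodes, replace = TRUE, prob = w)
  while (sum(d) %% 2L == 1L) {
    i <- sample.int(n_nodes, 1L)
    d[i] <- sample.int(max_degree, 1L, prob = w)
  }
  as.integer(d)
}

#' Assemble a configuration-model (Reed-Molloy) graph from a degree list
#'
#' Each node `i` receives `degrees[i]` edge stubs; pairs of stubs are
#' joined uniformly at random without replacement. Self-loops are then
#' removed and multiple edges collapsed, so the realised degree of a node
#' never exceeds its requested degree and the result is only an
#' approximation to the requested degree sequence.
#'
#' @param degrees integer degree per node; the sum must be even.
#' @return a simple contact network on `length(degrees)` nodes.
#' @export
assemble_configuration_model <- function(degrees) {
  degrees <- as.integer(degrees)
  if (any(degrees < 0)) stop("degrees must be non-negative")
  if (sum(degrees) %% 2L != 0L) stop("sum of degrees must be even")
  g <- igraph::sample_degseq(degrees, method = "configuration")
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  igraph::V(g)$name <- as.character(seq_along(degrees))
  g
}

#' Sample an approximate power-law network
#'
#' Convenience wrapper: draws degrees with [sample_power_law_degrees()] and
#' assembles the graph with [assemble_configuration_model()].
#'
#' @inheritParams sample_power_law_degrees
#' @return a contact network.
#' @export
sample_power_law <- function(n_nodes, exponent,
                             max_degree = n_nodes - 1L) {
  assemble_configuration_model(
    sample_power_law_degrees(n_nodes, exponent, max_degree))
}

#' Largest connected component of a network
#'
#' Returns the node-induced subgraph on the largest connected component,
#' with original node labels retained. Ties in component size are broken
#' by the component containing the smallest node id.
#'
#' @param net a contact network.
#' @return a contact network (possibly `net` itself, possibly empty).
#' @export
largest_component <- function(net) {
  if (igraph::vcount(net) == 0) return(net)
  comp <- igraph::components(net)
  biggest <- which(comp$csize == max(comp$csize))
  if (length(biggest) > 1) {
    ids <- node_ids(net)
    min_id <- vapply(biggest, function(m) min(ids[comp$membership == m]),
                     numeric(1))
    biggest <- biggest[which.min(min_id)]
  }
  igraph::induced_subgraph(net, which(comp$membership == biggest))
}

#' Local clustering coefficient of one node
#'
#' For a node `i` with degree `d_i > 1` and `n_i` edges among its
#' neighbours, `C_i = 2 n_i / (d_i (d_i - 1))`, the fraction of possible
#' neighbour pairs that are connected. For `d_i <= 1`, `C_i = 0` by
#' convention.
#'
#' @param net a contact network.
#' @param node a node id (label).
#' @return a coefficient in `[0, 1]`.
#' @export
local_clustering <- function(net, node) {
  v <- match(as.character(node), igraph::V(net)$name)
  if (is.na(v)) stop("unknown node id: ", node)
  ci <- igraph::transitivity(net, type = "local", vids = v,
                             isolates = "zero")
  as.numeric(ci)
}

#' Global clustering coefficient of a network
#'
#' The arithmetic mean of the local clustering coefficients over all `N`
#' nodes, counting nodes of degree 0 or 1 as 0. An empty network returns
#' 0 by convention.
#'
#' @param net a contact network.
#' @return a coefficient in `[0, 1]`.
#' @export
global_clustering <- function(net) {
  if (igraph::vcount(net) == 0) return(0)
  igraph::transitivity(net, type = "localaverage", isolates = "zero")
}

#' Degree histogram of a network
#'
#' @param net a contact network.
#' @return integer vector whose entry for degree `k` (names `"0"`,
#'   `"1"`, ...) counts the nodes of that degree, up to the maximum degree.
#' @export
degree_histogram <- function(net) {
  d <- igraph::degree(net)
  h <- tabulate(d + 1L, nbins = max(d, 0L) + 1L)
  names(h) <- as.character(seq_along(h) - 1L)
  h
}

#' Read or write a network as a plain-text edge list
#'
#' The edge-list format is two tab-separated integer columns, one edge per
#' line, no header, each undirected edge written once with the smaller id
#' first. Isolated nodes are not representable; `n_nodes` may be given on
#' read to pad them back.
#'
#' @param net a contact network.
#' @param file path.
#' @param n_nodes total node count on read (default: largest id seen).
#' @return `write_edgelist` returns `file` invisibly; `read_edgelist`
#'   returns a contact network.
#' @export
write_edgelist <- function(net, file) {
  el <- igraph::as_edgelist(net, names = TRUE)
  storage.mode(el) <- "integer"
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  utils::write.table(el[order(el[, 1], el[, 2]), , drop = FALSE], file,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(file, n_nodes = NULL) {
  el <- utils::read.table(file, header = FALSE,
                          colClasses = c("integer", "integer"))
  if (is.null(n_nodes)) n_nodes <- max(el)
  contact_network(n_nodes, as.matrix(el))
}

#' Read or write a network in GraphML format
#'
#' Thin wrappers over [igraph::write_graph()] / [igraph::read_graph()]
#' preserving node labels.
#'
#' @param net a contact network.
#' @param file path.
#' @return `write_graphml` returns `file` invisibly; `read_graphml`
#'   returns a contact network.
#' @export
write_graphml <- function(net, file) {
  igraph::write_graph(net, file, format = "graphml")
  invisible(file)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(file) {
  g <- igraph::read_graph(file, format = "graphml")
  g <- igraph::as_undirected(g, mode = "collapse")
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  validate_network(g)
  g
}
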