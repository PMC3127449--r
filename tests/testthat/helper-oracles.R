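# Independent brute-force oracles used to cross-check the implementation.
# All work from the raw adjacency matrix or raw event log, never through
# the code paths they verify.

adj_matrix <- function(net) {
  as.matrix(igraph::as_adjacency_matrix(net, names = FALSE))
}

# local clustering by explicit neighbour-pair enumeration
oracle_local_clustering <- function(net, v_idx) {
  A <- adj_matrix(net)
  nbr <- which(A[v_idx, ] == 1)
  d <- length(nbr)
  if (d <= 1) return(0)
  n_i <- 0
  for (a in seq_len(d - 1))
    for (b in (a + 1):d)
      n_i <- n_i + A[nbr[a], nbr[b]]
  2 * n_i / (d * (d - 1))
}

oracle_global_clustering <- function(net) {
  n <- igraph::vcount(net)
  mean(vapply(seq_len(n), function(v) oracle_local_clustering(net, v),
              numeric(1)))
}

# shared partners from adjacency-matrix row products
oracle_shared_partners <- function(net, i_idx, j_idx) {
  A <- adj_matrix(net)
  sum(A[i_idx, ] * A[j_idx, ])
}

# esp spectrum and gwesp by a direct double loop over edges
oracle_esp <- function(net) {
  el <- igraph::as_edgelist(net, names = FALSE)
  vapply(seq_len(nrow(el)),
         function(r) oracle_shared_partners(net, el[r, 1], el[r, 2]),
         numeric(1))
}

oracle_gwesp <- function(net, tau) {
  sp <- oracle_esp(net)
  sum(exp(tau) * (1 - (1 - exp(-tau))^sp))
}

# connected component containing each node, by hand-rolled BFS
oracle_component_of <- function(net, start_idx) {
  A <- adj_matrix(net)
  seen <- logical(nrow(A))
  queue <- start_idx
  seen[start_idx] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nxt <- which(A[v, ] == 1 & !seen)
    seen[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  which(seen)
}

oracle_largest_component_nodes <- function(net) {
  n <- igraph::vcount(net)
  remaining <- seq_len(n)
  best <- integer(0)
  while (length(remaining)) {
    comp <- oracle_component_of(net, remaining[1])
    if (length(comp) > length(best)) best <- comp
    remaining <- setdiff(remaining, comp)
  }
  best
}

# naive configuration-model draw: shuffle stubs, pair consecutively,
# drop loops, collapse multi-edges; returns realised mean degree
oracle_config_mean_degree <- function(degrees) {
  stubs <- sample(rep(seq_along(degrees), degrees))
  e <- matrix(stubs, ncol = 2, byrow = TRUE)
  e <- e[e[, 1] != e[, 2], , drop = FALSE]
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  2 * length(unique(key)) / length(degrees)
}

# infective descendants via the leaf-ancestor definition: the number of
# leaves having an internal node (t, u, v) as an ancestor. An individual's
# own leaf sits on the continuation of its timeline, below its own
# transmission nodes, and is not a descendant of itself, so it is excluded.
oracle_descendants <- function(tree) {
  inds <- tree$individual[tree$type != "leaf"]
  desc <- stats::setNames(integer(length(inds)), inds)
  leaves <- tree$node[tree$type == "leaf"]
  for (leaf in leaves) {
    infectors <- integer(0)
    node <- tree$parent[leaf]
    while (!is.na(node)) {
      if (tree$type[node] == "internal")
        infectors <- c(infectors, tree$infector[node])
      node <- tree$parent[node]
    }
    for (v in setdiff(unique(infectors), tree$individual[leaf]))
      desc[as.character(v)] <- desc[as.character(v)] + 1L
  }
  desc
}

# all valid double-edge swaps of a network, by exhaustive enumeration
oracle_enumerate_swaps <- function(net) {
  el <- igraph::as_edgelist(net, names = TRUE)
  storage.mode(el) <- "integer"
  m <- nrow(el)
  A <- adj_matrix(net)
  nm <- igraph::V(net)$name
  out <- list()
  for (i in seq_len(m - 1)) for (j in (i + 1):m) for (mode in 1:2) {
    a <- el[i, 1]; b <- el[i, 2]; c <- el[j, 1]; d <- el[j, 2]
    new1 <- if (mode == 1) c(a, d) else c(a, c)
    new2 <- if (mode == 1) c(c, b) else c(b, d)
    if (new1[1] == new1[2] || new2[1] == new2[2]) next
    if (all(sort(new1) == sort(new2))) next
    exists_after <- function(e) {
      same <- function(x, y) all(sort(x) == sort(y))
      if (same(e, el[i, ]) || same(e, el[j, ])) return(FALSE)
      A[match(as.character(e[1]), nm), match(as.character(e[2]), nm)] == 1
    }
    if (exists_after(new1) || exists_after(new2)) next
    out[[length(out) + 1]] <- list(edge_a = c(a, b), edge_b = c(c, d),
                                   new_a = new1, new_b = new2)
  }
  out
}

# canonical text form of a swap (unordered everywhere) for set comparison
swap_signature <- function(edge_a, edge_b, new_a, new_b) {
  pair <- function(e) paste(sort(e), collapse = "-")
  removed <- sort(c(pair(edge_a), pair(edge_b)))
  added <- sort(c(pair(new_a), pair(new_b)))
  paste(c(removed, added), collapse = "|")
}

# small fixed graphs
graph_k3 <- function() contact_network(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
graph_path3 <- function() contact_network(3, rbind(c(1, 2), c(2, 3)))
graph_k4_minus <- function() {
  # K4 with edge (3,4) removed: nodes 1 and 2 have degree 3
  contact_network(4, rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4)))
}
graph_k4 <- function() {
  contact_network(4, rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4),
                           c(3, 4)))
}
graph_k5 <- function() {
  e <- t(utils::combn(5, 2))
  contact_network(5, e)
}

random_net <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

# hand-traced two-host log: A(=1) exposed at 0, infects B(=2) at
# 1.3, A recovers at 3.1, B recovers at 4.0 (B onset at 2.0)
two_host_log <- function() {
  log <- data.frame(
    time = c(0, 0.5, 1.3, 2.0, 3.1, 4.0),
    kind = c("exposure", "onset", "exposure", "onset", "recovery",
             "recovery"),
    individual = c(1L, 1L, 2L, 2L, 1L, 2L),
    infector = c(NA, NA, 1L, NA, NA, NA))
  attr(log, "index_node") <- 1L
  class(log) <- c("event_log", "data.frame")
  log
}

single_host_log <- function() {
  log <- data.frame(
    time = c(0, 1, 3.1),
    kind = c("exposure", "onset", "recovery"),
    individual = c(7L, 7L, 7L),
    infector = c(NA_integer_, NA_integer_, NA_integer_))
  attr(log, "index_node") <- 7L
  class(log) <- c("event_log", "data.frame")
  log
}

# three-host chain: 1 infects 2, 2 infects 3, both transmissions before
# any recovery
chain3_log <- function() {
  log <- data.frame(
    time = c(0, 0.4, 1.0, 1.2, 2.0, 3.0, 3.5, 4.0, 5.0),
    kind = c("exposure", "onset", "exposure", "onset", "exposure",
             "recovery", "onset", "recovery", "recovery"),
    individual = c(1L, 1L, 2L, 2L, 3L, 1L, 3L, 2L, 3L),
    infector = c(NA, NA, 1L, NA, 2L, NA, NA, NA, NA))
  attr(log, "index_node") <- 1L
  class(log) <- c("event_log", "data.frame")
  log
}
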