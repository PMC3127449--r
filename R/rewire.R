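#' Edgewise shared partners of a node pair
#'
#' The number of nodes adjacent to both `i` and `j`, i.e.
#' `|N_i intersect N_j|`. When `(i, j)` is an edge, each shared partner
#' closes a triangle through that edge.
#'
#' @param net a contact network.
#' @param i,j distinct node ids.
#' @return integer count.
#' @export
shared_partners <- function(net, i, j) {
  if (identical(as.character(i), as.character(j)))
    stop("shared_partners requires two distinct nodes")
  vi <- match(as.character(i), igraph::V(net)$name)
  vj <- match(as.character(j), igraph::V(net)$name)
  if (is.na(vi) || is.na(vj)) stop("unknown node id")
  .sp_idx(net, vi, vj)
}

# shared partners by igraph vertex index
.sp_idx <- function(g, vi, vj) {
  length(intersect(as.integer(igraph::neighbors(g, vi)),
                   as.integer(igraph::neighbors(g, vj))))
}

#' Edgewise shared-partner histogram
#'
#' Entry `i + 1` (name `"0"`, `"1"`, ...) counts the edges whose endpoints
#' share exactly `i` partners. The entries sum to the edge count.
#'
#' @param net a contact network.
#' @return named integer vector `EP_0, EP_1, ...`.
#' @export
esp_histogram <- function(net) {
  el <- igraph::as_edgelist(net, names = FALSE)
  if (nrow(el) == 0) {
    h <- integer(1)
  } else {
    sp <- vapply(seq_len(nrow(el)),
                 function(r) .sp_idx(net, el[r, 1], el[r, 2]), integer(1))
    h <- tabulate(sp + 1L, nbins = max(sp) + 1L)
  }
  names(h) <- as.character(seq_along(h) - 1L)
  h
}

# gwesp weight of one edge with s shared partners
.gwesp_weight <- function(s, decay) {
  exp(decay) * (1 - (1 - exp(-decay))^s)
}

#' Geometrically weighted edgewise-shared-partner (gwesp) statistic
#'
#' The triangle-sensitive graph statistic
#' `u(Y; tau) = e^tau * sum_{i >= 1} (1 - (1 - e^-tau)^i) EP_i(Y)`,
#' where `EP_i` is the number of edges with exactly `i` shared partners.
#' Each edge contributes a weight that increases with its shared-partner
#' count but with geometrically diminishing returns governed by the decay
#' `tau`; a triangle-free graph scores 0. Used with a fixed decay as the
#' clustering-controlling term of an exponential random graph density.
#'
#' @param net a contact network.
#' @param decay decay parameter `tau >= 0` (the study fixes 0.2).
#' @return non-negative statistic value.
#' @export
gwesp_statistic <- function(net, decay) {
  stopifnot(decay >= 0)
  ep <- esp_histogram(net)
  s <- seq_along(ep) - 1L
  sum(ep * .gwesp_weight(s, decay))
}

#' Propose a degree-preserving double-edge swap
#'
#' Draws two distinct edges `(a, b)` and `(c, d)` uniformly at random and,
#' with probability 1/2 each, proposes replacing them by `(a, d), (c, b)`
#' or by `(a, c), (b, d)`. Either rewiring preserves every node's degree.
#' The proposal is marked invalid if it would create a self-loop or a
#' duplicate edge.
#'
#' @param net a contact network with at least 2 edges.
#' @return an object of class `swap_proposal` with fields `edge_a`,
#'   `edge_b` (the removed edges, as length-2 id vectors), `new_a`,
#'   `new_b` (the inserted edges), `mode` (1 or 2) and `valid`.
#' @export
propose_swap <- function(net) {
  m <- igraph::ecount(net)
  if (m < 2) stop("need at least 2 edges to propose a swap")
  el <- igraph::as_edgelist(net, names = TRUE)
  idx <- sample.int(m, 2L)
  e1 <- as.integer(el[idx[1], ])
  e2 <- as.integer(el[idx[2], ])
  mode <- sample.int(2L, 1L)
  if (mode == 1L) {
    new_a <- c(e1[1], e2[2]); new_b <- c(e2[1], e1[2])
  } else {
    new_a <- c(e1[1], e2[1]); new_b <- c(e1[2], e2[2])
  }
  swap <- structure(
    list(edge_a = e1, edge_b = e2, new_a = new_a, new_b = new_b,
         mode = mode, valid = FALSE),
    class = "swap_proposal")
  swap$valid <- .swap_is_valid(net, swap)
  swap
}

# a swap is valid iff, after removing edge_a and edge_b, both new edges
# can be added without creating a loop or a duplicate
.swap_is_valid <- function(net, swap) {
  same_pair <- function(x, y) all(sort(x) == sort(y))
  if (swap$new_a[1] == swap$new_a[2]) return(FALSE)
  if (swap$new_b[1] == swap$new_b[2]) return(FALSE)
  if (same_pair(swap$new_a, swap$new_b)) return(FALSE)
  g <- igraph::delete_edges(
    net, igraph::get_edge_ids(net, as.character(c(swap$edge_a, swap$edge_b))))
  for (e in list(swap$new_a, swap$new_b))
    if (igraph::are_adjacent(g, as.character(e[1]), as.character(e[2])))
      return(FALSE)
  TRUE
}

#' Apply a valid swap proposal to a network
#'
#' @param net a contact network.
#' @param swap a valid `swap_proposal`.
#' @return the rewired contact network.
#' @export
apply_swap <- function(net, swap) {
  if (!swap$valid) stop("cannot apply an invalid swap proposal")
  g <- igraph::delete_edges(
    net, igraph::get_edge_ids(net, as.character(c(swap$edge_a, swap$edge_b))))
  igraph::add_edges(g, as.character(c(swap$new_a, swap$new_b)))
}

# delta of the gwesp statistic from removing (d_sign = -1) or adding
# (d_sign = +1) one edge, touching only edges incident to its endpoints;
# returns list(g = updated graph, delta = change)
.edge_op_delta <- function(g, e, decay, add) {
  nm <- igraph::V(g)$name
  a <- match(as.character(e[1]), nm)
  b <- match(as.character(e[2]), nm)
  phi <- function(s) .gwesp_weight(s, decay)
  delta <- 0
  for (ends in list(c(a, b), c(b, a))) {
    x <- ends[1]; y <- ends[2]
    for (z in as.integer(igraph::neighbors(g, x))) {
      if (z == y) next
      if (igraph::are_adjacent(g, z, y)) {
        s <- .sp_idx(g, x, z)  # before the change; excludes/includes y accordingly
        delta <- delta + if (add) phi(s + 1) - phi(s) else phi(s - 1) - phi(s)
      }
    }
  }
  if (add) {
    delta <- delta + phi(.sp_idx(g, a, b))
    g <- igraph::add_edges(g, c(a, b))
  } else {
    delta <- delta - phi(.sp_idx(g, a, b))
    g <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(a, b)))
  }
  list(g = g, delta = delta)
}

#' Incremental gwesp change of a swap
#'
#' Computes `gwesp(after) - gwesp(before)` for a valid swap proposal by
#' updating only the edges whose shared-partner counts change (those
#' incident to the four endpoints), never recomputing the full statistic.
#'
#' @param net a contact network.
#' @param swap a valid `swap_proposal`.
#' @param decay gwesp decay `tau`.
#' @return the change in the statistic.
#' @export
delta_gwesp <- function(net, swap, decay) {
  if (!swap$valid) stop("delta_gwesp requires a valid swap proposal")
  g <- net
  total <- 0
  for (e in list(swap$edge_a, swap$edge_b)) {
    op <- .edge_op_delta(g, e, decay, add = FALSE)
    g <- op$g; total <- total + op$delta
  }
  for (e in list(swap$new_a, swap$new_b)) {
    op <- .edge_op_delta(g, e, decay, add = TRUE)
    g <- op$g; total <- total + op$delta
  }
  total
}

#' Rewiring configuration
#'
#' Bundles the tuning parameters of [rewire_network()]. The study settings
#' are `decay = 0.2` with `coefficient = +5` (high clustering) or `-5`
#' (low clustering) and a burn-in of `5e5` proposals.
#'
#' @param coefficient gwesp coefficient `theta`; positive favours, negative
#'   penalises shared partners.
#' @param decay gwesp decay `tau >= 0`.
#' @param burnin number of proposals to run (valid or not).
#' @return an object of class `rewire_config`.
#' @export
rewire_config <- function(coefficient, decay = 0.2, burnin = 5e5) {
  stopifnot(decay >= 0, burnin >= 0)
  structure(list(coefficient = coefficient, decay = decay,
                 burnin = burnin),
            class = "rewire_config")
}

#' Rewire a network towards high or low clustering
#'
#' Metropolis-Hastings sampling from the exponential random graph density
#' `p(Y) propto exp(theta * gwesp(Y; tau))` restricted to graphs with the
#' input's exact per-node degree sequence. Proposals are uniform
#' double-edge swaps (see [propose_swap()]); a valid proposal is accepted
#' with probability `min(1, exp(theta * delta_gwesp))` (the proposal is
#' symmetric, so the Hastings ratio reduces to the density ratio). Invalid
#' proposals are rejected and still count toward the burn-in. The state
#' after `burnin` proposals is returned; with `theta = +5` the output is a
#' triangle-rich graph, with `theta = -5` triangles are driven out, and
#' every node keeps its degree exactly.
#'
#' Randomness comes from R's RNG: call `set.seed()` for reproducibility.
#'
#' @param net a contact network.
#' @param config a [rewire_config()]; alternatively pass `coefficient`,
#'   `decay`, `burnin` directly.
#' @param coefficient,decay,burnin used when `config` is missing.
#' @param verbose print a progress line every 1e4 proposals.
#' @return the rewired contact network, with attributes
#'   `rewire_accepted`, `rewire_invalid`, `rewire_proposals` and
#'   `rewire_gwesp` (the statistic of the returned state).
#' @export
rewire_network <- function(net, config = NULL, coefficient = NULL,
                           decay = 0.2, burnin = 5e5, verbose = FALSE) {
  if (is.null(config)) {
    if (is.null(coefficient))
      stop("provide either a rewire_config or a coefficient")
    config <- rewire_config(coefficient, decay, burnin)
  }
  el <- igraph::as_edgelist(net, names = FALSE)
  storage.mode(el) <- "integer"
  res <- cpp_rewire(el, igraph::vcount(net), config$decay,
                    config$coefficient, config$burnin, verbose)
  out <- igraph::make_empty_graph(igraph::vcount(net), directed = FALSE)
  out <- igraph::add_edges(out, t(res$edges))
  igraph::V(out)$name <- igraph::V(net)$name
  attr(out, "rewire_accepted") <- res$accepted
  attr(out, "rewire_invalid") <- res$invalid
  attr(out, "rewire_proposals") <- res$proposals
  attr(out, "rewire_gwesp") <- res$gwesp
  out
}
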