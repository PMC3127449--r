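#' Transmission trees
#'
#' A transmission tree is a timed rooted tree encoding who infected whom
#' and when. It has three kinds of nodes: one root `(t_0, u_0, 0)` for the
#' index exposure; one internal node `(t, u, v)` per transmission event
#' ("`v` infected `u` at time `t`"); and one leaf `(t, u)` per recovery.
#' Branches follow each individual's timeline: an internal node's two
#' children are the continuation of the infector's timeline and the start
#' of the infectee's timeline, so the root emits one branch and every
#' internal node two, giving `2 * n_leaves - 1` branches whose lengths sum
#' to the total infected time.
#'
#' @param log a valid `event_log` (see [validate_event_log()]).
#' @return an object of class `transmission_tree`: a data frame of tree
#'   nodes with columns `node` (id within the tree), `type` (`"root"`,
#'   `"internal"`, `"leaf"`), `time`, `individual` (the infectee `u` for
#'   internal nodes), `infector` (`v`; `NA` for root and leaves), `parent`
#'   (tree-node id, `NA` for the root) and `branch_length`
#'   (`time - parent time`).
#' @export
build_tree <- function(log) {
  validate_event_log(log)
  index <- attr(log, "index_node")
  ex <- log[log$kind == "exposure", ]
  rec <- log[log$kind == "recovery", ]
  inds <- ex$individual
  n <- length(inds)

  # tree node ids: exposure node of each individual first (root = that of
  # the index), then one leaf per individual
  exp_node <- stats::setNames(seq_len(n), inds)
  leaf_node <- stats::setNames(n + seq_len(n), rec$individual)

  node <- integer(2 * n); type <- character(2 * n)
  time <- numeric(2 * n); individual <- integer(2 * n)
  infector <- rep(NA_integer_, 2 * n); parent <- rep(NA_integer_, 2 * n)

  for (r in seq_len(n)) {
    i <- exp_node[as.character(ex$individual[r])]
    node[i] <- i
    type[i] <- if (ex$individual[r] == index) "root" else "internal"
    time[i] <- ex$time[r]
    individual[i] <- ex$individual[r]
    infector[i] <- ex$infector[r]
  }
  for (r in seq_len(nrow(rec))) {
    i <- leaf_node[as.character(rec$individual[r])]
    node[i] <- i
    type[i] <- "leaf"
    time[i] <- rec$time[r]
    individual[i] <- rec$individual[r]
  }

  # chain each individual's timeline: exposure node, then the internal
  # nodes of the transmissions it caused (in time order), then its leaf
  for (u in inds) {
    caused <- ex[!is.na(ex$infector) & ex$infector == u, ]
    caused <- caused[order(caused$time), ]
    chain <- c(exp_node[as.character(u)],
               exp_node[as.character(caused$individual)],
               leaf_node[as.character(u)])
    for (k in seq_len(length(chain) - 1L))
      parent[chain[k + 1L]] <- chain[k]
  }

  tree <- data.frame(node = node, type = type, time = time,
                     individual = individual, infector = infector,
                     parent = parent, stringsAsFactors = FALSE)
  tree$branch_length <- tree$time - tree$time[tree$parent]
  attr(tree, "index_node") <- index
  class(tree) <- c("transmission_tree", "data.frame")
  validate_tree(tree)
}

#' Validate a transmission tree
#'
#' Asserts the structural invariants: one root; `n_internal = n_leaves - 1`;
#' `2 * n_leaves - 1` branches; every non-root node strictly later than its
#' parent; and branch lengths summing to the total infected duration.
#'
#' @param tree a `transmission_tree`.
#' @return `tree`, invisibly.
#' @export
validate_tree <- function(tree) {
  n_leaf <- sum(tree$type == "leaf")
  if (sum(tree$type == "root") != 1) stop("tree must have exactly one root")
  if (sum(tree$type == "internal") != n_leaf - 1)
    stop("tree must have n_leaves - 1 internal nodes")
  has_parent <- !is.na(tree$parent)
  if (sum(has_parent) != 2 * n_leaf - 1)
    stop("tree must have 2 * n_leaves - 1 branches")
  if (any(tree$branch_length[has_parent] <= 0))
    stop("every branch must have positive length")
  non_leaf <- tree[tree$type != "leaf", ]
  leaf <- tree[tree$type == "leaf", ]
  dur <- sum(leaf$time -
               non_leaf$time[match(leaf$individual, non_leaf$individual)])
  if (abs(sum(tree$branch_length[has_parent]) - dur) > 1e-9)
    stop("branch lengths must sum to total infected time")
  invisible(tree)
}

# children (tree-node ids) of each tree node, as a list indexed by node id
.tree_children <- function(tree) {
  kids <- vector("list", nrow(tree))
  has_parent <- which(!is.na(tree$parent))
  for (i in has_parent)
    kids[[tree$parent[i]]] <- c(kids[[tree$parent[i]]], tree$node[i])
  kids
}

#' Mean internal and external branch lengths
#'
#' Branches are classified by their child endpoint: branches ending in an
#' internal node measure times between successive transmission events
#' ("internal"), branches ending in a leaf measure times from an
#' individual's last event to its removal ("external"). A tree with no
#' internal-child branches (a single infected individual) has an undefined
#' internal mean, returned as `NA`.
#'
#' @param tree a `transmission_tree`.
#' @return list with `mean_internal` (days or `NA`) and `mean_external`
#'   (days).
#' @export
branch_length_summaries <- function(tree) {
  has_parent <- !is.na(tree$parent)
  internal <- tree$branch_length[has_parent & tree$type == "internal"]
  external <- tree$branch_length[has_parent & tree$type == "leaf"]
  list(mean_internal = if (length(internal)) mean(internal) else NA_real_,
       mean_external = mean(external))
}

#' Count cherries in a transmission tree
#'
#' A cherry is a pair of leaves adjacent to a common internal node, i.e.
#' an internal node both of whose child branches end in leaves.
#'
#' @param tree a `transmission_tree`.
#' @return integer count.
#' @export
count_cherries <- function(tree) {
  kids <- .tree_children(tree)
  internal <- tree$node[tree$type == "internal"]
  sum(vapply(internal, function(i) {
    k <- kids[[i]]
    length(k) == 2 && all(tree$type[k] == "leaf")
  }, logical(1)))
}

#' Maximum possible number of cherries for an outbreak size
#'
#' @param n_leaves number of infected individuals (leaves), `>= 1`.
#' @return `floor(n_leaves / 2)`.
#' @export
max_cherries <- function(n_leaves) {
  stopifnot(n_leaves >= 1)
  n_leaves %/% 2L
}

#' Secondary infections caused by each infected individual
#'
#' For each infected individual `v`, the number of internal nodes of the
#' form `(t, u, v)`; zeros are included, and the counts sum to
#' `n_leaves - 1`.
#'
#' @param tree a `transmission_tree`.
#' @return named integer vector indexed by individual id.
#' @export
secondary_infection_counts <- function(tree) {
  inds <- tree$individual[tree$type != "leaf"]
  v <- tree$infector[tree$type == "internal"]
  counts <- table(factor(v, levels = inds))
  stats::setNames(as.integer(counts), names(counts))
}

#' Infective descendants of each infected individual
#'
#' The recursive total of secondary infections: `v`'s secondary
#' infections, plus their secondary infections, and so on. The index's
#' count is `n_leaves - 1`. Equivalently, the number of leaves having a
#' transmission node `(t, u, v)` as an ancestor.
#'
#' @param tree a `transmission_tree`.
#' @return named integer vector indexed by individual id.
#' @export
infective_descendant_counts <- function(tree) {
  internal <- tree[tree$type == "internal", ]
  inds <- tree$individual[tree$type != "leaf"]
  desc <- stats::setNames(integer(length(inds)), inds)
  # process transmissions latest-first so children's totals are complete
  internal <- internal[order(internal$time, decreasing = TRUE), ]
  for (r in seq_len(nrow(internal))) {
    u <- as.character(internal$individual[r])
    v <- as.character(internal$infector[r])
    desc[v] <- desc[v] + 1L + desc[u]
  }
  desc
}

#' Write a transmission tree as a rooted Newick string
#'
#' Leaves are labelled with individual ids; branch lengths are the timed
#' intervals along each timeline. The root's single child subtree is
#' wrapped in an outer pair of parentheses, which standard Newick parsers
#' read as a root with one (singleton) descendant.
#'
#' @param tree a `transmission_tree`.
#' @param file optional path; when given, the string is also written there.
#' @return the Newick string, invisibly if `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  kids <- .tree_children(tree)
  fmt <- function(i) {
    len <- tree$branch_length[i]
    if (tree$type[i] == "leaf")
      sprintf("%s:%.9g", tree$individual[i], len)
    else
      sprintf("(%s):%.9g", paste(vapply(kids[[i]], fmt, character(1)),
                                 collapse = ","), len)
  }
  root <- tree$node[tree$type == "root"]
  child <- kids[[root]]
  txt <- if (length(child) == 0) {
    sprintf("%s:0;", tree$individual[root])  # degenerate: no branches
  } else {
    sprintf("(%s);", fmt(child))
  }
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Write a transmission tree as TSV
#'
#' One row per tree node: `type`, `time`, `individual`, `infector`
#' (mirroring the `(t, u, v)` triples; empty for root and leaves).
#'
#' @param tree a `transmission_tree`.
#' @param file path.
#' @return `file`, invisibly.
#' @export
write_tree_tsv <- function(tree, file) {
  utils::write.table(
    tree[, c("type", "time", "individual", "infector")], file,
    sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  invisible(file)
}

#' Worked-example five-host event log
#'
#' A small hand-constructed epidemic among five hosts used throughout the
#' documentation and tests: host 1 is exposed at time 0 and infects host 2
#' at `t = 1.3`; host 2 infects hosts 3 and 4; host 4 infects host 5; the
#' recoveries of hosts 4 (`t = 5.2`) and 5 (`t = 6.2`) form the tree's
#' single cherry, out of a possible maximum of two for five hosts.
#'
#' @return an `event_log`.
#' @export
example_transmission_log <- function() {
  log <- data.frame(
    time = c(0, 0.9, 1.3, 1.5, 2.1, 2.3, 2.5, 3.0, 3.1, 3.4, 4.0,
             4.2, 4.5, 5.2, 6.2),
    kind = c("exposure", "onset", "exposure", "onset", "exposure",
             "onset", "exposure", "onset", "recovery", "exposure",
             "recovery", "onset", "recovery", "recovery", "recovery"),
    individual = c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 1L, 5L, 3L,
                   5L, 2L, 4L, 5L),
    infector = c(NA, NA, 1L, NA, 2L, NA, 2L, NA, NA, 4L, NA,
                 NA, NA, NA, NA),
    stringsAsFactors = FALSE)
  attr(log, "index_node") <- 1L
  class(log) <- c("event_log", "data.frame")
  log
}
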