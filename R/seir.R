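#' Epidemic parameters
#'
#' Parameters of the stochastic SEIR model: per-edge transmission rate
#' `beta` (per day), gamma-distributed latent period with shape `k_e` and
#' scale `theta_e` (days, mean `k_e * theta_e`), gamma-distributed
#' infectious period with shape `k_i` and scale `theta_i`, and the
#' conditioning threshold `min_outbreak` (a run counts as a major outbreak
#' when at least that many individuals are ever infected). Defaults are
#' the study settings: `beta = 0.1`, `k_e = k_i = 1`,
#' `theta_e = theta_i = 3`, `min_outbreak = 20`.
#'
#' @param beta per-edge transmission rate, `>= 0`.
#' @param k_e,theta_e latent-period gamma shape and scale, `> 0`.
#' @param k_i,theta_i infectious-period gamma shape and scale, `> 0`.
#' @param min_outbreak minimum final size for conditioning, `>= 1`.
#' @return an object of class `epidemic_params`.
#' @export
epidemic_params <- function(beta = 0.1, k_e = 1, theta_e = 3,
                            k_i = 1, theta_i = 3, min_outbreak = 20L) {
  if (beta < 0) stop("beta must be non-negative")
  if (any(c(k_e, theta_e, k_i, theta_i) <= 0))
    stop("gamma shapes and scales must be positive")
  if (min_outbreak < 1) stop("min_outbreak must be at least 1")
  structure(list(beta = beta, k_e = k_e, theta_e = theta_e,
                 k_i = k_i, theta_i = theta_i,
                 min_outbreak = as.integer(min_outbreak)),
            class = "epidemic_params")
}

#' Draw a gamma-distributed waiting period
#'
#' Thin wrapper over [stats::rgamma()] in the shape/scale parameterisation
#' used for latent and infectious periods: mean `shape * scale`, variance
#' `shape * scale^2`.
#'
#' @param n number of draws.
#' @param shape,scale gamma parameters, both `> 0`.
#' @return positive durations in days.
#' @export
draw_gamma_period <- function(n, shape, scale) {
  if (shape <= 0 || scale <= 0)
    stop("shape and scale must be positive")
  stats::rgamma(n, shape = shape, scale = scale)
}

# event kinds, in tie-break order
.EXPOSURE <- 1L
.ONSET <- 2L
.RECOVERY <- 3L
.KIND_NAMES <- c("exposure", "onset", "recovery")

#' Simulate one stochastic SEIR epidemic over a network
#'
#' Event-driven simulation. The index node is exposed at time 0; after a
#' gamma latent period it becomes infectious, and after a gamma infectious
#' period it is removed. While a node is infectious, infection crosses
#' each edge to a susceptible neighbour as a Poisson process with rate
#' `beta`; since re-infection cannot occur, only the first potential
#' contact per infectious-susceptible pair matters, so one exponential
#' first-contact time is drawn per such pair and takes effect only if it
#' falls inside the infectious period and the neighbour is still
#' susceptible at that moment. Removed nodes play no further part. The
#' process stops when no exposed or infectious nodes remain.
#'
#' Simultaneous events are ordered by (time, kind with
#' exposure < onset < recovery, node id) for deterministic replay; with a
#' fixed seed the event log is reproducible exactly.
#'
#' @param net a contact network.
#' @param params an [epidemic_params()].
#' @param index the id of the initially exposed node.
#' @return an `event_log`: a data frame with columns `time` (days),
#'   `kind` (`"exposure"`, `"onset"`, `"recovery"`), `individual` and
#'   `infector` (`NA` for the index exposure and all non-exposure rows),
#'   ordered by event time, with the index id in `attr(, "index_node")`.
#' @export
simulate_seir <- function(net, params, index) {
  nm <- igraph::V(net)$name
  idx <- match(as.character(index), nm)
  if (is.na(idx)) stop("unknown index node: ", index)
  n <- igraph::vcount(net)
  ids <- as.integer(nm)
  adj <- igraph::as_adj_list(net)  # vertex indices

  state <- integer(n)  # 0 S, 1 E, 2 I, 3 R
  # event queue as growing parallel vectors
  cap <- 256L
  q_time <- numeric(cap); q_kind <- integer(cap)
  q_who <- integer(cap); q_from <- integer(cap); q_live <- logical(cap)
  n_q <- 0L
  push <- function(time, kind, who, from) {
    n_q <<- n_q + 1L
    if (n_q > cap) {
      cap <<- cap * 2L
      length(q_time) <<- cap; length(q_kind) <<- cap
      length(q_who) <<- cap; length(q_from) <<- cap
      q_live <<- c(q_live, logical(cap %/% 2L))
    }
    q_time[n_q] <<- time; q_kind[n_q] <<- kind
    q_who[n_q] <<- who; q_from[n_q] <<- from; q_live[n_q] <<- TRUE
  }

  out_time <- numeric(0); out_kind <- integer(0)
  out_who <- integer(0); out_from <- integer(0)

  push(0, .EXPOSURE, idx, NA_integer_)
  repeat {
    live <- which(q_live[seq_len(n_q)])
    if (length(live) == 0L) break
    # next event: min (time, kind, who)
    t_live <- q_time[live]
    cand <- live[t_live == min(t_live)]
    if (length(cand) > 1L) {
      cand <- cand[q_kind[cand] == min(q_kind[cand])]
      if (length(cand) > 1L) cand <- cand[which.min(q_who[cand])]
    }
    ev <- cand[1L]
    q_live[ev] <- FALSE
    t <- q_time[ev]; kind <- q_kind[ev]
    u <- q_who[ev]; v <- q_from[ev]

    if (kind == .EXPOSURE) {
      if (state[u] != 0L) next  # already exposed by an earlier contact
      state[u] <- 1L
      latent <- stats::rgamma(1L, shape = params$k_e, scale = params$theta_e)
      push(t + latent, .ONSET, u, NA_integer_)
    } else if (kind == .ONSET) {
      state[u] <- 2L
      len <- stats::rgamma(1L, shape = params$k_i, scale = params$theta_i)
      push(t + len, .RECOVERY, u, NA_integer_)
      if (params$beta > 0) {
        nbr <- as.integer(adj[[u]])
        nbr <- nbr[state[nbr] == 0L]
        for (w in sort(nbr)) {
          contact <- t + stats::rexp(1L, rate = params$beta)
          if (contact < t + len) push(contact, .EXPOSURE, w, u)
        }
      }
    } else {
      state[u] <- 3L
    }
    out_time <- c(out_time, t); out_kind <- c(out_kind, kind)
    out_who <- c(out_who, u); out_from <- c(out_from, v)
  }

  log <- data.frame(
    time = out_time,
    kind = .KIND_NAMES[out_kind],
    individual = ids[out_who],
    infector = ifelse(is.na(out_from), NA_integer_, ids[out_from]),
    stringsAsFactors = FALSE)
  attr(log, "index_node") <- ids[idx]
  class(log) <- c("event_log", "data.frame")
  log
}

#' Validate an epidemic event log
#'
#' Checks the structural invariants: per individual, exposure < onset <
#' recovery with each occurring exactly once; at most one exposure per
#' individual (no re-infection); the index exposed at time 0 with no
#' infector; every other exposure naming an infector whose
#' `[onset, recovery)` interval contains the exposure time.
#'
#' @param log an `event_log`.
#' @return `log`, invisibly; errors if an invariant fails.
#' @export
validate_event_log <- function(log) {
  index <- attr(log, "index_node")
  if (is.null(index)) stop("event log lacks an index_node attribute")
  for (kind in .KIND_NAMES) {
    sub <- log[log$kind == kind, ]
    if (anyDuplicated(sub$individual))
      stop("individual with repeated ", kind, " event")
  }
  exp_t <- stats::setNames(log$time[log$kind == "exposure"],
                           log$individual[log$kind == "exposure"])
  ons_t <- stats::setNames(log$time[log$kind == "onset"],
                           log$individual[log$kind == "onset"])
  rec_t <- stats::setNames(log$time[log$kind == "recovery"],
                           log$individual[log$kind == "recovery"])
  if (!setequal(names(exp_t), names(ons_t)) ||
      !setequal(names(exp_t), names(rec_t)))
    stop("every infected individual must have exposure, onset and recovery")
  for (id in names(exp_t)) {
    if (!(exp_t[id] < ons_t[id] && ons_t[id] < rec_t[id]))
      stop("event order violated for individual ", id)
  }
  ex <- log[log$kind == "exposure", ]
  idx_row <- ex[ex$individual == index, ]
  if (nrow(idx_row) != 1 || idx_row$time != 0 || !is.na(idx_row$infector))
    stop("index exposure must be at time 0 with no infector")
  oth <- ex[ex$individual != index, ]
  if (nrow(oth) > 0) {
    if (any(is.na(oth$infector)))
      stop("non-index exposure without an infector")
    for (r in seq_len(nrow(oth))) {
      v <- as.character(oth$infector[r])
      if (!(ons_t[v] <= oth$time[r] && oth$time[r] < rec_t[v]))
        stop("exposure outside the infector's infectious interval")
    }
  }
  invisible(log)
}

#' Final size of an epidemic
#'
#' @param log an `event_log`.
#' @return the number of individuals ever infected (exposure events).
#' @export
final_size <- function(log) sum(log$kind == "exposure")

#' Simulate an SEIR epidemic conditioned on a major outbreak
#'
#' Re-runs [simulate_seir()] from the same index with fresh randomness
#' until the outbreak infects at least `params$min_outbreak` individuals.
#'
#' @inheritParams simulate_seir
#' @param max_attempts attempts before giving up.
#' @return a qualifying `event_log` with the attempt count in
#'   `attr(, "attempts")`; errors (class `seirtrees_conditioning_failure`,
#'   carrying the index in `$index`) if `max_attempts` is exhausted.
#' @export
simulate_conditioned <- function(net, params, index, max_attempts = 500L) {
  if (max_attempts < 1) stop("max_attempts must be at least 1")
  for (attempt in seq_len(max_attempts)) {
    log <- simulate_seir(net, params, index)
    if (final_size(log) >= params$min_outbreak) {
      attr(log, "attempts") <- attempt
      return(log)
    }
  }
  stop(structure(
    class = c("seirtrees_conditioning_failure", "error", "condition"),
    list(message = sprintf(
           "no outbreak of size >= %d from index %s in %d attempts",
           params$min_outbreak, index, max_attempts),
         call = sys.call(-1), index = index)))
}

#' Paired conditioned epidemics on two degree-matched networks
#'
#' Chooses one index node uniformly from the ids present in the largest
#' connected component of both networks, then runs a conditioned epidemic
#' on each network from that same index.
#'
#' @param net_hi,net_lo two contact networks sharing a node-id space
#'   (typically high- and low-clustering rewirings of one base network).
#' @param params an [epidemic_params()].
#' @param max_attempts conditioning attempts per network.
#' @return list with elements `hi` and `lo` (`event_log`s) and `index`.
#' @export
paired_epidemics <- function(net_hi, net_lo, params,
                             max_attempts = 500L) {
  shared <- intersect(node_ids(largest_component(net_hi)),
                      node_ids(largest_component(net_lo)))
  if (length(shared) == 0)
    stop("the largest components of the two networks share no nodes")
  index <- shared[sample.int(length(shared), 1L)]
  list(hi = simulate_conditioned(net_hi, params, index, max_attempts),
       lo = simulate_conditioned(net_lo, params, index, max_attempts),
       index = index)
}

#' Write or read an event log as TSV
#'
#' Columns `time` (decimal days), `kind`, `individual`, `infector`
#' (empty for the index and for non-exposure rows).
#'
#' @param log an `event_log`.
#' @param file path.
#' @return `write_event_log` returns `file` invisibly; `read_event_log`
#'   returns an `event_log`.
#' @export
write_event_log <- function(log, file) {
  df <- as.data.frame(log)
  utils::write.table(df, file, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(file)
}

#' @rdname write_event_log
#' @param index_node index node id on read (default: the infector-less
#'   exposure).
#' @export
read_event_log <- function(file, index_node = NULL) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          na.strings = "", stringsAsFactors = FALSE)
  if (is.null(index_node))
    index_node <- df$individual[df$kind == "exposure" & is.na(df$infector)][1]
  attr(df, "index_node") <- index_node
  class(df) <- c("event_log", "data.frame")
  df
}
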