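#' Epidemic prevalence curve on a time grid
#'
#' Number of currently infected individuals (by default exposed or
#' infectious, i.e. anyone between exposure and recovery) at each grid
#' time from 0 to the last recovery.
#'
#' @param log an `event_log`.
#' @param step grid spacing in days (default 1).
#' @param compartments which compartments count as "infected": `"EI"`
#'   (exposed + infectious, the default) or `"I"` (infectious only).
#' @return data frame with columns `time` and `infected`.
#' @export
prevalence_curve <- function(log, step = 1, compartments = c("EI", "I")) {
  stopifnot(step > 0)
  compartments <- match.arg(compartments)
  start_kind <- if (compartments == "EI") "exposure" else "onset"
  start <- log$time[log$kind == start_kind]
  end <- log$time[log$kind == "recovery"][
    match(log$individual[log$kind == start_kind],
          log$individual[log$kind == "recovery"])]
  grid <- seq(0, max(log$time[log$kind == "recovery"]), by = step)
  infected <- vapply(grid, function(t) sum(start <= t & t < end), integer(1))
  data.frame(time = grid, infected = infected)
}

#' Scalar summaries of the epidemic curve
#'
#' Computes the final size (individuals ever infected), the epidemic
#' length (first infection to last recovery, in days), and the peak of
#' the prevalence curve. Prevalence is piecewise constant, changing only
#' at exposure (+1) and recovery (-1) events, so the peak and its time
#' are computed exactly from the event log rather than on a grid; ties in
#' the maximum are resolved to the earliest time.
#'
#' @param log an `event_log`.
#' @param compartments as in [prevalence_curve()].
#' @return list with `final_size`, `epidemic_length`, `peak_prevalence`
#'   and `peak_time`.
#' @export
summarize_curve <- function(log, compartments = c("EI", "I")) {
  compartments <- match.arg(compartments)
  start_kind <- if (compartments == "EI") "exposure" else "onset"
  changes <- log[log$kind %in% c(start_kind, "recovery"), ]
  delta <- ifelse(changes$kind == start_kind, 1L, -1L)
  prev <- cumsum(delta)
  peak <- max(prev)
  list(final_size = final_size(log),
       epidemic_length = max(log$time[log$kind == "recovery"]) -
         log$time[log$kind == "exposure"][1],
       peak_prevalence = peak,
       peak_time = changes$time[which(prev == peak)[1]])
}

#' Summaries of a transmission tree
#'
#' Assembles the tree statistics: mean internal and external branch
#' lengths, the secondary-infection and infective-descendant
#' distributions, and the cherry ratio (cherries over the maximum
#' possible, `NA` when a single-host outbreak admits no cherry).
#'
#' @param tree a `transmission_tree`.
#' @return list with `mean_internal_branch`, `mean_external_branch`,
#'   `secondary_counts`, `descendant_counts`, `n_cherries`,
#'   `cherry_ratio` and `n_leaves`.
#' @export
summarize_tree <- function(tree) {
  bl <- branch_length_summaries(tree)
  n_leaves <- sum(tree$type == "leaf")
  ch <- count_cherries(tree)
  mx <- max_cherries(n_leaves)
  list(mean_internal_branch = bl$mean_internal,
       mean_external_branch = bl$mean_external,
       secondary_counts = secondary_infection_counts(tree),
       descendant_counts = infective_descendant_counts(tree),
       n_cherries = ch,
       cherry_ratio = if (mx > 0) ch / mx else NA_real_,
       n_leaves = n_leaves)
}

#' One replicate-arm summary row
#'
#' Reduces an event log (and the tree built from it) to the scalar
#' summary row used in the experiment tables.
#'
#' @param log an `event_log`.
#' @param compartments as in [prevalence_curve()].
#' @return one-row data frame with the curve and tree scalars.
#' @export
summarize_replicate <- function(log, compartments = c("EI", "I")) {
  cs <- summarize_curve(log, compartments)
  ts <- summarize_tree(build_tree(log))
  data.frame(final_size = cs$final_size,
             epidemic_length = cs$epidemic_length,
             peak_prevalence = cs$peak_prevalence,
             peak_time = cs$peak_time,
             mean_internal_branch = ts$mean_internal_branch,
             mean_external_branch = ts$mean_external_branch,
             mean_secondary = mean(ts$secondary_counts),
             cherry_ratio = ts$cherry_ratio)
}
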