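#' Experiment configuration
#'
#' Bundles every parameter of the paired-clustering experiment: the
#' network model and its parameters, the rewiring settings for the high-
#' and low-clustering arms, the epidemic parameters, the number of
#' replicates and the master seed. The defaults are the study settings:
#' Bernoulli networks with `N = 500`, `p = 0.014` (or power-law networks
#' with `N = 600`, `alpha = 1.8`), gwesp decay 0.2 with coefficients +5
#' and -5, burn-in `5e5` proposals, and the default [epidemic_params()].
#'
#' @param model `"bernoulli"` or `"powerlaw"`.
#' @param n_nodes network size (default 500 for Bernoulli, 600 for
#'   power-law).
#' @param edge_prob Bernoulli edge probability.
#' @param exponent power-law exponent.
#' @param decay gwesp decay `tau`.
#' @param theta_hi,theta_lo gwesp coefficients of the two arms.
#' @param burnin rewiring proposals per arm.
#' @param params an [epidemic_params()].
#' @param n_replicates number of paired replicates (the study runs 500).
#' @param seed master seed; per-replicate seeds are derived from it so
#'   each replicate is individually reproducible.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(model = c("bernoulli", "powerlaw"),
                              n_nodes = NULL, edge_prob = 0.014,
                              exponent = 1.8, decay = 0.2,
                              theta_hi = 5, theta_lo = -5, burnin = 5e5,
                              params = epidemic_params(),
                              n_replicates = 500L, seed = 1L) {
  model <- match.arg(model)
  if (is.null(n_nodes))
    n_nodes <- if (model == "bernoulli") 500L else 600L
  stopifnot(n_replicates >= 1)
  structure(list(model = model, n_nodes = as.integer(n_nodes),
                 edge_prob = edge_prob, exponent = exponent,
                 decay = decay, theta_hi = theta_hi, theta_lo = theta_lo,
                 burnin = burnin, params = params,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' The file's keys mirror the [experiment_config()] arguments, with
#' epidemic parameters nested under `params` (keys as in
#' [epidemic_params()]). Missing keys fall back to the defaults.
#'
#' @param file path to a YAML file.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(file) {
  y <- yaml::read_yaml(file)
  params <- do.call(epidemic_params, as.list(y$params))
  y$params <- NULL
  do.call(experiment_config, c(y, list(params = params)))
}

# deterministic per-replicate substream seed (kept under 2^31)
replicate_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) * 48271 + i * 16807) %%
               2147483647)
}

# sample a base network for the configured model
.sample_base_network <- function(config) {
  if (config$model == "bernoulli")
    sample_bernoulli(config$n_nodes, config$edge_prob)
  else
    sample_power_law(config$n_nodes, config$exponent)
}

#' Run one paired replicate of the clustering experiment
#'
#' Samples a base network, rewires it once toward high and once toward
#' low clustering (both arms keep every node's degree), restricts each
#' arm to its largest connected component, runs paired conditioned SEIR
#' epidemics from a common index node, and summarises both outbreaks.
#' If conditioning fails for the chosen index, a fresh index is drawn
#' (both arms restart); after `max_index_draws` failures the replicate is
#' marked failed rather than silently dropped.
#'
#' @param i replicate id.
#' @param config an [experiment_config()].
#' @param max_index_draws index redraws before giving up.
#' @return a two-row data frame (arms `"hi"` and `"lo"`) with the
#'   replicate id, arm, substream seed, attained clustering coefficient,
#'   component size, index node, curve and tree summaries, and a
#'   `failed` flag (a failed replicate yields two rows of `NA`
#'   summaries).
#' @export
run_replicate <- function(i, config, max_index_draws = 10L) {
  seed_i <- replicate_seed(config$seed, i)
  set.seed(seed_i)
  base <- .sample_base_network(config)
  net_hi <- rewire_network(base, rewire_config(config$theta_hi,
                                               config$decay, config$burnin))
  net_lo <- rewire_network(base, rewire_config(config$theta_lo,
                                               config$decay, config$burnin))
  comp_hi <- largest_component(net_hi)
  comp_lo <- largest_component(net_lo)

  # clustering is reported for the whole rewired graph; the component is
  # what the epidemic runs on
  row_skeleton <- function(arm, net, comp) {
    data.frame(replicate = i, arm = arm, seed = seed_i,
               clustering = global_clustering(net),
               component_size = igraph::vcount(comp),
               stringsAsFactors = FALSE)
  }
  pair <- NULL
  for (draw in seq_len(max_index_draws)) {
    pair <- tryCatch(
      paired_epidemics(comp_hi, comp_lo, config$params),
      seirtrees_conditioning_failure = function(e) NULL)
    if (!is.null(pair)) break
  }
  if (is.null(pair)) {
    na_row <- data.frame(
      final_size = NA_integer_, epidemic_length = NA_real_,
      peak_prevalence = NA_integer_, peak_time = NA_real_,
      mean_internal_branch = NA_real_, mean_external_branch = NA_real_,
      mean_secondary = NA_real_, cherry_ratio = NA_real_)
    out <- rbind(cbind(row_skeleton("hi", net_hi, comp_hi), index = NA,
                       na_row, failed = TRUE),
                 cbind(row_skeleton("lo", net_lo, comp_lo), index = NA,
                       na_row, failed = TRUE))
    return(out)
  }
  rbind(cbind(row_skeleton("hi", net_hi, comp_hi), index = pair$index,
              summarize_replicate(pair$hi), failed = FALSE),
        cbind(row_skeleton("lo", net_lo, comp_lo), index = pair$index,
              summarize_replicate(pair$lo), failed = FALSE))
}

#' Run the replicated paired experiment
#'
#' Repeats [run_replicate()] for `i = 1, ..., n_replicates`, deriving an
#' independent RNG substream per replicate from the master seed, so the
#' result is fully determined by the configuration and any single
#' replicate can be re-run in isolation.
#'
#' @param config an [experiment_config()].
#' @param outdir optional directory; when given, writes
#'   `summaries_hi.csv`, `summaries_lo.csv` and `comparison.csv`.
#' @param verbose print one line per replicate.
#' @return the summary table: a data frame with two rows per replicate
#'   (arms `"hi"` and `"lo"`).
#' @export
run_experiment <- function(config, outdir = NULL, verbose = FALSE) {
  rows <- vector("list", config$n_replicates)
  for (i in seq_len(config$n_replicates)) {
    rows[[i]] <- run_replicate(i, config)
    if (verbose)
      message(sprintf("replicate %d/%d: clustering hi %.3f lo %.3f",
                      i, config$n_replicates,
                      rows[[i]]$clustering[1], rows[[i]]$clustering[2]))
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(table[table$arm == "hi", ],
                     file.path(outdir, "summaries_hi.csv"),
                     row.names = FALSE)
    utils::write.csv(table[table$arm == "lo", ],
                     file.path(outdir, "summaries_lo.csv"),
                     row.names = FALSE)
    utils::write.csv(compare_distributions(table),
                     file.path(outdir, "comparison.csv"),
                     row.names = FALSE)
  }
  table
}

# overlap coefficient of two closed intervals: |intersection| / |union|;
# degenerate (zero-width) ranges give 1 when equal points, else 0
.range_overlap <- function(a, b) {
  lo <- max(min(a), min(b)); hi <- min(max(a), max(b))
  width_union <- max(max(a), max(b)) - min(min(a), min(b))
  if (width_union == 0) return(1)
  max(hi - lo, 0) / width_union
}

#' Compare the high- and low-clustering summary distributions
#'
#' For every scalar summary statistic, reports per-arm mean, minimum and
#' maximum plus a range-overlap coefficient
#' `|range intersection| / |range union|` in `[0, 1]` quantifying how
#' much the two arms' observed ranges overlap (1 = identical ranges,
#' 0 = disjoint).
#'
#' @param table a summary table from [run_experiment()] (or any data
#'   frame with an `arm` column and numeric statistic columns).
#' @param statistics columns to compare (default: the numeric summary
#'   columns present).
#' @return data frame with one row per statistic.
#' @export
compare_distributions <- function(table, statistics = NULL) {
  if ("failed" %in% names(table))
    table <- table[!(table$failed %in% TRUE), ]
  if (is.null(statistics)) {
    candidates <- c("clustering", "component_size", "final_size",
                    "epidemic_length", "peak_prevalence", "peak_time",
                    "mean_internal_branch", "mean_external_branch",
                    "mean_secondary", "cherry_ratio")
    statistics <- intersect(candidates, names(table))
  }
  hi <- table[table$arm == "hi", ]
  lo <- table[table$arm == "lo", ]
  if (nrow(hi) < 2 || nrow(lo) < 2)
    stop("need at least 2 rows per arm to compare distributions")
  rows <- lapply(statistics, function(s) {
    x <- hi[[s]][!is.na(hi[[s]])]
    y <- lo[[s]][!is.na(lo[[s]])]
    data.frame(statistic = s,
               hi_mean = mean(x), hi_min = min(x), hi_max = max(x),
               lo_mean = mean(y), lo_min = min(y), lo_max = max(y),
               range_overlap = .range_overlap(x, y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
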