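test_that("Bernoulli sampling handles degenerate probabilities and rejects bad input", {
  set.seed(1)
  expect_equal(igraph::ecount(sample_bernoulli(5, 0)), 0)
  expect_equal(igraph::ecount(sample_bernoulli(5, 1)), 10)
  expect_error(sample_bernoulli(5, 1.2), "probability")
  expect_error(sample_bernoulli(5, -0.1), "probability")
  expect_error(sample_bernoulli(1, 0.5), "at least 2")
})

test_that("Bernoulli edge counts match the Binomial(N(N-1)/2, p) law", {
  set.seed(2024)
  n_rep <- 200
  counts <- replicate(n_rep, igraph::ecount(sample_bernoulli(500, 0.014)))
  trials <- 500 * 499 / 2
  mu <- trials * 0.014
  sigma2 <- trials * 0.014 * (1 - 0.014)
  se_mean <- sqrt(sigma2 / n_rep)
  expect_lt(abs(mean(counts) - mu), 3 * se_mean)
  # variance check at 3 SE (normal-approximation SE of a sample variance)
  se_var <- sigma2 * sqrt(2 / (n_rep - 1))
  expect_lt(abs(var(counts) - sigma2), 3 * se_var)
})

test_that("generated networks satisfy the simple-graph invariants", {
  for (s in 1:5) {
    set.seed(s)
    expect_silent(validate_network(sample_bernoulli(100, 0.05)))
    expect_silent(validate_network(sample_power_law(80, 1.8)))
  }
})

test_that("power-law degrees follow the truncated k^-alpha law", {
  set.seed(11)
  # mass concentrates at 1 for a huge exponent
  d <- sample_power_law_degrees(1000, exponent = 50)
  expect_true(all(d == 1) || mean(d == 1) > 0.999)
  # parity fix-up always yields an even total
  for (s in 1:20) {
    set.seed(s)
    expect_equal(sum(sample_power_law_degrees(51, 1.8)) %% 2, 0)
  }
  # frequency ratio P(1)/P(2) ~ 2^1.8 at alpha = 1.8 (3 SE, delta method)
  set.seed(99)
  d <- sample_power_law_degrees(1e5, 1.8, max_degree = 599)
  z <- sum((1:599)^-1.8)
  p1 <- 1 / z
  p2 <- 2^-1.8 / z
  ratio_se <- (p1 / p2) * sqrt((1 - p1) / (1e5 * p1) + (1 - p2) / (1e5 * p2))
  expect_lt(abs(mean(d == 1) / mean(d == 2) - 2^1.8), 3 * ratio_se)
  expect_error(sample_power_law_degrees(10, -1), "positive")
})

test_that("configuration-model assembly pairs all stubs and only loses degree to cleanup", {
  set.seed(3)
  g <- assemble_configuration_model(c(1, 1))
  expect_equal(igraph::ecount(g), 1)
  expect_true(igraph::are_adjacent(g, "1", "2"))
  # two nodes wanting degree 2 collapse to at most one edge
  g2 <- assemble_configuration_model(c(2, 2))
  expect_lte(igraph::ecount(g2), 1)
  expect_error(assemble_configuration_model(c(1, 1, 1)), "even")
  # realised degrees never exceed requested
  for (s in 1:10) {
    set.seed(s)
    deg <- sample_power_law_degrees(60, 1.8)
    g <- assemble_configuration_model(deg)
    expect_true(all(igraph::degree(g) <= deg))
  }
})

test_that("configuration-model degree loss matches a naive stub-pairing oracle", {
  n_rep <- 1e4
  set.seed(123)
  ours <- replicate(n_rep, {
    g <- assemble_configuration_model(c(3, 3, 3, 3))
    2 * igraph::ecount(g) / 4
  })
  set.seed(456)
  oracle <- replicate(n_rep, oracle_config_mean_degree(c(3, 3, 3, 3)))
  expect_lt(mean(ours), 3)  # cleanup strictly loses degree on average
  se <- sqrt(var(ours) / n_rep + var(oracle) / n_rep)
  expect_lt(abs(mean(ours) - mean(oracle)), 3 * se)
})

test_that("largest_component keeps original labels and matches a BFS oracle", {
  k3 <- graph_k3()
  expect_equal(node_ids(largest_component(k3)), node_ids(k3))
  # two triangles plus an isolated node: tie broken by smallest node id
  g <- contact_network(7, rbind(c(1, 2), c(2, 3), c(1, 3),
                                c(4, 5), c(5, 6), c(4, 6)))
  lc <- largest_component(g)
  expect_equal(sort(node_ids(lc)), 1:3)
  expect_equal(igraph::ecount(lc), 3)
  # empty graph passes through
  expect_equal(igraph::vcount(largest_component(contact_network(0))), 0)
  set.seed(5)
  b <- sample_bernoulli(500, 0.014)
  expect_equal(sort(node_ids(largest_component(b))),
               sort(oracle_largest_component_nodes(b)))
})

test_that("clustering coefficients match their definitions and a brute-force oracle", {
  k3 <- graph_k3()
  expect_equal(local_clustering(k3, 1), 1)
  expect_equal(global_clustering(k3), 1)
  p3 <- graph_path3()
  expect_equal(local_clustering(p3, 2), 0)
  expect_equal(global_clustering(p3), 0)
  km <- graph_k4_minus()
  expect_equal(local_clustering(km, 1), 2 / 3)
  expect_equal(local_clustering(km, 1), oracle_local_clustering(km, 1))
  expect_equal(global_clustering(km), 5 / 6)
  expect_equal(global_clustering(contact_network(0)), 0)
  expect_error(local_clustering(k3, 99), "unknown node")
  # triangle-free graphs score 0 globally
  expect_equal(global_clustering(contact_network(4, rbind(c(1, 2), c(3, 4)))), 0)
  for (s in 1:10) {
    set.seed(s)
    g <- random_net(15, 0.3)
    expect_equal(global_clustering(g), oracle_global_clustering(g))
  }
})

test_that("degree_histogram counts nodes per degree from 0 upward", {
  expect_equal(unname(degree_histogram(contact_network(3))), 3)
  expect_equal(unname(degree_histogram(graph_k3())), c(0, 0, 3))
  star <- contact_network(5, cbind(1, 2:5))
  expect_equal(unname(degree_histogram(star)), c(0, 4, 0, 0, 1))
  expect_equal(names(degree_histogram(star)), as.character(0:4))
})

test_that("edge-list and GraphML round trips preserve the network", {
  set.seed(8)
  g <- sample_bernoulli(40, 0.1)
  f1 <- tempfile(fileext = ".edgelist")
  write_edgelist(g, f1)
  g1 <- read_edgelist(f1, n_nodes = 40)
  expect_true(igraph::identical_graphs(
    igraph::permute(g1, match(igraph::V(g1)$name, igraph::V(g)$name)), g) ||
    setequal(apply(igraph::as_edgelist(g), 1, function(e) paste(sort(e), collapse = "-")),
             apply(igraph::as_edgelist(g1), 1, function(e) paste(sort(e), collapse = "-"))))
  el <- utils::read.table(f1)
  expect_true(all(el[, 1] < el[, 2]))  # smaller id first, no loops
  f2 <- tempfile(fileext = ".graphml")
  write_graphml(g, f2)
  g2 <- read_graphml(f2)
  expect_equal(sort(node_ids(g2)), sort(node_ids(g)))
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  unlink(c(f1, f2))
})
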