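make_signal_dtable <- function(n, seed) {
  set.seed(seed)
  a <- sample(0:2, n, TRUE)
  b <- (a + sample(0:1, n, TRUE, prob = c(0.8, 0.2))) %% 3L
  c_ <- sample(0:2, n, TRUE)
  make_dtable(cbind(a = a, b = b, c = c_), arity = c(3, 3, 3))
}

fast_settings <- function() search_settings(n_iterations = 3000, n_restarts = 5)

test_that("subsamples hold floor(frac * n) distinct indices", {
  dt <- make_signal_dtable(40, 70)
  ens <- run_bootstrap(dt, settings = fast_settings(), B = 5, frac = 0.95,
                       seed = 1)
  for (idx in ens$indices) {
    expect_length(idx, 38L)  # floor(0.95 * 40)
    expect_false(anyDuplicated(idx) > 0)
  }
  expect_equal(floor(0.95 * 527), 500)  # study-scale arithmetic
  # frac = 1 uses every sample in every replicate
  ens_full <- run_bootstrap(dt, settings = fast_settings(), B = 3, frac = 1,
                            seed = 2)
  for (idx in ens_full$indices) expect_identical(idx, 1:40)
})

test_that("bootstrap refuses undersized problems", {
  dt <- make_signal_dtable(15, 71)
  expect_error(run_bootstrap(dt, settings = fast_settings(), B = 3, seed = 1),
               class = "ecobnet_usage_error")
})

test_that("the ensemble is reproducible from its master seed", {
  dt <- make_signal_dtable(50, 72)
  e1 <- run_bootstrap(dt, settings = fast_settings(), B = 6, seed = 9)
  e2 <- run_bootstrap(dt, settings = fast_settings(), B = 6, seed = 9)
  expect_identical(e1$indices, e2$indices)
  for (b in seq_len(e1$B))
    expect_identical(e1$dags[[b]]$parents, e2$dags[[b]]$parents)
  e3 <- run_bootstrap(dt, settings = fast_settings(), B = 6, seed = 10)
  expect_false(identical(e1$indices, e3$indices))
})

test_that("edge occurrence is invariant to replicate order", {
  dt <- make_signal_dtable(60, 73)
  ens <- run_bootstrap(dt, settings = fast_settings(), B = 8, seed = 3)
  stats1 <- edge_stats(ens)
  perm <- sample(ens$B)
  ens_perm <- ens
  ens_perm$dags <- ens$dags[perm]
  ens_perm$indices <- ens$indices[perm]
  stats2 <- edge_stats(ens_perm)
  expect_equal(stats1$occurrence, stats2$occurrence)
  expect_equal(stats1$forward_fraction, stats2$forward_fraction)
})

test_that("mixture threshold separates a bimodal occurrence distribution", {
  set.seed(80)
  occ <- c(rnorm(30, 0.10, 0.03), rnorm(10, 0.90, 0.03))
  thr <- occurrence_threshold(occ)
  expect_gt(thr, max(occ[1:30]))
  expect_lt(thr, min(occ[31:40]))
  # equal-variance crossing has a closed form:
  # x = (mu1+mu2)/2 + sigma^2 * log(pi1/pi2) / (mu2-mu1)
  expect_equal(ecobnet:::gaussian_crossing(c(0.10, 0.90), c(0.03, 0.03),
                                           c(0.75, 0.25)),
               0.5 + 0.03^2 * log(3) / 0.8, tolerance = 1e-10)
  # degenerate cases fall back to simple majority
  expect_equal(occurrence_threshold(rep(0.7, 10)), 0.5)
})

test_that("direction rule maps forward fractions to edge types", {
  dt <- make_signal_dtable(60, 74)
  ens <- run_bootstrap(dt, settings = fast_settings(), B = 10, seed = 5)
  # hand-crafted stats exercise the 0.4/0.6 boundaries through assembly
  fake <- ens
  dagf <- function(parents) new_dag(c("a", "b", "c"), parents)
  fake$B <- 10
  fake$dags <- c(replicate(7, dagf(list(b = "a")), simplify = FALSE),
                 replicate(3, dagf(list(a = "b")), simplify = FALSE))
  fake$indices <- replicate(10, 1:57, simplify = FALSE)
  net <- assemble_consensus(fake, dt, threshold = 0.5)
  expect_identical(net$edges$direction, "forward")   # 7/10 forward
  expect_equal(net$edges$occurrence, 1)

  fake$dags <- c(replicate(5, dagf(list(b = "a")), simplify = FALSE),
                 replicate(5, dagf(list(a = "b")), simplify = FALSE))
  net2 <- assemble_consensus(fake, dt, threshold = 0.5)
  expect_identical(net2$edges$direction, "mutual")   # 5/10 is in (0.4, 0.6)

  fake$dags <- c(replicate(4, dagf(list(b = "a")), simplify = FALSE),
                 replicate(6, dagf(list(a = "b")), simplify = FALSE))
  net3 <- assemble_consensus(fake, dt, threshold = 0.5)
  expect_identical(net3$edges$direction, "backward") # 4/10 forward
})

test_that("network summary matches the published property definitions", {
  # 8 connected nodes, 10 edges -> link density 1.25, connectance 10/56
  nodes <- sprintf("n%d", 1:8)
  edges <- data.frame(
    source = c("n1", "n1", "n2", "n2", "n3", "n4", "n5", "n5", "n6", "n7"),
    target = c("n2", "n3", "n3", "n4", "n5", "n6", "n6", "n7", "n8", "n8"),
    direction = "forward", occurrence = 0.9,
    mean_is = c(rep(0.4, 9), -0.2), stringsAsFactors = FALSE)
  net <- consensus_network(nodes, edges, threshold = 0.5)
  expect_equal(net$summary$link_density, 1.25)
  expect_equal(net$summary$connectance, 10 / (8 * 7))
  expect_equal(net$summary$nodes, 8L)
  expect_equal(net$summary$n_positive, 9L)
  expect_equal(net$summary$n_negative, 1L)
  expect_equal(net$summary$n_mutual, 0L)
})

test_that("chain statistics match the igraph path-enumeration oracle", {
  set.seed(90)
  for (i in 1:15) {
    net <- random_consensus_network(n_nodes = sample(4:9, 1),
                                    n_edges = sample(2:10, 1))
    mine <- chain_statistics(net)
    oracle <- igraph_chain_stats(net)
    expect_equal(mine$max_length, oracle$max_length)
    expect_equal(mine$n_chains, oracle$n_chains)
    expect_equal(mine$mean_length, oracle$mean_length)
  }
})

test_that("edges excluded by the prefilter have occurrence zero", {
  dt <- make_signal_dtable(80, 75)
  excl <- exclusion_set(excluded_pairs = data.frame(
    var1 = "a", var2 = "b", statistic = 0, df = 4, p_value = 1,
    stringsAsFactors = FALSE))
  ens <- run_bootstrap(dt, excl, fast_settings(), B = 10, seed = 6)
  stats <- edge_stats(ens)
  expect_false(any(stats$var1 == "a" & stats$var2 == "b"))
})
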