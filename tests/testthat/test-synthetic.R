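test_that("ground truth generation is deterministic and respects limits", {
  g1 <- simulate_ground_truth(n_taxa = 5, n_edges = 6, seed = 7)
  g2 <- simulate_ground_truth(n_taxa = 5, n_edges = 6, seed = 7)
  expect_identical(dag_edges(g1$dag), dag_edges(g2$dag))
  expect_identical(g1$cpts$cpts, g2$cpts$cpts)
  g3 <- simulate_ground_truth(n_taxa = 5, n_edges = 6, seed = 8)
  expect_false(identical(dag_edges(g1$dag), dag_edges(g3$dag)))
  expect_error(simulate_ground_truth(n_taxa = 2, n_edges = 7),
               class = "ecobnet_usage_error")
  expect_error(simulate_ground_truth(lambda = 1.5),
               class = "ecobnet_usage_error")
  expect_true(all(lengths(g1$dag$parents) <= 3L))
})

test_that("lambda spans no-signal to full-signal CPTs", {
  g0 <- simulate_ground_truth(n_taxa = 4, n_edges = 4, lambda = 0, seed = 3)
  for (e in seq_len(nrow(g0$edge_signs)))
    expect_equal(influence_score(g0$cpts, g0$edge_signs$from[e],
                                 g0$edge_signs$to[e]), 0)
  g1 <- simulate_ground_truth(n_taxa = 2, n_edges = 1, lambda = 1, seed = 4)
  expect_equal(influence_score(g1$cpts, g1$edge_signs$from[1],
                               g1$edge_signs$to[1]), 1)
  gneg <- simulate_ground_truth(n_taxa = 2, n_edges = 1, lambda = 1, seed = 4,
                                signs = -1)
  expect_equal(influence_score(gneg$cpts, gneg$edge_signs$from[1],
                               gneg$edge_signs$to[1]), -1)
})

test_that("state 0 never emits a positive count", {
  gt <- simulate_ground_truth(n_taxa = 6, n_edges = 7, seed = 5)
  tab <- sample_community(gt, n_photos = 500, photos_per_event = 25, seed = 6)
  latent <- attr(tab, "latent_states")
  taxa <- tab$specs$name[tab$specs$role == "taxon"]
  for (v in taxa) {
    expect_true(all(tab$values[[v]][latent[, v] == 0L] == 0L))
    expect_true(all(tab$values[[v]][latent[, v] > 0L] > 0L))
  }
})

test_that("event layout and grouping arithmetic match the survey design", {
  gt <- simulate_ground_truth(n_taxa = 3, n_edges = 3, seed = 9)
  tab <- sample_community(gt, n_photos = 525, photos_per_event = 25, seed = 2)
  expect_length(unique(tab$grouping), 21L)
  ev <- aggregate_events(tab)
  expect_length(ev$sample_ids, 21L)
  expect_error(sample_community(gt, n_photos = 523, photos_per_event = 25),
               class = "ecobnet_usage_error")
  # substrate and depth are shared within an event
  for (e in unique(tab$grouping)) {
    idx <- which(unname(tab$grouping) == e)
    expect_length(unique(tab$values$substrate[idx]), 1L)
    expect_length(unique(tab$values$depth[idx] %/% 125), 1L)
  }
})

test_that("a 0.85 zero-state marginal emits about 85% zero cells", {
  # parent-free taxa with zero_hi = zero_lo pin the state-0 marginal exactly
  gt <- simulate_ground_truth(n_taxa = 4, n_edges = 0, lambda = 1, seed = 12,
                              include_depth = FALSE,
                              zero_hi = 0.85, zero_lo = 0.85)
  for (v in sprintf("taxon%02d", 1:4))
    expect_equal(gt$cpts$marginals[[v]][1], 0.85, tolerance = 1e-12)
  tab <- sample_community(gt, n_photos = 2500, photos_per_event = 25, seed = 13)
  expect_equal(zero_fraction(tab), 0.85, tolerance = 0.02)  # 10,000 cells
})

test_that("discretization recovers latent states from disjoint emission ranges", {
  # balanced case: equally many low-range and high-range counts put the
  # positive median exactly between the ranges, so recovery is exact
  counts <- c(0L, 0L, 1L, 2L, 3L, 4L, 5L, 8L, 12L, 20L)
  latent <- c(0L, 0L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L)
  d <- discretize_counts(counts)
  expect_equal(d$boundary, 4.5)
  expect_identical(d$states, latent)

  # sampled communities: zero states recover exactly, and overall latent
  # agreement stays high even when the low/high split is not balanced
  gt <- simulate_ground_truth(n_taxa = 4, n_edges = 0, lambda = 1, seed = 20,
                              include_depth = FALSE,
                              zero_hi = 0.5, zero_lo = 0.5)
  tab <- sample_community(gt, n_photos = 1000, photos_per_event = 25, seed = 21)
  latent_m <- attr(tab, "latent_states")
  dt <- discretize_table(tab)
  for (v in sprintf("taxon%02d", 1:4)) {
    expect_identical(unname(dt$states[, v] == 0L), unname(latent_m[, v] == 0L))
    expect_gte(mean(dt$states[, v] == latent_m[, v]), 0.95)
  }
})

test_that("recovery metrics follow the stated conventions", {
  gt <- simulate_ground_truth(n_taxa = 4, n_edges = 4, seed = 30,
                              include_depth = FALSE)
  truth_edges <- gt$edge_signs
  perfect <- consensus_network(gt$dag$nodes, data.frame(
    source = truth_edges$from, target = truth_edges$to, direction = "forward",
    occurrence = 1, mean_is = 1, stringsAsFactors = FALSE))
  m <- recovery_metrics(perfect, gt)
  expect_equal(m$edge_precision, 1)
  expect_equal(m$edge_recall, 1)
  expect_equal(m$f1, 1)
  expect_equal(m$direction_accuracy, 1)

  empty <- consensus_network(gt$dag$nodes, data.frame(
    source = character(0), target = character(0), direction = character(0),
    occurrence = numeric(0), mean_is = numeric(0), stringsAsFactors = FALSE))
  m0 <- recovery_metrics(empty, gt)
  expect_equal(m0$edge_precision, 1)  # no false positives by convention
  expect_equal(m0$edge_recall, 0)
  expect_equal(m0$f1, 0)

  wrong <- consensus_network(gt$dag$nodes, data.frame(
    source = "substrate", target = "substrate_fake", direction = "forward",
    occurrence = 1, mean_is = 1, stringsAsFactors = FALSE))
  expect_equal(recovery_metrics(wrong, gt)$edge_precision, 0)
})

test_that("f1 is the harmonic mean of precision and recall", {
  gt <- simulate_ground_truth(n_taxa = 4, n_edges = 4, seed = 31,
                              include_depth = FALSE)
  truth_edges <- gt$edge_signs
  # keep half the true edges, add one false edge
  mixed <- consensus_network(gt$dag$nodes, data.frame(
    source = c(truth_edges$from[1:2], "zzfake"),
    target = c(truth_edges$to[1:2], "zzfake2"),
    direction = "forward", occurrence = 1, mean_is = 1,
    stringsAsFactors = FALSE))
  m <- recovery_metrics(mixed, gt)
  expect_equal(m$f1, 2 * m$edge_precision * m$edge_recall /
                 (m$edge_precision + m$edge_recall))
})
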