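# two-node fixture used across the Bayes-inversion cases:
# P(child | parent) rows = parent states; marginal of parent is 0.5/0.5
two_node_cpts <- function() {
  make_cptset(
    c("child", "parent"), c(child = 2, parent = 2),
    list(parent = character(0), child = "parent"),
    list(parent = matrix(c(0.5, 0.5), 1, 2),
         child = matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)),
    list(parent = c(0.5, 0.5), child = c(0.55, 0.45)))
}

two_node_net <- function() consensus_network(
  c("child", "parent"),
  data.frame(source = "child", target = "parent", direction = "backward",
             occurrence = 1, mean_is = 0.6, stringsAsFactors = FALSE))

test_that("chains are shortest undirected paths with lexicographic ties", {
  mk_net <- function(pairs) consensus_network(
    unique(c(pairs)), data.frame(source = pairs[, 1], target = pairs[, 2],
                                 direction = "forward", occurrence = 1,
                                 mean_is = 0.5, stringsAsFactors = FALSE))
  direct <- mk_net(rbind(c("A", "B")))
  expect_identical(find_chain(direct, "A", "B")$nodes, c("A", "B"))

  via_c <- mk_net(rbind(c("A", "C"), c("B", "C")))
  expect_identical(find_chain(via_c, "A", "B")$nodes, c("A", "C", "B"))

  two_paths <- mk_net(rbind(c("A", "C"), c("B", "C"), c("A", "D"), c("B", "D")))
  expect_identical(find_chain(two_paths, "A", "B")$nodes, c("A", "C", "B"))

  disconnected <- mk_net(rbind(c("A", "B"), c("C", "D")))
  expect_error(find_chain(disconnected, "A", "D"),
               class = "ecobnet_no_chain_error")
})

test_that("a single along-edge step reproduces the CPT row", {
  cpts <- two_node_cpts()
  net <- two_node_net()
  chain <- find_chain(net, "parent", "child")
  expect_equal(propagate(chain, cpts, 0), c(0.9, 0.1))
  expect_equal(propagate(chain, cpts, 1), c(0.2, 0.8))
})

test_that("an against-edge step applies the Bayes inversion", {
  cpts <- two_node_cpts()
  net <- two_node_net()
  chain <- find_chain(net, "child", "parent")
  # forcing child = 1: P(parent = 1 | child = 1) = 0.8 / (0.1 + 0.8) = 8/9
  expect_equal(propagate(chain, cpts, 1), c(1 / 9, 8 / 9), tolerance = 1e-12)
  # forcing child = 0: P(parent = 1 | child = 0) = 0.2 / (0.9 + 0.2)
  expect_equal(propagate(chain, cpts, 0), c(0.9 / 1.1, 0.2 / 1.1),
               tolerance = 1e-12)
})

test_that("state change reports carry zero-sum shifts and the hand-computed contrast", {
  cpts <- two_node_cpts()
  net <- two_node_net()
  rep_ <- state_change_report(net, cpts, "child", 1, 0)
  tg <- rep_$targets[rep_$targets$target == "parent", ]
  # delta p(parent = 1) = 0.2/1.1 - 8/9
  expect_equal(tg$delta_p[tg$state == 1], 0.2 / 1.1 - 8 / 9, tolerance = 1e-12)
  expect_equal(sum(tg$delta_p), 0, tolerance = 1e-9)
  expect_equal(rep_$mean_delta_p, mean(abs(tg$delta_p)), tolerance = 1e-12)
})

test_that("three-node chain propagation equals exact joint conditioning", {
  set.seed(110)
  for (i in 1:10) {
    # A -> C -> B with random 3-state CPTs
    pl <- list(A = matrix(random_dirichlet_row(3), 1, 3),
               C = t(vapply(1:3, function(j) random_dirichlet_row(3), numeric(3))),
               B = t(vapply(1:3, function(j) random_dirichlet_row(3), numeric(3))))
    parents <- list(A = character(0), C = "A", B = "C")
    jt <- joint_table(c("A", "C", "B"), c(A = 3, C = 3, B = 3), parents, pl)
    marg <- lapply(c("A", "C", "B"), function(v)
      vapply(0:2, function(s) sum(jt$p[jt$grid[, v] == s]), numeric(1)))
    names(marg) <- c("A", "C", "B")
    cpts <- make_cptset(c("A", "C", "B"), c(A = 3, C = 3, B = 3), parents, pl,
                        marg)
    net <- consensus_network(c("A", "B", "C"), data.frame(
      source = c("A", "B"), target = c("C", "C"),
      direction = c("forward", "backward"), occurrence = 1, mean_is = 0.5,
      stringsAsFactors = FALSE))
    chain <- find_chain(net, "A", "B")
    for (s in 0:2)
      expect_equal(propagate(chain, cpts, s),
                   exact_conditional(cpts, "A", "B", s), tolerance = 1e-10)
  }
})

test_that("propagation yields valid distributions on random directed trees", {
  set.seed(111)
  for (i in 1:20) {
    cpts <- random_tree_cptset(sample(3:7, 1))
    nodes <- cpts$dag$nodes
    e <- dag_edges(cpts$dag)
    net <- consensus_network(nodes, data.frame(
      source = e$from, target = e$to, direction = "forward",
      occurrence = 1, mean_is = 0.5, stringsAsFactors = FALSE))
    pick <- sample(nodes, 2)
    chain <- find_chain(net, pick[1], pick[2])
    for (s in 0:2) expect_distribution(propagate(chain, cpts, s))
  }
})

test_that("unconnected targets report zero shift and stay out of the mean", {
  cpts <- make_cptset(
    c("a", "b", "c"), c(a = 2, b = 2, c = 2),
    list(a = character(0), b = "a", c = character(0)),
    list(a = matrix(c(0.5, 0.5), 1, 2),
         b = matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE),
         c = matrix(c(0.5, 0.5), 1, 2)),
    list(a = c(0.5, 0.5), b = c(0.55, 0.45), c = c(0.5, 0.5)))
  net <- consensus_network(c("a", "b", "c"), data.frame(
    source = "a", target = "b", direction = "forward", occurrence = 1,
    mean_is = 0.5, stringsAsFactors = FALSE))
  rep_ <- state_change_report(net, cpts, "a", 1, 0)
  un <- rep_$targets[rep_$targets$target == "c", ]
  expect_equal(un$delta_p, c(0, 0))
  expect_false(any(un$connected))
  con <- rep_$targets[rep_$targets$target == "b", ]
  expect_equal(rep_$mean_delta_p, mean(abs(con$delta_p)))
})

test_that("substrate contrasts resolve labels and are swap-symmetric", {
  cpts <- make_cptset(
    c("substrate", "tx"), c(substrate = 3, tx = 3),
    list(substrate = character(0), tx = "substrate"),
    list(substrate = matrix(1 / 3, 1, 3),
         tx = matrix(c(0.7, 0.2, 0.1, 0.3, 0.4, 0.3, 0.1, 0.2, 0.7),
                     3, 3, byrow = TRUE)),
    list(substrate = rep(1 / 3, 3), tx = rep(1 / 3, 3)),
    state_labels = list(substrate = c("Gravel", "Rocky", "Silt")))
  net <- consensus_network(c("substrate", "tx"), data.frame(
    source = "substrate", target = "tx", direction = "forward",
    occurrence = 1, mean_is = 0.8, stringsAsFactors = FALSE))
  ab <- substrate_contrast(net, cpts, "substrate", "Silt", "Rocky")
  ba <- substrate_contrast(net, cpts, "substrate", "Rocky", "Silt")
  expect_equal(ab, ba, tolerance = 1e-12)
  expect_gt(ab, 0)
  expect_error(substrate_contrast(net, cpts, "substrate", "Sand", "Silt"),
               class = "ecobnet_usage_error")
  # a substrate with no connections shifts nothing
  net0 <- consensus_network(c("substrate", "tx"), data.frame(
    source = character(0), target = character(0), direction = character(0),
    occurrence = numeric(0), mean_is = numeric(0), stringsAsFactors = FALSE))
  expect_equal(substrate_contrast(net0, cpts, "substrate", "Silt", "Rocky"), 0)
})

test_that("probability shifts attenuate along noisy-copy chains", {
  # homogeneous chain of noisy-copy CPTs: the shift from forcing the head
  # must not grow with distance
  noisy <- matrix(c(0.8, 0.15, 0.05,
                    0.15, 0.7, 0.15,
                    0.05, 0.15, 0.8), 3, 3, byrow = TRUE)
  n_nodes <- 6
  nodes <- sprintf("n%d", seq_len(n_nodes))
  parents <- c(list(character(0)),
               lapply(seq_len(n_nodes - 1), function(i) nodes[i]))
  names(parents) <- nodes
  pl <- c(list(matrix(1 / 3, 1, 3)), replicate(n_nodes - 1, noisy,
                                               simplify = FALSE))
  names(pl) <- nodes
  jt <- joint_table(nodes, setNames(rep(3, n_nodes), nodes), parents, pl)
  marg <- lapply(nodes, function(v)
    vapply(0:2, function(s) sum(jt$p[jt$grid[, v] == s]), numeric(1)))
  names(marg) <- nodes
  cpts <- make_cptset(nodes, setNames(rep(3, n_nodes), nodes), parents, pl, marg)
  net <- consensus_network(nodes, data.frame(
    source = nodes[-n_nodes], target = nodes[-1], direction = "forward",
    occurrence = 1, mean_is = 0.9, stringsAsFactors = FALSE))
  shifts <- vapply(nodes[-1], function(tg) {
    chain <- find_chain(net, nodes[1], tg)
    max(abs(propagate(chain, cpts, 2) - propagate(chain, cpts, 0)))
  }, numeric(1))
  expect_true(all(diff(shifts) <= 1e-9))
})

test_that("inference reports round-trip to JSON and TSV", {
  cpts <- two_node_cpts()
  net <- two_node_net()
  rep_ <- state_change_report(net, cpts, "child", 1, 0)
  json <- withr::local_tempfile(fileext = ".json")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep_, json, tsv)
  raw <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(raw$mean_delta_p, rep_$mean_delta_p, tolerance = 1e-12)
  tab <- read.delim(tsv)
  expect_identical(names(tab), c("target", "state", "p_from", "p_to", "delta_p"))
})
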