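test_that("BDeu matches the closed-form single-variable marginal likelihood", {
  # binary variable, counts 3 ones / 1 zero, ess 1:
  # Gamma(1)/Gamma(5) * Gamma(3.5)Gamma(1.5)/Gamma(0.5)^2 = 0.0390625
  dt <- make_dtable(cbind(x = c(1L, 1L, 1L, 0L)), arity = 2)
  dag <- new_dag("x")
  expect_equal(bde_score(dt, dag, ess = 1), log(0.0390625), tolerance = 1e-9)
})

test_that("BDeu agrees with an independent R implementation on random data", {
  set.seed(55)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    states <- cbind(a = sample(0:2, n, TRUE), b = sample(0:1, n, TRUE),
                    c = sample(0:3, n, TRUE))
    dt <- make_dtable(states, arity = c(3, 2, 4))
    dag <- new_dag(c("a", "b", "c"),
                   list(b = "a", c = c("a", "b")))
    ess <- sample(c(1, 2, 10), 1)
    expected <- r_bdeu_family(states[, "a"], NULL, 3L, integer(0), ess) +
      r_bdeu_family(states[, "b"], states[, "a", drop = FALSE], 2L, 3L, ess) +
      r_bdeu_family(states[, "c"], states[, c("a", "b")], 4L, c(3L, 2L), ess)
    expect_equal(bde_score(dt, dag, ess), expected, tolerance = 1e-8)
  }
})

test_that("the score is decomposable and invariant to row permutation", {
  set.seed(56)
  states <- cbind(a = sample(0:2, 40, TRUE), b = sample(0:2, 40, TRUE))
  dt <- make_dtable(states, arity = c(3, 3))
  dag <- new_dag(c("a", "b"), list(b = "a"))
  s_ab <- bde_score(dt, dag)
  # family decomposition: score(a) + score(b | a), families scored separately
  s_a <- bde_score(make_dtable(states[, "a", drop = FALSE], 3), new_dag("a"))
  s_b_given_a <- r_bdeu_family(states[, "b"], states[, "a", drop = FALSE],
                               3L, 3L, 1)
  expect_equal(s_ab, s_a + s_b_given_a, tolerance = 1e-10)
  perm <- sample(40)
  dt_perm <- make_dtable(states[perm, ], arity = c(3, 3))
  expect_equal(bde_score(dt_perm, dag), s_ab, tolerance = 1e-10)
  # empty-graph score is the sum of single-variable scores
  s_b <- bde_score(make_dtable(states[, "b", drop = FALSE], 3), new_dag("b"))
  expect_equal(bde_score(dt, new_dag(c("a", "b"))), s_a + s_b,
               tolerance = 1e-10)
})

test_that("independent variables yield the empty DAG, dependent ones an edge", {
  set.seed(60)
  a <- sample(0:1, 500, TRUE)
  b <- sample(0:1, 500, TRUE)
  dt <- make_dtable(cbind(a = a, b = b), arity = c(2, 2))
  # score oracle: independence must beat the edge before greedy is trusted
  expect_gt(bde_score(dt, new_dag(c("a", "b"))),
            bde_score(dt, new_dag(c("a", "b"), list(b = "a"))))
  dag <- greedy_search(dt, settings = search_settings(n_iterations = 5000,
                                                      n_restarts = 5, seed = 1))
  expect_equal(nrow(dag_edges(dag)), 0L)

  # deterministic copy: one edge between the pair
  x <- sample(0:1, 200, TRUE)
  dt2 <- make_dtable(cbind(a = x, b = x), arity = c(2, 2))
  expect_gt(bde_score(dt2, new_dag(c("a", "b"), list(b = "a"))),
            bde_score(dt2, new_dag(c("a", "b"))))
  dag2 <- greedy_search(dt2, settings = search_settings(n_iterations = 5000,
                                                        n_restarts = 5, seed = 1))
  expect_equal(nrow(dag_edges(dag2)), 1L)
})

test_that("search respects constraints, determinism and the empty-DAG floor", {
  set.seed(61)
  x <- sample(0:1, 200, TRUE)
  dt <- make_dtable(cbind(a = x, b = x, c = sample(0:1, 200, TRUE)),
                    arity = c(2, 2, 2))
  excl <- exclusion_set(excluded_pairs = data.frame(
    var1 = "a", var2 = "b", statistic = 0, df = 1, p_value = 1,
    stringsAsFactors = FALSE))
  dag <- greedy_search(dt, excl, search_settings(n_iterations = 5000,
                                                 n_restarts = 10, seed = 3))
  e <- dag_edges(dag)
  expect_false(any((e$from == "a" & e$to == "b") |
                   (e$from == "b" & e$to == "a")))
  # reproducible bit-for-bit from seed
  dag_again <- greedy_search(dt, excl, search_settings(n_iterations = 5000,
                                                       n_restarts = 10, seed = 3))
  expect_identical(dag$parents, dag_again$parents)
  expect_identical(attr(dag, "score"), attr(dag_again, "score"))
  # never below the empty DAG
  expect_gte(attr(dag, "score") + 1e-9, bde_score(dt, new_dag(dt$vars)))

  # all pairs excluded -> empty DAG with a warning
  excl_all <- exclusion_set(excluded_pairs = data.frame(
    var1 = c("a", "a", "b"), var2 = c("b", "c", "c"),
    statistic = 0, df = 1, p_value = 1, stringsAsFactors = FALSE))
  expect_warning(dag0 <- greedy_search(dt, excl_all),
                 class = "ecobnet_search_warning")
  expect_equal(nrow(dag_edges(dag0)), 0L)
})

test_that("parent cap and acyclicity are enforced in learned DAGs", {
  set.seed(62)
  n <- 300
  root <- sample(0:2, n, TRUE)
  kids <- vapply(1:5, function(i)
    (root + sample(0:1, n, TRUE, prob = c(0.85, 0.15))) %% 3L,
    integer(n))
  states <- cbind(root = root, kids)
  colnames(states) <- c("root", paste0("k", 1:5))
  dt <- make_dtable(states, arity = rep(3, 6))
  dag <- greedy_search(dt, settings = search_settings(n_iterations = 20000,
                                                      n_restarts = 10, seed = 4,
                                                      max_parents = 2))
  expect_true(all(lengths(dag$parents) <= 2L))
  expect_s3_class(dag, "bn_dag")  # new_dag validates acyclicity on build
})

test_that("greedy with restarts attains the exhaustive 3-node optimum", {
  set.seed(63)
  hits <- 0L
  for (i in 1:30) {
    n <- sample(15:50, 1)
    a <- sample(0:1, n, TRUE)
    b <- (a + sample(0:1, n, TRUE, prob = c(0.7, 0.3))) %% 2L
    c_ <- sample(0:1, n, TRUE)
    dt <- make_dtable(cbind(a = a, b = b, c = c_), arity = c(2, 2, 2))
    ex <- exhaustive_search(dt)
    expect_equal(ex$n_dags, 25L)
    dag <- greedy_search(dt, settings = search_settings(n_iterations = 50000,
                                                        n_restarts = 25, seed = i))
    if (abs(attr(dag, "score") - ex$best_score) < 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, 29L)
})
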