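# Independent oracles and fixture builders shared by the test files.
# These deliberately re-derive quantities by different routes than the
# package implementation (closed forms, exhaustive enumeration, igraph).

# --- fixture builders -------------------------------------------------------

# hand-built discretized table (0-based states)
make_dtable <- function(states, arity, roles = NULL, boundaries = NULL) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  vars <- colnames(states)
  if (is.null(vars)) {
    vars <- paste0("v", seq_len(ncol(states)))
    colnames(states) <- vars
  }
  if (is.null(roles)) roles <- setNames(rep("taxon", length(vars)), vars)
  structure(list(
    sample_ids = sprintf("s%04d", seq_len(nrow(states))),
    vars = vars, states = states,
    arity = setNames(as.integer(arity), vars),
    boundaries = boundaries, roles = roles),
    class = "discretized_table")
}

# hand-built CPT set; prob_list maps node -> (q x r) row-stochastic matrix,
# parents_list maps node -> parent names, marginals maps node -> vector
make_cptset <- function(nodes, arity, parents_list, prob_list, marginals,
                        state_labels = list()) {
  cpts <- lapply(nodes, function(v) {
    pa <- if (is.null(parents_list[[v]])) character(0) else parents_list[[v]]
    list(child = v, parents = pa, child_arity = arity[[v]],
         parent_arities = if (length(pa)) as.integer(arity[pa]) else integer(0),
         prob = prob_list[[v]], alpha = 0)
  })
  names(cpts) <- nodes
  dag <- new_dag(nodes, parents_list, max_parents = 8L)
  structure(list(cpts = cpts, marginals = marginals,
                 arity = setNames(as.integer(arity[nodes]), nodes), dag = dag,
                 alpha = 0, state_labels = state_labels),
            class = "cpt_set")
}

random_dirichlet_row <- function(k) {
  g <- rgamma(k, shape = 1)
  g / sum(g)
}

# random directed tree (every non-root node has exactly one parent) with
# random Dirichlet CPTs; marginals are made exactly consistent with the
# joint by enumeration so Bayes inversion is exact
random_tree_cptset <- function(n_nodes, arity = 3L) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  ord <- sample(nodes)
  parents_list <- setNames(vector("list", n_nodes), nodes)
  for (i in seq_along(ord)) parents_list[[ord[i]]] <-
    if (i == 1L) character(0) else ord[sample.int(i - 1L, 1L)]
  ar <- setNames(rep(as.integer(arity), n_nodes), nodes)
  prob_list <- list()
  for (v in nodes) {
    q <- if (length(parents_list[[v]])) arity else 1L
    prob_list[[v]] <- t(vapply(seq_len(q), function(i) random_dirichlet_row(arity),
                               numeric(arity)))
  }
  joint <- joint_table(nodes, ar, parents_list, prob_list)
  marg <- lapply(nodes, function(v)
    vapply(0:(ar[[v]] - 1L), function(s) sum(joint$p[joint$grid[, v] == s]),
           numeric(1)))
  names(marg) <- nodes
  make_cptset(nodes, ar, parents_list, prob_list, marg)
}

# --- exact-inference oracle -------------------------------------------------

joint_table <- function(nodes, arity, parents_list, prob_list) {
  grid <- as.matrix(do.call(expand.grid,
    setNames(lapply(nodes, function(v) 0:(arity[[v]] - 1L)), nodes)))
  p <- rep(1, nrow(grid))
  for (v in nodes) {
    pa <- parents_list[[v]]
    idx <- rep(1L, nrow(grid))
    for (u in if (is.null(pa)) character(0) else pa)
      idx <- (idx - 1L) * arity[[u]] + grid[, u] + 1L
    p <- p * prob_list[[v]][cbind(idx, grid[, v] + 1L)]
  }
  list(grid = grid, p = p)
}

# exact P(target | source = s) by joint enumeration
exact_conditional <- function(cptset, source, target, source_state) {
  nodes <- cptset$dag$nodes
  prob_list <- lapply(cptset$cpts, `[[`, "prob")
  parents_list <- cptset$dag$parents
  jt <- joint_table(nodes, cptset$arity, parents_list, prob_list)
  sel <- jt$grid[, source] == source_state
  w <- jt$p[sel]
  tg <- jt$grid[sel, target]
  vapply(0:(cptset$arity[[target]] - 1L),
         function(s) sum(w[tg == s]) / sum(w), numeric(1))
}

# --- independent BDeu family score (plain R, direct lgamma formula) ---------

r_bdeu_family <- function(child_states, parent_state_matrix, r, parent_arities,
                          ess) {
  q <- prod(c(1L, parent_arities))
  idx <- rep(1L, length(child_states))
  if (!is.null(parent_state_matrix) && ncol(parent_state_matrix) > 0) {
    for (t in seq_len(ncol(parent_state_matrix)))
      idx <- (idx - 1L) * parent_arities[t] + parent_state_matrix[, t] + 1L
  }
  ajk <- ess / (q * r); aj <- ess / q
  total <- 0
  for (j in seq_len(q)) {
    nj <- sum(idx == j)
    if (nj == 0) next
    total <- total + lgamma(aj) - lgamma(aj + nj)
    for (k in 0:(r - 1L)) {
      njk <- sum(idx == j & child_states == k)
      if (njk > 0) total <- total + lgamma(ajk + njk) - lgamma(ajk)
    }
  }
  total
}

# --- chain-statistics oracle via igraph simple-path machinery ---------------

igraph_chain_stats <- function(network) {
  e <- network$edges
  if (nrow(e) == 0L)
    return(list(max_length = 0L, n_chains = 0L, mean_length = NA_real_))
  g <- igraph::graph_from_data_frame(e[, c("source", "target")],
                                     directed = FALSE)
  vs <- igraph::V(g)$name
  best <- list()
  for (v in vs) {
    paths <- igraph::all_simple_paths(g, from = v)
    for (pth in paths) {
      names_pth <- igraph::V(g)$name[as.integer(pth)]
      len <- length(names_pth) - 1L
      if (len < 2L) next
      ends <- c(names_pth[1L], names_pth[length(names_pth)])
      nb1 <- igraph::V(g)$name[as.integer(igraph::neighbors(g, ends[1L]))]
      nb2 <- igraph::V(g)$name[as.integer(igraph::neighbors(g, ends[2L]))]
      if (length(setdiff(nb1, names_pth)) > 0L) next
      if (length(setdiff(nb2, names_pth)) > 0L) next
      key <- paste(sort(ends), collapse = "|")
      if (is.null(best[[key]]) || best[[key]] < len) best[[key]] <- len
    }
  }
  if (length(best) == 0L)
    return(list(max_length = 0L, n_chains = 0L, mean_length = NA_real_))
  lens <- unlist(best)
  list(max_length = max(lens), n_chains = length(lens),
       mean_length = mean(lens))
}

# --- misc -------------------------------------------------------------------

random_consensus_network <- function(n_nodes = 6, n_edges = 5) {
  nodes <- sprintf("node%02d", seq_len(n_nodes))
  pairs <- t(utils::combn(nodes, 2))
  pick <- pairs[sample.int(nrow(pairs), min(n_edges, nrow(pairs))), ,
                drop = FALSE]
  edges <- data.frame(
    source = pick[, 1], target = pick[, 2],
    direction = sample(c("forward", "backward", "mutual"), nrow(pick),
                       replace = TRUE),
    occurrence = round(runif(nrow(pick), 0.4, 1), 6),
    mean_is = round(runif(nrow(pick), -1, 1), 6),
    stringsAsFactors = FALSE)
  consensus_network(nodes, edges, threshold = 0.5)
}

expect_distribution <- function(p, tol = 1e-9) {
  expect_true(all(p >= -tol))
  expect_equal(sum(p), 1, tolerance = tol)
}
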