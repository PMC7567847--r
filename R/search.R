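#' Construct a directed acyclic graph over named nodes
#'
#' @param nodes character vector of variable names.
#' @param parents named list mapping each node to its parent names; nodes
#'   absent from the list have no parents.
#' @param max_parents parent cap (default 3, which limits artefactual dense
#'   families in small zero-inflated data sets).
#' @return An object of class `bn_dag`.
#' @export
new_dag <- function(nodes, parents = list(), max_parents = 3L) {
  full <- setNames(vector("list", length(nodes)), nodes)
  for (nm in nodes) full[[nm]] <- character(0)
  for (nm in names(parents)) {
    if (!nm %in% nodes)
      abort_ecobnet(sprintf("unknown node '%s' in parent list", nm), "ecobnet_usage_error")
    pa <- as.character(parents[[nm]])
    if (!all(pa %in% nodes))
      abort_ecobnet(sprintf("unknown parent(s) of '%s'", nm), "ecobnet_usage_error")
    if (length(pa) > max_parents)
      abort_ecobnet(sprintf("node '%s' exceeds the parent cap of %d", nm, max_parents),
                    "ecobnet_usage_error")
    full[[nm]] <- pa
  }
  dag <- structure(list(nodes = nodes, parents = full,
                        max_parents = as.integer(max_parents)),
                   class = "bn_dag")
  if (!dag_is_acyclic(dag))
    abort_ecobnet("parent lists contain a directed cycle", "ecobnet_usage_error")
  dag
}

#' @export
print.bn_dag <- function(x, ...) {
  e <- dag_edges(x)
  cat(sprintf("bn_dag: %d nodes, %d edges (parent cap %d)\n",
              length(x$nodes), nrow(e), x$max_parents))
  if (nrow(e) > 0)
    cat(paste(sprintf("  %s -> %s", e$from, e$to), collapse = "\n"), "\n")
  invisible(x)
}

#' Edge list of a DAG
#' @param dag a `bn_dag`.
#' @return Data frame with columns `from`, `to`, sorted.
#' @export
dag_edges <- function(dag) {
  rows <- lapply(dag$nodes, function(v) {
    pa <- dag$parents[[v]]
    if (length(pa) == 0L) return(NULL)
    data.frame(from = pa, to = v, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(from = character(0), to = character(0), stringsAsFactors = FALSE))
  out[order(out$from, out$to), , drop = FALSE]
}

dag_is_acyclic <- function(dag) {
  # Kahn's algorithm on the parent lists
  indeg <- vapply(dag$parents, length, integer(1))
  children <- setNames(vector("list", length(dag$nodes)), dag$nodes)
  for (v in dag$nodes) for (u in dag$parents[[v]])
    children[[u]] <- c(children[[u]], v)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0L) {
    u <- queue[1L]; queue <- queue[-1L]; seen <- seen + 1L
    for (v in children[[u]]) {
      indeg[v] <- indeg[v] - 1L
      if (indeg[v] == 0L) queue <- c(queue, v)
    }
  }
  seen == length(dag$nodes)
}

#' Settings for the greedy structure search
#'
#' `n_iterations` is the total budget of proposal evaluations (candidate
#' single-edge moves scored), split across `n_restarts` random restarts;
#' restarts stop early once the budget is spent. The study-scale setting of
#' ten million proposals is configurable; the default of 50,000 is sized
#' for desk runs.
#'
#' @param n_iterations total proposal budget (>= 1).
#' @param n_restarts number of hill-climbing restarts; the first restart
#'   starts from the empty DAG, later ones from a random legal DAG.
#' @param ess equivalent sample size of the BDeu score prior (> 0).
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @param max_parents parent cap.
#' @param init_prob probability that a random restart includes each legal
#'   edge (before acyclicity repair).
#' @return A list of class `search_settings`.
#' @export
search_settings <- function(n_iterations = 50000, n_restarts = 50, ess = 1,
                            seed = NULL, max_parents = 3, init_prob = 0.1) {
  if (n_iterations < 1) abort_ecobnet("n_iterations must be >= 1", "ecobnet_usage_error")
  if (ess <= 0) abort_ecobnet("ess must be > 0", "ecobnet_usage_error")
  structure(list(n_iterations = n_iterations, n_restarts = as.integer(n_restarts),
                 ess = ess, seed = seed, max_parents = as.integer(max_parents),
                 init_prob = init_prob),
            class = "search_settings")
}

#' Log BDeu score of a DAG on discretized data
#'
#' The Bayesian Dirichlet equivalent uniform marginal likelihood with a
#' uniform structure prior: the score is the sum over nodes of the family
#' marginal likelihood under a Dirichlet prior with total pseudo-count
#' `ess` spread uniformly over the family's cells, so structures compare by
#' data likelihood alone.
#'
#' @param dtable a `discretized_table`.
#' @param dag a `bn_dag` whose nodes are a subset of the table variables.
#' @param ess equivalent sample size (default 1).
#' @return The log marginal likelihood (a single number, decomposable as a
#'   sum of per-family terms).
#' @export
bde_score <- function(dtable, dag, ess = 1) {
  stopifnot(inherits(dtable, "discretized_table"), inherits(dag, "bn_dag"))
  if (!all(dag$nodes %in% dtable$vars))
    abort_ecobnet("DAG contains nodes absent from the discretized table",
                  "ecobnet_usage_error")
  idx <- match(dag$nodes, dtable$vars)
  states <- dtable$states[, idx, drop = FALSE]
  arity <- unname(dtable$arity[idx])
  for (j in seq_along(idx)) {
    bad <- states[, j] < 0L | states[, j] >= arity[j]
    if (any(bad))
      abort_ecobnet(sprintf("variable '%s' has states outside its declared arity",
                            dag$nodes[j]), "ecobnet_validation_error")
  }
  parent_list <- lapply(dag$nodes, function(v)
    as.integer(match(dag$parents[[v]], dag$nodes) - 1L))
  cpp_bde_score(states, as.integer(arity), parent_list, ess)
}

#' Greedy hill-climbing structure search
#'
#' Steepest-ascent hill climbing over single-edge moves (add, delete,
#' reverse) scored by BDeu, under the parent cap and the excluded-pair
#' constraint, with random restarts. Only strictly improving moves are
#' accepted; ties between equal-scoring moves are broken by lexicographic
#' (source, target, move-type) order, so the search is deterministic given
#' the seed. The best-scoring DAG visited across all restarts is returned
#' and is never worse than the empty DAG.
#'
#' @param dtable a `discretized_table`.
#' @param constraint optional [exclusion_set()]; excluded pairs are barred
#'   as edges in either direction, and excluded variables are dropped.
#' @param settings a [search_settings()].
#' @return A `bn_dag` with attributes `score` (log BDeu), `proposals`
#'   (moves evaluated) and `restarts` (restarts run).
#' @export
greedy_search <- function(dtable, constraint = NULL,
                          settings = search_settings()) {
  stopifnot(inherits(dtable, "discretized_table"))
  vars <- dtable$vars
  if (!is.null(constraint) && nrow(constraint$excluded_variables) > 0L)
    vars <- setdiff(vars, constraint$excluded_variables$name)
  if (length(vars) < 2L)
    abort_ecobnet("fewer than two variables survive filtering", "ecobnet_usage_error")
  idx <- match(vars, dtable$vars)
  states <- dtable$states[, idx, drop = FALSE]
  arity <- as.integer(unname(dtable$arity[idx]))
  allowed <- matrix(TRUE, length(vars), length(vars))
  diag(allowed) <- FALSE
  if (!is.null(constraint)) {
    ep <- constraint$excluded_pairs
    for (k in seq_len(nrow(ep))) {
      i <- match(ep$var1[k], vars); j <- match(ep$var2[k], vars)
      if (!is.na(i) && !is.na(j)) allowed[i, j] <- allowed[j, i] <- FALSE
    }
  }
  if (!any(allowed)) {
    warn_ecobnet("all variable pairs are excluded: returning the empty DAG",
                 "ecobnet_search_warning")
    dag <- new_dag(vars, max_parents = settings$max_parents)
    attr(dag, "score") <- bde_score(dtable_subset_vars(dtable, vars), dag,
                                    settings$ess)
    attr(dag, "proposals") <- 0
    attr(dag, "restarts") <- 0L
    return(dag)
  }
  if (!is.null(settings$seed)) set.seed(settings$seed)
  res <- cpp_greedy_search(states, arity, allowed, settings$max_parents,
                           settings$n_restarts, settings$n_iterations,
                           settings$ess, settings$init_prob)
  parents <- setNames(lapply(res$parents, function(p) vars[p]), vars)
  dag <- new_dag(vars, parents, max_parents = settings$max_parents)
  attr(dag, "score") <- res$score
  attr(dag, "proposals") <- res$proposals
  attr(dag, "restarts") <- res$restarts
  dag
}

dtable_subset_vars <- function(dtable, vars) {
  idx <- match(vars, dtable$vars)
  structure(list(sample_ids = dtable$sample_ids, vars = vars,
                 states = dtable$states[, idx, drop = FALSE],
                 arity = dtable$arity[idx], boundaries = dtable$boundaries[vars],
                 roles = dtable$roles[idx]),
            class = "discretized_table")
}

#' Enumerate and score all DAGs on a small variable set
#'
#' Exhaustive search used as an optimality oracle for tiny problems (the 25
#' DAGs on three labelled nodes, for instance). Not intended for more than
#' five variables.
#'
#' @param dtable a `discretized_table` with few variables.
#' @param ess BDeu equivalent sample size.
#' @param max_parents parent cap.
#' @return A list with `best` (a `bn_dag`), `best_score`, and `n_dags`
#'   (number of DAGs enumerated).
#' @export
exhaustive_search <- function(dtable, ess = 1, max_parents = 3) {
  vars <- dtable$vars
  p <- length(vars)
  if (p > 5L) abort_ecobnet("exhaustive search limited to 5 variables",
                            "ecobnet_usage_error")
  pairs <- utils::combn(p, 2)
  npairs <- ncol(pairs)
  best <- NULL; best_score <- -Inf; n_dags <- 0L
  # each unordered pair is absent, forward, or backward: 3^npairs digraphs
  for (code in 0:(3^npairs - 1)) {
    digits <- integer(npairs); c0 <- code
    for (k in seq_len(npairs)) { digits[k] <- c0 %% 3L; c0 <- c0 %/% 3L }
    parents <- setNames(lapply(vars, function(v) character(0)), vars)
    for (k in seq_len(npairs)) {
      if (digits[k] == 1L)
        parents[[vars[pairs[2, k]]]] <- c(parents[[vars[pairs[2, k]]]], vars[pairs[1, k]])
      else if (digits[k] == 2L)
        parents[[vars[pairs[1, k]]]] <- c(parents[[vars[pairs[1, k]]]], vars[pairs[2, k]])
    }
    if (any(vapply(parents, length, integer(1)) > max_parents)) next
    dag <- tryCatch(new_dag(vars, parents, max_parents = max_parents),
                    ecobnet_usage_error = function(e) NULL)
    if (is.null(dag)) next
    n_dags <- n_dags + 1L
    s <- bde_score(dtable, dag, ess)
    if (s > best_score) { best_score <- s; best <- dag }
  }
  list(best = best, best_score = best_score, n_dags = n_dags)
}
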