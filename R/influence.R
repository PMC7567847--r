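#' Fit conditional probability tables for a DAG
#'
#' Each node's CPT is estimated by smoothed relative frequencies: for a
#' parent configuration with row total \eqn{n_j}, the probability of child
#' state \eqn{k} is \eqn{(n_{jk} + \alpha) / (n_j + \alpha r)} with child
#' arity \eqn{r}. The pseudo-count keeps every cell positive, which the
#' downstream Bayes inversion of [propagate()] relies on. Node marginals
#' are empirical state frequencies.
#'
#' @param dtable a `discretized_table`.
#' @param dag a `bn_dag` on (a subset of) the table variables.
#' @param alpha smoothing pseudo-count (default 1).
#' @return An object of class `cpt_set`: per-node CPTs (`$cpts`), empirical
#'   marginals (`$marginals`), arities, the DAG, and state labels for
#'   categorical variables when the table records them.
#' @export
fit_cpts <- function(dtable, dag, alpha = 1) {
  stopifnot(inherits(dtable, "discretized_table"), inherits(dag, "bn_dag"))
  if (!all(dag$nodes %in% dtable$vars))
    abort_ecobnet("DAG contains nodes absent from the discretized table",
                  "ecobnet_usage_error")
  n <- length(dtable$sample_ids)
  cpts <- list(); marginals <- list()
  for (v in dag$nodes) {
    r <- dtable$arity[[v]]
    child <- dtable$states[, v]
    pa <- dag$parents[[v]]
    pa_ar <- if (length(pa)) as.integer(dtable$arity[pa]) else integer(0)
    q <- prod(c(1L, pa_ar))
    counts <- matrix(0, nrow = q, ncol = r)
    if (n > 0) {
      rowidx <- rep(1L, n)
      for (t in seq_along(pa))
        rowidx <- (rowidx - 1L) * pa_ar[t] + dtable$states[, pa[t]] + 1L
      counts <- unclass(table(factor(rowidx, levels = seq_len(q)),
                              factor(child, levels = 0:(r - 1L))))
      dimnames(counts) <- NULL
    }
    prob <- (counts + alpha) / (rowSums(counts) + alpha * r)
    m <- tabulate(child + 1L, nbins = r)
    marginals[[v]] <- if (n > 0) m / n else rep(1 / r, r)
    cpts[[v]] <- list(child = v, parents = pa, child_arity = r,
                      parent_arities = pa_ar, prob = prob, alpha = alpha)
  }
  labels <- list()
  for (v in dag$nodes) {
    b <- dtable$boundaries[[v]]
    if (!is.null(b) && identical(b$rule, "categorical_passthrough"))
      labels[[v]] <- b$levels
  }
  structure(list(cpts = cpts, marginals = marginals,
                 arity = setNames(vapply(dag$nodes, function(v) dtable$arity[[v]],
                                         integer(1)), dag$nodes),
                 dag = dag, alpha = alpha, state_labels = labels),
            class = "cpt_set")
}

# row index into a CPT's prob matrix for a named parent-state assignment;
# first parent is the most significant digit
cpt_row_index <- function(cpt, parent_states) {
  idx <- 1L
  for (t in seq_along(cpt$parents))
    idx <- (idx - 1L) * cpt$parent_arities[t] + parent_states[[cpt$parents[t]]] + 1L
  idx
}

# enumerate state configurations (list of named integer vectors) of vars
enumerate_configs <- function(vars, arities) {
  if (length(vars) == 0L) return(list(setNames(integer(0), character(0))))
  grid <- do.call(expand.grid, setNames(lapply(arities, function(a) 0:(a - 1L)), vars))
  lapply(seq_len(nrow(grid)), function(i)
    setNames(as.integer(grid[i, ]), vars))
}

#' Signed influence score of an edge
#'
#' Quantifies the direction and strength of a dependency in \eqn{[-1, 1]}
#' by cumulative-distribution dominance. For every configuration of the
#' child's other parents and every ordered pair of parent states
#' \eqn{p < p'}, the child-state CDFs under the two parent states are
#' compared: a vote of +1 if the higher parent state shifts the child
#' distribution toward higher states (its CDF is everywhere at or below,
#' and somewhere strictly below, the other), -1 for the opposite
#' dominance, 0 when the CDFs cross. Votes are weighted by the probability
#' of the other-parent configuration (product of empirical marginals) and
#' normalized by the total weighted vote count, so a strictly monotone
#' increasing CPT scores +1, a decreasing one -1, and an independent or
#' non-monotone relationship 0.
#'
#' @param cptset a `cpt_set` from [fit_cpts()].
#' @param parent name of the parent node of the edge.
#' @param child name of the child node of the edge.
#' @return A single number in \eqn{[-1, 1]}.
#' @export
influence_score <- function(cptset, parent, child) {
  cpt <- cptset$cpts[[child]]
  if (is.null(cpt) || !parent %in% cpt$parents)
    abort_ecobnet(sprintf("edge %s -> %s is not in the DAG", parent, child),
                  "ecobnet_usage_error")
  others <- setdiff(cpt$parents, parent)
  pa_arity <- cptset$arity[[parent]]
  configs <- enumerate_configs(others, cptset$arity[others])
  weights <- vapply(configs, function(cf) {
    if (length(others) == 0L) return(1)
    prod(vapply(others, function(o) cptset$marginals[[o]][cf[[o]] + 1L], numeric(1)))
  }, numeric(1))
  tol <- 1e-12
  total <- 0; signed <- 0
  for (ci in seq_along(configs)) {
    cf <- configs[[ci]]
    rows <- vapply(0:(pa_arity - 1L), function(s) {
      cpt_row_index(cpt, c(cf, setNames(s, parent)))
    }, integer(1))
    cdfs <- t(apply(cpt$prob[rows, , drop = FALSE], 1, cumsum))
    for (p1 in 1:(pa_arity - 1L)) {
      for (p2 in (p1 + 1L):pa_arity) {
        d <- cdfs[p2, -cpt$child_arity] - cdfs[p1, -cpt$child_arity]
        vote <- 0
        if (all(d <= tol) && any(d < -tol)) vote <- 1       # shift to higher states
        else if (all(d >= -tol) && any(d > tol)) vote <- -1 # shift to lower states
        signed <- signed + weights[ci] * vote
        total <- total + weights[ci]
      }
    }
  }
  if (total == 0) return(0)
  signed / total
}

#' Per-replicate influence scores for every edge of a bootstrap ensemble
#'
#' For each bootstrap replicate, CPTs are fitted on that replicate's
#' subsample and the influence score of every edge of the replicate's DAG
#' is recorded, keyed by the unordered variable pair. These per-replicate
#' values feed the consensus network's mean IS per connection.
#'
#' @param ensemble a `bootstrap_ensemble` from [run_bootstrap()].
#' @param dtable the `discretized_table` the ensemble was built from.
#' @param alpha CPT smoothing pseudo-count.
#' @return A named list mapping `"a|b"` (with `a < b`) to the numeric
#'   vector of IS values from the replicates containing that edge.
#' @export
ensemble_edge_is <- function(ensemble, dtable, alpha = 1) {
  stopifnot(inherits(ensemble, "bootstrap_ensemble"))
  out <- list()
  for (b in seq_len(ensemble$B)) {
    dag <- ensemble$dags[[b]]
    edges <- dag_edges(dag)
    if (nrow(edges) == 0L) next
    sub <- subset_discretized(dtable, ensemble$indices[[b]])
    cpts <- fit_cpts(sub, dag, alpha = alpha)
    for (k in seq_len(nrow(edges))) {
      is_val <- influence_score(cpts, edges$from[k], edges$to[k])
      key <- pair_key(edges$from[k], edges$to[k])
      out[[key]] <- c(out[[key]], is_val)
    }
  }
  out
}

pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

#' Export a CPT set to JSON
#' @param cptset a `cpt_set`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_cpts <- function(cptset, path) {
  nodes <- lapply(cptset$dag$nodes, function(v) {
    cpt <- cptset$cpts[[v]]
    list(child = v, parents = cpt$parents, child_arity = cpt$child_arity,
         parent_arities = cpt$parent_arities,
         prob = as.vector(t(cpt$prob)),  # row-major
         marginal = cptset$marginals[[v]],
         state_labels = cptset$state_labels[[v]])
  })
  jsonlite::write_json(list(alpha = cptset$alpha, nodes = nodes), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a CPT set written by [write_cpts()]
#' @param path JSON path.
#' @return A `cpt_set`.
#' @export
read_cpts <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- raw$nodes
  cpts <- list(); marginals <- list(); arity <- integer(0); parents <- list()
  labels <- list()
  for (i in seq_len(nrow(nodes))) {
    v <- nodes$child[i]
    pa <- as.character(unlist(nodes$parents[i]))
    pa_ar <- as.integer(unlist(nodes$parent_arities[i]))
    r <- as.integer(nodes$child_arity[i])
    q <- prod(c(1L, pa_ar))
    prob <- matrix(as.numeric(unlist(nodes$prob[i])), nrow = q, ncol = r, byrow = TRUE)
    cpts[[v]] <- list(child = v, parents = pa, child_arity = r,
                      parent_arities = pa_ar, prob = prob, alpha = raw$alpha)
    marginals[[v]] <- as.numeric(unlist(nodes$marginal[i]))
    arity[v] <- r
    parents[[v]] <- pa
    lab <- nodes$state_labels[i][[1]]
    if (!is.null(lab) && length(lab)) labels[[v]] <- as.character(unlist(lab))
  }
  dag <- new_dag(names(cpts), parents, max_parents = max(c(1L, lengths(parents))))
  structure(list(cpts = cpts, marginals = marginals, arity = arity, dag = dag,
                 alpha = raw$alpha, state_labels = labels),
            class = "cpt_set")
}
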