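#' Shortest dependency chain between two nodes of a consensus network
#'
#' Returns the shortest undirected path from `source` to `target`; ties
#' between equal-length paths are broken by the lexicographically smallest
#' node sequence, so the chain is deterministic.
#'
#' @param network a `consensus_network`.
#' @param source,target node names.
#' @return An object of class `dependency_chain` holding the ordered node
#'   sequence.
#' @export
find_chain <- function(network, source, target) {
  stopifnot(inherits(network, "consensus_network"))
  if (!source %in% network$nodes || !target %in% network$nodes)
    abort_ecobnet("source or target not in network", "ecobnet_usage_error")
  if (source == target)
    abort_ecobnet("source and target must differ", "ecobnet_usage_error")
  nbr <- adjacency_list(network)
  # BFS distances from target, then greedy lexicographic descent from source
  dist <- setNames(rep(Inf, length(network$nodes)), network$nodes)
  dist[target] <- 0
  queue <- target
  while (length(queue) > 0L) {
    u <- queue[1L]; queue <- queue[-1L]
    for (v in nbr[[u]]) if (is.infinite(dist[v])) {
      dist[v] <- dist[u] + 1
      queue <- c(queue, v)
    }
  }
  if (is.infinite(dist[source]))
    abort_ecobnet(sprintf("no chain connects %s and %s", source, target),
                  "ecobnet_no_chain_error")
  path <- source
  cur <- source
  while (cur != target) {
    cand <- nbr[[cur]][dist[nbr[[cur]]] == dist[cur] - 1]
    cur <- sort(cand)[1L]
    path <- c(path, cur)
  }
  structure(list(nodes = path), class = "dependency_chain")
}

adjacency_list <- function(network) {
  nbr <- setNames(vector("list", length(network$nodes)), network$nodes)
  e <- network$edges
  for (k in seq_len(nrow(e))) {
    nbr[[e$source[k]]] <- c(nbr[[e$source[k]]], e$target[k])
    nbr[[e$target[k]]] <- c(nbr[[e$target[k]]], e$source[k])
  }
  nbr
}

#' Orient a consensus network into a DAG for CPT fitting
#'
#' Forward and backward edges keep their majority orientation; mutual edges
#' are oriented from the lexicographically smaller node to the larger.
#' Edges are applied in decreasing occurrence order (ties by node names)
#' and an edge whose orientation would close a directed cycle is flipped,
#' which is always possible when the partial graph is acyclic.
#'
#' @param network a `consensus_network`.
#' @return A `bn_dag` on the network's nodes.
#' @export
consensus_to_dag <- function(network) {
  e <- network$edges
  parents <- setNames(lapply(network$nodes, function(v) character(0)),
                      network$nodes)
  if (nrow(e) > 0L) {
    ord <- order(-e$occurrence, e$source, e$target)
    has_path <- function(from, to) {
      if (from == to) return(TRUE)
      seen <- from; stack <- from
      while (length(stack) > 0L) {
        u <- stack[length(stack)]; stack <- stack[-length(stack)]
        kids <- names(parents)[vapply(parents, function(pa) u %in% pa, logical(1))]
        for (v in kids) if (!v %in% seen) {
          if (v == to) return(TRUE)
          seen <- c(seen, v); stack <- c(stack, v)
        }
      }
      FALSE
    }
    for (k in ord) {
      from <- switch(e$direction[k], backward = e$target[k], e$source[k])
      to <- switch(e$direction[k], backward = e$source[k], e$target[k])
      if (has_path(to, from)) { tmp <- from; from <- to; to <- tmp }
      parents[[to]] <- c(parents[[to]], from)
    }
  }
  new_dag(network$nodes, parents,
          max_parents = max(3L, max(c(0L, lengths(parents)))))
}

# P(child states | parent states) with the child's other parents
# marginalized by the product of their empirical marginals
marginalized_cpt <- function(cpts, child, parent) {
  cpt <- cpts$cpts[[child]]
  if (is.null(cpt) || !parent %in% cpt$parents)
    abort_ecobnet(sprintf("edge %s -> %s not in CPT set", parent, child),
                  "ecobnet_usage_error")
  others <- setdiff(cpt$parents, parent)
  configs <- enumerate_configs(others, cpts$arity[others])
  weights <- vapply(configs, function(cf) {
    if (length(others) == 0L) return(1)
    prod(vapply(others, function(o) cpts$marginals[[o]][cf[[o]] + 1L], numeric(1)))
  }, numeric(1))
  weights <- weights / sum(weights)
  pa_arity <- cpts$arity[[parent]]
  M <- matrix(0, nrow = pa_arity, ncol = cpt$child_arity)
  for (s in 0:(pa_arity - 1L)) {
    for (ci in seq_along(configs)) {
      row <- cpt_row_index(cpt, c(configs[[ci]], setNames(s, parent)))
      M[s + 1L, ] <- M[s + 1L, ] + weights[ci] * cpt$prob[row, ]
    }
  }
  M
}

# one-step conditional P(to | from) given the fitted DAG: a CPT row when
# the edge points along the traversal, Bayes inversion when it points
# against it
step_conditional <- function(cpts, from, to) {
  along <- from %in% cpts$dag$parents[[to]]
  against <- to %in% cpts$dag$parents[[from]]
  if (along) return(marginalized_cpt(cpts, to, from))
  if (!against)
    abort_ecobnet(sprintf("%s and %s are not adjacent in the DAG", from, to),
                  "ecobnet_usage_error")
  C <- marginalized_cpt(cpts, from, to)        # P(from | to), to_arity x from_arity
  m_to <- cpts$marginals[[to]]
  M <- matrix(0, nrow = cpts$arity[[from]], ncol = cpts$arity[[to]])
  for (x in seq_len(cpts$arity[[from]])) {
    num <- C[, x] * m_to
    M[x, ] <- num / sum(num)                   # denominator of the Bayes inversion
  }
  M
}

#' Propagate a forced source state along a dependency chain
#'
#' Starting from a point mass on `source_state`, the distribution is pushed
#' through one conditional per chain step: a marginalized CPT row when the
#' learned edge points along the traversal, and a Bayes inversion
#' \eqn{P(\mathrm{parent} \mid \mathrm{child}) = P(\mathrm{child} \mid
#' \mathrm{parent}) P(\mathrm{parent}) / \sum_m P(\mathrm{child} \mid m)
#' P(m)} when it points against it. Other parents of chain nodes are
#' marginalized by their empirical marginals.
#'
#' @param chain a `dependency_chain` from [find_chain()].
#' @param cpts a `cpt_set` covering all chain nodes.
#' @param source_state state (0-based integer) forced at the chain's first
#'   node.
#' @return Probability vector over the states of the chain's last node.
#' @export
propagate <- function(chain, cpts, source_state) {
  stopifnot(inherits(chain, "dependency_chain"), inherits(cpts, "cpt_set"))
  nodes <- chain$nodes
  src <- nodes[1L]
  source_state <- resolve_state(cpts, src, source_state)
  v <- rep(0, cpts$arity[[src]])
  v[source_state + 1L] <- 1
  for (k in seq_len(length(nodes) - 1L))
    v <- as.vector(v %*% step_conditional(cpts, nodes[k], nodes[k + 1L]))
  v
}

# accept 0-based integers, recorded category labels, or the conventional
# zero/low/high names for 3-state count variables
resolve_state <- function(cpts, node, state) {
  arity <- cpts$arity[[node]]
  if (is.numeric(state)) {
    state <- as.integer(state)
    if (state < 0L || state >= arity)
      abort_ecobnet(sprintf("state %d out of range for %s (arity %d)",
                            state, node, arity), "ecobnet_usage_error")
    return(state)
  }
  labels <- cpts$state_labels[[node]]
  if (!is.null(labels)) {
    i <- match(state, labels)
    if (!is.na(i)) return(i - 1L)
  }
  if (arity == 3L) {
    i <- match(tolower(state), c("zero", "low", "high"))
    if (!is.na(i)) return(i - 1L)
  }
  abort_ecobnet(sprintf("unknown state label '%s' for node %s", state, node),
                "ecobnet_usage_error")
}

#' State-probability shifts of every connected node under a forced change
#'
#' For every node connected to `source` in the consensus network (over
#' chains of any length), computes the target's state probabilities with
#' the source forced to `from_state` and to `to_state`, and the difference
#' \eqn{\Delta p = P(\cdot \mid \mathrm{to}) - P(\cdot \mid \mathrm{from})}.
#' The scalar summary `mean_delta_p` is the mean of \eqn{|\Delta p|} over
#' all states of all connected targets; unconnected nodes are reported
#' with zero shifts but do not enter the mean.
#'
#' @param network a `consensus_network`.
#' @param cpts a `cpt_set` fitted on a DAG compatible with the network
#'   (see [consensus_to_dag()]).
#' @param source node whose state is forced.
#' @param from_state,to_state the contrast, e.g. `"high"` to `"zero"` for a
#'   taxon-removal scenario (0-based integers also accepted).
#' @return An object of class `inference_report`.
#' @export
state_change_report <- function(network, cpts, source, from_state, to_state) {
  stopifnot(inherits(network, "consensus_network"))
  if (!source %in% network$nodes)
    abort_ecobnet("source not in network", "ecobnet_usage_error")
  targets <- setdiff(network$nodes, source)
  rows <- list(); chains <- list()
  deltas_connected <- numeric(0)
  for (tg in targets) {
    chain <- tryCatch(find_chain(network, source, tg),
                      ecobnet_no_chain_error = function(e) NULL)
    if (is.null(chain)) {
      arity <- if (!is.null(cpts$arity[[tg]])) cpts$arity[[tg]] else NA_integer_
      nstates <- if (is.na(arity)) 0L else arity
      if (nstates > 0L)
        rows[[tg]] <- data.frame(target = tg, state = 0:(nstates - 1L),
                                 p_from = NA_real_, p_to = NA_real_,
                                 delta_p = 0, chain_length = NA_integer_,
                                 connected = FALSE, stringsAsFactors = FALSE)
      next
    }
    p_from <- propagate(chain, cpts, from_state)
    p_to <- propagate(chain, cpts, to_state)
    delta <- p_to - p_from
    deltas_connected <- c(deltas_connected, delta)
    rows[[tg]] <- data.frame(target = tg, state = seq_along(delta) - 1L,
                             p_from = p_from, p_to = p_to, delta_p = delta,
                             chain_length = length(chain$nodes) - 1L,
                             connected = TRUE, stringsAsFactors = FALSE)
    chains[[tg]] <- chain$nodes
  }
  targets_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(target = character(0), state = integer(0), p_from = numeric(0),
               p_to = numeric(0), delta_p = numeric(0),
               chain_length = integer(0), connected = logical(0))
  rownames(targets_df) <- NULL
  structure(list(source = source,
                 from_state = resolve_state(cpts, source, from_state),
                 to_state = resolve_state(cpts, source, to_state),
                 targets = targets_df, chains = chains,
                 mean_delta_p = if (length(deltas_connected))
                   mean(abs(deltas_connected)) else 0),
            class = "inference_report")
}

#' Mean probability shift between two states of a source node
#'
#' Convenience wrapper around [state_change_report()] used for substrate
#' contrasts: returns only the scalar `mean_delta_p` for forcing
#' `substrate_var` from `state_a` to `state_b`. Category labels recorded at
#' discretization time are accepted.
#'
#' @param network a `consensus_network`.
#' @param cpts a `cpt_set`.
#' @param substrate_var the source node (typically the substrate variable).
#' @param state_a,state_b the contrasted states (labels or 0-based
#'   integers).
#' @return The mean absolute probability shift, a single number.
#' @export
substrate_contrast <- function(network, cpts, substrate_var, state_a, state_b) {
  state_change_report(network, cpts, substrate_var, state_a, state_b)$mean_delta_p
}

#' @export
print.inference_report <- function(x, ...) {
  cat(sprintf("inference_report: %s forced %d -> %d; mean |delta p| = %.4f\n",
              x$source, x$from_state, x$to_state, x$mean_delta_p))
  invisible(x)
}

#' Export an inference report as JSON and TSV
#' @param report an `inference_report`.
#' @param json_path output JSON path (`NULL` to skip).
#' @param tsv_path output TSV path (`NULL` to skip); columns target, state,
#'   p_from, p_to, delta_p.
#' @return `json_path` or `tsv_path`, invisibly.
#' @export
write_report <- function(report, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(
      list(source = report$source, from_state = report$from_state,
           to_state = report$to_state, mean_delta_p = report$mean_delta_p,
           targets = report$targets, chains = report$chains),
      json_path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv_path)) {
    df <- report$targets[, c("target", "state", "p_from", "p_to", "delta_p")]
    write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(if (!is.null(json_path)) json_path else tsv_path)
}
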