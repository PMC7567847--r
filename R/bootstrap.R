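#' Repeated structure searches on bootstrap subsamples
#'
#' To minimise outlier bias, the structure search is repeated on `B`
#' subsamples each holding `floor(frac * n)` distinct samples drawn without
#' replacement. Each replicate runs one greedy search with its own derived
#' seed, so the whole ensemble is reproducible from the master seed.
#'
#' @param dtable a `discretized_table` with at least 20 samples.
#' @param constraint optional [exclusion_set()] passed to every search.
#' @param settings a [search_settings()]; its `seed` field is ignored in
#'   favour of the per-replicate derived seeds.
#' @param B number of replicates (default 100).
#' @param frac subsample fraction (default 0.95).
#' @param seed master seed for subsampling and searches.
#' @return An object of class `bootstrap_ensemble` with the per-replicate
#'   subsample indices and learned DAGs.
#' @export
run_bootstrap <- function(dtable, constraint = NULL,
                          settings = search_settings(), B = 100, frac = 0.95,
                          seed = 1) {
  stopifnot(inherits(dtable, "discretized_table"))
  n <- length(dtable$sample_ids)
  if (n < 20L)
    abort_ecobnet("bootstrap needs at least 20 samples", "ecobnet_usage_error")
  m <- floor(frac * n)
  if (m < 10L)
    abort_ecobnet("subsample size below 10: increase frac or sample count",
                  "ecobnet_usage_error")
  set.seed(seed)
  rep_seeds <- sample.int(2147483646L, B)
  indices <- vector("list", B)
  dags <- vector("list", B)
  settings$seed <- NULL
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    indices[[b]] <- sort(sample.int(n, m))
    sub <- subset_discretized(dtable, indices[[b]])
    dags[[b]] <- greedy_search(sub, constraint, settings)
  }
  structure(list(B = B, frac = frac, indices = indices, dags = dags,
                 seed = seed, rep_seeds = rep_seeds, nodes = dtable$vars,
                 settings = settings),
            class = "bootstrap_ensemble")
}

#' @export
print.bootstrap_ensemble <- function(x, ...) {
  cat(sprintf("bootstrap_ensemble: B=%d, frac=%.2f, %d nodes, seed=%s\n",
              x$B, x$frac, length(x$nodes), format(x$seed)))
  invisible(x)
}

#' Per-pair occurrence and orientation frequencies of an ensemble
#'
#' @param ensemble a `bootstrap_ensemble`.
#' @return Data frame with one row per unordered variable pair appearing in
#'   at least one replicate: `var1`, `var2` (lexicographic), `occurrence`
#'   (fraction of replicates containing the edge in either direction),
#'   `forward_fraction` (among those, fraction oriented `var1 -> var2`),
#'   and `n_present`.
#' @export
edge_stats <- function(ensemble) {
  stopifnot(inherits(ensemble, "bootstrap_ensemble"))
  present <- list(); forward <- list()
  for (b in seq_len(ensemble$B)) {
    edges <- dag_edges(ensemble$dags[[b]])
    for (k in seq_len(nrow(edges))) {
      key <- pair_key(edges$from[k], edges$to[k])
      present[[key]] <- c(present[[key]], b)
      forward[[key]] <- c(forward[[key]],
                          edges$from[k] < edges$to[k])  # var1 -> var2?
    }
  }
  keys <- sort(names(present))
  if (length(keys) == 0L)
    return(data.frame(var1 = character(0), var2 = character(0),
                      occurrence = numeric(0), forward_fraction = numeric(0),
                      n_present = integer(0), stringsAsFactors = FALSE))
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(
    var1 = vapply(parts, `[`, "", 1L),
    var2 = vapply(parts, `[`, "", 2L),
    occurrence = vapply(keys, function(k) length(present[[k]]) / ensemble$B, numeric(1)),
    forward_fraction = vapply(keys, function(k) mean(forward[[k]]), numeric(1)),
    n_present = vapply(keys, function(k) length(present[[k]]), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Occurrence threshold from a Gaussian mixture of edge frequencies
#'
#' Edge occurrence frequencies across bootstrap replicates are typically
#' bimodal: a low mode of artefactual connections and a high mode of well
#' supported ones. One- and two-component Gaussian mixtures are fitted by
#' EM ([mclust::Mclust]) and compared by BIC. If two components win, the
#' threshold is the density-crossing point between the two component means
#' (the midpoint of the means when the densities do not cross between
#' them); otherwise a simple majority threshold of 0.5 is used. EM failure
#' falls back to 0.5 with a warning.
#'
#' @param occurrences numeric vector of per-pair occurrence frequencies
#'   (at least two distinct values).
#' @return The occurrence threshold, a single number.
#' @importFrom mclust Mclust mclustBIC
#' @export
occurrence_threshold <- function(occurrences) {
  if (length(unique(occurrences)) < 2L)
    return(0.5)
  fit <- tryCatch(
    mclust::Mclust(occurrences, G = 1:2, modelNames = c("E", "V"),
                   verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) {
    warn_ecobnet("mixture fit failed: falling back to majority threshold 0.5",
                 "ecobnet_mixture_warning")
    return(0.5)
  }
  if (fit$G < 2L) return(0.5)
  mu <- fit$parameters$mean
  sigma <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sigma) == 1L) sigma <- rep(sigma, 2L)
  pro <- fit$parameters$pro
  o <- order(mu)
  gaussian_crossing(mu[o], sigma[o], pro[o])
}

# density crossing of two weighted normals between their means:
# solve pro1 * f1(x) = pro2 * f2(x), a quadratic in x
gaussian_crossing <- function(mu, sigma, pro) {
  c1 <- 1 / sigma[1]^2; c2 <- 1 / sigma[2]^2
  A <- c1 - c2
  Bc <- -2 * (mu[1] * c1 - mu[2] * c2)
  Cc <- mu[1]^2 * c1 - mu[2]^2 * c2 - 2 * log(pro[1] * sigma[2] / (pro[2] * sigma[1]))
  mid <- mean(mu)
  if (abs(A) < 1e-12) {
    if (abs(Bc) < 1e-12) return(mid)
    x <- -Cc / Bc
    return(if (x > mu[1] && x < mu[2]) x else mid)
  }
  disc <- Bc^2 - 4 * A * Cc
  if (disc < 0) return(mid)
  roots <- (-Bc + c(-1, 1) * sqrt(disc)) / (2 * A)
  inside <- roots[roots > mu[1] & roots < mu[2]]
  if (length(inside) == 0L) return(mid)
  inside[1L]
}

#' Assemble the consensus network from a bootstrap ensemble
#'
#' Keeps the unordered pairs whose occurrence is at or above the threshold.
#' Direction follows the majority orientation across replicates containing
#' the edge: `forward` (`source -> target`) when the forward fraction is at
#' least 0.6, `backward` when at most 0.4, and `mutual` (bi-directional)
#' in between. The mean influence score of each connection is averaged
#' over the replicates containing it. Summary statistics (connected nodes,
#' positive/negative/mutual dependency counts, connectance, link density,
#' chain statistics) are attached.
#'
#' @param ensemble a `bootstrap_ensemble`.
#' @param dtable the `discretized_table` the ensemble was built from (used
#'   to fit per-replicate CPTs for the influence scores).
#' @param threshold occurrence cutoff; `NULL` (default) derives it with
#'   [occurrence_threshold()].
#' @param alpha CPT smoothing pseudo-count for the influence scores.
#' @return An object of class `consensus_network`: `$nodes`, `$edges`
#'   (source, target, direction, occurrence, mean_is with `source < target`),
#'   `$threshold`, `$summary`.
#' @export
assemble_consensus <- function(ensemble, dtable, threshold = NULL, alpha = 1) {
  stopifnot(inherits(ensemble, "bootstrap_ensemble"))
  stats <- edge_stats(ensemble)
  is_lists <- ensemble_edge_is(ensemble, dtable, alpha = alpha)
  if (is.null(threshold))
    threshold <- if (nrow(stats) > 0L) occurrence_threshold(stats$occurrence) else 0.5
  keep <- stats[stats$occurrence >= threshold, , drop = FALSE]
  edges <- data.frame(source = character(0), target = character(0),
                      direction = character(0), occurrence = numeric(0),
                      mean_is = numeric(0), stringsAsFactors = FALSE)
  if (nrow(keep) > 0L) {
    direction <- ifelse(keep$forward_fraction >= 0.6, "forward",
                        ifelse(keep$forward_fraction <= 0.4, "backward", "mutual"))
    mean_is <- vapply(seq_len(nrow(keep)), function(k)
      mean(is_lists[[pair_key(keep$var1[k], keep$var2[k])]]), numeric(1))
    edges <- data.frame(source = keep$var1, target = keep$var2,
                        direction = direction, occurrence = keep$occurrence,
                        mean_is = mean_is, stringsAsFactors = FALSE)
    edges <- edges[order(edges$source, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
  }
  consensus_network(ensemble$nodes, edges, threshold)
}

#' Construct a consensus network from an edge list
#'
#' @param nodes all variable names in the analysis (connected or not).
#' @param edges data frame with columns `source`, `target`, `direction`
#'   (`forward`/`backward`/`mutual`), `occurrence`, `mean_is`; one row per
#'   undirected pair.
#' @param threshold the occurrence cutoff that produced the edges (may be
#'   `NA` for hand-built networks).
#' @return A `consensus_network` with summary statistics attached.
#' @export
consensus_network <- function(nodes, edges, threshold = NA_real_) {
  stopifnot(is.data.frame(edges))
  needed <- c("source", "target", "direction", "occurrence", "mean_is")
  if (!all(needed %in% names(edges)))
    abort_ecobnet("edge table must have columns source, target, direction, occurrence, mean_is",
                  "ecobnet_usage_error")
  edges <- edges[, needed, drop = FALSE]
  if (nrow(edges) > 0L) {
    if (!all(edges$direction %in% c("forward", "backward", "mutual")))
      abort_ecobnet("direction must be forward, backward or mutual", "ecobnet_usage_error")
    if (any(abs(edges$mean_is) > 1 + 1e-9))
      abort_ecobnet("mean_is outside [-1, 1]", "ecobnet_usage_error")
    swap <- edges$source > edges$target
    if (any(swap)) {  # canonicalise to source < target
      tmp <- edges$source[swap]
      edges$source[swap] <- edges$target[swap]
      edges$target[swap] <- tmp
      edges$direction[swap] <- ifelse(edges$direction[swap] == "forward", "backward",
                                      ifelse(edges$direction[swap] == "backward",
                                             "forward", "mutual"))
    }
    edges <- edges[order(edges$source, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- sort(unique(c(nodes, edges$source, edges$target)))
  net <- structure(list(nodes = nodes, edges = edges, threshold = threshold,
                        summary = NULL),
                   class = "consensus_network")
  net$summary <- network_summary(net)
  net
}

#' Summary statistics of a consensus network
#'
#' Mirrors the standard network property table: mean IS over connections,
#' number of connected nodes, counts of positive, negative and mutual
#' dependencies, connectance \eqn{E / (N (N-1))}, link density \eqn{E / N}
#' (both over the \eqn{N} connected nodes), and chain statistics where a
#' chain is a maximal simple path of at least two connections in the
#' undirected consensus graph, counted per distinct endpoint pair.
#'
#' @param network a `consensus_network`.
#' @return A list of summary statistics.
#' @export
network_summary <- function(network) {
  e <- network$edges
  connected <- sort(unique(c(e$source, e$target)))
  n_nodes <- length(connected)
  n_edges <- nrow(e)
  ch <- chain_statistics(network)
  list(mean_is = if (n_edges) mean(e$mean_is) else NA_real_,
       nodes = n_nodes,
       n_positive = sum(e$mean_is > 0),
       n_negative = sum(e$mean_is < 0),
       n_mutual = sum(e$direction == "mutual"),
       connectance = if (n_nodes > 1) n_edges / (n_nodes * (n_nodes - 1)) else NA_real_,
       link_density = if (n_nodes > 0) n_edges / n_nodes else NA_real_,
       max_chain_length = ch$max_length,
       n_chains = ch$n_chains,
       mean_chain_length = ch$mean_length)
}

#' Chain statistics of the undirected consensus graph
#'
#' A chain is a maximal simple path (not extendable at either end) with at
#' least two connections. Chains are counted per distinct endpoint pair;
#' for each endpoint pair the longest maximal path is taken. Lengths are
#' in connections (edges).
#'
#' @param network a `consensus_network`.
#' @return A list with `max_length`, `n_chains`, `mean_length`.
#' @export
chain_statistics <- function(network) {
  e <- network$edges
  if (nrow(e) == 0L)
    return(list(max_length = 0L, n_chains = 0L, mean_length = NA_real_))
  nodes <- sort(unique(c(e$source, e$target)))
  nbr <- setNames(vector("list", length(nodes)), nodes)
  for (k in seq_len(nrow(e))) {
    nbr[[e$source[k]]] <- c(nbr[[e$source[k]]], e$target[k])
    nbr[[e$target[k]]] <- c(nbr[[e$target[k]]], e$source[k])
  }
  best <- list()  # endpoint pair -> max length (edges)
  record <- function(path) {
    len <- length(path) - 1L
    if (len < 2L) return()
    # maximal: no neighbour of either endpoint outside the path
    if (length(setdiff(nbr[[path[1L]]], path)) > 0L) return()
    if (length(setdiff(nbr[[path[length(path)]]], path)) > 0L) return()
    key <- pair_key(path[1L], path[length(path)])
    if (is.null(best[[key]]) || best[[key]] < len) best[[key]] <<- len
  }
  extend <- function(path) {
    nxt <- setdiff(nbr[[path[length(path)]]], path)
    record(path)
    for (v in nxt) extend(c(path, v))
  }
  for (v in nodes) extend(v)
  if (length(best) == 0L)
    return(list(max_length = 0L, n_chains = 0L, mean_length = NA_real_))
  lens <- unlist(best)
  list(max_length = max(lens), n_chains = length(lens), mean_length = mean(lens))
}

#' @export
print.consensus_network <- function(x, ...) {
  s <- x$summary
  cat(sprintf("consensus_network: %d nodes (%d connected), %d edges, threshold %s\n",
              length(x$nodes), s$nodes, nrow(x$edges),
              ifelse(is.na(x$threshold), "NA", format(round(x$threshold, 3)))))
  if (nrow(x$edges) > 0) {
    cat(sprintf("  mean IS %.4f; +%d / -%d / mutual %d; connectance %.3f, link density %.3f\n",
                s$mean_is, s$n_positive, s$n_negative, s$n_mutual,
                s$connectance, s$link_density))
  }
  invisible(x)
}
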