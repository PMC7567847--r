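#' Simulate a ground-truth network for a zero-inflated community
#'
#' Builds a random DAG over a categorical substrate root (3 states), an
#' optional continuous depth covariate (4 latent states), and `n_taxa`
#' three-state taxa, together with conditional probability tables whose
#' rows are a mixture `lambda * monotone + (1 - lambda) * uniform`. The
#' monotone component shifts a taxon away from its zero state and toward
#' its high state as the (sign-adjusted) mean parent level rises, so every
#' edge's influence-score sign is known by construction: `lambda = 0`
#' gives fully uniform tables (no signal, true IS 0 everywhere) and
#' `lambda = 1` strict CDF dominance (true IS of +1 or -1 per the edge
#' sign).
#'
#' The zero state dominates by design: a taxon's probability of state 0 is
#' `zero_hi` when all parents are at their lowest level and shrinks by the
#' factor `zero_lo / zero_hi` for every parent at full level (so a single
#' fully-active parent takes it to `zero_lo`, independent of how many
#' other parents the child has), echoing the zero-inflation
#' characteristic of photographic seafloor surveys.
#'
#' @param n_taxa number of taxa (default 8).
#' @param n_edges number of edges; must be feasible under the parent cap
#'   of 3 (default 8).
#' @param lambda monotone signal strength in \eqn{[0, 1]} (default 0.8).
#' @param seed integer seed.
#' @param include_depth include the latent 4-state depth covariate.
#' @param signs optional vector of +1/-1 recycled over edges (default all
#'   +1).
#' @param zero_hi,zero_lo zero-state probability of the monotone component
#'   at drive 0 and drive 1. The defaults keep every taxon's occupancy
#'   above the 1/3 rare-taxon threshold (mirroring the coarse taxonomic
#'   groups that such analyses retain); push both toward 1 to emulate the
#'   far heavier zero-inflation of raw fine-taxonomy survey tables.
#' @return An object of class `ground_truth` with fields `dag`, `cpts`
#'   (a `cpt_set` with exact marginals), `edge_signs`, `emission`,
#'   `lambda`, `seed`.
#' @export
simulate_ground_truth <- function(n_taxa = 8, n_edges = 8, lambda = 0.8,
                                  seed = 1, include_depth = TRUE,
                                  signs = 1,
                                  zero_hi = 0.70, zero_lo = 0.25) {
  if (lambda < 0 || lambda > 1)
    abort_ecobnet("lambda must be in [0, 1]", "ecobnet_usage_error")
  if (n_edges > 3 * n_taxa)
    abort_ecobnet(sprintf("%d edges infeasible for %d taxa under the parent cap of 3",
                          n_edges, n_taxa), "ecobnet_usage_error")
  taxa <- sprintf("taxon%02d", seq_len(n_taxa))
  nodes <- c("substrate", if (include_depth) "depth", taxa)
  arity <- setNames(c(3L, if (include_depth) 4L, rep(3L, n_taxa)), nodes)
  # candidate edges: roots feed taxa; taxa feed later taxa (topological)
  cand <- rbind(
    data.frame(from = "substrate", to = taxa, stringsAsFactors = FALSE),
    if (include_depth) data.frame(from = "depth", to = taxa, stringsAsFactors = FALSE),
    if (n_taxa >= 2) {
      ij <- utils::combn(n_taxa, 2)
      data.frame(from = taxa[ij[1, ]], to = taxa[ij[2, ]], stringsAsFactors = FALSE)
    })
  set.seed(seed)
  for (try in 1:1000) {
    pick <- cand[sample.int(nrow(cand), n_edges), , drop = FALSE]
    if (n_edges == 0L || max(table(pick$to)) <= 3L) break
    if (try == 1000)
      abort_ecobnet("could not draw a DAG satisfying the parent cap",
                    "ecobnet_usage_error")
  }
  pick <- pick[order(pick$from, pick$to), , drop = FALSE]
  rownames(pick) <- NULL
  pick$sign <- rep_len(signs, n_edges)
  parents <- split(pick$from, pick$to)
  dag <- new_dag(nodes, parents, max_parents = 3L)

  cpts <- list()
  for (v in nodes) {
    pa <- dag$parents[[v]]
    pa_ar <- if (length(pa)) unname(arity[pa]) else integer(0)
    r <- arity[[v]]
    q <- prod(c(1L, pa_ar))
    prob <- matrix(0, nrow = q, ncol = r)
    if (v %in% c("substrate", "depth")) {
      prob[1, ] <- rep(1 / r, r)
    } else {
      esigns <- setNames(pick$sign[pick$to == v], pick$from[pick$to == v])
      configs <- enumerate_configs(pa, arity[pa])
      for (cf in configs) {
        lv <- if (length(pa) == 0L) 0.5 else vapply(pa, function(u) {
          lev <- cf[[u]] / (arity[[u]] - 1)
          if (esigns[[u]] < 0) 1 - lev else lev
        }, numeric(1))
        row_idx <- cpt_row_index(list(parents = pa, parent_arities = pa_ar), cf)
        prob[row_idx, ] <- lambda * monotone_taxon_row(lv, zero_hi, zero_lo) +
          (1 - lambda) / r
      }
    }
    cpts[[v]] <- list(child = v, parents = pa, child_arity = r,
                      parent_arities = pa_ar, prob = prob, alpha = 0)
  }
  marginals <- exact_marginals(cpts, nodes, arity)
  cptset <- structure(list(cpts = cpts, marginals = marginals, arity = arity,
                           dag = dag, alpha = 0,
                           state_labels = list(substrate = c("Gravel", "Rocky", "Silt"))),
                      class = "cpt_set")
  structure(list(dag = dag, cpts = cptset, edge_signs = pick,
                 emission = list(low = c(1L, 4L), high = c(5L, 20L),
                                 depth_breaks = seq(500, 1000, length.out = 5),
                                 substrate_levels = c("Gravel", "Rocky", "Silt")),
                 lambda = lambda, zero_hi = zero_hi, zero_lo = zero_lo,
                 seed = seed),
            class = "ground_truth")
}

# monotone 3-state row from sign-adjusted parent levels lv in [0, 1].
# The zero state responds multiplicatively to each parent level —
# p0 = zero_hi * (zero_lo/zero_hi)^sum(lv) — so every edge shifts the
# child by the same factor regardless of how many other parents the
# child has; the high-state share of the non-zero mass grows with the
# mean level. Both effects are strictly monotone in every single level,
# giving strict CDF dominance (IS +1/-1) edge by edge.
monotone_taxon_row <- function(lv, zero_hi, zero_lo) {
  p0 <- zero_hi * (zero_lo / zero_hi)^sum(lv)
  rest <- 1 - p0
  p2 <- rest * (0.25 + 0.5 * mean(lv))
  c(p0, rest - p2, p2)
}

# exact node marginals by joint enumeration in topological order
exact_marginals <- function(cpts, nodes, arity) {
  total <- prod(arity)
  if (total > 2e6)
    abort_ecobnet("ground truth too large for exact marginals", "ecobnet_usage_error")
  ord <- topological_order(nodes, lapply(cpts, `[[`, "parents"))
  grid <- as.matrix(do.call(expand.grid,
                            setNames(lapply(nodes, function(v) 0:(arity[[v]] - 1L)),
                                     nodes)))
  p <- rep(1, nrow(grid))
  for (v in ord) {
    cpt <- cpts[[v]]
    idx <- rep(1L, nrow(grid))
    for (t in seq_along(cpt$parents))
      idx <- (idx - 1L) * cpt$parent_arities[t] + grid[, cpt$parents[t]] + 1L
    p <- p * cpt$prob[cbind(idx, grid[, v] + 1L)]
  }
  out <- lapply(nodes, function(v)
    vapply(0:(arity[[v]] - 1L), function(s) sum(p[grid[, v] == s]), numeric(1)))
  setNames(out, nodes)
}

topological_order <- function(nodes, parents) {
  ord <- character(0); placed <- character(0)
  while (length(placed) < length(nodes)) {
    ready <- setdiff(nodes[vapply(nodes, function(v)
      all(parents[[v]] %in% placed), logical(1))], placed)
    if (length(ready) == 0L)
      abort_ecobnet("cyclic parent structure", "ecobnet_usage_error")
    ord <- c(ord, ready); placed <- c(placed, ready)
  }
  ord
}

#' Sample a photographic survey from a ground-truth network
#'
#' Substrate and depth states are drawn once per transect event and shared
#' by the event's photographs, mimicking transect-level habitat
#' homogeneity; taxa states are drawn per photograph from the ground-truth
#' CPTs. States are then emitted as observations: taxon state 0 always
#' emits count 0, state 1 a count from the low range, state 2 from the
#' high range (disjoint uniform integer ranges, so discretization can
#' recover the latent states exactly); depth states emit a continuous
#' depth from the state's band and substrate states their category label.
#'
#' @param gt a `ground_truth` from [simulate_ground_truth()].
#' @param n_photos number of photographs; must be divisible by
#'   `photos_per_event`.
#' @param photos_per_event photographs per transect event (default 25).
#' @param seed integer seed.
#' @return A photo-scale [abundance_table()] with a photo-to-event
#'   grouping key.
#' @export
sample_community <- function(gt, n_photos, photos_per_event = 25, seed = 1) {
  stopifnot(inherits(gt, "ground_truth"))
  if (n_photos %% photos_per_event != 0)
    abort_ecobnet("n_photos must be divisible by photos_per_event",
                  "ecobnet_usage_error")
  set.seed(seed)
  n_events <- n_photos %/% photos_per_event
  nodes <- gt$dag$nodes
  arity <- gt$cpts$arity
  roots_shared <- intersect(c("substrate", "depth"), nodes)
  taxa <- setdiff(nodes, roots_shared)
  ord <- topological_order(nodes, gt$dag$parents)
  states <- matrix(0L, nrow = n_photos, ncol = length(nodes),
                   dimnames = list(NULL, nodes))
  event_of <- rep(seq_len(n_events), each = photos_per_event)
  for (v in roots_shared) {
    ev_states <- sample.int(arity[[v]], n_events, replace = TRUE,
                            prob = gt$cpts$cpts[[v]]$prob[1, ]) - 1L
    states[, v] <- ev_states[event_of]
  }
  for (v in ord) {
    if (v %in% roots_shared) next
    cpt <- gt$cpts$cpts[[v]]
    idx <- rep(1L, n_photos)
    for (t in seq_along(cpt$parents))
      idx <- (idx - 1L) * cpt$parent_arities[t] + states[, cpt$parents[t]] + 1L
    u <- runif(n_photos)
    cum <- t(apply(cpt$prob, 1, cumsum))
    states[, v] <- rowSums(u > cum[idx, , drop = FALSE])
  }
  # emission
  values <- data.frame(row.names = seq_len(n_photos))
  for (v in taxa) {
    s <- states[, v]
    counts <- integer(n_photos)
    low <- s == 1L; high <- s == 2L
    counts[low] <- sample(gt$emission$low[1]:gt$emission$low[2], sum(low),
                          replace = TRUE)
    counts[high] <- sample(gt$emission$high[1]:gt$emission$high[2], sum(high),
                           replace = TRUE)
    values[[v]] <- counts
  }
  if ("depth" %in% nodes) {
    br <- gt$emission$depth_breaks
    s <- states[, "depth"]
    values$depth <- br[s + 1L] + runif(n_photos) * (br[s + 2L] - br[s + 1L])
  }
  values$substrate <- gt$emission$substrate_levels[states[, "substrate"] + 1L]
  specs <- variable_specs(do.call(rbind, c(
    lapply(taxa, function(v) variable_spec(v, "taxon")),
    if ("depth" %in% nodes) list(variable_spec("depth", "continuous")),
    list(variable_spec("substrate", "categorical")))))
  photo_ids <- sprintf("p%05d", seq_len(n_photos))
  grouping <- setNames(sprintf("e%03d", event_of), photo_ids)
  out <- abundance_table(values, specs, sample_ids = photo_ids,
                         grouping = grouping, scale = "photo")
  attr(out, "latent_states") <- states
  out
}

#' Fraction of zero entries among taxon counts
#' @param table an [abundance_table()].
#' @return Fraction in \eqn{[0, 1]}.
#' @export
zero_fraction <- function(table) {
  taxa <- table$specs$name[table$specs$role %in% c("taxon", "bin_group")]
  vals <- as.matrix(table$values[, taxa, drop = FALSE])
  mean(vals == 0)
}

#' Edge recovery metrics of a consensus network against the truth
#'
#' Precision and recall are over undirected true edges; an empty consensus
#' has precision 1 by convention (no false positives). F1 is the harmonic
#' mean (0 when precision + recall is 0). Direction accuracy is judged on
#' the correctly recovered edges: a mutual consensus edge counts as
#' correct for either true orientation.
#'
#' @param consensus a `consensus_network`.
#' @param gt the `ground_truth` the data were sampled from.
#' @return A list with `edge_precision`, `edge_recall`, `f1`,
#'   `direction_accuracy`, `n_true`, `n_recovered`, `n_correct`.
#' @export
recovery_metrics <- function(consensus, gt) {
  truth <- gt$edge_signs
  true_keys <- mapply(pair_key, truth$from, truth$to)
  e <- consensus$edges
  rec_keys <- if (nrow(e)) mapply(pair_key, e$source, e$target) else character(0)
  tp <- intersect(rec_keys, true_keys)
  precision <- if (length(rec_keys) == 0L) 1 else length(tp) / length(rec_keys)
  recall <- if (length(true_keys) == 0L) 1 else length(tp) / length(true_keys)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  dir_ok <- 0L
  for (key in tp) {
    i <- match(key, rec_keys); j <- match(key, true_keys)
    if (e$direction[i] == "mutual") { dir_ok <- dir_ok + 1L; next }
    oriented_from <- if (e$direction[i] == "forward") e$source[i] else e$target[i]
    if (oriented_from == truth$from[j]) dir_ok <- dir_ok + 1L
  }
  list(edge_precision = precision, edge_recall = recall, f1 = f1,
       direction_accuracy = if (length(tp)) dir_ok / length(tp) else NA_real_,
       n_true = length(true_keys), n_recovered = length(rec_keys),
       n_correct = length(tp))
}

#' Export a ground truth to JSON
#' @param gt a `ground_truth`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(
    list(nodes = gt$dag$nodes, edges = gt$edge_signs, lambda = gt$lambda,
         zero_hi = gt$zero_hi, zero_lo = gt$zero_lo, seed = gt$seed,
         emission = gt$emission),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d nodes, %d edges, lambda=%.2f, seed=%s\n",
              length(x$dag$nodes), nrow(x$edge_signs), x$lambda, format(x$seed)))
  invisible(x)
}
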