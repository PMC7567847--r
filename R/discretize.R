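#' Discretize zero-inflated counts into zero/low/high states
#'
#' Zero counts form their own state because absence is ecologically distinct
#' from low abundance. Positive counts are split at the median of the
#' positive values only: values at or below the boundary are "low"
#' (state 1), values above it are "high" (state 2).
#'
#' @param values non-negative integer vector with at least one positive
#'   entry.
#' @return A list with `states` (integer vector in 0..2) and `boundary`
#'   (median of the positive values).
#' @examples
#' discretize_counts(c(0, 0, 1, 2, 3, 4))
#' @export
discretize_counts <- function(values) {
  pos <- values[values > 0]
  if (length(pos) == 0L)
    abort_ecobnet("all-zero count vector: variable is degenerate (should have been removed by the rare filter)",
                  "ecobnet_degenerate_error")
  boundary <- median(pos)
  states <- integer(length(values))
  states[values > 0 & values <= boundary] <- 1L
  states[values > boundary] <- 2L
  if (!any(states == 2L))
    warn_ecobnet("no counts above the positive median: high state is empty",
                 "ecobnet_degenerate_warning")
  list(states = states, boundary = boundary)
}

#' Discretize a continuous variable into quartile states
#'
#' Empirical quartiles (type-7 interpolation) define four states: values at
#' or below Q1 map to state 0, at or below the median to 1, at or below Q3
#' to 2, and above Q3 to 3.
#'
#' @param values numeric vector with at least four distinct values.
#' @return A list with `states` (integer vector in 0..3) and `cuts`
#'   (the three quartile boundaries).
#' @examples
#' discretize_quartiles(1:8)
#' @export
discretize_quartiles <- function(values) {
  if (length(unique(values)) < 4L)
    abort_ecobnet(sprintf("only %d distinct value(s): quartile discretization is degenerate (declare the variable categorical instead)",
                          length(unique(values))),
                  "ecobnet_degenerate_error")
  cuts <- unname(quantile(values, probs = c(0.25, 0.5, 0.75), type = 7))
  states <- apply_quartile_cuts(values, cuts)
  list(states = states, cuts = cuts)
}

apply_quartile_cuts <- function(values, cuts) {
  as.integer((values > cuts[1]) + (values > cuts[2]) + (values > cuts[3]))
}

#' Discretize a categorical variable
#'
#' Categories are mapped to integer states by a stable lexicographic
#' ordering of the observed category labels, so the map does not depend on
#' row order.
#'
#' @param values character vector with at least two observed categories.
#' @return A list with `states` (integer vector) and `levels` (state `i`
#'   corresponds to `levels[i + 1]`).
#' @examples
#' discretize_categorical(c("Silt", "Gravel", "Rocky", "Silt"))
#' @export
discretize_categorical <- function(values) {
  values <- as.character(values)
  levels <- sort(unique(values))
  if (length(levels) < 2L)
    abort_ecobnet("single observed category: variable is degenerate",
                  "ecobnet_degenerate_error")
  list(states = match(values, levels) - 1L, levels = levels)
}

#' Discretize every variable of an abundance table
#'
#' Applies the rule declared in each variable's spec: [discretize_counts()]
#' for taxon/bin-group columns, [discretize_quartiles()] for continuous
#' columns, [discretize_categorical()] for categorical columns. Variables
#' that are degenerate under their rule (all-zero counts, fewer than four
#' distinct continuous values, a single category) are dropped with a
#' warning so the pipeline continues; set `drop_degenerate = FALSE` to
#' error instead.
#'
#' @param table an [abundance_table()].
#' @param drop_degenerate drop degenerate variables with a warning
#'   (default) rather than erroring.
#' @return An object of class `discretized_table` with fields
#'   `sample_ids`, `vars`, `states` (0-based integer matrix), `arity`,
#'   `boundaries` (per-variable cut points or category maps), `roles`.
#' @export
discretize_table <- function(table, drop_degenerate = TRUE) {
  stopifnot(inherits(table, "abundance_table"))
  states <- list(); arity <- integer(0); boundaries <- list(); roles <- character(0)
  for (i in seq_len(nrow(table$specs))) {
    nm <- table$specs$name[i]
    rule <- table$specs$rule[i]
    res <- tryCatch(
      switch(rule,
        zero_low_high = {
          d <- discretize_counts(table$values[[nm]])
          list(states = d$states, arity = 3L,
               boundary = list(rule = rule, boundary = d$boundary))
        },
        quartile = {
          d <- discretize_quartiles(table$values[[nm]])
          list(states = d$states, arity = 4L,
               boundary = list(rule = rule, cuts = d$cuts))
        },
        categorical_passthrough = {
          d <- discretize_categorical(table$values[[nm]])
          list(states = d$states, arity = length(d$levels),
               boundary = list(rule = rule, levels = d$levels))
        }),
      ecobnet_degenerate_error = function(e) {
        if (!drop_degenerate) stop(e)
        warn_ecobnet(sprintf("dropping degenerate variable '%s': %s",
                             nm, conditionMessage(e)),
                     "ecobnet_degenerate_warning")
        NULL
      })
    if (is.null(res)) next
    states[[nm]] <- res$states
    arity <- c(arity, res$arity)
    boundaries[[nm]] <- res$boundary
    roles <- c(roles, table$specs$role[i])
  }
  if (length(states) == 0L)
    abort_ecobnet("no variable survived discretization", "ecobnet_degenerate_error")
  mat <- do.call(cbind, states)
  rownames(mat) <- table$sample_ids
  structure(list(sample_ids = table$sample_ids, vars = colnames(mat),
                 states = mat, arity = setNames(arity, colnames(mat)),
                 boundaries = boundaries,
                 roles = setNames(roles, colnames(mat))),
            class = "discretized_table")
}

#' Re-apply recorded discretization boundaries to raw values
#'
#' Used to verify that recorded boundaries reproduce the state matrix
#' deterministically, and to discretize new samples on the boundaries of a
#' reference data set.
#'
#' @param values raw vector for one variable.
#' @param boundary one entry of `discretized_table$boundaries`.
#' @return Integer state vector.
#' @export
apply_boundaries <- function(values, boundary) {
  switch(boundary$rule,
    zero_low_high = {
      states <- integer(length(values))
      states[values > 0 & values <= boundary$boundary] <- 1L
      states[values > boundary$boundary] <- 2L
      states
    },
    quartile = apply_quartile_cuts(values, boundary$cuts),
    categorical_passthrough = {
      m <- match(as.character(values), boundary$levels)
      if (anyNA(m))
        abort_ecobnet("category not present in recorded map", "ecobnet_usage_error")
      m - 1L
    },
    abort_ecobnet("unknown discretization rule", "ecobnet_usage_error"))
}

#' Aggregate photo-scale samples into event-scale samples
#'
#' Groups photographs by the table's grouping key: taxon and bin-group
#' counts are summed within each event, continuous variables are averaged,
#' and categorical variables take the mode (ties broken by the
#' lexicographically smallest category). Event ids (sorted) become the
#' sample ids of the returned table.
#'
#' @param table a photo-scale [abundance_table()] with a grouping key.
#' @return An event-scale [abundance_table()].
#' @export
aggregate_events <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (is.null(table$grouping))
    abort_ecobnet("aggregate_events() needs a grouping key", "ecobnet_usage_error")
  events <- sort(unique(unname(table$grouping)))
  rows <- lapply(events, function(ev) {
    idx <- which(unname(table$grouping[table$sample_ids]) == ev)
    vals <- lapply(seq_len(nrow(table$specs)), function(i) {
      col <- table$values[[table$specs$name[i]]][idx]
      switch(table$specs$role[i],
        taxon = sum(col), bin_group = sum(col),
        continuous = mean(col),
        categorical = {
          tab <- table(col)
          winners <- names(tab)[tab == max(tab)]
          sort(winners)[1L]  # lexicographic tie-break
        })
    })
    setNames(as.data.frame(vals, stringsAsFactors = FALSE), table$specs$name)
  })
  abundance_table(do.call(rbind, rows), table$specs, sample_ids = events,
                  scale = "event")
}

#' Export a discretized table as CSV plus a JSON boundary sidecar
#' @param dtable a `discretized_table`.
#' @param csv_path path for the integer state matrix CSV.
#' @param json_path path for the boundaries/maps JSON sidecar.
#' @return `csv_path`, invisibly.
#' @export
write_discretized <- function(dtable, csv_path, json_path) {
  out <- cbind(data.frame(sample_id = dtable$sample_ids, stringsAsFactors = FALSE),
               as.data.frame(dtable$states))
  write.csv(out, csv_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(vars = dtable$vars, arity = as.list(dtable$arity),
         roles = as.list(dtable$roles), boundaries = dtable$boundaries),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' Read a discretized table written by [write_discretized()]
#' @param csv_path state matrix CSV path.
#' @param json_path boundary sidecar JSON path.
#' @return A `discretized_table`.
#' @export
read_discretized <- function(csv_path, json_path) {
  raw <- read.csv(csv_path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  vars <- meta$vars
  mat <- as.matrix(raw[, vars, drop = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- raw$sample_id
  boundaries <- lapply(meta$boundaries, function(b) {
    b$rule <- as.character(b$rule)
    b
  })
  structure(list(sample_ids = as.character(raw$sample_id), vars = vars,
                 states = mat,
                 arity = setNames(as.integer(unlist(meta$arity[vars])), vars),
                 boundaries = boundaries[vars],
                 roles = setNames(as.character(unlist(meta$roles[vars])), vars)),
            class = "discretized_table")
}

#' @export
print.discretized_table <- function(x, ...) {
  cat(sprintf("discretized_table: %d samples x %d variables\n",
              length(x$sample_ids), length(x$vars)))
  cat("  arity:", paste(sprintf("%s=%d", x$vars, x$arity), collapse = ", "), "\n")
  invisible(x)
}

# row subset preserving boundaries (used by the bootstrap)
subset_discretized <- function(dtable, idx) {
  structure(list(sample_ids = dtable$sample_ids[idx], vars = dtable$vars,
                 states = dtable$states[idx, , drop = FALSE],
                 arity = dtable$arity, boundaries = dtable$boundaries,
                 roles = dtable$roles),
            class = "discretized_table")
}
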