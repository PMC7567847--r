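#' Exclusion sets: variables and variable pairs barred from the search
#'
#' Zero-inflated count data generate spurious co-absence associations; two
#' filters guard against these Type I errors before structure learning.
#' [exclude_rare()] removes taxa observed in under a third of samples;
#' [contingency_exclusions()] bars edges between variable pairs whose joint
#' state distribution shows no evidence of deviating from the product of
#' their marginals (Pearson chi-squared, p above an anti-conservative 0.25
#' threshold).
#'
#' @param excluded_variables data frame with columns `name`, `occupancy`.
#' @param excluded_pairs data frame with columns `var1`, `var2`,
#'   `statistic`, `df`, `p_value` (unordered pairs, `var1 < var2`).
#' @return An object of class `exclusion_set`.
#' @export
exclusion_set <- function(excluded_variables = NULL, excluded_pairs = NULL) {
  if (is.null(excluded_variables))
    excluded_variables <- data.frame(name = character(0), occupancy = numeric(0),
                                     stringsAsFactors = FALSE)
  if (is.null(excluded_pairs))
    excluded_pairs <- data.frame(var1 = character(0), var2 = character(0),
                                 statistic = numeric(0), df = numeric(0),
                                 p_value = numeric(0), stringsAsFactors = FALSE)
  structure(list(excluded_variables = excluded_variables,
                 excluded_pairs = excluded_pairs),
            class = "exclusion_set")
}

#' Remove rare taxa before network inference
#'
#' Taxon and bin-group variables present (count > 0) in strictly fewer than
#' `threshold` of the samples are excluded. Physical variables (continuous,
#' categorical) are never excluded by this rule.
#'
#' @param table an [abundance_table()].
#' @param threshold occupancy fraction below which a taxon is rare
#'   (default 1/3).
#' @return A list with `kept` (variable names surviving the filter) and
#'   `exclusions` (an [exclusion_set()] recording the dropped taxa).
#' @examples
#' # a taxon present in 6 of 21 samples (28.6%) is excluded; 7 of 21 is kept
#' @export
exclude_rare <- function(table, threshold = 1 / 3) {
  stopifnot(inherits(table, "abundance_table"))
  n <- length(table$sample_ids)
  dropped <- character(0); occ_dropped <- numeric(0)
  kept <- character(0)
  for (i in seq_len(nrow(table$specs))) {
    nm <- table$specs$name[i]
    if (table$specs$role[i] %in% c("taxon", "bin_group")) {
      present <- sum(table$values[[nm]] > 0)
      if (present < threshold * n) {
        dropped <- c(dropped, nm)
        occ_dropped <- c(occ_dropped, present / n)
        next
      }
    }
    kept <- c(kept, nm)
  }
  list(kept = kept,
       exclusions = exclusion_set(
         excluded_variables = data.frame(name = dropped, occupancy = occ_dropped,
                                         stringsAsFactors = FALSE)))
}

#' Bar variable pairs with no evidence of joint dependence
#'
#' For every unordered variable pair, a Pearson chi-squared test (no
#' continuity correction) compares the observed state contingency table
#' with the product of the marginals; rows and columns with zero marginal
#' are dropped before computing the degrees of freedom. Pairs with
#' p > `p_threshold` are excluded as candidate edges in all subsequent
#' searches. The default threshold of 0.25 is deliberately
#' anti-conservative: only clear artefacts (e.g. joint zero-inflation) are
#' removed, never plausibly dependent pairs.
#'
#' @param dtable a `discretized_table`.
#' @param p_threshold exclusion p-value threshold (default 0.25).
#' @return An [exclusion_set()] with the excluded pairs and their test
#'   statistics.
#' @export
contingency_exclusions <- function(dtable, p_threshold = 0.25) {
  stopifnot(inherits(dtable, "discretized_table"))
  vars <- dtable$vars
  rows <- list()
  if (length(vars) >= 2L) {
    for (i in seq_len(length(vars) - 1L)) {
      for (j in seq(i + 1L, length(vars))) {
        res <- pair_chisq(dtable$states[, i], dtable$states[, j],
                          dtable$arity[i], dtable$arity[j])
        if (res$p_value > p_threshold)
          rows[[length(rows) + 1L]] <-
            data.frame(var1 = vars[i], var2 = vars[j],
                       statistic = res$statistic, df = res$df,
                       p_value = res$p_value, stringsAsFactors = FALSE)
      }
    }
  }
  exclusion_set(excluded_pairs = if (length(rows)) do.call(rbind, rows) else NULL)
}

# Pearson chi-squared on the observed state contingency table; empty rows
# and columns are dropped so df reflects the occupied table.
pair_chisq <- function(x, y, ax, ay) {
  tab <- table(factor(x, levels = 0:(ax - 1L)), factor(y, levels = 0:(ay - 1L)))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    return(list(statistic = 0, df = 0, p_value = 1))
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Merge exclusion sets
#' @param ... `exclusion_set` objects.
#' @return A single combined [exclusion_set()].
#' @export
merge_exclusions <- function(...) {
  sets <- list(...)
  exclusion_set(
    excluded_variables = unique(do.call(rbind, lapply(sets, `[[`, "excluded_variables"))),
    excluded_pairs = unique(do.call(rbind, lapply(sets, `[[`, "excluded_pairs"))))
}

#' Export an exclusion set to JSON
#' @param exclusions an [exclusion_set()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_exclusions <- function(exclusions, path) {
  jsonlite::write_json(
    list(excluded_variables = exclusions$excluded_variables,
         excluded_pairs = exclusions$excluded_pairs),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an exclusion set written by [write_exclusions()]
#' @param path JSON path.
#' @return An [exclusion_set()].
#' @export
read_exclusions <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- if (length(raw$excluded_variables)) as.data.frame(raw$excluded_variables) else NULL
  ep <- if (length(raw$excluded_pairs)) as.data.frame(raw$excluded_pairs) else NULL
  exclusion_set(excluded_variables = ev, excluded_pairs = ep)
}

#' @export
print.exclusion_set <- function(x, ...) {
  cat(sprintf("exclusion_set: %d rare variable(s), %d excluded pair(s)\n",
              nrow(x$excluded_variables), nrow(x$excluded_pairs)))
  invisible(x)
}
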