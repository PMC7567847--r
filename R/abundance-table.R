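#' Construct an abundance table
#'
#' A sample-by-variable table of community observations: integer counts for
#' taxon and bin-group columns, finite numeric values for continuous
#' columns, character categories for categorical columns. Samples are
#' photographs (`scale = "photo"`) or aggregated transect events
#' (`scale = "event"`); an optional grouping key maps each photo to its
#' event for [aggregate_events()].
#'
#' @param values data frame of observations, one row per sample, columns in
#'   spec order.
#' @param specs spec set from [variable_specs()].
#' @param sample_ids character vector of unique sample identifiers.
#' @param grouping optional named character vector mapping every sample id
#'   to an event id.
#' @param scale `"photo"` or `"event"`.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, specs, sample_ids = NULL,
                            grouping = NULL, scale = c("photo", "event")) {
  scale <- match.arg(scale)
  specs <- variable_specs(specs)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%04d", seq_len(nrow(values)))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    abort_ecobnet("duplicate sample ids", "ecobnet_validation_error")
  if (length(sample_ids) != nrow(values))
    abort_ecobnet("sample_ids length does not match rows", "ecobnet_validation_error")
  missing_cols <- setdiff(specs$name, names(values))
  if (length(missing_cols) > 0L)
    abort_ecobnet(sprintf("missing declared column(s): %s",
                          paste(missing_cols, collapse = ", ")),
                  "ecobnet_schema_error")
  values <- values[, specs$name, drop = FALSE]
  for (i in seq_len(nrow(specs))) {
    nm <- specs$name[i]
    col <- values[[nm]]
    if (specs$role[i] %in% c("taxon", "bin_group")) {
      colnum <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(colnum) | colnum < 0 | colnum != round(colnum))
      if (length(bad) > 0L)
        abort_ecobnet(
          sprintf("column '%s', row %d (sample '%s'): value '%s' is not a non-negative integer count",
                  nm, bad[1L], sample_ids[bad[1L]], as.character(col[bad[1L]])),
          "ecobnet_validation_error")
      values[[nm]] <- as.integer(colnum)
    } else if (specs$role[i] == "continuous") {
      colnum <- suppressWarnings(as.numeric(col))
      bad <- which(!is.finite(colnum))
      if (length(bad) > 0L)
        abort_ecobnet(
          sprintf("column '%s', row %d (sample '%s'): value '%s' is not finite",
                  nm, bad[1L], sample_ids[bad[1L]], as.character(col[bad[1L]])),
          "ecobnet_validation_error")
      values[[nm]] <- colnum
    } else {
      if (anyNA(col) || any(!nzchar(as.character(col))))
        abort_ecobnet(sprintf("column '%s': empty or missing category", nm),
                      "ecobnet_validation_error")
      values[[nm]] <- as.character(col)
    }
  }
  if (!is.null(grouping)) {
    grouping <- grouping[sample_ids]
    if (anyNA(grouping))
      abort_ecobnet("grouping key does not cover every sample", "ecobnet_validation_error")
    names(grouping) <- sample_ids
  }
  rownames(values) <- NULL
  structure(list(sample_ids = sample_ids, specs = specs, values = values,
                 grouping = grouping, scale = scale),
            class = "abundance_table")
}

#' Read an abundance table from CSV
#'
#' The file must be RFC-4180 CSV with a header row naming every declared
#' variable; one row per sample. Extra columns can carry sample ids and the
#' photo-to-event grouping key.
#'
#' @param path CSV file path.
#' @param specs spec set from [variable_specs()] or [read_variable_specs()].
#' @param id_col optional name of a column holding sample ids.
#' @param group_col optional name of a column holding event ids (the
#'   grouping key).
#' @param scale `"photo"` (default) or `"event"`.
#' @return An [abundance_table()].
#' @export
read_samples <- function(path, specs, id_col = NULL, group_col = NULL,
                         scale = "photo") {
  if (!file.exists(path))
    abort_ecobnet(sprintf("input file not found: %s", path), "ecobnet_usage_error")
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  specs <- variable_specs(specs)
  sample_ids <- if (!is.null(id_col)) {
    if (!id_col %in% names(raw))
      abort_ecobnet(sprintf("missing declared column(s): %s", id_col),
                    "ecobnet_schema_error")
    as.character(raw[[id_col]])
  } else NULL
  grouping <- NULL
  if (!is.null(group_col)) {
    if (!group_col %in% names(raw))
      abort_ecobnet(sprintf("missing declared column(s): %s", group_col),
                    "ecobnet_schema_error")
    ids <- if (is.null(sample_ids)) sprintf("s%04d", seq_len(nrow(raw))) else sample_ids
    grouping <- setNames(as.character(raw[[group_col]]), ids)
  }
  abundance_table(raw, specs, sample_ids = sample_ids, grouping = grouping,
                  scale = scale)
}

#' Write an abundance table to CSV
#'
#' Inverse of [read_samples()]: writes sample ids in column `sample_id` and,
#' when a grouping key is present, event ids in column `event_id`.
#'
#' @param table an [abundance_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(table, path) {
  out <- cbind(data.frame(sample_id = table$sample_ids, stringsAsFactors = FALSE),
               table$values)
  if (!is.null(table$grouping))
    out$event_id <- unname(table$grouping[table$sample_ids])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d variables (%s scale)\n",
              length(x$sample_ids), nrow(x$specs), x$scale))
  tab <- table(x$specs$role)
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(x$grouping))
    cat(sprintf("  grouping: %d events\n", length(unique(x$grouping))))
  invisible(x)
}
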