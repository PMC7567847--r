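#' Declare a variable of an abundance table
#'
#' Every column of an abundance table carries a role that determines how it
#' is discretized and filtered: `taxon` and `bin_group` columns are
#' non-negative integer counts binned into zero/low/high states, `continuous`
#' columns (depth, percent encrusting) are binned into quartiles, and
#' `categorical` columns (region, substrate) are passed through as observed
#' categories.
#'
#' @param name column name, unique within a spec set.
#' @param role one of `"taxon"`, `"continuous"`, `"categorical"`,
#'   `"bin_group"`.
#' @param rule discretization rule; defaults to the only rule valid for the
#'   role (`zero_low_high` for counts, `quartile` for continuous,
#'   `categorical_passthrough` for categories).
#' @return A one-row data frame with columns `name`, `role`, `rule`.
#' @examples
#' variable_spec("Porifera", "taxon")
#' variable_spec("Depth", "continuous")
#' @export
variable_spec <- function(name, role, rule = NULL) {
  roles <- c("taxon", "continuous", "categorical", "bin_group")
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    abort_ecobnet("variable name must be a non-empty string", "ecobnet_usage_error")
  role <- match.arg(role, roles)
  default_rule <- switch(role,
    taxon = "zero_low_high", bin_group = "zero_low_high",
    continuous = "quartile", categorical = "categorical_passthrough")
  if (is.null(rule)) rule <- default_rule
  rule <- match.arg(rule, c("zero_low_high", "quartile", "categorical_passthrough"))
  if (rule != default_rule)
    abort_ecobnet(
      sprintf("role '%s' requires rule '%s', got '%s'", role, default_rule, rule),
      "ecobnet_usage_error")
  data.frame(name = name, role = role, rule = rule, stringsAsFactors = FALSE)
}

#' Combine variable specs into a spec set
#'
#' @param ... one-row spec data frames from [variable_spec()], or a single
#'   data frame with columns `name`, `role`, `rule`.
#' @return A data frame of specs; names are checked for uniqueness.
#' @export
variable_specs <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.data.frame(parts[[1L]]) && nrow(parts[[1L]]) > 1L)
    specs <- parts[[1L]]
  else
    specs <- do.call(rbind, parts)
  if (anyDuplicated(specs$name))
    abort_ecobnet("duplicate variable names in spec set", "ecobnet_usage_error")
  # re-validate each row through the constructor
  for (i in seq_len(nrow(specs)))
    variable_spec(specs$name[i], specs$role[i], specs$rule[i])
  rownames(specs) <- NULL
  specs
}

#' Read variable specs from a plain-text config file
#'
#' Each non-blank, non-comment line declares one variable as
#' `name = role` or `name = role rule`. Lines starting with `#` are ignored.
#'
#' @param path path to the config file.
#' @return A spec set data frame as from [variable_specs()].
#' @export
read_variable_specs <- function(path) {
  if (!file.exists(path))
    abort_ecobnet(sprintf("spec file not found: %s", path), "ecobnet_usage_error")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    abort_ecobnet("spec file declares no variables", "ecobnet_schema_error")
  rows <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], "=", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      abort_ecobnet(sprintf("line %d: expected 'name = role [rule]'", i),
                    "ecobnet_parse_error")
    name <- trimws(parts[1L])
    rhs <- strsplit(trimws(parts[2L]), "[[:space:]]+")[[1L]]
    variable_spec(name, rhs[1L], if (length(rhs) > 1L) rhs[2L] else NULL)
  })
  variable_specs(do.call(rbind, rows))
}

#' Write variable specs to a plain-text config file
#' @param specs spec set data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variable_specs <- function(specs, path) {
  writeLines(sprintf("%s = %s", specs$name, specs$role), path)
  invisible(path)
}
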