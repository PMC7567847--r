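#' Write a consensus network to disk
#'
#' Three formats are supported. `tsv` is a canonical edge list with one row
#' per undirected pair (columns `source`, `target`, `direction`,
#' `occurrence`, `mean_is`, numeric fields at 6 decimal places); `graphml`
#' goes through igraph with the same edge attributes; `json` additionally
#' preserves isolated nodes, the occurrence threshold and the summary
#' block.
#'
#' @param network a `consensus_network`.
#' @param path output file path.
#' @param format `"tsv"`, `"graphml"` or `"json"`; inferred from the file
#'   extension when missing.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = NULL) {
  stopifnot(inherits(network, "consensus_network"))
  format <- resolve_format(path, format)
  e <- network$edges
  if (format == "tsv") {
    lines <- c("source\ttarget\tdirection\toccurrence\tmean_is",
               if (nrow(e)) sprintf("%s\t%s\t%s\t%.6f\t%.6f",
                                    e$source, e$target, e$direction,
                                    e$occurrence, e$mean_is))
    writeLines(lines, path)
  } else if (format == "graphml") {
    g <- igraph::make_empty_graph(n = length(network$nodes), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = network$nodes)
    if (nrow(e) > 0L)
      g <- igraph::add_edges(g, rbind(e$source, e$target),
                             direction = e$direction,
                             occurrence = round(e$occurrence, 6),
                             mean_is = round(e$mean_is, 6))
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "json") {
    jsonlite::write_json(
      list(nodes = network$nodes, edges = e, threshold = network$threshold,
           summary = network$summary),
      path, dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    abort_ecobnet(sprintf("unknown network format '%s'", format),
                  "ecobnet_usage_error")
  }
  invisible(path)
}

#' Read a consensus network written by [write_network()]
#'
#' @param path file path.
#' @param format `"tsv"`, `"graphml"` or `"json"`; inferred from the
#'   extension when missing.
#' @return A `consensus_network`. The TSV and GraphML forms carry no
#'   occurrence threshold; it is restored as `NA`.
#' @export
read_network <- function(path, format = NULL) {
  if (!file.exists(path))
    abort_ecobnet(sprintf("network file not found: %s", path), "ecobnet_usage_error")
  format <- resolve_format(path, format)
  if (format == "tsv") {
    lines <- readLines(path, warn = FALSE)
    header <- "source\ttarget\tdirection\toccurrence\tmean_is"
    if (length(lines) == 0L || lines[1L] != header)
      abort_ecobnet("line 1: malformed or missing TSV header", "ecobnet_parse_error")
    rows <- lapply(seq_along(lines)[-1L], function(i) {
      parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
      if (length(parts) != 5L)
        abort_ecobnet(sprintf("line %d: expected 5 tab-separated fields, got %d",
                              i, length(parts)), "ecobnet_parse_error")
      occ <- suppressWarnings(as.numeric(parts[4L]))
      mis <- suppressWarnings(as.numeric(parts[5L]))
      if (is.na(occ) || is.na(mis))
        abort_ecobnet(sprintf("line %d: non-numeric occurrence or mean_is", i),
                      "ecobnet_parse_error")
      data.frame(source = parts[1L], target = parts[2L], direction = parts[3L],
                 occurrence = occ, mean_is = mis, stringsAsFactors = FALSE)
    })
    edges <- if (length(rows)) do.call(rbind, rows) else
      data.frame(source = character(0), target = character(0),
                 direction = character(0), occurrence = numeric(0),
                 mean_is = numeric(0), stringsAsFactors = FALSE)
    consensus_network(unique(c(edges$source, edges$target)), edges)
  } else if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- igraph::vertex_attr(g, "name")
    if (igraph::ecount(g) > 0L) {
      ends <- igraph::as_edgelist(g)
      edges <- data.frame(source = ends[, 1L], target = ends[, 2L],
                          direction = igraph::edge_attr(g, "direction"),
                          occurrence = igraph::edge_attr(g, "occurrence"),
                          mean_is = igraph::edge_attr(g, "mean_is"),
                          stringsAsFactors = FALSE)
    } else {
      edges <- data.frame(source = character(0), target = character(0),
                          direction = character(0), occurrence = numeric(0),
                          mean_is = numeric(0), stringsAsFactors = FALSE)
    }
    consensus_network(nodes, edges)
  } else if (format == "json") {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    edges <- if (length(raw$edges)) as.data.frame(raw$edges) else
      data.frame(source = character(0), target = character(0),
                 direction = character(0), occurrence = numeric(0),
                 mean_is = numeric(0), stringsAsFactors = FALSE)
    thr <- if (is.null(raw$threshold)) NA_real_ else as.numeric(raw$threshold)
    consensus_network(raw$nodes, edges, threshold = thr)
  } else {
    abort_ecobnet(sprintf("unknown network format '%s'", format),
                  "ecobnet_usage_error")
  }
}

resolve_format <- function(path, format) {
  if (!is.null(format)) {
    if (!format %in% c("tsv", "graphml", "json"))
      abort_ecobnet(sprintf("unknown network format '%s'", format),
                    "ecobnet_usage_error")
    return(format)
  }
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("tsv", "graphml", "json"))
    abort_ecobnet(sprintf("cannot infer network format from extension '.%s'", ext),
                  "ecobnet_usage_error")
  ext
}

#' Write a DAG as a TSV edge list
#' @param dag a `bn_dag`.
#' @param path output path (columns `source`, `target`).
#' @return `path`, invisibly.
#' @export
write_dag <- function(dag, path) {
  e <- dag_edges(dag)
  writeLines(c("source\ttarget",
               if (nrow(e)) sprintf("%s\t%s", e$from, e$to)), path)
  invisible(path)
}
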