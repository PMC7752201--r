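#' Export and import co-sort networks
#'
#' Networks are written with canonical quote ids as node names, an integer
#' `weight` edge attribute, the researcher count as a `researchers` graph
#' attribute and, when a grouping assignment is supplied, a `group` node
#' attribute. GraphML, GML and the plain edge-list round-trip exactly
#' through [import_network()]; DOT is write-only (a rendering format).
#'
#' The edge-list format is one `i j w` line per edge, preceded by comment
#' lines (`# researchers: R`, `# nodes: ...`) that preserve the researcher
#' count and isolated nodes.
#'
#' @param net a [cosort_network()].
#' @param path output file path.
#' @param format one of `"graphml"`, `"gml"`, `"dot"`, `"edgelist"`.
#' @param assignment optional grouping to embed as `group` node attribute.
#' @return `export_network()` returns `path` invisibly; `import_network()`
#'   returns a [cosort_network()].
#' @export
export_network <- function(net, path,
                           format = c("graphml", "gml", "dot", "edgelist"),
                           assignment = NULL) {
  stopifnot(inherits(net, "cosort_network"))
  format <- tryCatch(match.arg(format),
                     error = function(e) pte_stop("usage",
                       "unknown network format: ", format[1]))
  if (format == "edgelist") {
    ids <- rownames(net$weights)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste("# researchers:", net$n_researchers),
                 paste("# nodes:", paste(ids, collapse = " "))), con)
    if (!is.null(assignment)) {
      miss <- setdiff(ids, names(assignment))
      if (length(miss)) {
        pte_stop("coverage", "assignment misses node(s): ",
                 paste(miss, collapse = ", "))
      }
      writeLines(paste("# groups:",
                       paste(as.character(assignment[ids]), collapse = " ")),
                 con)
    }
    ut <- which(upper.tri(net$weights) & net$weights > 0, arr.ind = TRUE)
    if (nrow(ut)) {
      writeLines(paste(ids[ut[, 1]], ids[ut[, 2]],
                       net$weights[ut]), con)
    }
    return(invisible(path))
  }
  g <- cosort_igraph(net, assignment)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path, format = NULL) {
  if (!file.exists(path)) pte_stop("io", "file not found: ", path)
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
    if (format %in% c("txt", "el")) format <- "edgelist"
  }
  if (!format %in% c("graphml", "gml", "edgelist")) {
    pte_stop("usage", "cannot import format ", sQuote(format),
             " (supported: graphml, gml, edgelist)")
  }
  if (format == "edgelist") {
    lines <- readLines(path, warn = FALSE)
    hdr <- function(key) {
      l <- grep(paste0("^#\\s*", key, ":"), lines, value = TRUE)
      if (!length(l)) return(NULL)
      strsplit(trimws(sub(paste0("^#\\s*", key, ":"), "", l[1])), "\\s+")[[1]]
    }
    nodes <- hdr("nodes")
    nr <- hdr("researchers")
    edges <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    parts <- strsplit(trimws(edges), "\\s+")
    if (length(parts) && any(lengths(parts) != 3L)) {
      pte_stop("format", "edge-list lines must be 'i j w'")
    }
    ei <- vapply(parts, `[`, "", 1)
    ej <- vapply(parts, `[`, "", 2)
    ew <- as.numeric(vapply(parts, `[`, "", 3))
    if (is.null(nodes)) nodes <- unique(c(ei, ej))
    q <- parse_quote_id(nodes)
    ids <- format_quote_id(q)
    W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    ii <- match(format_quote_id(parse_quote_id(ei)), ids)
    jj <- match(format_quote_id(parse_quote_id(ej)), ids)
    W[cbind(ii, jj)] <- ew
    W[cbind(jj, ii)] <- ew
    if (is.null(nr)) {
      pte_stop("format", "edge-list lacks the '# researchers:' header")
    }
    return(cosort_network(W, n_researchers = as.integer(nr)))
  }
  g <- igraph::read_graph(path, format = format)
  nm <- igraph::vertex_attr(g, "name")
  if (is.null(nm)) nm <- igraph::vertex_attr(g, "label")
  if (is.null(nm)) pte_stop("format", "graph file carries no node names")
  g <- igraph::set_vertex_attr(g, "name", value = nm)
  W <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight",
                                             sparse = FALSE))
  nr <- igraph::graph_attr(g, "researchers")
  if (is.null(nr)) pte_stop("format", "graph file lacks the 'researchers' ",
                            "graph attribute")
  cosort_network(W, n_researchers = as.integer(round(as.numeric(nr))))
}
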