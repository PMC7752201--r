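#' Build the quote co-occurrence network
#'
#' Nodes are quotes; two quotes are connected if at least one researcher
#' placed them in the same pile, and the edge weight counts the researchers
#' who did so. All quotes are retained as nodes, including quotes never
#' co-placed with any other (isolated nodes become singleton groupings
#' downstream). Weights are raw researcher counts, never normalized, so
#' `0 <= weight <= R` for `R` researchers.
#'
#' @param study a [sorting_study()].
#' @return Object of class `cosort_network`: list with `weights` (symmetric
#'   integer matrix with zero diagonal, dimnames = canonical quote ids),
#'   `quotes` (integer quote values) and `n_researchers`.
#' @examples
#' rec <- data.frame(researcher = "r1", quote = 1:3, pile = c("A", "A", "B"))
#' build_cosort_network(sorting_study(rec))
#' @export
build_cosort_network <- function(study) {
  stopifnot(inherits(study, "sorting_study"))
  q <- study$quotes
  n <- length(q)
  ids <- format_quote_id(q)
  W <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (r in study$researchers) {
    for (pile in study_piles(study, r)) {
      if (length(pile) >= 2L) {
        idx <- match(pile, q)
        W[idx, idx] <- W[idx, idx] + 1L
      }
    }
  }
  diag(W) <- 0L
  cosort_network(W, n_researchers = length(study$researchers))
}

#' Low-level co-sort network constructor
#'
#' @param weights symmetric non-negative matrix with zero diagonal; dimnames
#'   must be canonical quote ids (or parseable quote ids).
#' @param n_researchers number of researchers whose sorts the weights count.
#' @return A `cosort_network`.
#' @export
cosort_network <- function(weights, n_researchers) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    pte_stop("format", "weight matrix must be square")
  }
  if (is.null(rownames(weights))) {
    pte_stop("format", "weight matrix must carry quote ids as dimnames")
  }
  quotes <- parse_quote_id(rownames(weights))
  if (anyDuplicated(quotes)) pte_stop("integrity", "duplicate quote ids")
  ord <- order(quotes)
  quotes <- quotes[ord]
  weights <- weights[ord, ord, drop = FALSE]
  ids <- format_quote_id(quotes)
  dimnames(weights) <- list(ids, ids)
  if (any(weights < 0)) pte_stop("format", "negative edge weight")
  if (any(diag(weights) != 0)) pte_stop("format", "self-loops are not allowed")
  if (!isTRUE(all.equal(weights, t(weights), check.attributes = FALSE))) {
    pte_stop("format", "weight matrix must be symmetric")
  }
  n_researchers <- as.integer(n_researchers)
  if (any(weights > n_researchers)) {
    pte_stop("format", "edge weight exceeds the number of researchers")
  }
  structure(list(weights = weights, quotes = quotes,
                 n_researchers = n_researchers),
            class = "cosort_network")
}

#' @export
print.cosort_network <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] > 0)
  iso <- sum(rowSums(x$weights) == 0)
  cat("Co-sort network: ", length(x$quotes), " quotes, ", ne,
      " edges (", iso, " isolated), ", x$n_researchers, " researchers\n",
      sep = "")
  invisible(x)
}

#' Convert a co-sort network to an igraph object
#'
#' Vertices are named by canonical quote ids and edges carry an integer
#' `weight` attribute; the researcher count is stored as graph attribute
#' `researchers`. An optional grouping assignment is attached as vertex
#' attribute `group`.
#'
#' @param net a [cosort_network()].
#' @param assignment optional named grouping vector covering all nodes.
#' @return An [igraph::graph] object.
#' @export
cosort_igraph <- function(net, assignment = NULL) {
  stopifnot(inherits(net, "cosort_network"))
  g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                           weighted = TRUE)
  g <- igraph::set_graph_attr(g, "researchers", net$n_researchers)
  if (!is.null(assignment)) {
    ids <- rownames(net$weights)
    missing <- setdiff(ids, names(assignment))
    if (length(missing)) {
      pte_stop("coverage", "assignment misses node(s): ",
               paste(missing, collapse = ", "))
    }
    igraph::V(g)$group <- as.character(assignment[ids])
  }
  g
}
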