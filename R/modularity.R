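#' Weighted modularity of a grouping
#'
#' Newman–Girvan modularity with a resolution parameter:
#' \deqn{Q = \frac{1}{2m}\sum_{ij}\left[w_{ij} -
#'   \gamma\frac{k_i k_j}{2m}\right]\delta(c_i, c_j)}
#' where \eqn{w_{ij}} is the co-sort weight, \eqn{k_i} the weighted degree
#' (strength) of quote \eqn{i}, \eqn{2m} the total weight, and
#' \eqn{\gamma} the resolution (1 recovers the classic definition). The
#' all-in-one-community grouping scores exactly 0 at \eqn{\gamma = 1}.
#'
#' @param net a [cosort_network()].
#' @param assignment named grouping vector covering every node of `net`.
#' @param resolution positive resolution parameter \eqn{\gamma}.
#' @return Numeric modularity value in `[-1, 1]`.
#' @examples
#' W <- matrix(0, 3, 3, dimnames = rep(list(c("ID01", "ID02", "ID03")), 2))
#' W[1, 2] <- W[2, 1] <- 1
#' net <- cosort_network(W, n_researchers = 1)
#' modularity_score(net, c(ID01 = 1, ID02 = 1, ID03 = 2))
#' @export
modularity_score <- function(net, assignment, resolution = 1) {
  stopifnot(inherits(net, "cosort_network"))
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0) {
    pte_stop("usage", "resolution must be a positive number")
  }
  W <- net$weights
  m2 <- sum(W)
  if (m2 <= 0) {
    pte_stop("degenerate", "modularity is undefined on a network ",
             "with no edges")
  }
  ids <- rownames(W)
  missing <- setdiff(ids, names(assignment))
  if (length(missing)) {
    pte_stop("coverage", "assignment misses node(s): ",
             paste(missing, collapse = ", "))
  }
  memb <- as.character(assignment[ids])
  k <- rowSums(W)
  same <- outer(memb, memb, `==`)
  sum((W - resolution * outer(k, k) / m2) * same) / m2
}

# Canonical community labels: 1..K ordered by community size (descending),
# ties broken by the smallest member quote value.
canonical_labels <- function(memb, quote_values) {
  f <- as.integer(factor(memb, levels = unique(memb)))
  size <- tabulate(f)
  minq <- vapply(seq_len(max(f)), function(c) min(quote_values[f == c]),
                 numeric(1))
  ord <- order(-size, minq)
  rank <- integer(length(ord))
  rank[ord] <- seq_along(ord)
  rank[f]
}
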