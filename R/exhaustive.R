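#' Exhaustive maximum-modularity grouping (small-graph oracle)
#'
#' Enumerates every set partition of the node set (restricted-growth-string
#' order) and returns one attaining maximal modularity. Intended as an
#' independent oracle for validating heuristic community detection on small
#' networks; guarded to at most 10 nodes (Bell(10) = 115,975 partitions).
#'
#' Ties within `tol` of the maximum are broken by fewest communities, then
#' by the lexicographically smallest restricted growth string (first found
#' in enumeration order).
#'
#' @param net a [cosort_network()] with at most 10 nodes and at least one
#'   edge.
#' @param resolution positive resolution parameter \eqn{\gamma}.
#' @param tol numeric tolerance used when comparing modularity values.
#' @return Named integer vector of canonical community labels, with the
#'   achieved modularity in attribute `"modularity"`.
#' @export
exhaustive_max_modularity <- function(net, resolution = 1, tol = 1e-12) {
  stopifnot(inherits(net, "cosort_network"))
  n <- length(net$quotes)
  if (n > 10L) {
    pte_stop("usage", "exhaustive search is limited to 10 nodes (got ",
             n, ")")
  }
  W <- net$weights
  storage.mode(W) <- "double"
  m2 <- sum(W)
  if (m2 <= 0) {
    pte_stop("degenerate", "modularity is undefined on a network ",
             "with no edges")
  }
  k <- rowSums(W)
  B <- W - resolution * outer(k, k) / m2   # modularity matrix (gamma-scaled)

  best_q <- -Inf
  best <- NULL
  best_k <- Inf
  a <- rep(1L, n)
  repeat {
    same <- outer(a, a, `==`)
    q <- sum(B[same]) / m2
    nc <- max(a)
    if (q > best_q + tol || (q > best_q - tol && nc < best_k)) {
      best_q <- max(q, best_q)
      best <- a
      best_k <- nc
    }
    # successor in restricted-growth-string order
    i <- n
    while (i >= 2L) {
      if (a[i] <= max(a[1:(i - 1L)])) break
      i <- i - 1L
    }
    if (i < 2L) break
    a[i] <- a[i] + 1L
    if (i < n) a[(i + 1L):n] <- 1L
  }
  out <- setNames(canonical_labels(best, net$quotes), rownames(W))
  attr(out, "modularity") <- modularity_score(net, out,
                                              resolution = resolution)
  out
}
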