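#' Louvain community detection on a co-sort network
#'
#' Greedy two-phase modularity maximization: nodes are repeatedly moved to
#' the neighbouring community with the largest modularity gain (local
#' moving), then communities are collapsed into single nodes (aggregation),
#' until a full level produces no move. Node visit order within each pass
#' is a seeded shuffle, so results are deterministic for a fixed seed; a
#' move is accepted only if its gain exceeds `tol`.
#'
#' Edge weights (researcher co-placement counts) drive the optimization by
#' default; `weighted = FALSE` collapses every edge to weight 1. Isolated
#' quotes end up in singleton communities. A network with no edges yields
#' the all-singletons grouping with a warning (its modularity is
#' undefined).
#'
#' Returned labels are canonical: consecutive integers `1..K` ordered by
#' community size (descending), ties broken by smallest member quote, so
#' groupings are comparable across runs and analyst groups.
#'
#' @param net a [cosort_network()].
#' @param seed integer seed for the node-order shuffles.
#' @param resolution positive resolution parameter \eqn{\gamma}; values
#'   below 1 favour fewer, larger groupings, values above 1 more, smaller
#'   ones.
#' @param weighted use researcher counts as edge weights (default) or treat
#'   all edges alike.
#' @param tol minimum modularity gain for accepting a move.
#' @return Named integer vector: canonical quote id -> community label.
#' @seealso [modularity_score()], [exhaustive_max_modularity()]
#' @export
louvain_communities <- function(net, seed = 0L, resolution = 1,
                                weighted = TRUE, tol = 1e-12) {
  stopifnot(inherits(net, "cosort_network"))
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0) {
    pte_stop("usage", "resolution must be a positive number")
  }
  W <- net$weights
  storage.mode(W) <- "double"
  if (!weighted) W <- (W > 0) * 1
  ids <- rownames(W)
  if (sum(W) <= 0) {
    warning("network has no edges; returning all-singleton groupings",
            call. = FALSE)
    return(setNames(canonical_labels(seq_along(ids), net$quotes), ids))
  }
  memb <- with_seed(seed, louvain_core(W, gamma = resolution, tol = tol))
  setNames(canonical_labels(memb, net$quotes), ids)
}

# Multi-level driver. `W` is a symmetric weight matrix whose diagonal holds
# twice the collapsed self-weight (zero at the first level), so rowSums()
# are strengths and sum(W) = 2m at every level.
louvain_core <- function(W, gamma, tol) {
  W0 <- W
  memb_global <- seq_len(nrow(W))
  repeat {
    memb <- louvain_local_pass(W, gamma, tol)
    memb_global <- memb[memb_global]
    uniq <- sort(unique(memb))
    if (length(uniq) == nrow(W)) break   # level brought no merge: done
    f <- factor(memb, levels = uniq)
    W <- rowsum(t(rowsum(W, f)), f)      # aggregate; diag = 2 * internal
    memb_global <- match(memb_global, uniq)
  }
  # refinement: one more round of single-node moves on the original graph,
  # seeded with the multi-level result (never decreases modularity)
  louvain_local_pass(W0, gamma, tol, init = memb_global)
}

# One level of local moving. Returns the community membership (arbitrary
# labels) reached when a complete pass moves no node.
louvain_local_pass <- function(W, gamma, tol, init = seq_len(nrow(W))) {
  n <- nrow(W)
  k <- rowSums(W)
  m2 <- sum(W)
  m <- m2 / 2
  memb <- init
  tot <- vapply(seq_len(n), function(c) sum(k[memb == c]), numeric(1))
  size <- tabulate(memb, nbins = n)
  repeat {
    moved <- FALSE
    for (i in sample.int(n)) {
      a <- memb[i]
      wi <- W[i, ]
      wi[i] <- 0
      tot[a] <- tot[a] - k[i]
      size[a] <- size[a] - 1L
      # candidate communities: neighbours, the current one, and a fresh
      # empty slot (so a node can always strike out on its own)
      nb <- memb[wi > 0]
      cand <- unique(c(a, nb))
      empty <- which(size == 0L)
      if (length(empty)) cand <- unique(c(cand, empty[1L]))
      wlink <- vapply(cand, function(c) sum(wi[memb == c]), numeric(1))
      gain <- wlink / m - gamma * k[i] * tot[cand] / (2 * m * m)
      best <- cand[which.max(gain)]
      if (best != a && max(gain) > gain[match(a, cand)] + tol) {
        memb[i] <- best
        moved <- TRUE
      }
      tot[memb[i]] <- tot[memb[i]] + k[i]
      size[memb[i]] <- size[memb[i]] + 1L
    }
    if (!moved) break
  }
  memb
}
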