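# Independent oracles and fixture builders shared across the test files.
# These deliberately use the most naive formulation available so they stay
# independent of the implementation paths they check.

# Random symmetric weight matrix over n quotes; guarantees >= 1 edge.
random_net <- function(n, p_edge = 0.5, w_max = 4L, n_researchers = w_max) {
  repeat {
    W <- matrix(0, n, n)
    ut <- upper.tri(W)
    w <- ifelse(runif(sum(ut)) < p_edge,
                sample.int(w_max, sum(ut), replace = TRUE), 0)
    W[ut] <- w
    W <- W + t(W)
    if (sum(W) > 0) break
  }
  dimnames(W) <- list(format_quote_id(seq_len(n)),
                      format_quote_id(seq_len(n)))
  cosort_network(W, n_researchers = n_researchers)
}

# Random sorting study built directly from records (independent of synth).
random_study <- function(n_quotes, n_researchers, max_piles = 5L) {
  recs <- do.call(rbind, lapply(seq_len(n_researchers), function(r) {
    repeat {
      piles <- sample.int(max_piles, n_quotes, replace = TRUE)
      if (length(unique(piles)) >= 2L) break
    }
    data.frame(researcher = paste0("r", r), quote = seq_len(n_quotes),
               pile = as.character(piles))
  }))
  sorting_study(recs)
}

# Direct double-sum modularity: Q = (1/2m) sum_ij (w_ij - g k_i k_j / 2m) d_ij
naive_modularity <- function(W, memb, gamma = 1) {
  n <- nrow(W)
  k <- rowSums(W)
  m2 <- sum(W)
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (memb[i] == memb[j]) {
        q <- q + W[i, j] - gamma * k[i] * k[j] / m2
      }
    }
  }
  unname(q) / m2
}

# First-principles ARI by classifying every unordered pair.
naive_ari <- function(a, b) {
  b <- b[names(a)]
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  np <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / np
  maximum <- ((n11 + n10) + (n11 + n01)) / 2
  if (maximum == expected) return(1)
  (n11 - expected) / (maximum - expected)
}

# Brute-force co-sort tally: count researchers co-placing each pair.
naive_cosort_weight <- function(study, qi, qj) {
  sum(vapply(study$researchers, function(r) {
    rec <- study$records[study$records$researcher == r, ]
    pi <- rec$pile[rec$quote == qi]
    pj <- rec$pile[rec$quote == qj]
    length(pi) == 1 && length(pj) == 1 && pi == pj
  }, logical(1)))
}

# Sum of C(|pile|, 2) over all researchers' piles (handshake identity RHS).
handshake_rhs <- function(study) {
  sum(vapply(study$researchers, function(r) {
    sum(choose(lengths(study_piles(study, r)), 2))
  }, numeric(1)))
}

extdata <- function(...) system.file("extdata", ..., package = "pte")
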