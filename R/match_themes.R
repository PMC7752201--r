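#' Match two theme collections by quote overlap
#'
#' Computes the full Jaccard matrix `|A_i ∩ B_j| / |A_i ∪ B_j|` between the
#' themes of two collections (e.g. the co-researcher and academic analyst
#' groups), then pairs themes greedily: the largest Jaccard first, each
#' theme matched at most once, ties broken by earlier theme index in the
#' first then the second collection. Pairs with zero overlap are never
#' matched. Greedy best-match mirrors the informal side-by-side comparison
#' done in a joint workshop; it is a transparent heuristic, not an optimal
#' assignment.
#'
#' @param a,b [theme_collection()] objects.
#' @return Object of class `theme_match`: list with `jaccard` (matrix,
#'   dimnames = theme labels) and `matches` (data frame with columns
#'   `theme_a`, `theme_b`, `jaccard`, `n_shared`, `shared` — shared quotes
#'   as a comma-separated canonical id string).
#' @examples
#' a <- theme_collection("social", list(c(14, 4, 2, 40, 49, 12, 80, 89)))
#' b <- theme_collection("social", list(c(2, 4, 12, 14, 80, 89, 10)))
#' match_theme_sets(a, b)
#' @export
match_theme_sets <- function(a, b) {
  stopifnot(inherits(a, "theme_collection"), inherits(b, "theme_collection"))
  na <- length(a$labels)
  nb <- length(b$labels)
  J <- matrix(0, na, nb, dimnames = list(a$labels, b$labels))
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      inter <- length(intersect(a$quotes[[i]], b$quotes[[j]]))
      uni <- length(union(a$quotes[[i]], b$quotes[[j]]))
      J[i, j] <- inter / uni
    }
  }

  free_a <- rep(TRUE, na)
  free_b <- rep(TRUE, nb)
  rows <- list()
  repeat {
    Jf <- J
    Jf[!free_a, ] <- -1
    Jf[, !free_b] <- -1
    if (all(Jf <= 0)) break
    # largest Jaccard; ties -> earliest a index, then earliest b index
    best <- which(Jf == max(Jf), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[[1]]
    j <- best[[2]]
    shared <- sort(intersect(a$quotes[[i]], b$quotes[[j]]))
    rows[[length(rows) + 1L]] <- data.frame(
      theme_a = a$labels[i], theme_b = b$labels[j],
      jaccard = J[i, j], n_shared = length(shared),
      shared = paste(format_quote_id(shared), collapse = ", "),
      stringsAsFactors = FALSE)
    free_a[i] <- FALSE
    free_b[j] <- FALSE
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(theme_a = character(), theme_b = character(),
               jaccard = numeric(), n_shared = integer(),
               shared = character(), stringsAsFactors = FALSE)
  structure(list(jaccard = J, matches = matches), class = "theme_match")
}

#' @export
print.theme_match <- function(x, ...) {
  cat("Theme overlap (Jaccard):\n")
  print(round(x$jaccard, 3))
  cat("\nBest-match pairs (greedy):\n")
  if (nrow(x$matches)) {
    print(x$matches[, c("theme_a", "theme_b", "jaccard", "n_shared")],
          row.names = FALSE)
  } else {
    cat("  (no overlapping themes)\n")
  }
  invisible(x)
}
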