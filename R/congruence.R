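#' Dominant grouping of a theme
#'
#' For a theme (a list of quotes) and a grouping assignment, tallies the
#' grouping labels of the theme's quotes. The dominant grouping is the
#' modal label; the associated percentage is the share of theme quotes
#' carrying it. When the maximal count is attained by two or more labels
#' there is no dominant grouping and the percentage is undefined (`N/A`),
#' reported instead as a breakdown string such as `"4 green; 4 pink; 3
#' blue"` (descending count, then label).
#'
#' @param theme_quotes quote ids of the theme (anything [parse_quote_id()]
#'   accepts).
#' @param assignment named grouping vector (names = canonical quote ids).
#' @return Object of class `dominant_grouping`: list with `counts` (named
#'   integer vector, descending), `dominant` (label or `NA` on ties),
#'   `percentage` (numeric in (0, 100] or `NA`), and `n_quotes`.
#' @examples
#' asg <- c(ID23 = "Blue", ID49 = "Blue", ID54 = "Blue")
#' dominant_grouping(c(23, 49, 54), asg)
#' @export
dominant_grouping <- function(theme_quotes, assignment) {
  q <- parse_quote_id(theme_quotes)
  ids <- format_quote_id(q)
  missing <- setdiff(ids, names(assignment))
  if (length(missing)) {
    pte_stop("coverage", "theme quote(s) missing from the grouping ",
             "assignment: ", paste(missing, collapse = ", "))
  }
  labs <- as.character(assignment[ids])
  tab <- table(labs)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts <- counts[order(-counts, names(counts))]
  tie <- sum(counts == counts[1]) > 1L
  structure(list(
    counts = counts,
    dominant = if (tie) NA_character_ else names(counts)[1],
    percentage = if (tie) NA_real_ else 100 * counts[[1]] / length(ids),
    n_quotes = length(ids)
  ), class = "dominant_grouping")
}

breakdown_string <- function(counts) {
  paste(sprintf("%d %s", counts, names(counts)), collapse = "; ")
}

#' Render a percentage under a rounding policy
#'
#' @param p numeric percentage (0-100) or `NA`.
#' @param rounding `"one_decimal"` (85.7%), `"integer"` (82%), or
#'   `"full"` (no rounding). `NA` renders as `"N/A"`.
#' @return Character rendering, e.g. `"85.7%"`.
#' @export
render_percentage <- function(p, rounding = c("one_decimal", "integer",
                                              "full")) {
  rounding <- match.arg(rounding)
  if (is.na(p)) return("N/A")
  switch(rounding,
         integer = sprintf("%d%%", as.integer(round(p))),
         one_decimal = paste0(sub("\\.0$", "", sprintf("%.1f", round(p, 1))),
                              "%"),
         full = paste0(format(p, digits = 15), "%"))
}

#' @export
print.dominant_grouping <- function(x, ...) {
  if (is.na(x$dominant)) {
    cat("No dominant grouping—", breakdown_string(x$counts), "\n",
        sep = "")
  } else {
    cat("Dominant grouping: ", x$dominant, " (",
        render_percentage(x$percentage), " of ", x$n_quotes, " quotes)\n",
        sep = "")
  }
  invisible(x)
}

#' Theme-by-theme congruence summary
#'
#' One row per theme, in input order: label, canonical quote list, the
#' dominant grouping (or, on ties, a `"No dominant grouping—k1 l1; k2 l2;
#' ..."` breakdown) and the dominant-grouping percentage rendered under the
#' chosen rounding policy (`"N/A"` on ties). The unrounded percentage is
#' kept in the numeric column `pct`.
#'
#' @param themes a [theme_collection()].
#' @param assignment named grouping vector covering every theme quote.
#' @param rounding presentation policy, see [render_percentage()].
#' @return A data frame with columns `theme`, `quotes`, `n_quotes`,
#'   `dominant`, `percentage`, `pct`.
#' @export
theme_congruence_table <- function(themes, assignment,
                                   rounding = c("one_decimal", "integer",
                                                "full")) {
  stopifnot(inherits(themes, "theme_collection"))
  rounding <- match.arg(rounding)
  rows <- lapply(seq_along(themes$labels), function(i) {
    dg <- dominant_grouping(themes$quotes[[i]], assignment)
    data.frame(
      theme = themes$labels[i],
      quotes = paste(format_quote_id(themes$quotes[[i]]), collapse = ", "),
      n_quotes = dg$n_quotes,
      dominant = if (is.na(dg$dominant)) {
        paste0("No dominant grouping—", breakdown_string(dg$counts))
      } else dg$dominant,
      percentage = render_percentage(dg$percentage, rounding),
      pct = unname(dg$percentage),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Adjusted Rand index between two groupings
#'
#' Chance-corrected agreement between two groupings of the same quote set,
#' computed from the pair-count contingency table under the permutation
#' model. 1 means identical groupings (up to relabelling), 0 is the
#' expected agreement of random groupings with the same margins; small
#' negative values indicate less-than-chance agreement.
#'
#' @param a,b named grouping vectors over identical quote sets.
#' @return Numeric ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (is.null(names(a)) || is.null(names(b))) {
    pte_stop("usage", "groupings must be named by quote id")
  }
  only_a <- setdiff(names(a), names(b))
  only_b <- setdiff(names(b), names(a))
  if (length(only_a) || length(only_b)) {
    pte_stop("coverage", "groupings cover different quote sets; ",
             "only in first: {", paste(only_a, collapse = ", "),
             "}; only in second: {", paste(only_b, collapse = ", "), "}")
  }
  b <- b[names(a)]
  n <- length(a)
  tab <- table(as.character(a), as.character(b))
  sij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  expected <- ai * bj / choose(n, 2)
  maximum <- (ai + bj) / 2
  if (maximum == expected) return(1)   # both groupings trivial and identical
  (sij - expected) / (maximum - expected)
}
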