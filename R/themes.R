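#' Construct a collection of themes
#'
#' A theme is a human-curated, labelled list of quotes developed during
#' interpretation. Themes may overlap (the same quote can support several
#' themes) and need not cover the whole quote set, so a theme collection is
#' deliberately *not* a partition.
#'
#' @param labels character vector of theme labels.
#' @param quotes list of quote-id vectors (anything [parse_quote_id()]
#'   accepts), one per label.
#' @return Object of class `theme_collection`: list with `labels` and
#'   `quotes` (integer vectors).
#' @seealso [read_theme_file()], [theme_congruence_table()],
#'   [match_theme_sets()]
#' @export
theme_collection <- function(labels, quotes) {
  labels <- as.character(labels)
  if (length(labels) != length(quotes)) {
    pte_stop("format", "labels and quote lists differ in length")
  }
  quotes <- lapply(seq_along(quotes), function(i) {
    q <- parse_quote_id(quotes[[i]])
    if (!length(q)) {
      pte_stop("format", "theme ", sQuote(labels[i]), " has no quotes")
    }
    if (anyDuplicated(q)) {
      pte_stop("integrity", "theme ", sQuote(labels[i]),
               " lists quote(s) more than once: ",
               paste(format_quote_id(unique(q[duplicated(q)])),
                     collapse = ", "))
    }
    q
  })
  structure(list(labels = labels, quotes = quotes),
            class = "theme_collection")
}

#' @export
length.theme_collection <- function(x) length(x$labels)

#' @export
print.theme_collection <- function(x, ...) {
  cat("Theme collection with", length(x), "theme(s)\n")
  for (i in seq_along(x$labels)) {
    cat("  ", x$labels[i], ": ",
        paste(format_quote_id(x$quotes[[i]]), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Read a theme file
#'
#' Two plain-text layouts are accepted. Line format: one theme per line,
#' `label: id, id, ...`. Tabular format: a two-column delimited file
#' (`label,quote`), one quote per row, rows with the same label aggregated
#' in first-appearance order; a header row is auto-detected. Quote ids are
#' normalized via [parse_quote_id()], so `"ID05"` and `"5"` denote the same
#' quote (and duplicate within one theme is an error).
#'
#' @param path file path.
#' @return A [theme_collection()].
#' @export
read_theme_file <- function(path) {
  if (!file.exists(path)) pte_stop("io", "file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (!length(lines)) pte_stop("format", "empty theme file: ", path)

  if (any(grepl(":", lines, fixed = TRUE))) {
    bad <- !grepl(":", lines, fixed = TRUE)
    if (any(bad)) {
      pte_stop("format", "theme line(s) without a 'label:' prefix: ",
               paste(sQuote(trimws(lines[bad])), collapse = ", "))
    }
    labels <- trimws(sub(":[^:]*$", "", lines))
    ids <- lapply(strsplit(sub("^.*:", "", lines), "[,;]"), trimws)
    ids <- lapply(ids, function(v) v[nzchar(v)])
    return(theme_collection(labels, ids))
  }

  delim <- guess_delim(lines[[1]])
  tab <- read.table(text = lines, sep = delim, colClasses = "character",
                    header = FALSE, strip.white = TRUE, comment.char = "")
  if (ncol(tab) != 2L) {
    pte_stop("format", "tabular theme file must have two columns ",
             "(label, quote), got ", ncol(tab))
  }
  if (inherits(tryCatch(parse_quote_id(tab[1, 2]), pte_error = identity),
               "pte_error")) {
    tab <- tab[-1, , drop = FALSE]
  }
  if (!nrow(tab)) pte_stop("format", "theme file has a header but no rows")
  labels <- unique(tab[[1]])
  theme_collection(labels,
                   lapply(labels, function(l) tab[[2]][tab[[1]] == l]))
}

#' Read and write grouping assignment files
#'
#' A grouping assignment maps every quote to a community (grouping) label —
#' the "coloured groupings" of a network diagram. On disk it is a
#' two-column delimited file `quote,group`; in memory it is a character (or
#' integer) vector named by canonical quote ids.
#'
#' @param path file path.
#' @return [read_grouping()] returns a named vector (names are canonical
#'   quote ids); [write_grouping()] returns `path` invisibly.
#' @export
read_grouping <- function(path) {
  if (!file.exists(path)) pte_stop("io", "file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) pte_stop("format", "empty grouping file: ", path)
  delim <- guess_delim(lines[[1]])
  tab <- read.table(text = lines, sep = delim, colClasses = "character",
                    header = FALSE, strip.white = TRUE, comment.char = "")
  if (ncol(tab) != 2L) {
    pte_stop("format", "grouping file must have two columns (quote, group)")
  }
  if (inherits(tryCatch(parse_quote_id(tab[1, 1]), pte_error = identity),
               "pte_error")) {
    tab <- tab[-1, , drop = FALSE]
  }
  q <- parse_quote_id(tab[[1]])
  if (anyDuplicated(q)) {
    pte_stop("integrity", "grouping file assigns quote(s) twice: ",
             paste(format_quote_id(unique(q[duplicated(q)])), collapse = ", "))
  }
  setNames(tab[[2]], format_quote_id(q))
}

#' @rdname read_grouping
#' @param assignment named vector, names canonical quote ids.
#' @export
write_grouping <- function(assignment, path) {
  out <- data.frame(quote = names(assignment),
                    group = as.character(assignment))
  write.table(out, path, sep = ",", row.names = FALSE, col.names = TRUE,
              quote = FALSE)
  invisible(path)
}
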