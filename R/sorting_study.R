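#' Construct a sorting study from long-format records
#'
#' A sorting study holds the independent open sorts of a shared quote set:
#' each researcher partitions every quote into two or more labelled piles.
#' Pile labels are opaque and compared only within one researcher; different
#' researchers may use different labels and different numbers of piles.
#'
#' Validation enforces the open-sorting rules: each researcher's piles must
#' form a partition of the quote set (every quote sorted exactly once), and
#' every researcher must have at least two piles (no single "miscellaneous"
#' pile). By default every researcher must sort every quote; with
#' `allow_partial = TRUE` a researcher may leave quotes unsorted, and those
#' quotes simply contribute no co-placements for that researcher.
#'
#' @param records data frame with columns `researcher`, `quote`, `pile`
#'   (extra columns are ignored). Quotes are normalized via
#'   [parse_quote_id()].
#' @param allow_partial logical; permit researchers to leave quotes unsorted.
#' @return An object of class `sorting_study`: a list with elements
#'   `records` (normalized long-format data frame), `researchers`
#'   (first-appearance order), `quotes` (sorted integer quote values).
#' @seealso [read_sorting_table()], [study_piles()], [build_cosort_network()]
#' @examples
#' rec <- data.frame(researcher = "r1", quote = 1:3, pile = c("A", "A", "B"))
#' sorting_study(rec)
#' @export
sorting_study <- function(records, allow_partial = FALSE) {
  records <- as.data.frame(records)
  need <- c("researcher", "quote", "pile")
  if (!all(need %in% names(records))) {
    if (ncol(records) == 3L) {
      names(records) <- need
    } else {
      pte_stop("format", "sorting records need exactly three columns: ",
               "researcher, quote, pile")
    }
  }
  records <- data.frame(
    researcher = as.character(records$researcher),
    quote      = parse_quote_id(records$quote),
    pile       = as.character(records$pile),
    stringsAsFactors = FALSE
  )
  if (nrow(records) == 0L) {
    pte_stop("format", "sorting table contains no records")
  }

  key <- paste(records$researcher, records$quote, sep = "\r")
  if (anyDuplicated(key)) {
    d <- records[duplicated(key), , drop = FALSE]
    pte_stop("integrity", "duplicate (researcher, quote) record(s): ",
             paste(unique(paste0(d$researcher, "/", format_quote_id(d$quote))),
                   collapse = ", "),
             " — each researcher sorts each quote exactly once")
  }

  researchers <- unique(records$researcher)
  quotes <- sort(unique(records$quote))

  for (r in researchers) {
    rq <- records$quote[records$researcher == r]
    missing <- setdiff(quotes, rq)
    if (length(missing) && !allow_partial) {
      pte_stop("coverage", "researcher ", sQuote(r), " did not sort quote(s) ",
               paste(format_quote_id(missing), collapse = ", "),
               " that other researchers sorted ",
               "(use allow_partial to accept ragged sorts)")
    }
    npiles <- length(unique(records$pile[records$researcher == r]))
    if (npiles < 2L) {
      pte_stop("constraint", "researcher ", sQuote(r), " used a single pile; ",
               "open sorting requires at least two piles")
    }
  }

  structure(list(records = records, researchers = researchers,
                 quotes = quotes),
            class = "sorting_study")
}

#' Piles of one researcher
#'
#' @param study a [sorting_study()].
#' @param researcher researcher identifier.
#' @return Named list of integer quote vectors, one per pile.
#' @export
study_piles <- function(study, researcher) {
  stopifnot(inherits(study, "sorting_study"))
  if (!researcher %in% study$researchers) {
    pte_stop("lookup", "unknown researcher ", sQuote(researcher))
  }
  rec <- study$records[study$records$researcher == researcher, , drop = FALSE]
  split(rec$quote, rec$pile)
}

#' @export
print.sorting_study <- function(x, ...) {
  cat("Sorting study: ", length(x$researchers), " researcher(s), ",
      length(x$quotes), " quote(s)\n", sep = "")
  for (r in x$researchers) {
    sizes <- vapply(study_piles(x, r), length, integer(1))
    cat("  ", r, ": ", length(sizes), " piles (sizes ",
        paste(sort(sizes, decreasing = TRUE), collapse = ", "), ")\n",
        sep = "")
  }
  invisible(x)
}

guess_delim <- function(line) {
  if (grepl("\t", line)) "\t" else ","
}

#' Read and write sorting tables
#'
#' The on-disk form of a sorting study is a three-column delimited text file
#' (comma or tab, auto-detected) with columns `researcher`, `quote`, `pile`.
#' A header row is detected automatically: a first row whose quote field does
#' not parse as a quote identifier is treated as a header.
#'
#' @param path file path.
#' @param delim field delimiter; `NULL` (default) auto-detects comma vs tab.
#' @param allow_partial passed to [sorting_study()].
#' @return [read_sorting_table()] returns a validated [sorting_study()];
#'   [write_sorting_table()] returns `path` invisibly.
#' @export
read_sorting_table <- function(path, delim = NULL, allow_partial = FALSE) {
  if (!file.exists(path)) pte_stop("io", "file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) pte_stop("format", "empty sorting table: ", path)
  if (is.null(delim)) delim <- guess_delim(lines[[1]])
  tab <- read.table(text = lines, sep = delim, colClasses = "character",
                    header = FALSE, strip.white = TRUE, quote = "\"",
                    comment.char = "")
  if (ncol(tab) != 3L) {
    pte_stop("format", "sorting table must have exactly three columns, got ",
             ncol(tab))
  }
  first_is_header <- inherits(
    tryCatch(parse_quote_id(tab[1, 2]), pte_error = identity), "pte_error")
  if (first_is_header) tab <- tab[-1, , drop = FALSE]
  if (!nrow(tab)) pte_stop("format", "sorting table has a header but no rows")
  names(tab) <- c("researcher", "quote", "pile")
  sorting_study(tab, allow_partial = allow_partial)
}

#' @rdname read_sorting_table
#' @param study a [sorting_study()].
#' @export
write_sorting_table <- function(study, path, delim = ",") {
  stopifnot(inherits(study, "sorting_study"))
  out <- data.frame(researcher = study$records$researcher,
                    quote = format_quote_id(study$records$quote),
                    pile = study$records$pile)
  write.table(out, path, sep = delim, row.names = FALSE, col.names = TRUE,
              quote = FALSE)
  invisible(path)
}
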