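#' Parse quote identifiers
#'
#' Quote identifiers appear in two interchangeable styles in sorting sheets
#' and theme lists: a bare integer (`"17"`) or an `ID`-prefixed,
#' possibly zero-padded form (`"ID17"`, `"id07"`). Both normalize to the
#' same positive integer value; [format_quote_id()] renders the canonical
#' form (`"ID"` followed by the value zero-padded to at least two digits).
#'
#' @param x character (or integer) vector of quote identifiers.
#' @return `parse_quote_id()` returns an integer vector of quote values;
#'   `format_quote_id()` returns the canonical character form.
#' @examples
#' parse_quote_id(c("ID17", "17", " id07 "))
#' format_quote_id(c(7, 89))
#' @export
parse_quote_id <- function(x) {
  x0 <- trimws(as.character(x))
  payload <- sub("^[Ii][Dd]", "", x0)
  ok <- grepl("^[0-9]+$", payload)
  val <- rep(NA_integer_, length(x0))
  val[ok] <- as.integer(payload[ok])
  bad <- !ok | is.na(val) | val < 1L
  if (any(bad)) {
    pte_stop("parse", "invalid quote identifier(s): ",
             paste(sQuote(x0[bad]), collapse = ", "),
             " (expected a positive integer or 'ID' + integer)")
  }
  val
}

#' @rdname parse_quote_id
#' @export
format_quote_id <- function(x) {
  sprintf("ID%02d", as.integer(x))
}
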