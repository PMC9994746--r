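#' Split a display author string into fore/last names
#'
#' Splits on the final whitespace token: everything after the last space is
#' the last name, everything before it the fore name. Particles therefore
#' stay in the fore name (`"Ludwig van der Rohe"` gives fore
#' `"Ludwig van der"`, last `"Rohe"`); this mirrors how the downstream flip
#' check compares single name fields.
#'
#' @param display A single author string such as `"Mary Jane Watson"`.
#' @return An [author_name()].
#' @export
split_author_name <- function(display) {
  display <- trimws(as.character(display))
  if (!nzchar(display)) stop("split_author_name: empty author string", call. = FALSE)
  tokens <- strsplit(display, "\\s+")[[1L]]
  n <- length(tokens)
  if (n == 1L) {
    author_name(NULL, tokens)
  } else {
    author_name(paste(tokens[-n], collapse = " "), tokens[n])
  }
}

#' Parse preprint metadata from JSON-lines
#'
#' Reads one preprint per line with fields `doi`, `title`, `abstract`,
#' `posted_date` (ISO-8601), `authors` (array of display strings, split with
#' [split_author_name()]), and optional `announced_pub_id`. Rows missing a
#' mandatory field are skipped with a warning; duplicate DOIs are an error.
#'
#' @param path JSON-lines file path.
#' @return List of [preprint_record()] objects, input order preserved.
#' @export
parse_preprints <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  records <- list()
  for (i in seq_along(lines)) {
    x <- jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE)
    mandatory <- c("doi", "title", "abstract", "posted_date", "authors")
    missing <- mandatory[vapply(mandatory, function(f) {
      is.null(x[[f]]) || (is.character(x[[f]]) && !nzchar(x[[f]]))
    }, logical(1L))]
    if (length(missing) > 0L) {
      warning("preprint row ", i, " skipped: missing ",
              paste(missing, collapse = ", "), call. = FALSE)
      next
    }
    records <- c(records, list(preprint_record(
      doi = x$doi, title = x$title, abstract = x$abstract,
      posted_date = as.Date(x$posted_date),
      authors = lapply(x$authors, split_author_name),
      announced_pub_id = if (is.null(x$announced_pub_id)) NA_character_ else x$announced_pub_id
    )))
  }
  dois <- vapply(records, `[[`, character(1L), "doi")
  dup <- unique(dois[duplicated(dois)])
  if (length(dup) > 0L) {
    stop("duplicate preprint DOIs: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  records
}
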