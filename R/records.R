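#' Author name
#'
#' Minimal structured author name: an optional fore (given) name and a
#' mandatory last (family) name. An empty or all-whitespace fore name is
#' treated as absent.
#'
#' @param fore Fore name, or `NULL`/`NA`/`""` when absent.
#' @param last Last name; must be non-empty.
#' @return An object of class `author_name`.
#' @examples
#' author_display(author_name("Ada", "Lovelace"))
#' @export
author_name <- function(fore = NULL, last) {
  last <- trimws(as.character(last))
  if (length(last) != 1L || is.na(last) || !nzchar(last)) {
    stop("author_name: `last` must be a non-empty string", call. = FALSE)
  }
  if (is.null(fore) || length(fore) == 0L || is.na(fore[1L]) || !nzchar(trimws(fore[1L]))) {
    fore <- NULL
  } else {
    fore <- trimws(as.character(fore[1L]))
  }
  structure(list(fore = fore, last = last), class = "author_name")
}

#' Display form of an author name
#'
#' `"<fore> <last>"` when a fore name is present, otherwise just `"<last>"` —
#' the single-string author representation used when building author sets.
#'
#' @param name An [author_name()].
#' @return A single string.
#' @export
author_display <- function(name) {
  stopifnot(inherits(name, "author_name"))
  if (is.null(name$fore)) name$last else paste(name$fore, name$last)
}

#' Published-paper record
#'
#' One published article's matched-on metadata as extracted from citation XML.
#'
#' @param pmid PubMed identifier; non-empty string.
#' @param title Article title, or `NA` when absent.
#' @param abstract Abstract text, or `NA` when absent.
#' @param pub_date Publication [Date].
#' @param authors List of [author_name()] objects (possibly empty, never NULL).
#' @param doi DOI string, or `NA`.
#' @param languages Character vector of 3-letter language codes.
#' @param pub_types Character vector of publication-type labels.
#' @return An object of class `paper_record`.
#' @export
paper_record <- function(pmid, title = NA_character_, abstract = NA_character_,
                         pub_date = as.Date(NA), authors = list(),
                         doi = NA_character_, languages = character(),
                         pub_types = character()) {
  pmid <- as.character(pmid)
  if (length(pmid) != 1L || is.na(pmid) || !nzchar(pmid)) {
    stop("paper_record: `pmid` must be a non-empty string", call. = FALSE)
  }
  stopifnot(is.list(authors))
  structure(list(
    pmid = pmid,
    doi = as.character(doi)[1L],
    title = as.character(title)[1L],
    abstract = as.character(abstract)[1L],
    pub_date = as.Date(pub_date),
    authors = authors,
    languages = as.character(languages),
    pub_types = as.character(pub_types)
  ), class = "paper_record")
}

#' Preprint record
#'
#' One preprint's metadata, plus the server-announced published version when
#' the server reported one.
#'
#' @param doi Preprint DOI; non-empty string.
#' @param title Title text.
#' @param abstract Abstract text.
#' @param posted_date Posting [Date].
#' @param authors Ordered list of [author_name()] objects.
#' @param announced_pub_id Announced published-paper identifier, or `NA`.
#' @return An object of class `preprint_record`.
#' @export
preprint_record <- function(doi, title, abstract, posted_date, authors,
                            announced_pub_id = NA_character_) {
  doi <- as.character(doi)
  if (length(doi) != 1L || is.na(doi) || !nzchar(doi)) {
    stop("preprint_record: `doi` must be a non-empty string", call. = FALSE)
  }
  stopifnot(is.list(authors))
  structure(list(
    doi = doi,
    title = as.character(title)[1L],
    abstract = as.character(abstract)[1L],
    posted_date = as.Date(posted_date),
    authors = authors,
    announced_pub_id = as.character(announced_pub_id)[1L]
  ), class = "preprint_record")
}

#' @export
print.paper_record <- function(x, ...) {
  cat("<paper_record>", x$pmid, "-", substr(x$title, 1L, 60L), "\n")
  invisible(x)
}

#' @export
print.preprint_record <- function(x, ...) {
  cat("<preprint_record>", x$doi, "-", substr(x$title, 1L, 60L), "\n")
  invisible(x)
}

# -- internal (de)serialization helpers ---------------------------------------

authors_to_plain <- function(authors) {
  lapply(authors, function(a) list(fore = a$fore, last = a$last))
}

authors_from_plain <- function(plain) {
  lapply(plain, function(a) author_name(a$fore, a$last))
}

#' Write paper records to JSON-lines
#'
#' One JSON object per line; dates in ISO-8601. The inverse of
#' [read_papers_jsonl()].
#'
#' @param records List of [paper_record()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_papers_jsonl <- function(records, path) {
  lines <- vapply(records, function(r) {
    jsonlite::toJSON(list(
      pmid = r$pmid, doi = r$doi, title = r$title, abstract = r$abstract,
      pub_date = format(r$pub_date, "%Y-%m-%d"),
      authors = authors_to_plain(r$authors),
      languages = r$languages, pub_types = r$pub_types
    ), auto_unbox = TRUE, null = "null", na = "null")
  }, character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read paper records from JSON-lines
#'
#' @param path File written by [write_papers_jsonl()].
#' @return List of [paper_record()] objects.
#' @export
read_papers_jsonl <- function(path) {
  lapply(readLines(path, encoding = "UTF-8"), function(line) {
    x <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    paper_record(
      pmid = x$pmid,
      doi = if (is.null(x$doi)) NA_character_ else x$doi,
      title = if (is.null(x$title)) NA_character_ else x$title,
      abstract = if (is.null(x$abstract)) NA_character_ else x$abstract,
      pub_date = as.Date(x$pub_date),
      authors = authors_from_plain(x$authors),
      languages = unlist(x$languages),
      pub_types = unlist(x$pub_types)
    )
  })
}

#' Write preprint records to JSON-lines
#'
#' @param records List of [preprint_record()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_preprints_jsonl <- function(records, path) {
  lines <- vapply(records, function(r) {
    jsonlite::toJSON(list(
      doi = r$doi, title = r$title, abstract = r$abstract,
      posted_date = format(r$posted_date, "%Y-%m-%d"),
      authors = vapply(r$authors, author_display, character(1L)),
      announced_pub_id = r$announced_pub_id
    ), auto_unbox = TRUE, null = "null", na = "null")
  }, character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
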