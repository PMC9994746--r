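# Publication types that mark a citation as not being the published version of
# a preprint (or as being the preprint itself).
EXCLUDED_PUB_TYPES <- c("Comment", "Published Erratum", "Review", "Preprint")

# Month assigned to a season string in a publication date: the season's first
# month under the northern-hemisphere meteorological convention.
SEASON_MONTHS <- c(spring = 3L, summer = 6L, fall = 9L, autumn = 9L, winter = 12L)

MONTH_ABBR <- tolower(month.abb)

#' Canonicalize a free-text publication date
#'
#' Journal publication dates come in varied formats (`"2020 Mar 15"`,
#' `"2019 Mar"`, `"2018"`, `"2019 Spring"`, numeric months). The rule set:
#' a 4-digit year is mandatory; a missing month is assumed to be January and a
#' missing day the first of the month; season strings map to the season's
#' first month (see `SEASON_MONTHS` in the source: Spring = March,
#' Summer = June, Fall/Autumn = September, Winter = December).
#'
#' @param raw Non-empty date string containing at least a 4-digit year.
#' @return A [Date].
#' @examples
#' canonicalize_pubdate("2020 Mar 15")  # 2020-03-15
#' canonicalize_pubdate("2019 Mar")     # 2019-03-01
#' canonicalize_pubdate("2018")         # 2018-01-01
#' @export
canonicalize_pubdate <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  tokens <- strsplit(trimws(gsub("[-/,.]", " ", raw)), "\\s+")[[1L]]
  tokens <- tokens[nzchar(tokens)]
  year_idx <- grep("^\\d{4}$", tokens)
  if (length(year_idx) == 0L) {
    stop("canonicalize_pubdate: no 4-digit year in ", dQuote(raw), call. = FALSE)
  }
  year <- as.integer(tokens[year_idx[1L]])
  rest <- tokens[-year_idx[1L]]

  month <- NA_integer_
  day <- NA_integer_
  for (tok in rest) {
    low <- tolower(tok)
    if (is.na(month) && substr(low, 1L, 3L) %in% MONTH_ABBR) {
      month <- match(substr(low, 1L, 3L), MONTH_ABBR)
    } else if (is.na(month) && low %in% names(SEASON_MONTHS)) {
      month <- SEASON_MONTHS[[low]]
    } else if (grepl("^\\d{1,2}$", tok)) {
      v <- as.integer(tok)
      if (is.na(month) && v >= 1L && v <= 12L) {
        month <- v
      } else if (is.na(day) && v >= 1L && v <= 31L) {
        day <- v
      }
    }
  }
  if (is.na(month)) month <- 1L
  if (is.na(day)) day <- 1L
  as.Date(sprintf("%04d-%02d-%02d", year, month, day))
}

xml_text1 <- function(node, xpath) {
  hit <- xml2::xml_find_first(node, xpath)
  if (inherits(hit, "xml_missing")) NA_character_ else xml2::xml_text(hit)
}

parse_citation_node <- function(node) {
  pmid <- xml_text1(node, ".//MedlineCitation/PMID")
  if (is.na(pmid) || !nzchar(pmid)) {
    warning("citation without PMID skipped", call. = FALSE)
    return(NULL)
  }
  title <- xml_text1(node, ".//Article/ArticleTitle")
  abs_nodes <- xml2::xml_find_all(node, ".//Article/Abstract/AbstractText")
  abstract <- if (length(abs_nodes) == 0L) {
    NA_character_
  } else {
    paste(xml2::xml_text(abs_nodes), collapse = " ")
  }
  doi <- xml_text1(node, ".//PubmedData//ArticleId[@IdType='doi']")

  pd <- xml2::xml_find_first(node, ".//Article/Journal/JournalIssue/PubDate")
  raw_date <- if (inherits(pd, "xml_missing")) {
    NA_character_
  } else {
    med <- xml_text1(pd, "./MedlineDate")
    if (!is.na(med)) {
      med
    } else {
      parts <- c(xml_text1(pd, "./Year"), xml_text1(pd, "./Month"), xml_text1(pd, "./Day"))
      paste(parts[!is.na(parts)], collapse = " ")
    }
  }
  pub_date <- tryCatch(canonicalize_pubdate(raw_date), error = function(e) {
    warning("PMID ", pmid, ": unparsable publication date ", dQuote(raw_date),
            "; record excluded", call. = FALSE)
    NULL
  })
  if (is.null(pub_date)) return(NULL)

  authors <- list()
  for (a in xml2::xml_find_all(node, ".//Article/AuthorList/Author")) {
    last <- xml_text1(a, "./LastName")
    if (is.na(last) || !nzchar(last)) {
      coll <- xml_text1(a, "./CollectiveName")
      warning("PMID ", pmid, ": author without last name",
              if (!is.na(coll)) paste0(" (collective: ", coll, ")"),
              " dropped", call. = FALSE)
      next
    }
    authors <- c(authors, list(author_name(xml_text1(a, "./ForeName"), last)))
  }

  paper_record(
    pmid = pmid, doi = doi, title = title, abstract = abstract,
    pub_date = pub_date, authors = authors,
    languages = xml2::xml_text(xml2::xml_find_all(node, ".//Article/Language")),
    pub_types = xml2::xml_text(
      xml2::xml_find_all(node, ".//Article/PublicationTypeList/PublicationType"))
  )
}

#' Parse MEDLINE/PubMed-dialect citation XML
#'
#' Extracts, for each citation, the PMID, DOI, title, abstract, publication
#' date, author list, languages and publication types. Missing optional
#' fields are `NA`, never empty-string sentinels. Citations without a PMID
#' are skipped with a warning; unparsable publication dates exclude the
#' record with a warning; malformed XML is a hard error.
#'
#' @param source Path to an XML file, a raw vector, or an XML string.
#' @return List of [paper_record()] objects.
#' @seealso [write_pubmed_xml()] for the fixture writer this round-trips with.
#' @export
parse_pubmed_xml <- function(source) {
  doc <- tryCatch(
    xml2::read_xml(source),
    error = function(e) stop("malformed XML: ", conditionMessage(e), call. = FALSE)
  )
  nodes <- xml2::xml_find_all(doc, "//PubmedArticle")
  records <- lapply(nodes, parse_citation_node)
  records[!vapply(records, is.null, logical(1L))]
}

#' Filter papers down to plausible published versions
#'
#' Retains exactly the records whose language set contains `"eng"` and whose
#' publication types are disjoint from \{Comment, Published Erratum, Review,
#' Preprint\}. Records with an absent title are also dropped: they cannot be
#' embedded, so they can never be retrieved as candidates. The filter is
#' total and idempotent.
#'
#' @param records List of [paper_record()] objects.
#' @return Filtered list, original order preserved.
#' @export
filter_papers <- function(records) {
  keep <- vapply(records, function(r) {
    "eng" %in% r$languages &&
      !any(r$pub_types %in% EXCLUDED_PUB_TYPES) &&
      !is.na(r$title) && nzchar(r$title)
  }, logical(1L))
  records[keep]
}
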