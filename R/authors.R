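#' Normalized last-name set
#'
#' Case-folded, whitespace-trimmed last names; duplicates collapse. Authors
#' match when their last names match exactly after this normalization (no
#' fuzzy or phonetic matching).
#'
#' @param authors List of [author_name()] objects.
#' @return Character vector (a set; possibly empty).
#' @export
last_name_set <- function(authors) {
  unique(tolower(trimws(vapply(authors, `[[`, character(1L), "last"))))
}

# the fore-name token compared in the flip check: the final given-name token
# (the flip phenomenon swaps single name fields)
fore_name_set <- function(authors) {
  fores <- vapply(authors, function(a) {
    if (is.null(a$fore)) return(NA_character_)
    tok <- strsplit(trimws(a$fore), "\\s+")[[1L]]
    tok[length(tok)]
  }, character(1L))
  unique(tolower(fores[!is.na(fores)]))
}

#' Jaccard similarity of two sets
#'
#' `|A n B| / |A u B|`, defined as 0 when both sets are empty so that
#' authorless records never match spuriously.
#'
#' @param a,b Character vectors treated as sets.
#' @return Proportion in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Author-similarity feature with flip check
#'
#' The straight score is the Jaccard similarity between the preprint and
#' paper last-name sets. Because fore and last names are occasionally flipped
#' in preprint metadata, the paper last names are also compared against the
#' preprint fore names, and the higher of the two scores is kept. The check
#' is one-directional (preprint fore vs paper last), so `author_score` is not
#' symmetric in its arguments.
#'
#' @param preprint_authors,paper_authors Lists of [author_name()] objects.
#' @return List with `straight_jaccard`, `flipped_jaccard` and `score`
#'   (`score = max` of the two).
#' @export
author_score <- function(preprint_authors, paper_authors) {
  paper_last <- last_name_set(paper_authors)
  straight <- jaccard(last_name_set(preprint_authors), paper_last)
  flipped <- jaccard(fore_name_set(preprint_authors), paper_last)
  list(straight_jaccard = straight, flipped_jaccard = flipped,
       score = max(straight, flipped))
}
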