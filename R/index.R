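#' Build a persisted vector index
#'
#' Writes a row-per-document matrix of sentence vectors as a little-endian
#' float32 file plus a JSON sidecar (ids, dimension, field kind). Rows are
#' expected to be unit- or zero-norm. The returned handle addresses rows by
#' position on disk; queries stream over the file in chunks, so the whole
#' matrix never has to live in working memory.
#'
#' @param vectors Numeric matrix (one row per document) or list of equal
#'   length numeric vectors.
#' @param ids Character vector of document identifiers (pmids), aligned with
#'   the rows.
#' @param field_kind `"title"` or `"abstract"`.
#' @param dir Directory to create the index in.
#' @return An object of class `vector_index`.
#' @export
build_index <- function(vectors, ids, field_kind = c("title", "abstract"), dir) {
  field_kind <- match.arg(field_kind)
  if (is.list(vectors)) {
    dims <- unique(lengths(vectors))
    if (length(dims) > 1L) stop("build_index: inconsistent vector dimensions", call. = FALSE)
    vectors <- do.call(rbind, vectors)
  }
  stopifnot(is.matrix(vectors))
  if (nrow(vectors) == 0L) stop("build_index: no vectors", call. = FALSE)
  ids <- as.character(ids)
  if (length(ids) != nrow(vectors)) {
    stop("build_index: ids/vectors length mismatch", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, paste0("index_", field_kind))
  con <- file(paste0(base, ".f32"), "wb")
  writeBin(as.numeric(t(vectors)), con, size = 4L, endian = "little")
  close(con)
  jsonlite::write_json(
    list(ids = ids, dim = ncol(vectors), n = nrow(vectors), field_kind = field_kind),
    paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  read_index(dir, field_kind)
}

#' Open a persisted vector index
#'
#' @param dir Index directory written by [build_index()].
#' @param field_kind `"title"` or `"abstract"`.
#' @return A `vector_index` handle.
#' @export
read_index <- function(dir, field_kind = c("title", "abstract")) {
  field_kind <- match.arg(field_kind)
  base <- file.path(dir, paste0("index_", field_kind))
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  structure(list(
    path = paste0(base, ".f32"), dir = dir, field_kind = field_kind,
    dim = as.integer(meta$dim), n = as.integer(meta$n),
    ids = as.character(meta$ids)
  ), class = "vector_index")
}

#' @export
print.vector_index <- function(x, ...) {
  cat(sprintf("<vector_index> field=%s rows=%d dim=%d (%s)\n",
              x$field_kind, x$n, x$dim, x$path))
  invisible(x)
}

#' Read index rows by position
#'
#' Seeks directly to the requested rows, reading only those; part of the
#' out-of-core access contract.
#'
#' @param index A `vector_index`.
#' @param rows 1-based row positions.
#' @return Numeric matrix with `length(rows)` rows.
#' @export
index_rows <- function(index, rows) {
  stopifnot(inherits(index, "vector_index"), all(rows >= 1L), all(rows <= index$n))
  con <- file(index$path, "rb")
  on.exit(close(con))
  out <- matrix(0, nrow = length(rows), ncol = index$dim)
  for (i in seq_along(rows)) {
    seek(con, where = (rows[i] - 1) * index$dim * 4, origin = "start")
    out[i, ] <- readBin(con, "numeric", n = index$dim, size = 4L, endian = "little")
  }
  out
}

#' Top-k cosine retrieval
#'
#' Streams over the index in chunks, computes the dot product of each row
#' with the query (rows and query unit- or zero-norm, so the dot product is
#' the cosine), and returns the `k` largest in nonincreasing order. Ties are
#' broken by ascending pmid for reproducibility.
#'
#' @param index A `vector_index`.
#' @param query Numeric query vector of the index dimension.
#' @param k Number of hits (default 100); `k > n` returns all rows.
#' @param chunk_rows Rows per streamed chunk.
#' @return `data.frame(pmid, sim)` with `min(k, n)` rows.
#' @export
top_k_cosine <- function(index, query, k = 100L, chunk_rows = 4096L) {
  stopifnot(inherits(index, "vector_index"))
  if (k <= 0L) stop("top_k_cosine: k must be positive", call. = FALSE)
  if (length(query) != index$dim) {
    stop("top_k_cosine: query dimension ", length(query),
         " does not match index dimension ", index$dim, call. = FALSE)
  }
  sims <- numeric(index$n)
  con <- file(index$path, "rb")
  on.exit(close(con))
  done <- 0L
  while (done < index$n) {
    take <- min(chunk_rows, index$n - done)
    block <- matrix(readBin(con, "numeric", n = take * index$dim, size = 4L,
                            endian = "little"),
                    nrow = take, ncol = index$dim, byrow = TRUE)
    sims[(done + 1L):(done + take)] <- as.numeric(block %*% query)
    done <- done + take
  }
  ord <- order(-sims, index$ids, method = "radix")
  top <- ord[seq_len(min(k, index$n))]
  data.frame(pmid = index$ids[top], sim = sims[top], stringsAsFactors = FALSE)
}

#' Union of title and abstract top-k lists
#'
#' Merges the two retrieval lists into one candidate set, keeping per-pmid
#' provenance flags. The union of two top-k lists has at most `2k` members.
#'
#' @param title_topk,abstract_topk Data frames from [top_k_cosine()].
#' @return An object of class `candidate_set`: `data.frame(pmid, from_title,
#'   from_abstract)` sorted by ascending pmid.
#' @export
candidate_union <- function(title_topk, abstract_topk) {
  pmids <- sort(unique(c(title_topk$pmid, abstract_topk$pmid)))
  out <- data.frame(
    pmid = pmids,
    from_title = pmids %in% title_topk$pmid,
    from_abstract = pmids %in% abstract_topk$pmid,
    stringsAsFactors = FALSE
  )
  class(out) <- c("candidate_set", "data.frame")
  out
}
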