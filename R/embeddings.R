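# Run code with a temporary RNG seed, restoring .Random.seed afterwards so
# library calls never perturb the caller's stream.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Tokenize text for embedding training
#'
#' Lowercases, strips punctuation to spaces, splits on whitespace. The same
#' tokenizer is used at training and inference time.
#'
#' @param text Character vector.
#' @return A list of character vectors (one per input element).
#' @export
tokenize_text <- function(text) {
  text <- tolower(as.character(text))
  text <- gsub("[^\\p{L}\\p{N}]+", " ", text, perl = TRUE)
  lapply(strsplit(trimws(text), "\\s+"), function(tok) tok[nzchar(tok)])
}

#' Sample a training corpus for embeddings
#'
#' Simple random sample without replacement of `floor(fraction * n)` texts of
#' the requested field, reproducible under `seed`. Titles and abstracts are
#' sampled as separate pools, matching the convention that title and abstract
#' models are trained independently.
#'
#' @param records List of [paper_record()] objects.
#' @param fraction Sampling fraction in (0, 1]; the canonical choice is 0.10.
#' @param seed Integer RNG seed.
#' @param field `"title"` or `"abstract"`.
#' @return Character vector of sampled texts (absent fields are dropped
#'   before sampling).
#' @export
sample_training_corpus <- function(records, fraction, seed, field = c("title", "abstract")) {
  field <- match.arg(field)
  if (length(records) == 0L) stop("sample_training_corpus: empty corpus", call. = FALSE)
  stopifnot(fraction > 0, fraction <= 1)
  texts <- vapply(records, function(r) r[[field]], character(1L))
  texts <- texts[!is.na(texts) & nzchar(texts)]
  if (length(texts) == 0L) stop("sample_training_corpus: no non-empty texts", call. = FALSE)
  size <- floor(fraction * length(texts))
  with_seed(seed, texts[sample.int(length(texts), size)])
}

#' Train a subword-aware embedding model
#'
#' Skip-gram with negative sampling over the supplied texts; each word is
#' represented as the mean of a per-word vector and hashed character n-gram
#' bucket vectors, so unseen tokens can still be embedded from their
#' n-grams. Training is single-threaded and deterministic under `seed`.
#'
#' @param texts Character vector of training texts (titles or abstracts).
#' @param field_kind `"title"` or `"abstract"`, recorded in the model.
#' @param dim Vector dimension (default 300).
#' @param seed Integer RNG seed.
#' @param window Skip-gram context window (default 5).
#' @param min_count Minimum token frequency to enter the vocabulary
#'   (default 5); rarer tokens are embedded purely from their n-grams.
#' @param minn,maxn Character n-gram lengths (defaults 3 and 6).
#' @param epochs Training epochs (default 5).
#' @param negative Negative samples per positive (default 5).
#' @param lr Initial learning rate, linearly decayed (default 0.05).
#' @param sample_t Frequent-word subsampling threshold (default 1e-4; 0
#'   disables). Tokens with corpus frequency f are kept with probability
#'   `sqrt(t/f) + t/f`, which stops ubiquitous function words from dragging
#'   every vector onto a common axis.
#' @param nbuckets Number of hashed n-gram buckets (default 16384).
#' @return An object of class `embedding_model`.
#' @export
train_embeddings <- function(texts, field_kind = c("title", "abstract"),
                             dim = 300L, seed = 1L, window = 5L,
                             min_count = 5L, minn = 3L, maxn = 6L,
                             epochs = 5L, negative = 5L, lr = 0.05,
                             sample_t = 1e-4, nbuckets = 16384L) {
  field_kind <- match.arg(field_kind)
  stopifnot(dim >= 1L, minn >= 1L, maxn >= minn)
  tokens <- tokenize_text(texts)
  all_tok <- unlist(tokens, use.names = FALSE)
  if (length(all_tok) == 0L) stop("train_embeddings: all texts empty", call. = FALSE)

  counts <- table(all_tok)
  counts <- counts[counts >= min_count]
  if (length(counts) == 0L) {
    stop("train_embeddings: no token reaches min_count = ", min_count, call. = FALSE)
  }
  # deterministic vocabulary order: frequency-descending, then alphabetical
  ord <- order(-as.integer(counts), names(counts), method = "radix")
  vocab <- names(counts)[ord]
  vcounts <- as.integer(counts)[ord]

  idx <- seq_along(vocab)
  names(idx) <- vocab
  sentences <- lapply(tokens, function(tok) {
    ids <- idx[tok]
    as.integer(ids[!is.na(ids)]) - 1L
  })
  sentences <- sentences[vapply(sentences, length, integer(1L)) > 0L]
  if (length(sentences) == 0L) stop("train_embeddings: no trainable sentences", call. = FALSE)

  subwords <- lapply(vocab, cpp_subword_ids, minn = minn, maxn = maxn, nbuckets = nbuckets)
  fit <- cpp_sgns_train(sentences, vcounts, subwords,
                        as.integer(dim), as.integer(nbuckets), as.integer(window),
                        as.integer(negative), as.integer(epochs), lr, sample_t,
                        as.integer(seed))

  # precompose per-word representations (word vector + subword buckets, mean)
  rep_vecs <- fit$word
  for (i in seq_along(vocab)) {
    g <- subwords[[i]] + 1L
    if (length(g) > 0L) {
      rep_vecs[i, ] <- (fit$word[i, ] + colSums(fit$bucket[g, , drop = FALSE])) /
        (1L + length(g))
    }
  }
  rownames(rep_vecs) <- vocab

  structure(c(list(
    field_kind = field_kind, dim = as.integer(dim), vocab = vocab,
    rep_vecs = rep_vecs, bucket_vecs = fit$bucket),
    embedding_postprocess(rep_vecs), list(
    minn = as.integer(minn), maxn = as.integer(maxn),
    nbuckets = as.integer(nbuckets), min_count = as.integer(min_count),
    window = as.integer(window), epochs = as.integer(epochs),
    negative = as.integer(negative), lr = lr, sample_t = sample_t,
    seed = as.integer(seed), n_texts = length(texts)
  )), class = "embedding_model")
}

# Common-component removal ("all-but-the-top"-style, mean only): small
# homogeneous training corpora leave a large shared direction in every
# vector that swamps the co-occurrence signal at sentence level. Token
# embeddings are unit-normalized rows minus the vocabulary-mean direction.
# Derived from rep_vecs, so it is recomputed (not persisted) on load.
embedding_postprocess <- function(rep_vecs) {
  norms <- sqrt(rowSums(rep_vecs * rep_vecs))
  ok <- norms > 1e-12
  U <- rep_vecs
  U[ok, ] <- rep_vecs[ok, , drop = FALSE] / norms[ok]
  center <- if (any(ok)) colMeans(U[ok, , drop = FALSE]) else numeric(ncol(rep_vecs))
  tok_vecs <- sweep(U, 2L, center)
  tok_vecs[!ok, ] <- 0
  rownames(tok_vecs) <- rownames(rep_vecs)
  list(center = center, tok_vecs = tok_vecs)
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("<embedding_model> field=%s dim=%d vocab=%d texts=%d seed=%d\n",
              x$field_kind, x$dim, length(x$vocab), x$n_texts, x$seed))
  invisible(x)
}

# embedding of a single token: centered unit representation for in-vocabulary
# words; composed from n-gram buckets (then centered the same way) otherwise
token_vector <- function(model, token) {
  i <- match(token, model$vocab)
  if (!is.na(i)) return(model$tok_vecs[i, ])
  g <- cpp_subword_ids(token, model$minn, model$maxn, model$nbuckets) + 1L
  if (length(g) == 0L) return(numeric(model$dim))
  v <- colMeans(model$bucket_vecs[g, , drop = FALSE])
  nrm <- sqrt(sum(v * v))
  if (nrm < 1e-12) return(numeric(model$dim))
  v / nrm - model$center
}

#' Map text to a unit-norm sentence vector
#'
#' A normalized average across the word vectors: each token embedding is a
#' unit-norm, mean-centered word vector (see `embedding_postprocess` in the
#' source: centering removes the large shared direction that small training
#' corpora leave in every vector), the embeddings are averaged, and the
#' result is scaled to unit Euclidean norm. Empty or unembeddable text yields the zero vector, with
#' the `"unit"` attribute set to `FALSE`. Because the composition is a bag
#' of vectors, token order does not affect the result.
#'
#' @param model An [train_embeddings()] model.
#' @param text A single string (or `NA`).
#' @return Numeric vector of length `model$dim` with attribute `"unit"`
#'   (`TRUE` for unit norm, `FALSE` for the zero vector).
#' @export
sentence_vector <- function(model, text) {
  stopifnot(inherits(model, "embedding_model"))
  zero <- structure(numeric(model$dim), unit = FALSE)
  if (length(text) != 1L || is.na(text)) return(zero)
  tok <- tokenize_text(text)[[1L]]
  if (length(tok) == 0L) return(zero)

  in_vocab <- match(tok, model$vocab)
  mat <- matrix(0, nrow = length(tok), ncol = model$dim)
  hit <- !is.na(in_vocab)
  if (any(hit)) mat[hit, ] <- model$tok_vecs[in_vocab[hit], , drop = FALSE]
  for (j in which(!hit)) mat[j, ] <- token_vector(model, tok[j])

  keep <- rowSums(mat * mat) > 1e-24
  if (!any(keep)) return(zero)
  v <- colMeans(mat[keep, , drop = FALSE])
  nrm <- sqrt(sum(v * v))
  if (nrm < 1e-12) return(zero)
  structure(v / nrm, unit = TRUE)
}

#' Cosine similarity between two vectors
#'
#' Zero when either vector has zero norm.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Scalar in \[-1, 1\].
#' @export
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a * a))
  nb <- sqrt(sum(b * b))
  if (na < 1e-12 || nb < 1e-12) return(0)
  sum(a * b) / (na * nb)
}

#' Persist an embedding model
#'
#' Writes a little-endian float32 binary (word representations, then n-gram
#' buckets, row-major) plus a JSON sidecar holding the vocabulary and
#' hyperparameters.
#'
#' @param model An `embedding_model`.
#' @param dir Output directory (created if needed).
#' @return The sidecar path, invisibly.
#' @export
save_embeddings <- function(model, dir) {
  stopifnot(inherits(model, "embedding_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, paste0("embedding_", model$field_kind))
  con <- file(paste0(base, ".f32"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(model$rep_vecs)), con, size = 4L, endian = "little")
  writeBin(as.numeric(t(model$bucket_vecs)), con, size = 4L, endian = "little")
  meta <- model[setdiff(names(model), c("rep_vecs", "bucket_vecs"))]
  jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(base, ".json"))
}

#' Load an embedding model saved by [save_embeddings()]
#'
#' @param dir Directory holding the model pair.
#' @param field_kind `"title"` or `"abstract"`.
#' @return An `embedding_model`.
#' @export
load_embeddings <- function(dir, field_kind = c("title", "abstract")) {
  field_kind <- match.arg(field_kind)
  base <- file.path(dir, paste0("embedding_", field_kind))
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  V <- length(meta$vocab)
  con <- file(paste0(base, ".f32"), "rb")
  on.exit(close(con))
  rep_vecs <- matrix(readBin(con, "numeric", n = V * meta$dim, size = 4L,
                             endian = "little"),
                     nrow = V, ncol = meta$dim, byrow = TRUE)
  rownames(rep_vecs) <- meta$vocab
  bucket_vecs <- matrix(readBin(con, "numeric", n = meta$nbuckets * meta$dim,
                                size = 4L, endian = "little"),
                        nrow = meta$nbuckets, ncol = meta$dim, byrow = TRUE)
  model <- c(meta[setdiff(names(meta), c("rep_vecs", "bucket_vecs"))],
             list(rep_vecs = rep_vecs, bucket_vecs = bucket_vecs),
             embedding_postprocess(rep_vecs))
  model <- model[c("field_kind", "dim", "vocab", "rep_vecs", "bucket_vecs",
                   "center", "tok_vecs",
                   "minn", "maxn", "nbuckets", "min_count", "window",
                   "epochs", "negative", "lr", "sample_t", "seed", "n_texts")]
  model$dim <- as.integer(model$dim)
  structure(model, class = "embedding_model")
}
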