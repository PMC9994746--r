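#' Rule-layer configuration
#'
#' The hard-coded thresholds of the decision layer, with their canonical
#' defaults: a "very high" title or abstract similarity (`> 0.999`) bypasses
#' the author veto; a positive classification with lower similarity must pass
#' a minimum author Jaccard of 0.33; the abstract-prefix rescue compares the
#' first 7 whitespace tokens; the large-author-set rescue needs more than 10
#' preprint authors with author Jaccard exactly 1; retrieval takes the top
#' 100 per field.
#'
#' @param very_high_sim Similarity above which the author veto is bypassed.
#' @param author_veto_min Minimum author Jaccard for a non-bypassed positive.
#' @param abstract_prefix_words Tokens compared by the abstract rescue.
#' @param large_authorset_min Author count that must be exceeded for the
#'   large-author-set rescue.
#' @param top_k Per-field retrieval depth.
#' @return A list of class `rule_config`.
#' @export
rule_config <- function(very_high_sim = 0.999, author_veto_min = 0.33,
                        abstract_prefix_words = 7L, large_authorset_min = 10L,
                        top_k = 100L) {
  stopifnot(very_high_sim > 0, very_high_sim <= 1,
            author_veto_min >= 0, author_veto_min <= 1,
            abstract_prefix_words >= 1L, large_authorset_min >= 0L, top_k >= 1L)
  structure(list(very_high_sim = very_high_sim,
                 author_veto_min = author_veto_min,
                 abstract_prefix_words = as.integer(abstract_prefix_words),
                 large_authorset_min = as.integer(large_authorset_min),
                 top_k = as.integer(top_k)), class = "rule_config")
}

# name a record list by pmid/doi for O(1) lookup
corpus_by_pmid <- function(records) {
  if (!is.null(names(records))) return(records)
  names(records) <- vapply(records, `[[`, character(1L), "pmid")
  records
}

# raw whitespace tokens (case preserved) for the exact prefix checks
ws_tokens <- function(text) {
  if (is.na(text)) return(character())
  tok <- strsplit(trimws(text), "\\s+")[[1L]]
  tok[nzchar(tok)]
}

abstract_prefix_equal <- function(a, b, n_words) {
  ta <- ws_tokens(a)
  tb <- ws_tokens(b)
  if (length(ta) == 0L || length(tb) == 0L) return(FALSE)
  pa <- head(ta, n_words)
  pb <- head(tb, n_words)
  length(pa) == length(pb) && all(pa == pb)
}

title_colon_equal <- function(a, b) {
  ka <- colon_key(a)
  kb <- colon_key(b)
  !is.na(ka) && !is.na(kb) && identical(ka, kb)
}

# comparison keys, precomputable corpus-side so the rescue checks are plain
# string equality in the batch path
prefix_key <- function(text, n_words) {
  tok <- ws_tokens(text)
  if (length(tok) == 0L) NA_character_ else paste(head(tok, n_words), collapse = " ")
}

colon_key <- function(title) {
  if (is.na(title) || !grepl(":", title, fixed = TRUE)) return(NA_character_)
  pre <- sub(":.*$", "", title)
  if (nzchar(pre)) pre else NA_character_
}

classifier_features <- function(classifier) {
  feats <- classifier$features
  if (is.null(feats)) c("title_sim", "abstract_sim", "author_sim") else feats
}

# the one rule table both decide() and the batch matcher go through
decision_path <- function(pred_positive, prefix_eq, colon_eq, large_auth_eq,
                          very_high, author_pass) {
  if (!pred_positive) {
    if (prefix_eq) {
      "rescue_abstract_prefix"
    } else if (colon_eq) {
      "rescue_title_colon"
    } else if (large_auth_eq) {
      "rescue_large_authorset"
    } else {
      "svm_negative"
    }
  } else if (!very_high && !author_pass) {
    "vetoed_author_threshold"
  } else {
    "svm_positive"
  }
}

ACCEPT_PATHS <- c("svm_positive", "rescue_abstract_prefix",
                  "rescue_title_colon", "rescue_large_authorset")

# per-paper caches (comparison keys, last-name sets), computed once per corpus
prepare_paper_aux <- function(corpus, config) {
  list(
    prefix = vapply(corpus, function(p) {
      prefix_key(p$abstract, config$abstract_prefix_words)
    }, character(1L)),
    colon = vapply(corpus, function(p) colon_key(p$title), character(1L)),
    last_set = lapply(corpus, function(p) last_name_set(p$authors))
  )
}

#' Score a preprint's candidate papers
#'
#' Computes, per candidate, the title cosine, abstract cosine and author
#' Jaccard (with flip check). The preprint's sentence vectors are recomputed
#' with the same models used to embed the corpus; candidate vectors are read
#' from the indices. A candidate with an absent abstract gets abstract
#' similarity 0 and is flagged.
#'
#' @param preprint A [preprint_record()].
#' @param candidates A `candidate_set` from [candidate_union()].
#' @param models List with `title` and `abstract` embedding models.
#' @param indices List with `title` and `abstract` vector indices.
#' @param corpus List of [paper_record()] objects (the indexed corpus).
#' @return `data.frame(pmid, title_sim, abstract_sim, author_sim,
#'   abstract_missing)`.
#' @export
score_candidates <- function(preprint, candidates, models, indices, corpus) {
  corpus <- corpus_by_pmid(corpus)
  miss <- setdiff(candidates$pmid, names(corpus))
  if (length(miss) > 0L) {
    stop("score_candidates: candidate pmids absent from corpus (index desync): ",
         paste(head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  tq <- sentence_vector(models$title, preprint$title)
  aq <- sentence_vector(models$abstract, preprint$abstract)
  tpos <- match(candidates$pmid, indices$title$ids)
  apos <- match(candidates$pmid, indices$abstract$ids)
  if (anyNA(tpos) || anyNA(apos)) {
    stop("score_candidates: candidate pmids absent from index", call. = FALSE)
  }
  title_sim <- as.numeric(index_rows(indices$title, tpos) %*% tq)
  abstract_sim <- as.numeric(index_rows(indices$abstract, apos) %*% aq)
  pre_last <- last_name_set(preprint$authors)
  pre_fore <- fore_name_set(preprint$authors)
  author_sim <- vapply(candidates$pmid, function(p) {
    paper_last <- last_name_set(corpus[[p]]$authors)
    max(jaccard(pre_last, paper_last), jaccard(pre_fore, paper_last))
  }, numeric(1L))
  abstract_missing <- vapply(candidates$pmid, function(p) {
    is.na(corpus[[p]]$abstract) || !nzchar(corpus[[p]]$abstract)
  }, logical(1L))
  abstract_sim[abstract_missing] <- 0
  data.frame(pmid = candidates$pmid, title_sim = title_sim,
             abstract_sim = abstract_sim, author_sim = author_sim,
             abstract_missing = abstract_missing,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Train the match classifier
#'
#' Fits the RBF-kernel SVM on labeled candidate scores: conventionally 100
#' matching and 100 non-matching preprint-paper pairs, the negatives mined as
#' hard negatives. Training is deterministic given fixed inputs.
#'
#' @param positives,negatives Data frames carrying the feature columns.
#' @param features Feature subset to train on (supports ablations).
#' @return An object of class `match_classifier`.
#' @export
train_svm <- function(positives, negatives,
                      features = c("title_sim", "abstract_sim", "author_sim")) {
  stopifnot(nrow(positives) > 0L, nrow(negatives) > 0L,
            all(features %in% names(positives)),
            all(features %in% names(negatives)))
  x <- rbind(as.matrix(positives[, features, drop = FALSE]),
             as.matrix(negatives[, features, drop = FALSE]))
  colnames(x) <- features
  y <- c(rep(1, nrow(positives)), rep(-1, nrow(negatives)))
  structure(list(svm = svm_train(x, y), features = features),
            class = "match_classifier")
}

#' @export
predict.match_classifier <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  predict(object$svm, x)
}

#' @export
print.match_classifier <- function(x, ...) {
  cat("<match_classifier> features:", paste(x$features, collapse = ", "), "\n")
  print(x$svm)
  invisible(x)
}

# full-corpus similarity scan, aligned with index$ids
index_all_sims <- function(index, query, chunk_rows = 4096L) {
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
  names(sims) <- index$ids
  sims
}

#' Mine hard negatives for classifier training
#'
#' For each sampled preprint without a server-announced publication, emits
#' the corpus paper with the highest product of title and abstract
#' similarity (exhaustive scan; ties broken by ascending pmid). These pairs
#' are high-similarity non-matches once true matches are removed — in the
#' original protocol by manual curation, here by the fixture ground truth.
#'
#' @param preprints List of [preprint_record()] objects.
#' @param models,indices,corpus As in [score_candidates()].
#' @param n Number of preprints to sample (default: all eligible).
#' @param seed RNG seed for the sample.
#' @return `data.frame(preprint_doi, pmid, title_sim, abstract_sim,
#'   author_sim, product)`.
#' @export
mine_hard_negatives <- function(preprints, models, indices, corpus,
                                n = NULL, seed = 1L) {
  eligible <- Filter(function(p) is.na(p$announced_pub_id), preprints)
  if (is.null(n)) n <- length(eligible)
  if (n == 0L || length(eligible) == 0L) {
    return(data.frame(preprint_doi = character(), pmid = character(),
                      title_sim = numeric(), abstract_sim = numeric(),
                      author_sim = numeric(), product = numeric(),
                      stringsAsFactors = FALSE))
  }
  n <- min(n, length(eligible))
  picked <- with_seed(seed, eligible[sample.int(length(eligible), n)])
  corpus <- corpus_by_pmid(corpus)
  rows <- lapply(picked, function(p) {
    ts <- index_all_sims(indices$title, sentence_vector(models$title, p$title))
    as <- index_all_sims(indices$abstract, sentence_vector(models$abstract, p$abstract))
    prod <- ts * as
    best <- names(prod)[order(-prod, names(prod), method = "radix")[1L]]
    data.frame(
      preprint_doi = p$doi, pmid = best,
      title_sim = ts[[best]], abstract_sim = as[[best]],
      author_sim = author_score(p$authors, corpus[[best]]$authors)$score,
      product = prod[[best]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Decide one candidate
#'
#' The decision layer, exactly: the classifier predicts first. On a negative
#' prediction the rescues apply in order — identical first-7-word abstract
#' prefixes; identical non-empty pre-colon title text (both titles must
#' contain a colon); more than `large_authorset_min` preprint authors with
#' author Jaccard exactly 1 — else the candidate is rejected. On a positive
#' prediction, unless title or abstract similarity is very high
#' (`> very_high_sim`), the author Jaccard must reach `author_veto_min` or
#' the match is thrown out.
#'
#' @param candidate One-row candidate score (list or data.frame row with
#'   `pmid`, `title_sim`, `abstract_sim`, `author_sim`).
#' @param preprint_author_count Number of authors on the preprint.
#' @param texts List with `preprint_title`, `preprint_abstract`,
#'   `paper_title`, `paper_abstract` (raw, untokenized).
#' @param config A [rule_config()].
#' @param classifier A [train_svm()] classifier.
#' @return A `match_decision`: list with `pmid`, `accepted`, `path`, and the
#'   candidate `scores`. `path` is one of `svm_positive`,
#'   `rescue_abstract_prefix`, `rescue_title_colon`,
#'   `rescue_large_authorset`, `vetoed_author_threshold`, `svm_negative`.
#' @export
decide <- function(candidate, preprint_author_count, texts, config, classifier) {
  candidate <- as.list(candidate)
  feats <- classifier_features(classifier)
  has_title <- "title_sim" %in% feats
  has_abstract <- "abstract_sim" %in% feats
  has_authors <- "author_sim" %in% feats
  pred <- predict(classifier, as.data.frame(candidate[c("title_sim", "abstract_sim",
                                                        "author_sim")]))
  path <- decision_path(
    pred_positive = pred >= 0,
    prefix_eq = has_abstract &&
      abstract_prefix_equal(texts$preprint_abstract, texts$paper_abstract,
                            config$abstract_prefix_words),
    colon_eq = has_title && title_colon_equal(texts$preprint_title, texts$paper_title),
    large_auth_eq = has_authors &&
      preprint_author_count > config$large_authorset_min &&
      candidate$author_sim == 1,
    very_high = (has_title && candidate$title_sim > config$very_high_sim) ||
      (has_abstract && candidate$abstract_sim > config$very_high_sim),
    author_pass = !has_authors || candidate$author_sim >= config$author_veto_min)
  structure(list(
    pmid = candidate$pmid,
    accepted = path %in% ACCEPT_PATHS,
    path = path,
    scores = candidate
  ), class = "match_decision")
}

#' Match one preprint against a corpus
#'
#' Retrieves the union of the per-field top-k candidates, scores and decides
#' each, and — under the assumption that the highest-similarity paper is the
#' published version — selects among accepted candidates the one with the
#' highest product of title and abstract similarity (ties by ascending
#' pmid). Returns no match when no candidate is accepted.
#'
#' @param preprint A [preprint_record()].
#' @param corpus List of [paper_record()] objects.
#' @param models,indices As in [score_candidates()].
#' @param classifier A [train_svm()] classifier.
#' @param config A [rule_config()].
#' @param keep_trace Keep the full per-candidate decision list.
#' @return A `match_result`: list with `preprint_doi`, `matched_pmid` (`NA`
#'   when no match), `path`, `scores`, and `decision_trace`.
#' @export
match_preprint <- function(preprint, corpus, models, indices, classifier,
                           config = rule_config(), keep_trace = FALSE,
                           .aux = NULL) {
  stopifnot(inherits(config, "rule_config"))
  if (length(corpus) == 0L) {
    return(structure(list(preprint_doi = preprint$doi, matched_pmid = NA_character_,
                          path = NA_character_, scores = NULL,
                          decision_trace = list()), class = "match_result"))
  }
  corpus <- corpus_by_pmid(corpus)
  if (is.null(.aux)) .aux <- prepare_paper_aux(corpus, config)
  feats <- classifier_features(classifier)
  has_title <- "title_sim" %in% feats
  has_abstract <- "abstract_sim" %in% feats
  has_authors <- "author_sim" %in% feats

  tq <- sentence_vector(models$title, preprint$title)
  aq <- sentence_vector(models$abstract, preprint$abstract)
  cands <- candidate_union(top_k_cosine(indices$title, tq, k = config$top_k),
                           top_k_cosine(indices$abstract, aq, k = config$top_k))
  scores <- score_candidates(preprint, cands, models, indices, corpus)
  n_auth <- length(preprint$authors)

  # the same rule table as decide(), evaluated batchwise over all candidates
  pred <- predict(classifier, scores)
  pre_prefix <- prefix_key(preprint$abstract, config$abstract_prefix_words)
  pre_colon <- colon_key(preprint$title)
  prefix_eq <- has_abstract && !is.na(pre_prefix) &
    !is.na(.aux$prefix[scores$pmid]) & .aux$prefix[scores$pmid] == pre_prefix
  colon_eq <- has_title && !is.na(pre_colon) &
    !is.na(.aux$colon[scores$pmid]) & .aux$colon[scores$pmid] == pre_colon
  large_eq <- has_authors & n_auth > config$large_authorset_min &
    scores$author_sim == 1
  very_high <- (has_title & scores$title_sim > config$very_high_sim) |
    (has_abstract & scores$abstract_sim > config$very_high_sim)
  author_pass <- !has_authors | scores$author_sim >= config$author_veto_min
  paths <- vapply(seq_len(nrow(scores)), function(i) {
    decision_path(pred[i] >= 0, prefix_eq[i], colon_eq[i], large_eq[i],
                  very_high[i], author_pass[i])
  }, character(1L))
  accepted <- paths %in% ACCEPT_PATHS

  sim_feats <- intersect(feats, c("title_sim", "abstract_sim"))
  if (length(sim_feats) == 0L) sim_feats <- c("title_sim", "abstract_sim")
  if (!any(accepted)) {
    best_pmid <- NA_character_
    best_path <- NA_character_
    best_scores <- NULL
  } else {
    prods <- apply(as.matrix(scores[accepted, sim_feats, drop = FALSE]), 1L, prod)
    pmids <- scores$pmid[accepted]
    best <- order(-prods, pmids, method = "radix")[1L]
    best_pmid <- pmids[best]
    best_path <- paths[accepted][best]
    best_scores <- as.list(scores[accepted, , drop = FALSE][best, ])
  }
  trace <- if (keep_trace) {
    lapply(seq_len(nrow(scores)), function(i) {
      structure(list(pmid = scores$pmid[i], accepted = accepted[i],
                     path = paths[i], scores = as.list(scores[i, ])),
                class = "match_decision")
    })
  } else {
    list()
  }
  structure(list(
    preprint_doi = preprint$doi, matched_pmid = best_pmid, path = best_path,
    scores = best_scores,
    decision_trace = trace
  ), class = "match_result")
}

#' Match a batch of preprints
#'
#' Vectorized convenience over [match_preprint()].
#'
#' @inheritParams match_preprint
#' @param preprints List of [preprint_record()] objects.
#' @return `data.frame(doi, pmid, path, title_sim, abstract_sim, author_sim)`
#'   with `NA` pmid for unmatched preprints.
#' @export
match_all <- function(preprints, corpus, models, indices, classifier,
                      config = rule_config()) {
  corpus <- corpus_by_pmid(corpus)
  aux <- if (length(corpus) > 0L) prepare_paper_aux(corpus, config)
  rows <- lapply(preprints, function(p) {
    r <- match_preprint(p, corpus, models, indices, classifier, config,
                        .aux = aux)
    data.frame(
      doi = r$preprint_doi,
      pmid = if (is.na(r$matched_pmid)) NA_character_ else r$matched_pmid,
      path = if (is.na(r$matched_pmid)) NA_character_ else r$path,
      title_sim = if (is.null(r$scores)) NA_real_ else r$scores$title_sim,
      abstract_sim = if (is.null(r$scores)) NA_real_ else r$scores$abstract_sim,
      author_sim = if (is.null(r$scores)) NA_real_ else r$scores$author_sim,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
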