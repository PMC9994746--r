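# Shared builders for a small matching stack. Kept deliberately tiny so
# per-file setup stays in the low seconds; the acceptance file builds the
# full-size corpora itself.

paper_texts <- function(papers, field) {
  vapply(papers, function(p) {
    v <- p[[field]]
    if (is.na(v)) "" else v
  }, character(1L))
}

train_stack_models <- function(corpus, dim = 30L, seed = 5L) {
  list(
    title = train_embeddings(paper_texts(corpus$papers, "title"), "title",
                             dim = dim, min_count = 2L, seed = seed),
    abstract = train_embeddings(paper_texts(corpus$papers, "abstract"), "abstract",
                                dim = dim, min_count = 2L, seed = seed + 1L))
}

build_stack_indices <- function(corpus, models, dir = tempfile("idx")) {
  pmids <- vapply(corpus$papers, `[[`, character(1L), "pmid")
  lapply(stats::setNames(c("title", "abstract"), c("title", "abstract")),
         function(field) {
    vecs <- t(vapply(corpus$papers, function(p) {
      as.numeric(sentence_vector(models[[field]], p[[field]]))
    }, numeric(models[[field]]$dim)))
    build_index(vecs, pmids, field, dir)
  })
}

# full small stack: corpus + models + indices + trained classifier
build_test_stack <- function(n_pairs = 25L, n_decoys = 30L, n_unpublished = 12L,
                             text_sub_rate = 0, seed = 42L, dim = 30L, ...) {
  cfg <- fixture_config(n_pairs = n_pairs, n_decoys = n_decoys,
                        n_unpublished = n_unpublished,
                        text_sub_rate = text_sub_rate, seed = seed, ...)
  corpus <- generate_corpus(cfg)
  models <- train_stack_models(corpus, dim = dim, seed = seed + 1L)
  indices <- build_stack_indices(corpus, models)
  pairs <- labeled_training_pairs(corpus, models, indices,
                                  n_pos = min(20L, n_pairs),
                                  n_neg = min(10L, n_unpublished),
                                  seed = seed + 2L)
  classifier <- train_svm(pairs$positives, pairs$negatives)
  list(corpus = corpus, models = models, indices = indices,
       classifier = classifier, pairs = pairs)
}

truth_labels <- function(truth) {
  data.frame(preprint_doi = names(truth),
             label = ifelse(is.na(truth), "true_negative", "true_positive"),
             truth_pmid = unname(truth), source = "fixture",
             stringsAsFactors = FALSE)
}

match_metrics <- function(res, truth) {
  pv <- res$pmid
  names(pv) <- res$doi
  labels <- truth_labels(truth)
  counts <- confusion_counts(pv[labels$preprint_doi], labels)
  c(precision_recall_f1(counts), list(counts = counts))
}

# a classifier stub with a fixed prediction, for exercising the rule layer
constant_classifier <- function(sign = 1,
                                features = c("title_sim", "abstract_sim",
                                             "author_sim")) {
  structure(list(features = features, sign = sign),
            class = c("constant_classifier", "match_classifier"))
}

predict.constant_classifier <- function(object, newdata, ...) {
  rep(object$sign, nrow(as.data.frame(newdata)))
}
registerS3method("predict", "constant_classifier", predict.constant_classifier,
                 envir = asNamespace("stats"))
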