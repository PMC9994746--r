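# one shared small stack for this file (zero revision noise)
stack <- build_test_stack(seed = 42L)

cand <- function(title_sim = 0.9, abstract_sim = 0.9, author_sim = 0.9,
                 pmid = "p1") {
  list(pmid = pmid, title_sim = title_sim, abstract_sim = abstract_sim,
       author_sim = author_sim)
}

texts0 <- list(preprint_title = "A plain title", preprint_abstract = "Plain words here",
               paper_title = "Other title", paper_abstract = "Different words entirely")

test_that("decide reproduces the documented example decisions", {
  cfg <- rule_config()
  neg <- constant_classifier(-1)
  pos <- constant_classifier(1)

  # SVM negative + identical first 7 abstract words -> rescued
  tx <- texts0
  tx$preprint_abstract <- "We present a new method for rapid genome assembly"
  tx$paper_abstract <- "We present a new method for rapid transcriptome work"
  d <- decide(cand(author_sim = 0), 3L, tx, cfg, neg)
  expect_true(d$accepted)
  expect_equal(d$path, "rescue_abstract_prefix")

  # SVM positive, sims below very-high, author 0.2 -> vetoed
  d2 <- decide(cand(0.95, 0.95, 0.2), 3L, texts0, cfg, pos)
  expect_false(d2$accepted)
  expect_equal(d2$path, "vetoed_author_threshold")

  # very-high title similarity bypasses the author veto
  d3 <- decide(cand(0.9995, 0.5, 0), 3L, texts0, cfg, pos)
  expect_true(d3$accepted)
  expect_equal(d3$path, "svm_positive")

  # SVM negative, 12 authors, perfect author Jaccard -> rescued
  d4 <- decide(cand(0.5, 0.5, 1), 12L, texts0, cfg, neg)
  expect_true(d4$accepted)
  expect_equal(d4$path, "rescue_large_authorset")

  # boundary: author_sim exactly at the veto threshold passes
  d5 <- decide(cand(0.9, 0.9, 0.33), 3L, texts0, cfg, pos)
  expect_equal(d5$path, "svm_positive")
  # boundary: exactly 10 authors is not "more than 10"
  d6 <- decide(cand(0.5, 0.5, 1), 10L, texts0, cfg, neg)
  expect_equal(d6$path, "svm_negative")
})

test_that("the colon rescue requires a colon in both titles and equal prefixes", {
  cfg <- rule_config()
  neg <- constant_classifier(-1)
  tx <- texts0
  tx$preprint_title <- "SpliceTool: fast splicing analysis"
  tx$paper_title <- "SpliceTool: a tool for splicing"
  expect_equal(decide(cand(author_sim = 0), 3L, tx, cfg, neg)$path,
               "rescue_title_colon")
  tx$paper_title <- "SpliceTool for splicing"  # no colon
  expect_equal(decide(cand(author_sim = 0), 3L, tx, cfg, neg)$path,
               "svm_negative")
  tx$paper_title <- "OtherTool: a tool for splicing"
  expect_equal(decide(cand(author_sim = 0), 3L, tx, cfg, neg)$path,
               "svm_negative")
})

test_that("score_candidates returns the 3-feature vector per candidate", {
  corpus <- stack$corpus
  truth <- corpus$truth
  doi <- names(truth)[!is.na(truth)][1L]
  pre <- corpus$preprints[[which(vapply(corpus$preprints, `[[`, "", "doi") == doi)]]
  cands <- structure(data.frame(pmid = truth[[doi]], from_title = TRUE,
                                from_abstract = TRUE, stringsAsFactors = FALSE),
                     class = c("candidate_set", "data.frame"))
  sc <- score_candidates(pre, cands, stack$models, stack$indices, corpus$papers)
  # zero revision noise: the true pair is a self-match on every feature
  expect_gt(sc$title_sim, 0.999)
  expect_gt(sc$abstract_sim, 0.999)
  expect_equal(sc$author_sim, 1)
  expect_false(sc$abstract_missing)

  bad <- structure(data.frame(pmid = "0000000", from_title = TRUE,
                              from_abstract = FALSE, stringsAsFactors = FALSE),
                   class = c("candidate_set", "data.frame"))
  expect_error(score_candidates(pre, bad, stack$models, stack$indices,
                                corpus$papers), "desync")
})

test_that("candidates with absent abstracts get zero abstract similarity, flagged", {
  pre <- stack$corpus$preprints[[1L]]
  bare <- paper_record(pmid = "7777777", title = pre$title,
                       abstract = NA_character_, pub_date = as.Date("2020-06-01"),
                       authors = pre$authors, languages = "eng")
  papers <- c(stack$corpus$papers, list(bare))
  indices <- build_stack_indices(list(papers = papers), stack$models)
  cands <- structure(data.frame(pmid = "7777777", from_title = TRUE,
                                from_abstract = FALSE, stringsAsFactors = FALSE),
                     class = c("candidate_set", "data.frame"))
  sc <- score_candidates(pre, cands, stack$models, indices, papers)
  expect_equal(sc$abstract_sim, 0)
  expect_true(sc$abstract_missing)
  expect_gt(sc$title_sim, 0.999)  # same title: it can still enter via title rank
})

test_that("mine_hard_negatives emits the exhaustive argmax of the product", {
  corpus <- stack$corpus
  mined <- mine_hard_negatives(corpus$preprints, stack$models, stack$indices,
                               corpus$papers, n = 5L, seed = 3L)
  expect_equal(nrow(mined), 5L)
  papers <- corpus$papers
  pmids <- vapply(papers, `[[`, "", "pmid")
  for (i in seq_len(nrow(mined))) {
    doi <- mined$preprint_doi[i]
    pre <- corpus$preprints[[which(vapply(corpus$preprints, `[[`, "", "doi") == doi)]]
    # brute force: score every paper, take the max product (tie: pmid order)
    tq <- sentence_vector(stack$models$title, pre$title)
    aq <- sentence_vector(stack$models$abstract, pre$abstract)
    prods <- vapply(seq_along(papers), function(j) {
      ts <- sum(index_rows(stack$indices$title, j) * tq)
      as_ <- sum(index_rows(stack$indices$abstract, j) * aq)
      ts * as_
    }, numeric(1L))
    best <- pmids[order(-prods, pmids, method = "radix")[1L]]
    expect_identical(mined$pmid[i], best)
  }
  # eligible preprints exclude announced ones
  ann <- vapply(corpus$preprints, function(p) !is.na(p$announced_pub_id), logical(1L))
  expect_false(any(mined$preprint_doi %in%
                     vapply(corpus$preprints[ann], `[[`, "", "doi")))
  empty <- mine_hard_negatives(corpus$preprints, stack$models, stack$indices,
                               corpus$papers, n = 0L)
  expect_equal(nrow(empty), 0L)
})

test_that("match_preprint recovers the twin and refuses unrelated corpora", {
  corpus <- stack$corpus
  truth <- corpus$truth
  dois <- vapply(corpus$preprints, `[[`, "", "doi")

  pub <- names(truth)[!is.na(truth)][1:5]
  for (doi in pub) {
    r <- match_preprint(corpus$preprints[[which(dois == doi)]], corpus$papers,
                        stack$models, stack$indices, stack$classifier,
                        keep_trace = TRUE)
    expect_identical(r$matched_pmid, unname(truth[[doi]]))
    # the match never leaves the candidate union
    expect_true(r$matched_pmid %in%
                  vapply(r$decision_trace, `[[`, "", "pmid"))
  }

  unp <- names(truth)[is.na(truth)][1:3]
  for (doi in unp) {
    r <- match_preprint(corpus$preprints[[which(dois == doi)]], corpus$papers,
                        stack$models, stack$indices, stack$classifier)
    expect_true(is.na(r$matched_pmid))
  }

  # empty corpus: no match, empty trace
  r0 <- match_preprint(corpus$preprints[[1L]], list(), stack$models,
                       stack$indices, stack$classifier)
  expect_true(is.na(r0$matched_pmid))
  expect_length(r0$decision_trace, 0L)
})

test_that("classifier persistence round-trips predictions", {
  path <- withr::local_tempfile(fileext = ".json")
  save_classifier(stack$classifier, path)
  back <- load_classifier(path)
  newdata <- rbind(stack$pairs$positives[, 3:5], stack$pairs$negatives[, 3:5])
  expect_equal(predict(back, newdata), predict(stack$classifier, newdata))
  expect_identical(back$features, stack$classifier$features)
})
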