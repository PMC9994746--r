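test_that("construct_test_set labels agreement, absence, and curated conflicts", {
  dois <- sprintf("d%02d", 1:10)
  # no announcements, no tool matches: all true negatives
  ts <- construct_test_set(dois)
  expect_equal(ts$counts$true_negative, 10L)
  expect_equal(ts$counts$true_positive, 0L)
  expect_true(all(ts$labels$source == "both_absent"))

  # one conflict resolved to the tool's pmid
  announced <- c(d01 = "p1")
  tool <- c(d01 = "p1", d02 = "p9")
  ts2 <- construct_test_set(dois, announced, tool, curation = c(d02 = "p9"))
  lab <- ts2$labels
  expect_equal(lab$label[lab$preprint_doi == "d01"], "true_positive")
  expect_equal(lab$source[lab$preprint_doi == "d01"], "both_agree")
  expect_equal(lab$label[lab$preprint_doi == "d02"], "true_positive")
  expect_equal(lab$source[lab$preprint_doi == "d02"], "curated")
  expect_equal(lab$truth_pmid[lab$preprint_doi == "d02"], "p9")

  # curated negative resolution
  ts3 <- construct_test_set(dois, announced, tool,
                            curation = c(d02 = NA_character_))
  expect_equal(ts3$labels$label[ts3$labels$preprint_doi == "d02"],
               "true_negative")

  # unresolved conflict is an error naming the preprint
  expect_error(construct_test_set(dois, announced, tool), "d02")

  # announced match not indexed: the preprint is excluded entirely
  ts4 <- construct_test_set(dois, announced, tool_matches = c(d02 = "p9"),
                            curation = c(d02 = "p9"),
                            indexed = function(pmid) pmid != "p1")
  expect_equal(ts4$counts$excluded, 1L)
  expect_false("d01" %in% ts4$labels$preprint_doi)
  # conservation: excluded + labeled = sampled
  expect_equal(ts4$counts$excluded + nrow(ts4$labels), length(dois))
})

test_that("confusion_counts implements the correctness definition", {
  labels <- data.frame(
    preprint_doi = sprintf("d%02d", 1:20),
    label = rep(c("true_positive", "true_negative"), c(12L, 8L)),
    truth_pmid = c(sprintf("p%02d", 1:12), rep(NA, 8L)),
    stringsAsFactors = FALSE)

  perfect <- c(sprintf("p%02d", 1:12), rep(NA, 8L))
  names(perfect) <- labels$preprint_doi
  cc <- confusion_counts(perfect, labels)
  expect_equal(unclass(cc)[c("tp", "fp", "fn", "tn")],
               list(tp = 12L, fp = 0L, fn = 0L, tn = 8L))

  none <- rep(NA_character_, 20L)
  names(none) <- labels$preprint_doi
  cc2 <- confusion_counts(none, labels)
  expect_equal(cc2$fn, 12L)
  expect_equal(cc2$tn, 8L)

  # hand tally: 10 correct positives, 1 wrong pmid, 1 missed,
  # 6 correct negatives, 2 spurious matches
  mixed <- c(sprintf("p%02d", 1:10), "WRONG", NA, "x1", "x2", rep(NA, 6L))
  names(mixed) <- labels$preprint_doi
  cc3 <- confusion_counts(mixed, labels)
  expect_equal(unclass(cc3)[c("tp", "fp", "fn", "tn", "wrong_pmid")],
               list(tp = 10L, fp = 3L, fn = 1L, tn = 6L, wrong_pmid = 1L))
  # additivity: tp+fp+fn+tn equals the number evaluated
  expect_equal(cc3$tp + cc3$fp + cc3$fn + cc3$tn, 20L)

  expect_error(confusion_counts(c(zz = "p1"), labels), "unknown")
  expect_error(confusion_counts(perfect[-1L], labels), "no prediction")
})

test_that("precision_recall_f1 follows the printed formulas", {
  m <- precision_recall_f1(list(tp = 9L, fp = 1L, fn = 1L))
  expect_equal(m$precision, 90)
  expect_equal(m$recall, 90)
  expect_equal(m$f1, 90)

  perfect <- precision_recall_f1(list(tp = 5L, fp = 0L, fn = 0L))
  expect_equal(unlist(perfect), c(precision = 100, recall = 100, f1 = 100))

  expect_equal(precision_recall_f1(list(tp = 0L, fp = 2L, fn = 3L))$recall, 0)
  # zero denominators are undefined, not zero
  expect_true(is.na(precision_recall_f1(list(tp = 0L, fp = 0L, fn = 2L))$precision))
  expect_true(is.na(precision_recall_f1(list(tp = 0L, fp = 0L, fn = 0L))$f1))
})

test_that("F1 is the harmonic mean of precision and recall (random counts)", {
  set.seed(77)
  for (i in 1:1000) {
    counts <- list(tp = sample(1:200, 1L), fp = sample(0:200, 1L),
                   fn = sample(0:200, 1L))
    m <- precision_recall_f1(counts)
    expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall),
                 tolerance = 1e-9)
    expect_equal(m$recall, 100 * counts$tp / (counts$tp + counts$fn))
    expect_equal(m$precision, 100 * counts$tp / (counts$tp + counts$fp))
  }
})

test_that("mcnemar_test reports the chi-square statistic and the exact p", {
  r <- mcnemar_test(4L, 4L)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_exact, 1)

  r2 <- mcnemar_test(5L, 1L)
  expect_equal(r2$statistic, (5 - 1)^2 / 6, tolerance = 1e-4)  # 2.667
  # exact two-sided binomial over 6 trials at 1/2
  expect_equal(r2$p_exact, binom.test(5L, 6L, 0.5)$p.value)

  r3 <- mcnemar_test(0L, 0L)
  expect_equal(r3$p_exact, 1)
  expect_equal(r3$statistic, 0)
  expect_true(r3$no_evidence)

  expect_error(mcnemar_test(-1L, 2L), "negative")

  # symmetry in (a, b)
  for (i in 1:25) {
    set.seed(i)
    a <- sample(0:30, 1L)
    b <- sample(0:30, 1L)
    expect_equal(mcnemar_test(a, b)$statistic, mcnemar_test(b, a)$statistic)
    expect_equal(mcnemar_test(a, b)$p_exact, mcnemar_test(b, a)$p_exact)
  }
})

test_that("pair_reporting bins by week and correlates gap with similarity", {
  # degenerate: all pairs on the same day
  same <- data.frame(posted_date = as.Date("2020-01-01"),
                     pub_date = as.Date("2020-01-01"),
                     title_sim = c(0.9, 0.8), abstract_sim = c(0.95, 0.85))
  rep0 <- pair_reporting(same)
  expect_equal(nrow(rep0$histogram), 1L)
  expect_equal(rep0$histogram$week, 0)
  expect_equal(rep0$median_gap_days, 0)

  # hand-built 5-pair table: two bins, hand-computed medians/means
  hand <- data.frame(
    posted_date = as.Date("2020-01-01"),
    pub_date = as.Date("2020-01-01") + c(1, 3, 5, 10, 12),
    title_sim = c(1, 0.9, 0.8, 0.6, 0.4),
    abstract_sim = c(1, 0.95, 0.9, 0.7, 0.5))
  reph <- pair_reporting(hand)
  expect_equal(reph$by_bin$week, c(0, 1))
  expect_equal(reph$by_bin$median_abstract_sim, c(0.95, 0.6))
  expect_equal(reph$by_bin$mean_title_sim, c(0.9, 0.5))
  expect_equal(reph$histogram$n, c(3L, 2L))

  # negative gaps are retained and counted
  neg <- hand
  neg$pub_date[1L] <- as.Date("2019-12-15")
  expect_equal(pair_reporting(neg)$n_negative_gaps, 1L)

  # a constructed decreasing trend gives a negative correlation
  set.seed(5)
  trend <- data.frame(
    posted_date = as.Date("2020-01-01"),
    pub_date = as.Date("2020-01-01") + rep(seq(7, 140, by = 7), each = 4L),
    title_sim = NA, abstract_sim = NA)
  gap <- as.integer(trend$pub_date - trend$posted_date)
  trend$abstract_sim <- 1 - gap / 200 + rnorm(nrow(trend), 0, 0.01)
  trend$title_sim <- 1 - gap / 300 + rnorm(nrow(trend), 0, 0.01)
  rept <- pair_reporting(trend)
  expect_lt(rept$r_abstract, -0.9)
  expect_lt(rept$r_title, -0.9)
})

test_that("ablation_run emits one row per strategy and rejects unknown ones", {
  stack <- build_test_stack(n_pairs = 15L, n_decoys = 20L, n_unpublished = 8L,
                            seed = 21L)
  corpus <- stack$corpus
  labels <- truth_labels(corpus$truth)
  strategies <- c("title", "abstract", "abstract+title", "title+authors", "full")
  tab <- ablation_run(strategies, corpus$preprints, corpus$papers,
                      stack$models, stack$indices,
                      stack$pairs$positives, stack$pairs$negatives, labels)
  expect_equal(nrow(tab), 5L)
  expect_identical(tab$method, strategies)
  expect_true(all(c("recall", "precision", "f1", "tp", "fp", "fn", "tn")
                  %in% names(tab)))
  # zero-noise fixtures are separable for the full strategy
  expect_equal(tab$f1[tab$method == "full"], 100)
  expect_error(ablation_run("authors-only", corpus$preprints, corpus$papers,
                            stack$models, stack$indices, stack$pairs$positives,
                            stack$pairs$negatives, labels), "unknown")
})
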