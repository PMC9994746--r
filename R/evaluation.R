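#' Construct a labeled test set from two match sources
#'
#' Implements the standard flow for building linkage ground truth without
#' exhaustive curation: starting from a random sample of preprints, announced
#' matches whose paper is not indexed are excluded; preprints matched by
#' neither the server announcements nor the tool are true negatives;
#' preprints matched identically by both are true positives; every other
#' case (one source silent, or the sources disagree) must be resolved by a
#' curation map.
#'
#' @param sampled_dois Character vector: the sampled preprints.
#' @param announced Named character vector, `doi -> pmid`, for preprints with
#'   a server-announced published version.
#' @param tool_matches Named character vector, `doi -> pmid`, of tool
#'   predictions (omit or set `NA` for no match).
#' @param curation Named character vector resolving conflicts: `doi -> pmid`
#'   for a curated positive, `doi -> NA` for a curated negative. An
#'   unresolved conflict is an error listing the preprints.
#' @param indexed Predicate for "published paper is indexed": a function of
#'   a pmid, or a character vector of indexed pmids. Default: everything
#'   indexed.
#' @return List with `labels` (`data.frame(preprint_doi, label, truth_pmid,
#'   source)`) and `counts` (sampled, excluded, true_positive,
#'   true_negative). Excluded plus labeled preprints always equals the
#'   sample size.
#' @export
construct_test_set <- function(sampled_dois, announced = character(),
                               tool_matches = character(), curation = character(),
                               indexed = NULL) {
  is_indexed <- if (is.null(indexed)) {
    function(pmid) TRUE
  } else if (is.function(indexed)) {
    indexed
  } else {
    function(pmid) pmid %in% indexed
  }
  get1 <- function(map, key) {
    if (key %in% names(map)) unname(map[[key]]) else NA_character_
  }

  rows <- list()
  excluded <- character()
  unresolved <- character()
  for (doi in sampled_dois) {
    ann <- get1(announced, doi)
    if (!is.na(ann) && !isTRUE(is_indexed(ann))) {
      excluded <- c(excluded, doi)
      next
    }
    tool <- get1(tool_matches, doi)
    if (is.na(ann) && is.na(tool)) {
      rows[[doi]] <- data.frame(preprint_doi = doi, label = "true_negative",
                                truth_pmid = NA_character_, source = "both_absent",
                                stringsAsFactors = FALSE)
    } else if (!is.na(ann) && !is.na(tool) && ann == tool) {
      rows[[doi]] <- data.frame(preprint_doi = doi, label = "true_positive",
                                truth_pmid = ann, source = "both_agree",
                                stringsAsFactors = FALSE)
    } else {
      if (!doi %in% names(curation)) {
        unresolved <- c(unresolved, doi)
        next
      }
      cur <- unname(curation[[doi]])
      rows[[doi]] <- data.frame(
        preprint_doi = doi,
        label = if (is.na(cur)) "true_negative" else "true_positive",
        truth_pmid = cur, source = "curated", stringsAsFactors = FALSE)
    }
  }
  if (length(unresolved) > 0L) {
    stop("construct_test_set: unresolved conflicts for ",
         length(unresolved), " preprints: ",
         paste(head(unresolved, 5L), collapse = ", "),
         if (length(unresolved) > 5L) ", ...", call. = FALSE)
  }
  labels <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(labels)) {
    labels <- data.frame(preprint_doi = character(), label = character(),
                         truth_pmid = character(), source = character(),
                         stringsAsFactors = FALSE)
  }
  list(labels = labels,
       counts = list(sampled = length(sampled_dois),
                     excluded = length(excluded),
                     true_positive = sum(labels$label == "true_positive"),
                     true_negative = sum(labels$label == "true_negative")))
}

#' Confusion counts against a labeled test set
#'
#' A prediction is correct when it names the same paper as the ground truth,
#' or correctly reports no match. A wrong-pmid prediction on a positive is
#' counted as a false positive only (the missed positive is reported
#' separately as `wrong_pmid`), keeping `tp + fp + fn + tn` equal to the
#' number of evaluated preprints.
#'
#' @param predictions Named character vector `doi -> pmid` (`NA` = no
#'   match). Every labeled doi must be present; predictions for unknown dois
#'   are an error.
#' @param labels The `labels` data frame from [construct_test_set()] (or any
#'   frame with `preprint_doi`, `label`, `truth_pmid`).
#' @return List of class `eval_counts`: `tp`, `fp`, `fn`, `tn`,
#'   `wrong_pmid`.
#' @export
confusion_counts <- function(predictions, labels) {
  unknown <- setdiff(names(predictions), labels$preprint_doi)
  if (length(unknown) > 0L) {
    stop("confusion_counts: predictions for unknown dois: ",
         paste(head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(labels$preprint_doi, names(predictions))
  if (length(missing) > 0L) {
    stop("confusion_counts: no prediction for ",
         paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  tp <- fp <- fn <- tn <- wrong <- 0L
  for (i in seq_len(nrow(labels))) {
    doi <- labels$preprint_doi[i]
    pred <- unname(predictions[[doi]])
    if (labels$label[i] == "true_positive") {
      if (is.na(pred)) {
        fn <- fn + 1L
      } else if (pred == labels$truth_pmid[i]) {
        tp <- tp + 1L
      } else {
        fp <- fp + 1L
        wrong <- wrong + 1L
      }
    } else {
      if (is.na(pred)) tn <- tn + 1L else fp <- fp + 1L
    }
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, wrong_pmid = wrong),
            class = "eval_counts")
}

#' Precision, recall and F1 as percentages
#'
#' `recall = TP/(TP+FN)`, `precision = TP/(TP+FP)`,
#' `F1 = 2TP/(2TP+FP+FN)`, each multiplied by 100. A zero denominator yields
#' `NA` (undefined), never 0.
#'
#' @param counts An `eval_counts` (or list with `tp`, `fp`, `fn`).
#' @return List with `precision`, `recall`, `f1` in percent.
#' @export
precision_recall_f1 <- function(counts) {
  tp <- counts$tp
  fp <- counts$fp
  fn <- counts$fn
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  safe <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  list(precision = safe(tp, tp + fp),
       recall = safe(tp, tp + fn),
       f1 = safe(2 * tp, 2 * tp + fp + fn))
}

#' McNemar paired comparison of two tools
#'
#' From the discordant counts — `a`: tool A correct and B incorrect, `b`:
#' the opposite — reports the chi-square statistic `(a-b)^2 / (a+b)` and the
#' exact two-sided binomial p-value over `a+b` trials at proportion 1/2
#' (McNemar's exact test). With no discordant pairs the statistic is 0 and
#' p = 1, flagged as carrying no evidence. Both outputs are symmetric in
#' `(a, b)`.
#'
#' @param a,b Nonnegative discordant counts.
#' @return List with `statistic`, `p_exact`, `p_chisq`, `no_evidence`.
#' @export
mcnemar_test <- function(a, b) {
  if (a < 0 || b < 0) stop("mcnemar_test: negative counts", call. = FALSE)
  n <- a + b
  if (n == 0) {
    return(list(statistic = 0, p_exact = 1, p_chisq = 1, no_evidence = TRUE))
  }
  stat <- (a - b)^2 / n
  list(statistic = stat,
       p_exact = stats::binom.test(a, n, p = 0.5)$p.value,
       p_chisq = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       no_evidence = FALSE)
}

ABLATION_FEATURES <- list(
  "title" = "title_sim",
  "abstract" = "abstract_sim",
  "abstract+title" = c("title_sim", "abstract_sim"),
  "title+authors" = c("title_sim", "author_sim"),
  "full" = c("title_sim", "abstract_sim", "author_sim")
)

#' Feature-ablation harness
#'
#' Re-trains the decision layer on a restricted feature subset (rules that
#' need an absent feature are disabled: the abstract-prefix rescue needs
#' abstracts, the title-colon rescue titles, the author veto and
#' large-author-set rescue authors), evaluates against the labeled test set,
#' and emits one comparison-table row per strategy. Candidate retrieval is
#' unchanged; only the decision layer is restricted.
#'
#' @param strategies Subset of `c("title", "abstract", "abstract+title",
#'   "title+authors", "full")`.
#' @param preprints Test preprints (list of [preprint_record()]).
#' @param corpus,models,indices As in [match_preprint()].
#' @param positives,negatives Labeled training pairs (feature data frames).
#' @param labels Test-set labels (see [confusion_counts()]).
#' @param config A [rule_config()].
#' @return Data frame with one row per strategy: method, recall, precision,
#'   f1, tp, fp, fn, tn.
#' @export
ablation_run <- function(strategies, preprints, corpus, models, indices,
                         positives, negatives, labels, config = rule_config()) {
  unknown <- setdiff(strategies, names(ABLATION_FEATURES))
  if (length(unknown) > 0L) {
    stop("ablation_run: unknown strategies: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(strategies, function(s) {
    clf <- train_svm(positives, negatives, features = ABLATION_FEATURES[[s]])
    preds <- match_all(preprints, corpus, models, indices, clf, config)
    pv <- preds$pmid
    names(pv) <- preds$doi
    counts <- confusion_counts(pv, labels)
    m <- precision_recall_f1(counts)
    data.frame(method = s, recall = m$recall, precision = m$precision,
               f1 = m$f1, tp = counts$tp, fp = counts$fp, fn = counts$fn,
               tn = counts$tn, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Time-gap and similarity reporting for matched pairs
#'
#' Computes the publication gap in days (paper date minus preprint posting
#' date; negative gaps are retained and counted), bins it into left-closed
#' 7-day weeks, and reports the per-bin median abstract similarity and mean
#' title similarity, plus the Pearson correlation between the bin index and
#' each per-bin statistic.
#'
#' @param pairs Data frame with columns `posted_date`, `pub_date`,
#'   `title_sim`, `abstract_sim`.
#' @return List: `pairs` (with `gap_days`, `week`), `histogram`
#'   (`data.frame(week, n)`), `by_bin` (per-week medians/means),
#'   `r_abstract`, `r_title`, `n_negative_gaps`, `median_gap_days`.
#' @export
pair_reporting <- function(pairs) {
  stopifnot(all(c("posted_date", "pub_date", "title_sim", "abstract_sim")
                %in% names(pairs)))
  gap <- as.integer(as.Date(pairs$pub_date) - as.Date(pairs$posted_date))
  week <- floor(gap / 7)
  pairs$gap_days <- gap
  pairs$week <- week

  weeks <- sort(unique(week))
  histogram <- data.frame(week = weeks,
                          n = vapply(weeks, function(w) sum(week == w), integer(1L)))
  by_bin <- data.frame(
    week = weeks,
    median_abstract_sim = vapply(weeks, function(w) {
      median(pairs$abstract_sim[week == w])
    }, numeric(1L)),
    mean_title_sim = vapply(weeks, function(w) {
      mean(pairs$title_sim[week == w])
    }, numeric(1L)),
    n = histogram$n)

  safe_cor <- function(x, y) {
    if (length(x) < 2L || var(x) == 0 || var(y) == 0) NA_real_ else cor(x, y)
  }
  list(pairs = pairs, histogram = histogram, by_bin = by_bin,
       r_abstract = safe_cor(by_bin$week, by_bin$median_abstract_sim),
       r_title = safe_cor(by_bin$week, by_bin$mean_title_sim),
       n_negative_gaps = sum(gap < 0),
       median_gap_days = median(gap))
}
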