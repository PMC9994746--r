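#' Persist a match classifier as JSON
#'
#' @param classifier A [train_svm()] classifier.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "match_classifier"))
  svm <- classifier$svm
  jsonlite::write_json(list(
    features = classifier$features,
    sv_x = apply(svm$sv_x, 1L, as.numeric, simplify = FALSE),
    sv_coef = svm$sv_coef, b = svm$b, gamma = svm$gamma, C = svm$C,
    n_train = svm$n_train
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a classifier saved by [save_classifier()]
#'
#' @param path JSON path.
#' @return A `match_classifier`.
#' @export
load_classifier <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sv_x <- if (is.list(x$sv_x)) do.call(rbind, x$sv_x) else as.matrix(x$sv_x)
  colnames(sv_x) <- x$features
  svm <- structure(list(sv_x = sv_x, sv_coef = as.numeric(x$sv_coef),
                        b = x$b, gamma = x$gamma, C = x$C,
                        features = x$features, n_train = x$n_train),
                   class = "svm_rbf")
  structure(list(svm = svm, features = x$features), class = "match_classifier")
}

#' Pipeline run configuration
#'
#' One JSON-serializable config drives every stage; it is hashed into each
#' stage manifest so completed deterministic stages can be skipped on rerun.
#'
#' @param workdir Directory for all stage outputs.
#' @param pubmed_xml Input citation XML (ingest stage).
#' @param preprints_jsonl Input preprint JSON-lines.
#' @param truth_jsonl Optional ground-truth JSON-lines (`{"doi":..,
#'   "pmid":..}` per line; null pmid = unpublished) for classifier training
#'   and evaluation.
#' @param embedding List: `dim`, `sample_fraction`, `seed`, `min_count`.
#' @param rules A [rule_config()] block as a list.
#' @param training List: `n_pos`, `n_neg`, `seed`.
#' @return List of class `run_config`.
#' @export
run_config <- function(workdir, pubmed_xml = NULL, preprints_jsonl = NULL,
                       truth_jsonl = NULL,
                       embedding = list(), rules = list(), training = list()) {
  embedding <- modifyList(list(dim = 300L, sample_fraction = 0.1, seed = 1L,
                               min_count = 5L), embedding)
  training <- modifyList(list(n_pos = 100L, n_neg = 100L, seed = 1L), training)
  structure(list(workdir = workdir, pubmed_xml = pubmed_xml,
                 preprints_jsonl = preprints_jsonl, truth_jsonl = truth_jsonl,
                 embedding = embedding, rules = rules, training = training),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}

manifest_path <- function(config, stage) {
  file.path(config$workdir, paste0("manifest_", gsub("-", "_", stage), ".json"))
}

write_manifest <- function(config, stage, counts, inputs = character()) {
  inputs <- inputs[file.exists(inputs)]
  jsonlite::write_json(list(
    stage = stage, config_hash = config_hash(config),
    inputs = as.list(unname(tools::md5sum(inputs))),
    counts = counts, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  ), manifest_path(config, stage), auto_unbox = TRUE, digits = NA)
}

stage_done <- function(config, stage, inputs = character()) {
  mp <- manifest_path(config, stage)
  if (!file.exists(mp)) return(FALSE)
  m <- jsonlite::read_json(mp, simplifyVector = TRUE)
  identical(m$config_hash, unname(config_hash(config))) &&
    identical(as.character(unlist(m$inputs)),
              as.character(unname(tools::md5sum(inputs[file.exists(inputs)]))))
}

need <- function(path, produced_by) {
  if (is.null(path) || !file.exists(path)) {
    stop("missing prerequisite ", if (is.null(path)) "(unset path)" else path,
         "; run the '", produced_by, "' stage (or set the path) first",
         call. = FALSE)
  }
  path
}

read_truth_jsonl <- function(path) {
  rows <- lapply(readLines(path, encoding = "UTF-8"), jsonlite::fromJSON,
                 simplifyVector = FALSE)
  truth <- vapply(rows, function(r) {
    if (is.null(r$pmid)) NA_character_ else as.character(r$pmid)
  }, character(1L))
  names(truth) <- vapply(rows, function(r) as.character(r$doi), character(1L))
  truth
}

#' Write a ground-truth map as JSON-lines
#'
#' @param truth Named character vector `doi -> pmid` (`NA` = unpublished).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_jsonl <- function(truth, path) {
  lines <- vapply(names(truth), function(doi) {
    jsonlite::toJSON(list(doi = doi, pmid = truth[[doi]]),
                     auto_unbox = TRUE, na = "null")
  }, character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Run the linkage pipeline
#'
#' Executes the requested stages in declared order, each writing its outputs
#' and a manifest (config hash, input checksums, counts) under
#' `config$workdir`. Rerunning a completed stage with an unchanged config
#' and inputs is a logged no-op unless `force = TRUE`. Stage prerequisites
#' are checked up front with an actionable error naming the stage to run
#' first.
#'
#' @param config A [run_config()].
#' @param stages Ordered subset of `c("ingest", "train-embeddings",
#'   "build-index", "train-classifier", "match", "evaluate")`.
#' @param force Rerun stages even when their manifests are current.
#' @param quiet Suppress per-stage progress messages.
#' @return Named list of stage statuses (`"run"` or `"skipped"`), invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("ingest", "train-embeddings", "build-index",
                                    "train-classifier", "match", "evaluate"),
                         force = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("ingest", "train-embeddings", "build-index",
                  "train-classifier", "match", "evaluate")
  unknown <- setdiff(stages, all_stages)
  if (length(unknown) > 0L) {
    stop("unknown stages: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  dir.create(config$workdir, showWarnings = FALSE, recursive = TRUE)
  wd <- function(f) file.path(config$workdir, f)
  say <- function(...) if (!quiet) message("[preplink] ", ...)
  status <- list()

  load_corpus <- function() {
    papers <- read_papers_jsonl(need(wd("papers.jsonl"), "ingest"))
    preprints <- parse_preprints(need(wd("preprints.jsonl"), "ingest"))
    list(papers = papers, preprints = preprints)
  }
  load_models <- function() {
    need(wd("embedding_title.json"), "train-embeddings")
    list(title = load_embeddings(config$workdir, "title"),
         abstract = load_embeddings(config$workdir, "abstract"))
  }
  load_indices <- function() {
    need(wd("index_title.json"), "build-index")
    list(title = read_index(config$workdir, "title"),
         abstract = read_index(config$workdir, "abstract"))
  }

  for (stage in stages) {
    inputs <- switch(stage,
      "ingest" = c(config$pubmed_xml, config$preprints_jsonl),
      "train-embeddings" = wd("papers.jsonl"),
      "build-index" = c(wd("papers.jsonl"), wd("embedding_title.f32"),
                        wd("embedding_abstract.f32")),
      "train-classifier" = c(wd("index_title.f32"), wd("index_abstract.f32"),
                             config$truth_jsonl),
      "match" = c(wd("preprints.jsonl"), wd("classifier.json")),
      "evaluate" = c(wd("matches.jsonl"), config$truth_jsonl))
    if (!force && stage_done(config, stage, inputs)) {
      say(stage, ": up to date, skipping")
      status[[stage]] <- "skipped"
      next
    }
    say(stage, ": running")
    counts <- switch(stage,
      "ingest" = {
        papers <- parse_pubmed_xml(need(config$pubmed_xml, "ingest (input)"))
        kept <- filter_papers(papers)
        write_papers_jsonl(kept, wd("papers.jsonl"))
        preprints <- parse_preprints(need(config$preprints_jsonl, "ingest (input)"))
        file.copy(config$preprints_jsonl, wd("preprints.jsonl"), overwrite = TRUE)
        say(sprintf("  parsed %d papers, kept %d after filters; %d preprints",
                    length(papers), length(kept), length(preprints)))
        list(papers_parsed = length(papers), papers_kept = length(kept),
             preprints = length(preprints))
      },
      "train-embeddings" = {
        papers <- read_papers_jsonl(need(wd("papers.jsonl"), "ingest"))
        emb <- config$embedding
        for (field in c("title", "abstract")) {
          texts <- sample_training_corpus(papers, emb$sample_fraction,
                                          emb$seed, field)
          model <- train_embeddings(texts, field, dim = emb$dim,
                                    seed = emb$seed, min_count = emb$min_count)
          save_embeddings(model, config$workdir)
          say(sprintf("  %s model: %d texts, vocab %d", field, length(texts),
                      length(model$vocab)))
        }
        list(sample_fraction = emb$sample_fraction, dim = emb$dim)
      },
      "build-index" = {
        cp <- load_corpus()
        models <- load_models()
        pmids <- vapply(cp$papers, `[[`, character(1L), "pmid")
        for (field in c("title", "abstract")) {
          vecs <- t(vapply(cp$papers, function(p) {
            as.numeric(sentence_vector(models[[field]], p[[field]]))
          }, numeric(models[[field]]$dim)))
          build_index(vecs, pmids, field, config$workdir)
        }
        list(rows = length(pmids))
      },
      "train-classifier" = {
        cp <- load_corpus()
        models <- load_models()
        indices <- load_indices()
        truth <- read_truth_jsonl(need(config$truth_jsonl, "train-classifier (input)"))
        corpus <- list(preprints = cp$preprints, papers = cp$papers, truth = truth)
        tr <- config$training
        pairs <- labeled_training_pairs(corpus, models, indices,
                                        n_pos = tr$n_pos, n_neg = tr$n_neg,
                                        seed = tr$seed)
        clf <- train_svm(pairs$positives, pairs$negatives)
        save_classifier(clf, wd("classifier.json"))
        list(n_pos = nrow(pairs$positives), n_neg = nrow(pairs$negatives),
             n_sv = nrow(clf$svm$sv_x))
      },
      "match" = {
        cp <- load_corpus()
        models <- load_models()
        indices <- load_indices()
        clf <- load_classifier(need(wd("classifier.json"), "train-classifier"))
        rules <- do.call(rule_config, config$rules)
        res <- match_all(cp$preprints, cp$papers, models, indices, clf, rules)
        lines <- vapply(seq_len(nrow(res)), function(i) {
          jsonlite::toJSON(as.list(res[i, ]), auto_unbox = TRUE, na = "null")
        }, character(1L))
        writeLines(lines, wd("matches.jsonl"), useBytes = TRUE)
        say(sprintf("  matched %d of %d preprints", sum(!is.na(res$pmid)),
                    nrow(res)))
        list(preprints = nrow(res), matched = sum(!is.na(res$pmid)))
      },
      "evaluate" = {
        truth <- read_truth_jsonl(need(config$truth_jsonl, "evaluate (input)"))
        rows <- lapply(readLines(need(wd("matches.jsonl"), "match")),
                       jsonlite::fromJSON, simplifyVector = FALSE)
        preds <- vapply(rows, function(r) {
          if (is.null(r$pmid)) NA_character_ else as.character(r$pmid)
        }, character(1L))
        names(preds) <- vapply(rows, function(r) as.character(r$doi), character(1L))
        labels <- data.frame(
          preprint_doi = names(truth),
          label = ifelse(is.na(truth), "true_negative", "true_positive"),
          truth_pmid = unname(truth), source = "fixture",
          stringsAsFactors = FALSE)
        counts <- confusion_counts(preds[labels$preprint_doi], labels)
        metrics <- precision_recall_f1(counts)
        jsonlite::write_json(list(counts = unclass(counts), metrics = metrics),
                             wd("report.json"), auto_unbox = TRUE, digits = NA)
        say(sprintf("  recall %.2f precision %.2f F1 %.2f",
                    metrics$recall, metrics$precision, metrics$f1))
        c(unclass(counts), metrics)
      })
    write_manifest(config, stage, counts, inputs)
    status[[stage]] <- "run"
  }
  invisible(status)
}
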