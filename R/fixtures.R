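#' Fixture-generator configuration
#'
#' The stated world of the synthetic corpora: `n_pairs` true preprint-paper
#' pairs, `n_decoys` unrelated papers drawn from an overlapping vocabulary
#' (so some decoys are hard negatives), `n_unpublished` preprints with no
#' published version. Revision noise between the preprint and its paper is
#' controlled by a per-token substitution probability (`text_sub_rate`,
#' optionally growing linearly with the simulated publication gap via
#' `gap_noise_slope`, in substitution-probability units per year) and by
#' per-author add/remove/flip probabilities. The publication gap is
#' log-normal with median `gap_median_days` (default 199 days, a typical
#' preprint-to-paper gap) and log-sd `gap_sdlog`.
#'
#' @param n_pairs,n_decoys,n_unpublished Nonnegative counts.
#' @param text_sub_rate Per-token substitution probability in \[0, 1\].
#' @param gap_noise_slope Added substitution probability per year of gap.
#' @param author_add_rate,author_remove_rate,author_flip_rate Per-author
#'   probabilities in \[0, 1\); `author_remove_rate` must be < 1 so a paper
#'   can never lose its whole author list.
#' @param announce_rate Fraction of true pairs whose preprint carries a
#'   server-announced publication id.
#' @param abstract_missing_rate Fraction of decoy papers with no abstract.
#' @param gap_median_days,gap_sdlog Log-normal gap parameters.
#' @param seed Integer seed; the whole corpus is a pure function of the
#'   config.
#' @return List of class `fixture_config`.
#' @export
fixture_config <- function(n_pairs = 200L, n_decoys = 300L, n_unpublished = 100L,
                           text_sub_rate = 0, gap_noise_slope = 0,
                           author_add_rate = 0, author_remove_rate = 0,
                           author_flip_rate = 0, announce_rate = 0.57,
                           abstract_missing_rate = 0.02,
                           gap_median_days = 199, gap_sdlog = 0.6, seed = 1L) {
  probs <- c(text_sub_rate, author_add_rate, author_remove_rate,
             author_flip_rate, announce_rate, abstract_missing_rate)
  stopifnot(all(probs >= 0), all(probs <= 1),
            n_pairs >= 0L, n_decoys >= 0L, n_unpublished >= 0L,
            gap_noise_slope >= 0, gap_median_days > 0, gap_sdlog >= 0)
  if (author_remove_rate >= 1) {
    stop("fixture_config: author_remove_rate must be < 1", call. = FALSE)
  }
  structure(list(
    n_pairs = as.integer(n_pairs), n_decoys = as.integer(n_decoys),
    n_unpublished = as.integer(n_unpublished),
    text_sub_rate = text_sub_rate, gap_noise_slope = gap_noise_slope,
    author_add_rate = author_add_rate, author_remove_rate = author_remove_rate,
    author_flip_rate = author_flip_rate, announce_rate = announce_rate,
    abstract_missing_rate = abstract_missing_rate,
    gap_median_days = gap_median_days, gap_sdlog = gap_sdlog,
    seed = as.integer(seed)
  ), class = "fixture_config")
}

# deterministic pseudo-biological word factory: 2-4 syllables
make_words <- function(n, syllables, min_syl = 2L, max_syl = 4L) {
  out <- character(0L)
  while (length(out) < n) {
    k <- sample(min_syl:max_syl, 1L)
    w <- paste(sample(syllables, k, replace = TRUE), collapse = "")
    out <- unique(c(out, w))
  }
  out[seq_len(n)]
}

# a wide consonant-vowel syllable grid: synthetic terms should share few
# character n-grams, as real domain terms mostly do
syllable_grid <- function() {
  cons <- c("b", "c", "d", "f", "g", "h", "j", "k", "l", "m", "n", "p", "qu",
            "r", "s", "t", "v", "w", "x", "z", "br", "ch", "cr", "dr", "fl",
            "gl", "gr", "kl", "pl", "pr", "sk", "sl", "sp", "st", "str", "th",
            "tr", "vr", "zh", "phr")
  vow <- c("a", "e", "i", "o", "u", "y", "ae", "ia", "io", "ou")
  as.vector(outer(cons, vow, paste0))
}

fixture_vocab <- function() {
  syl <- syllable_grid()
  list(
    subjects = make_words(120L, syl),
    methods = make_words(40L, syl),
    organisms = make_words(30L, syl),
    adjectives = make_words(30L, syl),
    common = c("the", "of", "in", "a", "for", "with", "and", "we", "using",
               "analysis", "study", "results", "show", "that", "is", "to",
               "on", "by", "data", "here", "novel", "approach", "find"),
    fore_names = vapply(make_words(60L, syl, 2L, 3L), cap1, character(1L)),
    last_names = vapply(make_words(150L, syl, 2L, 3L), cap1, character(1L))
  )
}

cap1 <- function(w) paste0(toupper(substr(w, 1L, 1L)), substr(w, 2L, nchar(w)))

# one topic: the lexical material a preprint/paper pair (or decoy) is built
# of; `tool` is unique per topic (as real tool names effectively are — the
# colon and abstract-prefix rules rest on that identity signal)
sample_topic <- function(vocab, tool) {
  list(
    subjects = sample(vocab$subjects, 4L),
    method = sample(vocab$methods, 2L),
    organism = sample(vocab$organisms, 1L),
    adj = sample(vocab$adjectives, 2L),
    tool = tool,
    colon_title = runif(1L) < 0.25
  )
}

topic_title <- function(tp, vocab) {
  if (tp$colon_title) {
    paste0(tp$tool, ": a ", tp$adj[1L], " ", tp$method[1L], " method for ",
           tp$subjects[1L], " ", tp$subjects[2L], " in ", tp$organism)
  } else {
    paste(cap1(tp$adj[1L]), tp$method[1L], "analysis of", tp$subjects[1L],
          tp$subjects[2L], "in", tp$organism)
  }
}

topic_abstract <- function(tp, vocab) {
  lead <- paste("We present", tp$tool, "a", tp$adj[1L], "method for",
                tp$subjects[1L], tp$subjects[2L], "in", tp$organism,
                "using", tp$method[1L])
  pool <- c(rep(c(tp$subjects, tp$method, tp$organism, tp$adj), 3L), vocab$common)
  body <- vapply(seq_len(sample(3:5, 1L)), function(i) {
    n <- sample(9:14, 1L)
    s <- sample(pool, n, replace = TRUE)
    paste0(cap1(paste(s, collapse = " ")), ".")
  }, character(1L))
  paste(c(paste0(lead, "."), body), collapse = " ")
}

sample_authors <- function(vocab) {
  # mostly small teams, occasional large consortium-style lists (> 10)
  n <- sample(c(2:9, 11:14), 1L, prob = c(rep(0.115, 8L), rep(0.02, 4L)))
  lapply(seq_len(n), function(i) {
    author_name(sample(vocab$fore_names, 1L), sample(vocab$last_names, 1L))
  })
}

substitute_tokens <- function(text, rate, pool) {
  if (rate <= 0) return(text)
  tok <- strsplit(text, " ", fixed = TRUE)[[1L]]
  hit <- runif(length(tok)) < rate
  tok[hit] <- sample(pool, sum(hit), replace = TRUE)
  paste(tok, collapse = " ")
}

revise_authors <- function(authors, config) {
  keep <- runif(length(authors)) >= config$author_remove_rate
  if (!any(keep)) keep[1L] <- TRUE  # a paper always retains an author
  authors <- authors[keep]
  authors <- lapply(authors, function(a) {
    if (!is.null(a$fore) && runif(1L) < config$author_flip_rate) {
      author_name(a$last, a$fore)  # swapped name fields
    } else {
      a
    }
  })
  n_add <- rbinom(1L, 2L, config$author_add_rate)
  if (n_add > 0L) {
    vocab <- fixture_vocab_cache()
    authors <- c(authors, lapply(seq_len(n_add), function(i) {
      author_name(sample(vocab$fore_names, 1L), sample(vocab$last_names, 1L))
    }))
  }
  authors
}

# the word factory is itself random; build it once per generate_corpus under
# the corpus seed and stash it for revise_authors
.fixture_env <- new.env(parent = emptyenv())
fixture_vocab_cache <- function() get("vocab", envir = .fixture_env)

#' Generate a labeled synthetic corpus
#'
#' Builds preprints, published papers and the ground-truth linkage map from
#' a [fixture_config()]. Each true pair shares a topic template; the paper
#' version applies per-token substitution (optionally scaled with the
#' simulated gap) and author edits including fore/last flips. Decoys draw
#' from the same word pools, creating hard negatives. The output is a pure
#' function of the config (byte-identical across runs).
#'
#' @param config A [fixture_config()].
#' @return List with `preprints` (list of [preprint_record()]), `papers`
#'   (list of [paper_record()]), `truth` (named character vector
#'   `doi -> pmid`, `NA` for unpublished preprints), and `config`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  with_seed(config$seed, {
    vocab <- fixture_vocab()
    assign("vocab", vocab, envir = .fixture_env)
    sub_pool <- c(vocab$subjects, vocab$methods, vocab$organisms,
                  vocab$adjectives, vocab$common)
    n_papers <- config$n_pairs + config$n_decoys
    pmids <- sprintf("%07d", sample.int(9000000L, n_papers) + 999999L)
    base_date <- as.Date("2018-01-01")
    # one distinct tool name per topic
    n_topics <- config$n_pairs + config$n_decoys + config$n_unpublished
    tools <- vapply(make_words(max(n_topics, 1L), syllable_grid(), 2L, 3L),
                    cap1, character(1L))

    preprints <- list()
    papers <- list()
    truth <- character(0L)

    for (i in seq_len(config$n_pairs)) {
      tp <- sample_topic(vocab, tools[i])
      title <- topic_title(tp, vocab)
      abstract <- topic_abstract(tp, vocab)
      authors <- sample_authors(vocab)
      posted <- base_date + sample.int(1095L, 1L)
      gap <- max(1L, round(rlnorm(1L, log(config$gap_median_days), config$gap_sdlog)))
      rate <- min(1, config$text_sub_rate + config$gap_noise_slope * gap / 365)
      doi <- sprintf("10.1101/syn.%06d", i)
      pmid <- pmids[i]
      announced <- runif(1L) < config$announce_rate

      preprints[[length(preprints) + 1L]] <- preprint_record(
        doi = doi, title = title, abstract = abstract, posted_date = posted,
        authors = authors,
        announced_pub_id = if (announced) pmid else NA_character_)
      papers[[length(papers) + 1L]] <- paper_record(
        pmid = pmid, doi = sprintf("10.1000/j.%06d", i),
        title = substitute_tokens(title, rate, sub_pool),
        abstract = substitute_tokens(abstract, rate, sub_pool),
        pub_date = posted + gap, authors = revise_authors(authors, config),
        languages = "eng", pub_types = "Journal Article")
      truth[doi] <- pmid
    }

    for (i in seq_len(config$n_decoys)) {
      tp <- sample_topic(vocab, tools[config$n_pairs + i])
      papers[[length(papers) + 1L]] <- paper_record(
        pmid = pmids[config$n_pairs + i],
        doi = sprintf("10.1000/d.%06d", i),
        title = topic_title(tp, vocab),
        abstract = if (runif(1L) < config$abstract_missing_rate) {
          NA_character_
        } else {
          topic_abstract(tp, vocab)
        },
        pub_date = base_date + sample.int(1460L, 1L),
        authors = sample_authors(vocab),
        languages = "eng", pub_types = "Journal Article")
    }

    for (i in seq_len(config$n_unpublished)) {
      tp <- sample_topic(vocab, tools[config$n_pairs + config$n_decoys + i])
      doi <- sprintf("10.1101/unp.%06d", i)
      preprints[[length(preprints) + 1L]] <- preprint_record(
        doi = doi, title = topic_title(tp, vocab),
        abstract = topic_abstract(tp, vocab),
        posted_date = base_date + sample.int(1095L, 1L),
        authors = sample_authors(vocab))
      truth[doi] <- NA_character_
    }

    list(preprints = preprints, papers = papers, truth = truth, config = config)
  })
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write papers as MEDLINE/PubMed-dialect citation XML
#'
#' Emits citation XML that [parse_pubmed_xml()] reads back to equal records
#' (the round-trip oracle for the ingest module). Language and
#' publication-type fields are included so the paper filters are
#' exercisable.
#'
#' @param papers List of [paper_record()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pubmed_xml <- function(papers, path) {
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>", "<PubmedArticleSet>")
  for (p in papers) {
    d <- as.POSIXlt(p$pub_date)
    author_xml <- vapply(p$authors, function(a) {
      paste0("      <Author><LastName>", xml_escape(a$last), "</LastName>",
             if (!is.null(a$fore)) {
               paste0("<ForeName>", xml_escape(a$fore), "</ForeName>")
             },
             "</Author>")
    }, character(1L))
    lines <- c(
      lines,
      "<PubmedArticle>",
      " <MedlineCitation>",
      paste0("  <PMID>", xml_escape(p$pmid), "</PMID>"),
      "  <Article>",
      "   <Journal><JournalIssue><PubDate>",
      sprintf("    <Year>%d</Year><Month>%s</Month><Day>%d</Day>",
              d$year + 1900L, month.abb[d$mon + 1L], d$mday),
      "   </PubDate></JournalIssue></Journal>",
      paste0("   <ArticleTitle>", xml_escape(p$title), "</ArticleTitle>"),
      if (!is.na(p$abstract)) {
        paste0("   <Abstract><AbstractText>", xml_escape(p$abstract),
               "</AbstractText></Abstract>")
      },
      if (length(p$authors) > 0L) c("   <AuthorList>", author_xml, "   </AuthorList>"),
      vapply(p$languages, function(l) {
        paste0("   <Language>", xml_escape(l), "</Language>")
      }, character(1L)),
      if (length(p$pub_types) > 0L) c(
        "   <PublicationTypeList>",
        vapply(p$pub_types, function(t) {
          paste0("    <PublicationType>", xml_escape(t), "</PublicationType>")
        }, character(1L)),
        "   </PublicationTypeList>"),
      "  </Article>",
      " </MedlineCitation>",
      " <PubmedData><ArticleIdList>",
      if (!is.na(p$doi)) {
        paste0("  <ArticleId IdType=\"doi\">", xml_escape(p$doi), "</ArticleId>")
      },
      " </ArticleIdList></PubmedData>",
      "</PubmedArticle>")
  }
  lines <- c(lines, "</PubmedArticleSet>")
  writeLines(lines[!vapply(lines, is.null, logical(1L))], path, useBytes = TRUE)
  invisible(path)
}

# features of one known preprint-paper pair, via the same indices the
# matcher uses
pair_features <- function(preprint, pmid, models, indices, corpus) {
  tq <- sentence_vector(models$title, preprint$title)
  aq <- sentence_vector(models$abstract, preprint$abstract)
  tpos <- match(pmid, indices$title$ids)
  apos <- match(pmid, indices$abstract$ids)
  data.frame(
    doi = preprint$doi, pmid = pmid,
    title_sim = as.numeric(index_rows(indices$title, tpos) %*% tq),
    abstract_sim = as.numeric(index_rows(indices$abstract, apos) %*% aq),
    author_sim = author_score(preprint$authors, corpus[[pmid]]$authors)$score,
    stringsAsFactors = FALSE)
}

#' Build labeled training pairs from a synthetic corpus
#'
#' Positives are sampled from the ground-truth pairs; negatives come from
#' [mine_hard_negatives()] with truth-matching pairs removed automatically —
#' the fixture truth stands in for the manual curation step of the original
#' protocol, which inspected each mined pair by hand.
#'
#' @param corpus Output of [generate_corpus()].
#' @param models,indices Trained embedding models and built indices over
#'   `corpus$papers`.
#' @param n_pos,n_neg Pair counts (canonically 100 and 100).
#' @param seed Sampling seed.
#' @return List with `positives` and `negatives` data frames (doi, pmid and
#'   the three features).
#' @export
labeled_training_pairs <- function(corpus, models, indices, n_pos = 100L,
                                   n_neg = 100L, seed = 1L) {
  papers <- corpus_by_pmid(corpus$papers)
  truth <- corpus$truth
  pos_dois <- names(truth)[!is.na(truth)]
  if (length(pos_dois) < n_pos) {
    stop("labeled_training_pairs: only ", length(pos_dois),
         " true pairs available, need ", n_pos, call. = FALSE)
  }
  pre_by_doi <- corpus$preprints
  names(pre_by_doi) <- vapply(pre_by_doi, `[[`, character(1L), "doi")

  picked <- with_seed(seed, sample(pos_dois, n_pos))
  positives <- do.call(rbind, lapply(picked, function(doi) {
    pair_features(pre_by_doi[[doi]], truth[[doi]], models, indices, papers)
  }))

  mined <- mine_hard_negatives(corpus$preprints, models, indices, papers,
                               seed = seed + 1L)
  mined_truth <- truth[mined$preprint_doi]
  mined <- mined[is.na(mined_truth) | mined_truth != mined$pmid, , drop = FALSE]
  if (nrow(mined) < n_neg) {
    stop("labeled_training_pairs: only ", nrow(mined),
         " hard negatives after truth filtering, need ", n_neg, call. = FALSE)
  }
  negatives <- with_seed(seed + 2L, mined[sample.int(nrow(mined), n_neg), , drop = FALSE])
  names(negatives)[names(negatives) == "preprint_doi"] <- "doi"
  rownames(negatives) <- NULL
  list(positives = positives,
       negatives = negatives[, c("doi", "pmid", "title_sim", "abstract_sim",
                                 "author_sim")])
}
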