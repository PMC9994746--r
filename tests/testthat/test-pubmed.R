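fixture_xml <- function() {
  paste0('<?xml version="1.0" encoding="UTF-8"?>
<PubmedArticleSet>
<PubmedArticle>
 <MedlineCitation><PMID>100</PMID>
  <Article>
   <Journal><JournalIssue><PubDate><Year>2020</Year><Month>Mar</Month><Day>15</Day></PubDate></JournalIssue></Journal>
   <ArticleTitle>Genome assembly of a model organism</ArticleTitle>
   <Abstract><AbstractText>We assembled a genome.</AbstractText></Abstract>
   <AuthorList>
    <Author><LastName>Lovelace</LastName><ForeName>Ada</ForeName></Author>
    <Author><LastName>Curie</LastName></Author>
   </AuthorList>
   <Language>eng</Language>
   <PublicationTypeList><PublicationType>Journal Article</PublicationType></PublicationTypeList>
  </Article>
 </MedlineCitation>
 <PubmedData><ArticleIdList><ArticleId IdType="doi">10.1000/x1</ArticleId></ArticleIdList></PubmedData>
</PubmedArticle>
<PubmedArticle>
 <MedlineCitation><PMID>101</PMID>
  <Article>
   <Journal><JournalIssue><PubDate><MedlineDate>2019 Mar</MedlineDate></PubDate></JournalIssue></Journal>
   <ArticleTitle>A title with no abstract</ArticleTitle>
   <Language>eng</Language>
  </Article>
 </MedlineCitation>
</PubmedArticle>
<PubmedArticle>
 <MedlineCitation><PMID>102</PMID>
  <Article>
   <Journal><JournalIssue><PubDate><Year>2018</Year></PubDate></JournalIssue></Journal>
   <ArticleTitle>Une etude en francais</ArticleTitle>
   <Abstract><AbstractText>Resume.</AbstractText></Abstract>
   <Language>fre</Language>
  </Article>
 </MedlineCitation>
</PubmedArticle>
</PubmedArticleSet>')
}

test_that("parse_pubmed_xml extracts fields and passes absent ones through", {
  recs <- parse_pubmed_xml(fixture_xml())
  expect_length(recs, 3L)
  expect_equal(vapply(recs, `[[`, "", "pmid"), c("100", "101", "102"))

  r <- recs[[1L]]
  expect_equal(r$doi, "10.1000/x1")
  expect_equal(r$title, "Genome assembly of a model organism")
  expect_equal(r$abstract, "We assembled a genome.")
  expect_equal(r$pub_date, as.Date("2020-03-15"))
  expect_equal(vapply(r$authors, author_display, ""), c("Ada Lovelace", "Curie"))
  expect_equal(r$languages, "eng")

  # missing optionals are NA, never ""
  expect_true(is.na(recs[[2L]]$abstract))
  expect_true(is.na(recs[[2L]]$doi))
  # MedlineDate "2019 Mar" canonicalizes with day defaulted
  expect_equal(recs[[2L]]$pub_date, as.Date("2019-03-01"))
})

test_that("citations without a PMID are skipped with a warning", {
  xml <- '<PubmedArticleSet><PubmedArticle><MedlineCitation>
    <Article><ArticleTitle>No id here</ArticleTitle></Article>
    </MedlineCitation></PubmedArticle></PubmedArticleSet>'
  expect_warning(recs <- parse_pubmed_xml(xml), "PMID")
  expect_length(recs, 0L)
})

test_that("malformed XML is a hard error", {
  expect_error(parse_pubmed_xml("<PubmedArticleSet><unclosed"), "malformed")
})

test_that("canonicalize_pubdate applies the month/day default rules", {
  expect_equal(canonicalize_pubdate("2020 Mar 15"), as.Date("2020-03-15"))
  expect_equal(canonicalize_pubdate("2019 Mar"), as.Date("2019-03-01"))
  expect_equal(canonicalize_pubdate("2018"), as.Date("2018-01-01"))
  expect_equal(canonicalize_pubdate("2020 3 15"), as.Date("2020-03-15"))
  expect_equal(canonicalize_pubdate("2020-03-15"), as.Date("2020-03-15"))
  # seasons map to the season's first month
  expect_equal(canonicalize_pubdate("2019 Spring"), as.Date("2019-03-01"))
  expect_equal(canonicalize_pubdate("2019 Winter"), as.Date("2019-12-01"))
  expect_error(canonicalize_pubdate("March fifteen"), "year")
})

test_that("canonicalize_pubdate is total on the fixture grammar and year-stable", {
  months <- c(month.abb, month.name, 1:12)
  for (m in sample(months, 8L)) {
    d <- canonicalize_pubdate(paste("2017", m))
    expect_s3_class(d, "Date")
    expect_equal(format(d, "%Y"), "2017")
  }
  for (season in c("Spring", "Summer", "Fall", "Autumn", "Winter")) {
    expect_equal(format(canonicalize_pubdate(paste("2001", season)), "%Y"), "2001")
  }
})

make_rec <- function(pmid, lang = "eng", types = "Journal Article",
                     title = "a title") {
  paper_record(pmid = pmid, title = title, pub_date = as.Date("2020-01-01"),
               languages = lang, pub_types = types)
}

test_that("filter_papers applies the language and type exclusions", {
  recs <- c(
    lapply(1:7, function(i) make_rec(as.character(i))),
    list(make_rec("8", lang = "fre"),
         make_rec("9", types = c("Journal Article", "Review")),
         make_rec("10", types = "Comment"))
  )
  kept <- filter_papers(recs)
  expect_length(kept, 7L)
  expect_equal(vapply(kept, `[[`, "", "pmid"), as.character(1:7))
  # idempotent
  expect_identical(filter_papers(kept), kept)
  # multi-language records containing eng are retained
  expect_length(filter_papers(list(make_rec("11", lang = c("eng", "fre")))), 1L)
  # each excluded type vetoes on its own
  for (tp in c("Comment", "Published Erratum", "Review", "Preprint")) {
    expect_length(filter_papers(list(make_rec("12", types = tp))), 0L)
  }
  # records without a title cannot be embedded and are dropped
  expect_length(filter_papers(list(make_rec("13", title = NA))), 0L)
})

test_that("author_display follows the fore/last format rule", {
  expect_equal(author_display(author_name("Ada", "Lovelace")), "Ada Lovelace")
  expect_equal(author_display(author_name(NULL, "Lovelace")), "Lovelace")
  expect_equal(author_display(author_name("", "X")), "X")
  expect_error(author_name("Ada", ""), "non-empty")
})

test_that("writer/reader round-trip preserves all matched-on fields", {
  corpus <- generate_corpus(fixture_config(n_pairs = 20L, n_decoys = 30L,
                                           n_unpublished = 0L, seed = 9L))
  papers <- corpus$papers
  path <- withr::local_tempfile(fileext = ".xml")
  write_pubmed_xml(papers, path)
  back <- parse_pubmed_xml(path)
  expect_length(back, length(papers))
  for (i in seq_along(papers)) {
    for (f in c("pmid", "doi", "title", "abstract", "languages", "pub_types")) {
      expect_identical(back[[i]][[f]], papers[[i]][[f]], label = paste(f, i))
    }
    expect_equal(back[[i]]$pub_date, papers[[i]]$pub_date)
    expect_identical(vapply(back[[i]]$authors, author_display, ""),
                     vapply(papers[[i]]$authors, author_display, ""))
  }
})
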