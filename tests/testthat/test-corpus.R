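test_that("retrieval expression carries all clauses and is constant", {
  q <- build_query()
  expect_true(grepl('“centenarian” [Title/Abstract]', q,
                    fixed = TRUE))
  n_terms <- lengths(regmatches(q, gregexpr("[Title/Abstract]", q,
                                            fixed = TRUE)))
  expect_identical(n_terms, 14L)
  expect_true(grepl("Journal Article", q, fixed = TRUE))
  expect_true(grepl("MeSH Terms", q, fixed = TRUE))
  expect_true(grepl("English", q, fixed = TRUE))
  expect_identical(q, build_query())
})

test_that("medline-json records round in with absent fields kept absent", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    list(pmid = "101", title = "A", abstract = "Aging is universal.",
         journal_title = "J1", authors = list("Doe J"),
         pub_types = list("Journal Article")),
    list(pmid = "102", title = "B"),
    list(pmid = "103", title = "C", abstract = "",
         impact_factor = 4.2)
  ), f, auto_unbox = TRUE)
  corpus <- read_literature(f, "medline-json")
  expect_identical(nrow(corpus), 3L)
  expect_identical(corpus$pmid, c("101", "102", "103"))
  expect_identical(corpus$abstract[2], "")   # retained, empty
  expect_true(is.na(corpus$impact_factor[1]))
  expect_identical(corpus$impact_factor[3], 4.2)
  expect_identical(corpus$authors[[1]], "Doe J")
})

test_that("duplicate PMIDs and malformed files are rejected", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(list(pmid = "7", title = "x"),
                            list(pmid = "7", title = "y")),
                       f, auto_unbox = TRUE)
  expect_error(read_literature(f, "medline-json"), "duplicate PMID")
  g <- tempfile(fileext = ".json")
  writeLines("{not json", g)
  expect_error(read_literature(g, "medline-json"), "malformed")
})

test_that("tagged-field dialect parses with continuation lines", {
  f <- tempfile(fileext = ".txt")
  writeLines(c(
    "PMID- 201",
    "TI  - A study of aging",
    "AB  - First half of the abstract",
    "      continues on a second line.",
    "JT  - Journal of Gerontology",
    "TA  - J Gerontol",
    "AU  - Doe J",
    "AU  - Roe R",
    "DP  - 2019 Mar",
    "",
    "PMID- 202",
    "TI  - No abstract here"
  ), f)
  corpus <- read_literature(f, "tagged-field")
  expect_identical(nrow(corpus), 2L)
  expect_identical(corpus$abstract[1],
                   "First half of the abstract continues on a second line.")
  expect_identical(corpus$authors[[1]], c("Doe J", "Roe R"))
  expect_identical(corpus$journal_abbrev[1], "J Gerontol")
  expect_identical(corpus$abstract[2], "")
})

test_that("corpus filter keeps human records with abstracts, preserving order", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    list(pmid = "1", abstract = "Human aging study."),
    list(pmid = "2"),                               # no abstract
    list(pmid = "3", abstract = "Mouse lifespan.")  # mouse-only species
  ), f, auto_unbox = TRUE)
  corpus <- read_literature(f, "medline-json")
  species <- data.frame(pmid = c("1", "2", "3"),
                        taxon_id = c("9606", "9606", "10090"),
                        stringsAsFactors = FALSE)
  kept <- filter_corpus(corpus, species)
  expect_identical(kept$pmid, "1")

  expect_identical(nrow(filter_corpus(corpus[0, ], species)), 0L)
  # all-human identity and idempotence
  species_all <- data.frame(pmid = corpus$pmid, taxon_id = "9606",
                            stringsAsFactors = FALSE)
  corpus$abstract[corpus$abstract == ""] <- "filled."
  ident <- filter_corpus(corpus, species_all)
  expect_identical(ident$pmid, corpus$pmid)
  expect_identical(filter_corpus(kept, species), kept)
  expect_true(all(kept$pmid %in% corpus$pmid))
})

test_that("sentence segmentation is offset-faithful and abbreviation-aware", {
  rec <- list(pmid = "9", abstract = "Aging is universal. Longevity is rare.")
  s <- segment_sentences(rec)
  expect_identical(nrow(s), 2L)
  expect_identical(s$text, c("Aging is universal.", "Longevity is rare."))
  # text equals the abstract slice
  for (i in seq_len(nrow(s)))
    expect_identical(substr(rec$abstract, s$char_start[i] + 1, s$char_end[i]),
                     s$text[i])

  expect_identical(nrow(segment_sentences(list(pmid = "9", abstract = ""))),
                   0L)

  v <- segment_sentences(list(pmid = "9",
                              abstract = "IL-6 rose vs. controls. CRP did not."))
  expect_identical(nrow(v), 2L)
  expect_identical(v$text[1], "IL-6 rose vs. controls.")
})

test_that("sentence slices reconstruct the abstract up to whitespace", {
  g <- generate_corpus(synth_config(n_abstracts = 8, seed = 3))
  for (i in seq_len(nrow(g$corpus))) {
    rec <- g$corpus[i, , drop = FALSE]
    s <- segment_sentences(rec)
    expect_gt(nrow(s), 0)
    expect_true(all(diff(s$char_start) > 0))
    expect_true(all(s$char_start < s$char_end))
    expect_true(all(utils::head(s$char_end, -1) <= s$char_start[-1]))
    glued <- paste(s$text, collapse = "")
    expect_identical(gsub("\\s", "", glued), gsub("\\s", "", rec$abstract))
  }
})

test_that("all-caps headings are stripped, mixed-case prefixes kept", {
  s <- rbind(mk_sentence("CONCLUSION: SIRT1 extends lifespan."),
             mk_sentence("SIRT1 extends lifespan.", index = 1L),
             mk_sentence("Aging: a process", index = 2L))
  out <- strip_heading(s)
  expect_identical(out$text[1], "SIRT1 extends lifespan.")
  expect_identical(out$char_start[1], 12L)
  expect_identical(out$text[2], "SIRT1 extends lifespan.")
  expect_identical(out$text[3], "Aging: a process")
  # idempotence
  expect_identical(strip_heading(out), out)
})
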