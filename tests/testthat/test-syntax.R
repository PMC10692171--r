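# hand-built parses in old-Stanford-style dependencies with Penn XPOS

parse_active <- function() mk_parse(list(
  list(1L, "SIRT1", "SIRT1", "NOUN", "NN", 2L, "nsubj"),
  list(2L, "activates", "activate", "VERB", "VBZ", 0L, "root"),
  list(3L, "FOXO3", "FOXO3", "NOUN", "NN", 2L, "dobj"),
  list(4L, ".", ".", "PUNCT", ".", 2L, "punct")))

parse_passive <- function() mk_parse(list(
  list(1L, "FOXO3", "FOXO3", "NOUN", "NN", 3L, "nsubjpass"),
  list(2L, "is", "be", "AUX", "VBZ", 3L, "auxpass"),
  list(3L, "activated", "activate", "VERB", "VBN", 0L, "root"),
  list(4L, "by", "by", "ADP", "IN", 3L, "prep"),
  list(5L, "SIRT1", "SIRT1", "NOUN", "NN", 4L, "pobj"),
  list(6L, ".", ".", "PUNCT", ".", 3L, "punct")))

parse_perfect <- function() mk_parse(list(
  list(1L, "CRP", "CRP", "NOUN", "NN", 3L, "nsubj"),
  list(2L, "has", "have", "AUX", "VBZ", 3L, "aux"),
  list(3L, "increased", "increase", "VERB", "VBN", 0L, "root"),
  list(4L, ".", ".", "PUNCT", ".", 3L, "punct")))

parse_negated <- function() mk_parse(list(
  list(1L, "Metformin", "metformin", "NOUN", "NN", 4L, "nsubj"),
  list(2L, "does", "do", "AUX", "VBZ", 4L, "aux"),
  list(3L, "not", "not", "PART", "RB", 4L, "advmod"),
  list(4L, "prevent", "prevent", "VERB", "VB", 0L, "root"),
  list(5L, "aging", "aging", "NOUN", "NN", 4L, "dobj"),
  list(6L, ".", ".", "PUNCT", ".", 4L, "punct")))

test_that("CoNLL-U files round-trip and invalid trees are rejected", {
  g <- generate_corpus(synth_config(n_abstracts = 2, seed = 13))
  f <- tempfile(fileext = ".conllu")
  write_conllu(g$parses, f)
  back <- read_conllu(f)
  expect_identical(length(back), length(g$parses))
  for (k in names(g$parses)) {
    expect_identical(back[[k]]$tokens, g$parses[[k]]$tokens)
    expect_identical(back[[k]]$text, g$parses[[k]]$text)
  }

  bad <- tempfile(fileext = ".conllu")
  writeLines(c("# sent_id = x",
               paste("1", "a", "a", "NOUN", "NN", "_", "1", "dep", "_", "_",
                     sep = "\t")), bad)
  expect_error(read_conllu(bad), "own head")

  tworoots <- tempfile(fileext = ".conllu")
  writeLines(c(paste("1", "a", "a", "NOUN", "NN", "_", "0", "root", "_", "_",
                     sep = "\t"),
               paste("2", "b", "b", "NOUN", "NN", "_", "0", "root", "_", "_",
                     sep = "\t")), tworoots)
  expect_error(read_conllu(tworoots), "one root")
})

test_that("finite verb tags are active and lemmatized", {
  va <- determine_voice(parse_active(), 2L)
  expect_identical(va$voice, "active")
  expect_identical(va$normalized_form, "activate")
  expect_error(determine_voice(parse_active(), 1L), "not a verb")
})

test_that("VBN is passive under a be-auxiliary, active under perfect have", {
  vp <- determine_voice(parse_passive(), 3L)
  expect_identical(vp$voice, "passive")
  expect_identical(vp$normalized_form, "activated")

  vh <- determine_voice(parse_perfect(), 3L)
  expect_identical(vh$voice, "active")
  expect_identical(vh$normalized_form, "increase")
})

test_that("a participle modifying a nominal is passive (reduced relative)", {
  p <- mk_parse(list(
    list(1L, "genes", "gene", "NOUN", "NNS", 0L, "root"),
    list(2L, "regulated", "regulate", "VERB", "VBN", 1L, "acl"),
    list(3L, "by", "by", "ADP", "IN", 2L, "prep"),
    list(4L, "SIRT1", "SIRT1", "NOUN", "NN", 3L, "pobj")),
    text = "genes regulated by SIRT1")
  v <- determine_voice(p, 2L)
  expect_identical(v$voice, "passive")
  expect_identical(v$normalized_form, "regulated")
})

test_that("passive is only ever assigned to VBN tokens", {
  g <- generate_corpus(synth_config(n_abstracts = 15, seed = 17))
  for (p in g$parses) {
    verbs <- p$tokens$id[p$tokens$xpos %in%
                           c("VB", "VBD", "VBG", "VBN", "VBP", "VBZ")]
    for (v in verbs) {
      res <- determine_voice(p, v)
      if (res$voice == "passive")
        expect_identical(p$tokens$xpos[p$tokens$id == v], "VBN")
    }
  }
})

test_that("negation is detected for governed adverbial negators", {
  expect_true(detect_negation(parse_negated(), 4L))
  # same sentence without the negator
  pos <- mk_parse(list(
    list(1L, "Metformin", "metformin", "NOUN", "NN", 2L, "nsubj"),
    list(2L, "prevents", "prevent", "VERB", "VBZ", 0L, "root"),
    list(3L, "aging", "aging", "NOUN", "NN", 2L, "dobj"),
    list(4L, ".", ".", "PUNCT", ".", 2L, "punct")))
  expect_false(detect_negation(pos, 2L))

  inv <- mk_parse(list(
    list(1L, "Rarely", "rarely", "ADV", "RB", 4L, "advmod"),
    list(2L, "does", "do", "AUX", "VBZ", 4L, "aux"),
    list(3L, "exercise", "exercise", "NOUN", "NN", 4L, "nsubj"),
    list(4L, "harm", "harm", "VERB", "VB", 0L, "root"),
    list(5L, "patients", "patient", "NOUN", "NNS", 4L, "dobj"),
    list(6L, ".", ".", "PUNCT", ".", 4L, "punct")))
  expect_true(detect_negation(inv, 4L))
})

test_that("every configured negator is recognized when verb-governed", {
  for (w in negation_words()) {
    p <- mk_parse(list(
      list(1L, "SIRT1", "SIRT1", "NOUN", "NN", 3L, "nsubj"),
      list(2L, w, w, "ADV", "RB", 3L, "advmod"),
      list(3L, "prevents", "prevent", "VERB", "VBZ", 0L, "root"),
      list(4L, "aging", "aging", "NOUN", "NN", 3L, "dobj"),
      list(5L, ".", ".", "PUNCT", ".", 3L, "punct")))
    expect_true(detect_negation(p, 3L))
    # a non-adverbial homograph must not trigger ("few" as adjective)
    q <- mk_parse(list(
      list(1L, "SIRT1", "SIRT1", "NOUN", "NN", 3L, "nsubj"),
      list(2L, w, w, "ADJ", "JJ", 3L, "amod"),
      list(3L, "prevents", "prevent", "VERB", "VBZ", 0L, "root"),
      list(4L, "aging", "aging", "NOUN", "NN", 3L, "dobj"),
      list(5L, ".", ".", "PUNCT", ".", 3L, "punct")))
    expect_false(detect_negation(q, 3L))
  }
})

test_that("two read paths of the same CoNLL-U yield identical verb analyses", {
  g <- generate_corpus(synth_config(n_abstracts = 4, seed = 29))
  f <- tempfile(fileext = ".conllu")
  write_conllu(g$parses, f)
  a <- read_conllu(f)
  f2 <- tempfile(fileext = ".conllu")
  writeLines(readLines(f), f2)   # byte-identical second source
  b <- read_conllu(f2)
  for (k in names(a)) {
    verbs <- a[[k]]$tokens$id[a[[k]]$tokens$xpos %in%
                                c("VB", "VBD", "VBG", "VBN", "VBP", "VBZ")]
    for (v in verbs)
      expect_identical(determine_voice(a[[k]], v),
                       determine_voice(b[[k]], v))
  }
})
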