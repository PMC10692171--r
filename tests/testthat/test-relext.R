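test_that("candidate pairs exclude self-relations", {
  m3 <- rbind(mk_mention("A", "gene", 0L, 1L),
              mk_mention("B", "disease", 3L, 4L),
              mk_mention("C", "gene", 6L, 7L))
  expect_length(candidate_pairs(m3), 3L)
  expect_length(candidate_pairs(m3[1, , drop = FALSE]), 0L)
  dup <- rbind(mk_mention("A", "gene", 0L, 1L),
               mk_mention("A", "gene", 6L, 7L))
  expect_length(candidate_pairs(dup), 0L)
})

test_that("the verb on the path is selected; no verb means no relation", {
  chain <- mk_parse(list(
    list(1L, "SIRT1", "SIRT1", "NOUN", "NN", 3L, "nsubj"),
    list(2L, "strongly", "strongly", "ADV", "RB", 3L, "advmod"),
    list(3L, "activates", "activate", "VERB", "VBZ", 0L, "root"),
    list(4L, "nuclear", "nuclear", "ADJ", "JJ", 5L, "amod"),
    list(5L, "FOXO3", "FOXO3", "NOUN", "NN", 3L, "dobj")),
    text = "SIRT1 strongly activates nuclear FOXO3")
  expect_identical(select_main_verb(chain, 1L, 5L), 3L)

  noverb <- mk_parse(list(
    list(1L, "SIRT1", "SIRT1", "NOUN", "NN", 3L, "nsubj"),
    list(2L, "and", "and", "CCONJ", "CC", 3L, "cc"),
    list(3L, "FOXO3", "FOXO3", "NOUN", "NN", 0L, "root")),
    text = "SIRT1 and FOXO3")
  expect_true(is.na(select_main_verb(noverb, 1L, 3L)))
})

test_that("equidistant verbs break ties toward the smaller token index", {
  p <- mk_parse(list(
    list(1L, "X", "X", "NOUN", "NN", 2L, "nsubj"),
    list(2L, "seems", "seem", "VERB", "VBZ", 0L, "root"),
    list(3L, "to", "to", "PART", "TO", 4L, "mark"),
    list(4L, "inhibit", "inhibit", "VERB", "VB", 2L, "xcomp"),
    list(5L, "Y", "Y", "NOUN", "NN", 4L, "dobj")),
    text = "X seems to inhibit Y")
  # both verbs lie on the 1-2-4-5 path with equal summed distance
  expect_identical(select_main_verb(p, 1L, 5L), 2L)
})

test_that("shortest-path selection equals exhaustive path enumeration", {
  g <- generate_corpus(synth_config(n_abstracts = 25, seed = 31))
  lex <- build_fixture_lexicon()
  res <- run_pipeline(g$corpus, g$species, g$parses, lex)
  m <- res$mentions
  checked <- 0L
  for (k in names(g$parses)) {
    p <- g$parses[[k]]
    if (nrow(p$tokens) > 12) next
    mm <- m[paste0(m$pmid, ":", m$sentence_index) == k, , drop = FALSE]
    spans <- gerolit:::.token_spans(p)
    heads <- vapply(seq_len(nrow(mm)), function(i)
      gerolit:::.mention_head_token(spans, mm$start[i], mm$end[i]),
      integer(1))
    for (pr in candidate_pairs(mm)) {
      a <- heads[pr[1]]; b <- heads[pr[2]]
      expect_identical(select_main_verb(p, a, b),
                       bf_select_main_verb(p, a, b))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 50L)
})

test_that("relation phrases grow over particles, complements and prepositions", {
  leads <- mk_parse(list(
    list(1L, "Obesity", "obesity", "NOUN", "NN", 2L, "nsubj"),
    list(2L, "leads", "lead", "VERB", "VBZ", 0L, "root"),
    list(3L, "to", "to", "ADP", "IN", 2L, "prep"),
    list(4L, "diabetes", "diabetes", "NOUN", "NN", 3L, "pobj")),
    text = "Obesity leads to diabetes")
  expect_identical(expand_relation_phrase(leads, 2L), "lead to")

  bare <- mk_parse(list(
    list(1L, "SIRT1", "SIRT1", "NOUN", "NN", 2L, "nsubj"),
    list(2L, "activates", "activate", "VERB", "VBZ", 0L, "root"),
    list(3L, "FOXO3", "FOXO3", "NOUN", "NN", 2L, "dobj")),
    text = "SIRT1 activates FOXO3")
  expect_identical(expand_relation_phrase(bare, 2L), "activate")

  targets <- mk_parse(list(
    list(1L, "Sirtuins", "sirtuin", "NOUN", "NNS", 3L, "nsubj"),
    list(2L, "may", "may", "AUX", "MD", 3L, "aux"),
    list(3L, "be", "be", "VERB", "VB", 0L, "root"),
    list(4L, "potential", "potential", "ADJ", "JJ", 5L, "amod"),
    list(5L, "targets", "target", "NOUN", "NNS", 3L, "attr"),
    list(6L, "for", "for", "ADP", "IN", 5L, "prep"),
    list(7L, "therapy", "therapy", "NOUN", "NN", 6L, "pobj")),
    text = "Sirtuins may be potential targets for therapy")
  expect_identical(expand_relation_phrase(targets, 3L),
                   "be potential targets for")
})

test_that("voice decides triple direction; negation suppresses the triple", {
  lex <- test_lexicon()
  act_sent <- mk_sentence("SIRT1 activates FOXO3.")
  act <- extract_sentence(
    mk_parse(list(
      list(1L, "SIRT1", "SIRT1", "NOUN", "NN", 2L, "nsubj"),
      list(2L, "activates", "activate", "VERB", "VBZ", 0L, "root"),
      list(3L, "FOXO3", "FOXO3", "NOUN", "NN", 2L, "dobj"),
      list(4L, ".", ".", "PUNCT", ".", 2L, "punct")),
      text = act_sent$text),
    match_dictionary(act_sent, lex))
  expect_identical(nrow(act), 1L)
  expect_identical(act$source_id, "SIRT1")
  expect_identical(act$target_id, "FOXO3")
  expect_identical(act$relation, "activate")
  expect_identical(act$voice, "active")

  pas_sent <- mk_sentence("FOXO3 is activated by SIRT1.")
  pas <- extract_sentence(
    mk_parse(list(
      list(1L, "FOXO3", "FOXO3", "NOUN", "NN", 3L, "nsubjpass"),
      list(2L, "is", "be", "AUX", "VBZ", 3L, "auxpass"),
      list(3L, "activated", "activate", "VERB", "VBN", 0L, "root"),
      list(4L, "by", "by", "ADP", "IN", 3L, "prep"),
      list(5L, "SIRT1", "SIRT1", "NOUN", "NN", 4L, "pobj"),
      list(6L, ".", ".", "PUNCT", ".", 3L, "punct")),
      text = pas_sent$text),
    match_dictionary(pas_sent, lex))
  expect_identical(nrow(pas), 1L)
  # same ordered pair as the active phrasing
  expect_identical(pas$source_id, "SIRT1")
  expect_identical(pas$target_id, "FOXO3")
  expect_identical(pas$relation, "activated")
  expect_identical(pas$voice, "passive")

  neg_sent <- mk_sentence("SIRT1 does not activate FOXO3.")
  neg <- extract_sentence(
    mk_parse(list(
      list(1L, "SIRT1", "SIRT1", "NOUN", "NN", 4L, "nsubj"),
      list(2L, "does", "do", "AUX", "VBZ", 4L, "aux"),
      list(3L, "not", "not", "PART", "RB", 4L, "advmod"),
      list(4L, "activate", "activate", "VERB", "VB", 0L, "root"),
      list(5L, "FOXO3", "FOXO3", "NOUN", "NN", 4L, "dobj"),
      list(6L, ".", ".", "PUNCT", ".", 4L, "punct")),
      text = neg_sent$text),
    match_dictionary(neg_sent, lex))
  expect_identical(nrow(neg), 0L)
})

test_that("no emitted triple has a negated main verb; counts bounded by C(m,2)", {
  g <- generate_corpus(synth_config(n_abstracts = 20, seed = 37,
                                    fraction_negated = 0.4))
  lex <- build_fixture_lexicon()
  res <- run_pipeline(g$corpus, g$species, g$parses, lex)
  # gold triples exclude negated ones; pipeline must agree exactly
  sc <- score_against_gold(res, g$gold)
  expect_identical(sc$precision, c(1, 1, 1))
  expect_identical(sc$recall, c(1, 1, 1))
  # per-sentence triple count <= C(m, 2)
  key_m <- paste(res$mentions$pmid, res$mentions$sentence_index)
  key_t <- paste(res$triples$pmid, res$triples$sentence_index)
  for (k in unique(key_t)) {
    m <- sum(key_m == k)
    expect_lte(sum(key_t == k), choose(m, 2))
  }
})
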