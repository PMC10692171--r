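graph_fixture <- function() {
  mentions <- rbind(
    mk_mention("SIRT1", "gene", 0L, 5L, pmid = "1"),
    mk_mention("SIRT1", "gene", 0L, 5L, pmid = "2"),
    mk_mention("SIRT1", "gene", 0L, 5L, pmid = "2", sidx = 1L),
    mk_mention("D1", "disease", 10L, 12L, pmid = "1"),
    mk_mention("D1", "disease", 10L, 12L, pmid = "2"),
    mk_mention("D1", "disease", 10L, 12L, pmid = "2", sidx = 1L),
    mk_mention("LONER", "gene", 20L, 25L, pmid = "1"))
  triples <- classify_triples(rbind(
    mk_triple("SIRT1", "gene", "D1", "disease", "prevent", pmid = "1"),
    mk_triple("SIRT1", "gene", "D1", "disease", "prevent", pmid = "2"),
    mk_triple("SIRT1", "gene", "D1", "disease", "prevent", pmid = "2",
              sidx = 1L)))
  list(mentions = mentions, triples = triples)
}

test_that("graph aggregation counts weights per occurrence and frequency per PMID", {
  fx <- graph_fixture()
  g <- build_graph(fx$mentions, fx$triples)
  edge <- g$edges[g$edges$relation == "prevent", ]
  expect_identical(edge$weight, 3L)           # 3 sentences
  freq <- g$nodes$frequency[g$nodes$ID == "gene:SIRT1"]
  expect_identical(freq, 2L)                  # 2 distinct PMIDs
  expect_identical(edge$type, "negative")
  expect_true("gene:LONER" %in% g$nodes$ID)   # isolated node kept
  expect_identical(sum(g$edges$weight), nrow(fx$triples))

  only_nodes <- build_graph(fx$mentions, fx$triples[0, ])
  expect_identical(nrow(only_nodes$edges), 0L)
  expect_identical(nrow(only_nodes$nodes), 3L)

  orphan <- mk_triple("GHOST", "gene", "D1", "disease", "cause")
  expect_error(build_graph(fx$mentions, classify_triples(orphan)),
               "absent from mentions")
})

test_that("edge-weight conservation holds on a generated corpus", {
  g <- generate_corpus(synth_config(n_abstracts = 12, seed = 43))
  res <- run_pipeline(g$corpus, g$species, g$parses,
                      build_fixture_lexicon())
  expect_identical(sum(res$graph$edges$weight), nrow(res$triples))
  expect_true(all(res$graph$nodes$frequency <= nrow(res$corpus)))
})

test_that("bulk-import CSVs use exact headers and round-trip with quoting", {
  fx <- graph_fixture()
  fx$mentions$canonical_name[fx$mentions$canonical_id == "D1"] <-
    'dementia, vascular "mixed"'
  g <- build_graph(fx$mentions, fx$triples)
  d <- tempfile(); dir.create(d)
  write_neo4j_csv(g, d)
  ents <- readLines(file.path(d, "Entities.csv"))
  roles <- readLines(file.path(d, "Roles.csv"))
  expect_identical(ents[1], "ID,name,type,frequency,label")
  expect_identical(roles[1], "start_ID,end_ID,relation,weight,method,type")
  expect_identical(length(ents), nrow(g$nodes) + 1L)
  expect_identical(length(roles), nrow(g$edges) + 1L)
  back <- read_neo4j_csv(d)
  expect_identical(back$nodes, g$nodes)
  expect_identical(back$edges, g$edges)
  expect_true(any(grepl('"dementia, vascular ""mixed"""', ents,
                        fixed = TRUE)))
})

test_that("the five JSON exports carry exactly the documented fields", {
  g <- generate_corpus(synth_config(n_abstracts = 6, seed = 47))
  lex <- build_fixture_lexicon()
  res <- run_pipeline(g$corpus, g$species, g$parses, lex)
  d <- tempfile(); dir.create(d)
  write_hald_json(res$corpus, res$mentions, res$triples, res$calls, d,
                  lexicon = lex)
  schemas <- json_schemas()
  chk <- function(file, schema) {
    x <- jsonlite::fromJSON(file.path(d, file), simplifyVector = FALSE)
    expect_gt(length(x), 0)
    for (rec in x) expect_identical(names(rec), schema)
  }
  chk("Literature_Info.json", schemas$literature)
  chk("Entity_Info.json", schemas$entity)
  chk("Relation_Info.json", schemas$relation)
  chk("Aging_Biomarkers.json", schemas$biomarker)
  chk("Longevity_Biomarkers.json", schemas$biomarker)

  ents <- jsonlite::fromJSON(file.path(d, "Entity_Info.json"),
                             simplifyVector = FALSE)
  flags <- vapply(ents, function(e) isTRUE(e[["aging biomarker"]]) ||
                    isTRUE(e[["longevity biomarker"]]), logical(1))
  expect_true(any(flags))
})

test_that("a biomarker-free corpus still yields valid, empty JSON arrays", {
  g <- generate_corpus(synth_config(n_abstracts = 3, seed = 53,
                                    disease_fraction = 0))
  res <- run_pipeline(g$corpus, g$species, g$parses,
                      build_fixture_lexicon())
  d <- tempfile(); dir.create(d)
  write_hald_json(res$corpus, res$mentions, res$triples, res$calls, d)
  ab <- jsonlite::fromJSON(file.path(d, "Aging_Biomarkers.json"))
  lb <- jsonlite::fromJSON(file.path(d, "Longevity_Biomarkers.json"))
  expect_length(ab, 0)
  expect_length(lb, 0)
})

test_that("path queries distinguish direct from indirect relations", {
  mentions <- rbind(mk_mention("A", "gene", 0L, 1L),
                    mk_mention("B", "disease", 2L, 3L),
                    mk_mention("C", "gene", 4L, 5L))
  triples <- classify_triples(rbind(
    mk_triple("A", "gene", "B", "disease", "cause"),
    mk_triple("B", "disease", "C", "gene", "associated with",
              head_lemma = "associate")))
  g <- build_graph(mentions, triples)
  direct <- query_paths(g, "gene:A", "disease:B", 1, 1)
  expect_length(direct, 1L)
  expect_identical(direct[[1]], c("gene:A", "disease:B"))
  indirect <- query_paths(g, "gene:A", "gene:C", 2, 2)
  expect_length(indirect, 1L)
  expect_identical(indirect[[1]], c("gene:A", "disease:B", "gene:C"))
  expect_length(query_paths(g, "gene:A", "gene:C", 1, 1), 0L)

  lone <- rbind(mentions, mk_mention("Z", "gene", 6L, 7L))
  g2 <- build_graph(lone, triples)
  expect_length(query_paths(g2, "gene:A", "gene:Z", 1, 3), 0L)
  expect_error(query_paths(g, "gene:NOPE", "gene:A", 1, 1), "unknown")
  expect_error(query_paths(g, "gene:A", "gene:C", 0, 1), "min_hops")
})

test_that("path queries equal brute-force simple-path enumeration", {
  # small random graphs over <= 10 nodes
  set.seed(59)
  for (rep in 1:8) {
    n <- sample(4:10, 1)
    ids <- paste0("gene:G", seq_len(n))
    mentions <- do.call(rbind, lapply(seq_len(n), function(i)
      mk_mention(paste0("G", i), "gene", 2L * i, 2L * i + 1L)))
    m <- sample(n:(2 * n), 1)
    ep <- cbind(sample(n, m, replace = TRUE), sample(n, m, replace = TRUE))
    ep <- ep[ep[, 1] != ep[, 2], , drop = FALSE]
    if (nrow(ep) == 0) next
    triples <- classify_triples(do.call(rbind, lapply(
      seq_len(nrow(ep)), function(k)
        mk_triple(paste0("G", ep[k, 1]), "gene", paste0("G", ep[k, 2]),
                  "gene", "cause", sidx = k))))
    g <- build_graph(mentions, triples)
    from <- ids[1]; to <- ids[n]
    ours <- query_paths(g, from, to, 1, 4)
    edges <- cbind(g$edges$start_ID, g$edges$end_ID)
    oracle <- bf_all_simple_paths(edges, from, to, max_len = 4)
    oracle <- oracle[vapply(oracle, length, integer(1)) >= 2]
    norm <- function(ps) sort(vapply(ps, paste, character(1),
                                     collapse = ">"))
    expect_identical(norm(ours), norm(oracle))
  }
})
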