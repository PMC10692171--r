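## End-to-end orchestration: corpus -> sentences -> mentions -> triples
## -> biomarkers -> knowledge graph.

#' Run the full literature-mining pipeline
#'
#' Applies, in order: corpus selection ([filter_corpus()]), sentence
#' segmentation and heading stripping, NER with reconciliation
#' ([annotate_sentences()]), dependency-path relation extraction
#' ([extract_corpus()]), polarity classification, biomarker calling and
#' knowledge-graph aggregation.
#'
#' @param corpus Literature data.frame ([read_literature()] or
#'   [generate_corpus()]`$corpus`).
#' @param species Species-annotation data.frame (`pmid`, `taxon_id`).
#' @param parses Named list of `gerolit_parse` keyed `"<pmid>:<index>"`.
#' @param lexicon A `gerolit_lexicon`.
#' @param polarity Polarity lexicon, see [polarity_lexicon()].
#' @param external_annotations Optional annotation data.frame from
#'   [read_pubtator()]`$annotations`.
#' @param negation_list Negator words.
#' @return A `gerolit_result`: `list(corpus, sentences, mentions,
#'   triples, calls, graph)`.
#' @export
run_pipeline <- function(corpus, species, parses, lexicon,
                         polarity = polarity_lexicon(),
                         external_annotations = NULL,
                         negation_list = negation_words()) {
  kept <- filter_corpus(corpus, species)
  sent <- lapply(seq_len(nrow(kept)), function(i)
    segment_sentences(kept[i, , drop = FALSE]))
  sentences <- if (length(sent)) do.call(rbind, sent) else
    .empty_sentences()
  sentences <- strip_heading(sentences)

  ext <- NULL
  if (!is.null(external_annotations) && nrow(external_annotations) > 0)
    ext <- external_to_mentions(external_annotations, sentences)
  mentions <- annotate_sentences(sentences, lexicon, ext)
  triples <- extract_corpus(parses, mentions, negation_list)
  triples <- classify_triples(triples, polarity)
  calls <- identify_biomarkers(triples, polarity)
  graph <- build_graph(mentions, triples)
  structure(list(corpus = kept, sentences = sentences,
                 mentions = mentions, triples = triples, calls = calls,
                 graph = graph),
            class = "gerolit_result")
}

#' @export
print.gerolit_result <- function(x, ...) {
  cat("<gerolit_result>\n",
      "  articles:            ", nrow(x$corpus), "\n",
      "  sentences:           ", nrow(x$sentences), "\n",
      "  entity mentions:     ", nrow(x$mentions), " (",
      length(unique(paste(x$mentions$entity_type, x$mentions$canonical_id))),
      " entities)\n",
      "  relation triples:    ", nrow(x$triples), "\n",
      "  aging biomarkers:    ",
      sum(x$calls$biomarker_class == "aging"), "\n",
      "  longevity biomarkers: ",
      sum(x$calls$biomarker_class == "longevity"), "\n", sep = "")
  invisible(x)
}

#' Precision/recall of a pipeline run against a gold standard
#'
#' Mentions are compared on (pmid, sentence, span, type, canonical id);
#' triples on (pmid, sentence, source, target, relation, voice,
#' polarity); biomarker calls on (entity, class).
#'
#' @param result A `gerolit_result`.
#' @param gold The `gold` element of [generate_corpus()].
#' @return Data.frame with rows mentions/triples/calls and columns
#'   `n_extracted`, `n_gold`, `n_matched`, `precision`, `recall`.
#' @export
score_against_gold <- function(result, gold) {
  mk <- function(df) paste(df$pmid, df$sentence_index, df$start, df$end,
                           df$entity_type, df$canonical_id)
  tk <- function(df) paste(df$pmid, df$sentence_index, df$source_id,
                           df$target_id, df$relation, df$voice,
                           df$polarity)
  ck <- function(df) paste(df$canonical_id, df$biomarker_class)
  one <- function(what, ours, theirs) {
    m <- length(intersect(unique(ours), unique(theirs)))
    data.frame(stage = what, n_extracted = length(unique(ours)),
               n_gold = length(unique(theirs)), n_matched = m,
               precision = if (length(unique(ours))) m / length(unique(ours)) else NA_real_,
               recall = if (length(unique(theirs))) m / length(unique(theirs)) else NA_real_,
               stringsAsFactors = FALSE)
  }
  rbind(one("mentions", mk(result$mentions), mk(gold$mentions)),
        one("triples", tk(result$triples), tk(gold$triples)),
        one("calls", ck(result$calls), ck(gold$calls)))
}
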