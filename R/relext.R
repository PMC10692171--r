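## Relation extraction: for every co-occurring entity pair in a sentence,
## find the main verb on the dependency path between the two mentions,
## resolve its voice, expand the relation phrase, and assemble a directed
## triple; negated relations are dropped.

.PARTICLE_DEPRELS <- c("prt", "compound:prt")
.PREP_DEPRELS <- c("prep")
.COMPLEMENT_DEPRELS <- c("attr", "acomp", "xcomp")
.COMPLEMENT_INNER <- c("amod", "compound", "nn")

.empty_triples <- function() {
  data.frame(pmid = character(), sentence_index = integer(),
             source_id = character(), source_name = character(),
             source_type = character(), target_id = character(),
             target_name = character(), target_type = character(),
             relation = character(), head_lemma = character(),
             voice = character(), method = character(),
             polarity = character(), sentence_text = character(),
             stringsAsFactors = FALSE)
}

## align token forms to the sentence text left-to-right; 0-based half-open
.token_spans <- function(parsed, text = parsed$text) {
  t <- parsed$tokens
  starts <- integer(nrow(t)); ends <- integer(nrow(t))
  cursor <- 0L
  for (i in seq_len(nrow(t))) {
    pos <- regexpr(t$form[i], substr(text, cursor + 1L, nchar(text)),
                   fixed = TRUE)
    if (pos == -1L) { starts[i] <- NA_integer_; ends[i] <- NA_integer_; next }
    starts[i] <- cursor + as.integer(pos) - 1L
    ends[i] <- starts[i] + nchar(t$form[i])
    cursor <- ends[i]
  }
  data.frame(id = t$id, start = starts, end = ends)
}

## head token of a mention span: the last parse token overlapping the span
.mention_head_token <- function(token_spans, start, end) {
  hit <- token_spans$id[!is.na(token_spans$start) &
                          token_spans$start < end & token_spans$end > start]
  if (length(hit) == 0) return(NA_integer_)
  max(hit)
}

#' Candidate entity pairs in a sentence
#'
#' All unordered pairs of mentions with distinct canonical identifiers
#' (a sentence must mention at least two entities to yield any relation;
#' self-relations are excluded).
#'
#' @param mentions Reconciled mention data.frame for one sentence.
#' @return List of length-2 integer vectors (row indices into `mentions`).
#' @export
candidate_pairs <- function(mentions) {
  n <- nrow(mentions)
  if (n < 2) return(list())
  out <- list()
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1L, n)) {
    if (mentions$canonical_id[i] == mentions$canonical_id[j]) next
    out[[length(out) + 1L]] <- c(i, j)
  }
  out
}

.parse_graph <- function(parsed) {
  t <- parsed$tokens
  arcs <- t[t$head != 0L, c("id", "head")]
  igraph::graph_from_data_frame(
    data.frame(from = as.character(arcs$head), to = as.character(arcs$id)),
    directed = FALSE,
    vertices = data.frame(name = as.character(t$id)))
}

#' Select the main verb between two mentions
#'
#' Builds an undirected graph over the sentence's dependency arcs and
#' returns the verb-tagged token lying on the shortest path between the
#' two mention head tokens. Among several such verbs the one with the
#' smallest summed distance to the two endpoints wins, ties broken by the
#' smallest token index. Returns `NA` when no verb lies on any shortest
#' path (no relation is extracted then).
#'
#' @param parsed A `gerolit_parse`.
#' @param head_a,head_b Token ids of the two mention heads.
#' @return Verb token id, or `NA_integer_`.
#' @export
select_main_verb <- function(parsed, head_a, head_b) {
  t <- parsed$tokens
  .stop_if(!head_a %in% t$id || !head_b %in% t$id,
           "mention head token not in parse")
  if (head_a == head_b) return(NA_integer_)
  g <- .parse_graph(parsed)
  d <- igraph::distances(g)
  ab <- d[as.character(head_a), as.character(head_b)]
  verbs <- t$id[t$xpos %in% .VERB_XPOS & t$id != head_a & t$id != head_b]
  if (length(verbs) == 0) return(NA_integer_)
  da <- d[as.character(verbs), as.character(head_a)]
  db <- d[as.character(verbs), as.character(head_b)]
  on_path <- (da + db) == ab  # lies on some shortest path
  if (!any(on_path)) return(NA_integer_)
  cand <- verbs[on_path]
  score <- (da + db)[on_path]
  cand <- cand[score == min(score)]
  min(cand)
}

#' Expand a relation phrase around the main verb
#'
#' The single main verb often understates the relation ("be" for "be
#' potential targets for"), so the phrase is grown over the verb's
#' attached particles, copular/adjectival complements (with their
#' adjective/compound modifiers and trailing prepositions) and the verb's
#' own prepositions, emitted in surface order. The verb itself appears as
#' `normalized_form` (lemma when active, past participle when passive);
#' under passive voice the agent marker "by" is not part of the phrase.
#'
#' @param parsed A `gerolit_parse`.
#' @param verb_index Token id of the main verb.
#' @param verb_analysis Optional result of [determine_voice()]; computed
#'   if missing.
#' @return The phrase string.
#' @export
expand_relation_phrase <- function(parsed, verb_index, verb_analysis = NULL) {
  if (is.null(verb_analysis)) verb_analysis <- determine_voice(parsed, verb_index)
  t <- parsed$tokens
  passive <- identical(verb_analysis$voice, "passive")
  keep <- c(verb_index)
  deps <- .deps_of(t, verb_index)
  # particles
  keep <- c(keep, deps$id[deps$deprel %in% .PARTICLE_DEPRELS])
  # verb-attached prepositions (minus the passive agent marker)
  preps <- deps[deps$deprel %in% .PREP_DEPRELS, , drop = FALSE]
  if (passive) preps <- preps[tolower(preps$form) != "by", , drop = FALSE]
  keep <- c(keep, preps$id)
  # complements and their local modifiers / trailing prepositions
  comps <- deps[deps$deprel %in% .COMPLEMENT_DEPRELS, , drop = FALSE]
  for (ci in comps$id) {
    keep <- c(keep, ci)
    cdeps <- .deps_of(t, ci)
    keep <- c(keep, cdeps$id[cdeps$deprel %in% .COMPLEMENT_INNER])
    cpreps <- cdeps[cdeps$deprel %in% .PREP_DEPRELS, , drop = FALSE]
    if (passive) cpreps <- cpreps[tolower(cpreps$form) != "by", , drop = FALSE]
    keep <- c(keep, cpreps$id)
  }
  keep <- sort(unique(keep))
  words <- t$form[match(keep, t$id)]
  words[keep == verb_index] <- verb_analysis$normalized_form
  paste(tolower(words), collapse = " ")
}

#' Assemble a directed relation triple
#'
#' Direction follows voice: under an active main verb the mention
#' preceding the verb (in token order) is the source; under a passive
#' one, the mention following the verb (the agent side) is the source and
#' the preceding mention the target. Returns `NULL` when the main verb is
#' negated.
#'
#' @param parsed A `gerolit_parse`.
#' @param mention_a,mention_b Single-row mention data.frames.
#' @param head_a,head_b Their head token ids.
#' @param verb_analysis Result of [determine_voice()] for the main verb.
#' @param phrase Relation phrase from [expand_relation_phrase()].
#' @param negation_list Negator words, see [detect_negation()].
#' @return A one-row triple data.frame, or `NULL`.
#' @export
assemble_triple <- function(parsed, mention_a, mention_b, head_a, head_b,
                            verb_analysis, phrase,
                            negation_list = negation_words()) {
  vid <- verb_analysis$token_index
  if (detect_negation(parsed, vid, negation_list)) return(NULL)
  a_first <- head_a < head_b
  before <- if (a_first) mention_a else mention_b
  after <- if (a_first) mention_b else mention_a
  # degenerate: both mentions on the same side of the verb -> token order
  if (identical(verb_analysis$voice, "passive")) {
    src <- after; tgt <- before
  } else {
    src <- before; tgt <- after
  }
  t <- parsed$tokens
  lemma <- tolower(t$lemma[t$id == vid])
  data.frame(
    pmid = src$pmid, sentence_index = src$sentence_index,
    source_id = src$canonical_id, source_name = src$canonical_name,
    source_type = src$entity_type, target_id = tgt$canonical_id,
    target_name = tgt$canonical_name, target_type = tgt$entity_type,
    relation = phrase, head_lemma = lemma,
    voice = verb_analysis$voice, method = "shortest_path",
    polarity = NA_character_,
    sentence_text = parsed$text %||% NA_character_,
    stringsAsFactors = FALSE)
}

#' Extract all relation triples from one parsed sentence
#'
#' Composition over all candidate pairs: main-verb selection on the
#' dependency path, voice resolution, phrase expansion, negation
#' filtering and directed assembly. Output is deterministically ordered
#' by source, target and relation.
#'
#' @param parsed A `gerolit_parse` whose `text` matches the sentence.
#' @param mentions Reconciled mentions of that sentence.
#' @param negation_list Negator words.
#' @return A triple data.frame (possibly empty).
#' @export
extract_sentence <- function(parsed, mentions,
                             negation_list = negation_words()) {
  if (nrow(mentions) < 2) return(.empty_triples())
  spans <- .token_spans(parsed)
  heads <- vapply(seq_len(nrow(mentions)), function(i)
    .mention_head_token(spans, mentions$start[i], mentions$end[i]),
    integer(1))
  out <- list()
  for (pr in candidate_pairs(mentions)) {
    ha <- heads[pr[1]]; hb <- heads[pr[2]]
    if (is.na(ha) || is.na(hb) || ha == hb) {
      if (is.na(ha) || is.na(hb))
        warning("mention head not resolvable in parse ", parsed$sent_id,
                "; pair skipped", call. = FALSE)
      next
    }
    vid <- select_main_verb(parsed, ha, hb)
    if (is.na(vid)) next
    va <- determine_voice(parsed, vid)
    phrase <- expand_relation_phrase(parsed, vid, va)
    tr <- assemble_triple(parsed, mentions[pr[1], ], mentions[pr[2], ],
                          ha, hb, va, phrase, negation_list)
    if (!is.null(tr)) out[[length(out) + 1L]] <- tr
  }
  if (length(out) == 0) return(.empty_triples())
  res <- do.call(rbind, out)
  res <- res[order(res$source_id, res$target_id, res$relation), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract triples for a whole corpus
#'
#' @param parses Named list of `gerolit_parse` keyed `"<pmid>:<index>"`.
#' @param mentions Reconciled mention data.frame for the corpus.
#' @param negation_list Negator words.
#' @return Combined triple data.frame.
#' @export
extract_corpus <- function(parses, mentions,
                           negation_list = negation_words()) {
  key <- paste0(mentions$pmid, ":", mentions$sentence_index)
  out <- list()
  for (k in unique(key)) {
    p <- parses[[k]]
    if (is.null(p)) next
    out[[length(out) + 1L]] <-
      extract_sentence(p, mentions[key == k, , drop = FALSE], negation_list)
  }
  if (length(out) == 0) return(.empty_triples())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
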