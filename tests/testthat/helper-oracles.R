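# Independent brute-force oracles and small fixture builders.
# Deliberately written without reusing package internals so dual-route
# checks stay meaningful.

# scan every surface form at every character position with a boundary
# check, then resolve same-type overlaps leftmost-longest
bf_match_dictionary <- function(text, lexicon) {
  is_word <- function(ch) length(ch) == 1 && grepl("[A-Za-z0-9-]", ch)
  lower <- tolower(text)
  n <- nchar(text)
  ent <- lexicon$entries
  cand <- list()
  for (i in seq_len(nrow(ent))) {
    for (s in ent$surface_forms[[i]]) {
      sl <- tolower(s); L <- nchar(sl)
      if (L == 0 || L > n) next
      for (pos in 1:(n - L + 1)) {
        if (substr(lower, pos, pos + L - 1) != sl) next
        left <- if (pos == 1) "" else substr(text, pos - 1, pos - 1)
        right <- if (pos + L - 1 == n) "" else substr(text, pos + L, pos + L)
        if ((left == "" || !is_word(left)) &&
            (right == "" || !is_word(right))) {
          cand[[length(cand) + 1L]] <- data.frame(
            start = pos - 1L, end = pos + L - 1L,
            type = ent$entity_type[i], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(cand) == 0)
    return(data.frame(start = integer(), end = integer(),
                      type = character(), stringsAsFactors = FALSE))
  cand <- unique(do.call(rbind, cand))
  out <- list()
  for (tp in unique(cand$type)) {
    sub <- cand[cand$type == tp, , drop = FALSE]
    sub <- sub[order(sub$start, -(sub$end - sub$start)), , drop = FALSE]
    kept <- sub[0, ]
    for (k in seq_len(nrow(sub))) {
      clash <- nrow(kept) > 0 &&
        any(sub$start[k] < kept$end & sub$end[k] > kept$start)
      if (!clash) kept <- rbind(kept, sub[k, ])
    }
    out[[tp]] <- kept
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$type), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# all simple paths between two vertices of an undirected graph given as
# an edge list (two-column matrix of vertex labels)
bf_all_simple_paths <- function(edges, from, to, max_len = Inf) {
  adj <- list()
  add <- function(a, b) adj[[a]] <<- unique(c(adj[[a]], b))
  for (i in seq_len(nrow(edges))) {
    a <- as.character(edges[i, 1]); b <- as.character(edges[i, 2])
    add(a, b); add(b, a)
  }
  paths <- list()
  walk <- function(node, seen) {
    if (length(seen) - 1 > max_len) return()
    if (node == to) { paths[[length(paths) + 1L]] <<- seen; return() }
    for (nb in adj[[node]]) if (!nb %in% seen) walk(nb, c(seen, nb))
  }
  if (!is.null(adj[[as.character(from)]])) walk(as.character(from),
                                               as.character(from))
  paths
}

# main verb between two token heads by exhaustive path enumeration
bf_select_main_verb <- function(parsed, head_a, head_b) {
  t <- parsed$tokens
  edges <- cbind(t$head[t$head != 0], t$id[t$head != 0])
  paths <- bf_all_simple_paths(edges, head_a, head_b)
  if (length(paths) == 0) return(NA_integer_)
  lens <- vapply(paths, length, integer(1))
  shortest <- paths[lens == min(lens)]
  verb_ids <- t$id[t$xpos %in% c("VB", "VBD", "VBG", "VBN", "VBP", "VBZ")]
  cands <- integer(0); scores <- integer(0)
  for (p in shortest) {
    inner <- as.integer(p[-c(1, length(p))])
    for (v in intersect(inner, verb_ids)) {
      pos <- match(v, as.integer(p))
      cands <- c(cands, v)
      scores <- c(scores, (pos - 1) + (length(p) - pos))
    }
  }
  if (length(cands) == 0) return(NA_integer_)
  best <- cands[scores == min(scores)]
  min(best)
}

# compact parse builder: df columns id, form, lemma, upos, xpos, head, deprel
mk_parse <- function(rows, sent_id = "t:0", text = NULL) {
  tokens <- do.call(rbind, lapply(rows, function(r)
    data.frame(id = r[[1]], form = r[[2]], lemma = r[[3]], upos = r[[4]],
               xpos = r[[5]], head = r[[6]], deprel = r[[7]],
               stringsAsFactors = FALSE)))
  if (is.null(text))
    text <- paste0(paste(tokens$form[-nrow(tokens)], collapse = " "),
                   tokens$form[nrow(tokens)])
  gerolit:::.new_parse(sent_id, text, tokens)
}

mk_sentence <- function(text, pmid = "1", index = 0L) {
  data.frame(pmid = pmid, index = index, text = text,
             char_start = 0L, char_end = nchar(text),
             stringsAsFactors = FALSE)
}

# one-row mention builder for relation/polarity tests
mk_mention <- function(id, type, start, end, surface = id, pmid = "1",
                       sidx = 0L, name = id, method = "dictionary") {
  data.frame(pmid = pmid, sentence_index = sidx, start = start, end = end,
             surface = surface, entity_type = type, canonical_id = id,
             canonical_name = name, method = method, overlap_flag = FALSE,
             stringsAsFactors = FALSE)
}

mk_triple <- function(src, src_type, tgt, tgt_type, relation,
                      head_lemma = strsplit(relation, " ")[[1]][1],
                      polarity = NA_character_, pmid = "1", sidx = 0L,
                      voice = "active") {
  data.frame(pmid = pmid, sentence_index = sidx,
             source_id = src, source_name = src, source_type = src_type,
             target_id = tgt, target_name = tgt, target_type = tgt_type,
             relation = relation, head_lemma = head_lemma, voice = voice,
             method = "shortest_path", polarity = polarity,
             sentence_text = "synthetic sentence",
             stringsAsFactors = FALSE)
}

# small shared lexicon for NER tests
test_lexicon <- function() {
  hgnc <- data.frame(
    approved_symbol = c("TP53", "SIRT1", "FOXO3", "INS", "IGF1"),
    approved_name = c("tumor protein p53", "sirtuin 1", "forkhead box O3",
                      "insulin", "insulin like growth factor 1"),
    previous_symbols = NA_character_,
    alias_symbols = c("p53", NA, NA, NA, NA),
    previous_names = NA_character_,
    alias_names = c(NA, NA, NA, NA, "insulin-like growth factor 1"),
    ncbi_gene_id = as.character(c(7157, 23411, 2309, 3630, 3479)),
    locus_type = "gene with protein product",
    stringsAsFactors = FALSE)
  dis <- list(list(mesh_id = "D055948", name = "sarcopenia",
                   terms = character()),
              list(mesh_id = "D003704", name = "dementia",
                   terms = character()))
  combine_lexicons(build_gene_rna_lexicon(hgnc),
                   build_mesh_lexicon(dis, "disease"))
}
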