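## Dependency-parse representation (CoNLL-U), main-verb voice rules and
## negation detection.
##
## Penn (XPOS) tags drive the verb rules: VB/VBD/VBG/VBP/VBZ are always
## active; VBN is passive only under a be-auxiliary or when the participle
## modifies a nominal. UPOS is a fallback only.

.VERB_XPOS <- c("VB", "VBD", "VBG", "VBN", "VBP", "VBZ")
.ADVERB_XPOS <- c("RB", "RBR", "RBS")
.BE_FORMS <- c("be", "is", "are", "was", "were", "been", "being", "am")
.AUX_DEPRELS <- c("aux", "auxpass", "aux:pass", "cop")
.NOMINAL_MOD_DEPRELS <- c("acl", "acl:relcl", "amod", "partmod", "vmod",
                          "rcmod")

#' Default negation word list
#'
#' Adverbial negators screened during relation extraction; a candidate
#' relation whose main verb governs one of these (tagged RB/RBR/RBS) is
#' discarded.
#'
#' @return Character vector.
#' @export
negation_words <- function() {
  c("no", "not", "never", "hardly", "barely", "scarcely", "rarely",
    "few", "little", "seldom", "neither", "nor")
}

.new_parse <- function(sent_id, text, tokens) {
  .stop_if(nrow(tokens) == 0, "parse with no tokens: ", sent_id)
  .stop_if(any(tokens$head == tokens$id),
           "token is its own head in parse ", sent_id)
  .stop_if(sum(tokens$head == 0L) != 1L,
           "parse must have exactly one root: ", sent_id)
  .stop_if(!all(tokens$head %in% c(0L, tokens$id)),
           "head index out of range in parse ", sent_id)
  # connectivity / acyclicity: every token must reach the root
  n <- nrow(tokens)
  head_of <- tokens$head; names(head_of) <- tokens$id
  for (i in tokens$id) {
    seen <- integer(0); cur <- i
    while (cur != 0L) {
      .stop_if(cur %in% seen, "cyclic parse: ", sent_id)
      seen <- c(seen, cur)
      cur <- head_of[[as.character(cur)]]
      .stop_if(length(seen) > n, "cyclic parse: ", sent_id)
    }
  }
  obj <- list(sent_id = sent_id, text = text, tokens = tokens)
  class(obj) <- "gerolit_parse"
  obj
}

#' @export
print.gerolit_parse <- function(x, ...) {
  cat("<gerolit_parse> ", x$sent_id, ": ", nrow(x$tokens), " tokens\n",
      sep = "")
  print(x$tokens[, c("id", "form", "lemma", "xpos", "head", "deprel")],
        row.names = FALSE)
  invisible(x)
}

#' Read dependency parses from a CoNLL-U file
#'
#' Standard 10-column CoNLL-U; `# sent_id` and `# text` comments are kept
#' as metadata. Multiword-token and empty-node lines are skipped. The
#' XPOS column is expected to carry Penn tags. Each sentence is validated
#' as a single-rooted tree (cyclic or multi-root parses are errors).
#'
#' @param path Path to a CoNLL-U file.
#' @return Named list of `gerolit_parse` objects keyed by `sent_id`.
#' @export
read_conllu <- function(path) {
  .stop_if(!file.exists(path), "file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  parses <- list()
  sent_id <- NA_character_; text <- NA_character_; rows <- list()
  flush <- function() {
    if (length(rows) == 0) return()
    tokens <- do.call(rbind, rows)
    rownames(tokens) <- NULL
    id <- if (!is.na(sent_id)) sent_id else as.character(length(parses) + 1L)
    parses[[id]] <<- .new_parse(id, text, tokens)
    rows <<- list(); sent_id <<- NA_character_; text <<- NA_character_
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) { flush(); next }
    if (startsWith(ln, "#")) {
      if (grepl("^# ?sent_id *=", ln))
        sent_id <- trimws(sub("^# ?sent_id *=", "", ln))
      if (grepl("^# ?text *=", ln))
        text <- trimws(sub("^# ?text *=", "", ln))
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    .stop_if(length(f) < 8, "malformed CoNLL-U line: ", ln)
    if (grepl("[-.]", f[1])) next  # multiword token / empty node
    rows[[length(rows) + 1L]] <- data.frame(
      id = as.integer(f[1]), form = f[2], lemma = f[3], upos = f[4],
      xpos = f[5], head = as.integer(f[7]), deprel = f[8],
      stringsAsFactors = FALSE)
  }
  flush()
  parses
}

#' Write parses to a CoNLL-U file
#'
#' @param parses Named list of `gerolit_parse` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conllu <- function(parses, path) {
  out <- character(0)
  for (p in parses) {
    out <- c(out, paste0("# sent_id = ", p$sent_id))
    if (!is.na(p$text)) out <- c(out, paste0("# text = ", p$text))
    t <- p$tokens
    out <- c(out, paste(t$id, t$form, t$lemma, t$upos, t$xpos, "_",
                        t$head, t$deprel, "_", "_", sep = "\t"), "")
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

.deps_of <- function(tokens, idx) tokens[tokens$head == idx, , drop = FALSE]

#' Main-verb voice and normalized form
#'
#' Verbs tagged VB, VBD, VBG, VBP or VBZ always express an active
#' relation and are normalized to the lemma. A VBN participle is passive
#' iff (i) it has an auxiliary/copula dependent whose lemma or form is a
#' conjugation of *be*, or (ii) it attaches to a nominal head as a
#' clausal/adjectival modifier (reduced relative, `acl`, `amod`, ...).
#' Passive verbs keep their past-participle surface as normalized form
#' (so triple direction can be reversed downstream); all other VBN uses
#' (e.g. perfect *have* + participle) are active and lemmatized.
#'
#' @param parsed A `gerolit_parse`.
#' @param verb_index Token id of a verb.
#' @return `list(token_index=, voice=, normalized_form=)`.
#' @export
determine_voice <- function(parsed, verb_index) {
  t <- parsed$tokens
  row <- t[t$id == verb_index, , drop = FALSE]
  .stop_if(nrow(row) == 0, "no token with id ", verb_index)
  xpos <- row$xpos
  if (!xpos %in% .VERB_XPOS) {
    if (identical(row$upos, "VERB") || identical(row$upos, "AUX")) {
      xpos <- "VB"  # UPOS fallback when XPOS is not a Penn verb tag
    } else {
      stop("token ", verb_index, " ('", row$form, "') is not a verb (xpos ",
           row$xpos, ")", call. = FALSE)
    }
  }
  if (xpos != "VBN") {
    return(list(token_index = verb_index, voice = "active",
                normalized_form = tolower(row$lemma)))
  }
  deps <- .deps_of(t, verb_index)
  aux <- deps[deps$deprel %in% .AUX_DEPRELS, , drop = FALSE]
  be_aux <- any(tolower(aux$lemma) %in% .BE_FORMS |
                  tolower(aux$form) %in% .BE_FORMS)
  head_row <- t[t$id == row$head, , drop = FALSE]
  nominal_mod <- row$deprel %in% .NOMINAL_MOD_DEPRELS && nrow(head_row) == 1 &&
    (head_row$upos %in% c("NOUN", "PROPN", "PRON") ||
       grepl("^NN", head_row$xpos))
  if (be_aux || nominal_mod) {
    list(token_index = verb_index, voice = "passive",
         normalized_form = tolower(row$form))
  } else {
    list(token_index = verb_index, voice = "active",
         normalized_form = tolower(row$lemma))
  }
}

#' Detect verb-scoped negation
#'
#' TRUE iff some token whose lower-cased form is in `words` and whose
#' XPOS is an adverb tag (RB, RBR, RBS) depends on the verb directly or
#' on one of the verb's auxiliaries.
#'
#' @param parsed A `gerolit_parse`.
#' @param verb_index Token id of the verb under consideration.
#' @param words Negator list; defaults to [negation_words()].
#' @return Logical scalar.
#' @export
detect_negation <- function(parsed, verb_index, words = negation_words()) {
  t <- parsed$tokens
  .stop_if(!verb_index %in% t$id, "no token with id ", verb_index)
  scope <- c(verb_index,
             t$id[t$head == verb_index & t$deprel %in% .AUX_DEPRELS])
  neg <- t$head %in% scope & tolower(t$form) %in% words &
    t$xpos %in% .ADVERB_XPOS
  any(neg)
}
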