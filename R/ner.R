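## Named entity recognition: dictionary matching with word boundaries,
## rule-based miRNA/lncRNA patterns, ingestion of external annotator
## exports, and channel reconciliation with the dictionary retention gate.

.empty_mentions <- function() {
  data.frame(pmid = character(), sentence_index = integer(),
             start = integer(), end = integer(), surface = character(),
             entity_type = character(), canonical_id = character(),
             canonical_name = character(), method = character(),
             overlap_flag = logical(), stringsAsFactors = FALSE)
}

.mention_row <- function(pmid, sidx, start, end, surface, type, cid, cname,
                         method) {
  data.frame(pmid = pmid, sentence_index = as.integer(sidx),
             start = as.integer(start), end = as.integer(end),
             surface = surface, entity_type = type, canonical_id = cid,
             canonical_name = cname, method = method, overlap_flag = FALSE,
             stringsAsFactors = FALSE)
}

## word-boundary check: flanking characters must not be alphanumeric or
## hyphen ("insulin-like" must not yield "insulin")
.boundary_ok <- function(text, start, end) {
  n <- nchar(text)
  left_ok <- start == 0L ||
    !.is_wordchar(substr(text, start, start))
  right_ok <- end == n ||
    !.is_wordchar(substr(text, end + 1L, end + 1L))
  left_ok && right_ok
}

## all word-boundary occurrences (0-based half-open) of `surface` in `text`,
## case-insensitive
.find_surface <- function(text_lower, text, surface_lower) {
  hits <- gregexpr(surface_lower, text_lower, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(NULL)
  len <- nchar(surface_lower)
  starts <- as.integer(hits) - 1L
  keep <- vapply(starts, function(s) .boundary_ok(text, s, s + len),
                 logical(1))
  if (!any(keep)) return(NULL)
  cbind(start = starts[keep], end = starts[keep] + len)
}

#' Dictionary-based entity matching in one sentence
#'
#' Scans the sentence for every surface form in the lexicon,
#' case-insensitively and at word boundaries (a match may not be flanked
#' by letters, digits or hyphens). Matching is leftmost-longest within
#' each entity type: overlapping candidates of the same type are resolved
#' by position, then by length (longest wins). Each retained mention is
#' normalized to its canonical identifier.
#'
#' @param sentence One row of a sentence data.frame (heading already
#'   stripped), or a list with `pmid`, `index`, `text`.
#' @param lexicon A `gerolit_lexicon`.
#' @return A mention data.frame (columns `pmid`, `sentence_index`,
#'   `start`, `end`, `surface`, `entity_type`, `canonical_id`,
#'   `canonical_name`, `method`, `overlap_flag`); spans are 0-based
#'   half-open within the sentence.
#' @export
match_dictionary <- function(sentence, lexicon) {
  text <- as.character(sentence$text)[1]
  pmid <- as.character(sentence$pmid)[1]
  sidx <- as.integer(sentence$index)[1]
  if (is.na(text) || !nzchar(text)) return(.empty_mentions())
  text_lower <- tolower(text)

  cand <- list()
  for (surf in ls(lexicon$index)) {
    occ <- .find_surface(text_lower, text, surf)
    if (is.null(occ)) next
    rows <- lexicon$index[[surf]]
    types <- unique(lexicon$entries$entity_type[rows])
    for (tp in types) {
      for (k in seq_len(nrow(occ))) {
        cand[[length(cand) + 1L]] <- list(start = occ[k, "start"],
                                          end = occ[k, "end"], type = tp)
      }
    }
  }
  if (length(cand) == 0) return(.empty_mentions())

  cdf <- data.frame(start = vapply(cand, `[[`, integer(1), "start"),
                    end = vapply(cand, `[[`, integer(1), "end"),
                    type = vapply(cand, `[[`, character(1), "type"),
                    stringsAsFactors = FALSE)
  out <- list()
  for (tp in unique(cdf$type)) {
    sub <- cdf[cdf$type == tp, , drop = FALSE]
    sub <- sub[order(sub$start, -(sub$end - sub$start)), , drop = FALSE]
    taken_end <- -1L
    for (k in seq_len(nrow(sub))) {
      if (sub$start[k] < taken_end) next  # overlaps a kept same-type match
      surface <- substr(text, sub$start[k] + 1L, sub$end[k])
      nm <- normalize_entity(surface, tp, lexicon)
      if (is.null(nm)) next
      out[[length(out) + 1L]] <- .mention_row(
        pmid, sidx, sub$start[k], sub$end[k], surface, tp,
        nm$canonical_id, nm$canonical_name, "dictionary")
      taken_end <- sub$end[k]
    }
  }
  if (length(out) == 0) return(.empty_mentions())
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$entity_type), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## miRNA: prefix MIR / MIRN / microRNA / hsa-miR then an optional hyphen and
## a numeric tail; lncRNA: linc followed by digits. Case-insensitive.
.RNA_PATTERN <- paste0(
  "(?i)\\b(",
  "(?:hsa-miR|microRNA|MIRN|MIR|miR)-?[0-9]+[A-Za-z0-9-]*",
  "|linc[0-9]+",
  ")\\b"
)

#' Rule-based miRNA/lncRNA recognition
#'
#' miRNA and lncRNA names follow fixed conventions that dictionaries lag
#' behind: miRNAs begin with `MIR`, `MIRN`, `microRNA` or `hsa-miR`
#' followed by a numeric identifier tail; lincRNAs begin with `linc` plus
#' digits. Matches are typed `rna` with `method = "rule"` and keep their
#' surface as canonical form.
#'
#' @inheritParams match_dictionary
#' @return A mention data.frame.
#' @export
match_rna_rules <- function(sentence) {
  text <- as.character(sentence$text)[1]
  pmid <- as.character(sentence$pmid)[1]
  sidx <- as.integer(sentence$index)[1]
  if (is.na(text) || !nzchar(text)) return(.empty_mentions())
  m <- gregexpr(.RNA_PATTERN, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(.empty_mentions())
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  out <- lapply(seq_along(starts), function(k) {
    surface <- substr(text, starts[k] + 1L, starts[k] + lens[k])
    .mention_row(pmid, sidx, starts[k], starts[k] + lens[k], surface,
                 "rna", surface, surface, "rule")
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a PubTator tab-separated annotation export
#'
#' Accepts the PubTator block format: optional `pmid|t|title` and
#' `pmid|a|abstract` lines are ignored; annotation lines are
#' `pmid<TAB>start<TAB>end<TAB>text<TAB>type<TAB>identifier` with offsets
#' into the abstract. Species rows (type `Species`) are returned
#' separately as species annotations, not as entity mentions. Rows whose
#' span is invalid (`end <= start`) are rejected with a warning.
#'
#' @param path Path to the export file.
#' @return `list(annotations = data.frame(pmid, start, end, text, type,
#'   identifier), species = data.frame(pmid, taxon_id))`.
#' @export
read_pubtator <- function(path) {
  .stop_if(!file.exists(path), "file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^[0-9]+\\|[ta]\\|", lines)]
  ann <- data.frame(pmid = character(), start = integer(), end = integer(),
                    text = character(), type = character(),
                    identifier = character(), stringsAsFactors = FALSE)
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- vapply(parts, function(p) length(p) < 5, logical(1))
    .stop_if(any(bad), "malformed annotation line(s): ",
             paste(which(bad), collapse = ", "))
    ann <- data.frame(
      pmid = vapply(parts, `[[`, character(1), 1),
      start = as.integer(vapply(parts, `[[`, character(1), 2)),
      end = as.integer(vapply(parts, `[[`, character(1), 3)),
      text = vapply(parts, `[[`, character(1), 4),
      type = vapply(parts, `[[`, character(1), 5),
      identifier = vapply(parts, function(p) if (length(p) >= 6) p[[6]] else NA_character_,
                          character(1)),
      stringsAsFactors = FALSE
    )
  }
  invalid <- ann$end <= ann$start | is.na(ann$start) | is.na(ann$end)
  if (any(invalid)) {
    warning(sum(invalid), " annotation row(s) with invalid span rejected",
            call. = FALSE)
    ann <- ann[!invalid, , drop = FALSE]
  }
  is_species <- tolower(ann$type) == "species"
  species <- data.frame(pmid = ann$pmid[is_species],
                        taxon_id = ann$identifier[is_species],
                        stringsAsFactors = FALSE)
  list(annotations = ann[!is_species, , drop = FALSE], species = species)
}

## map PubTator types onto lexicon entity types to try, in order
.EXTERNAL_TYPE_MAP <- list(
  gene = c("gene", "rna"),
  disease = "disease",
  chemical = c("pharmaceutical_preparations", "carbohydrate", "lipid",
               "peptide", "protein", "toxin"),
  mutation = "mutation"
)

#' Convert external abstract-level annotations to sentence-level mentions
#'
#' Annotation offsets are abstract-relative; each is assigned to the
#' sentence whose span contains it and rebased to sentence-relative
#' offsets (post heading-strip). Rows falling outside any sentence are
#' rejected with a warning. Mentions carry `method = "external"` and are
#' *not* yet gated against the lexicon — see [reconcile_mentions()].
#'
#' @param annotations Annotation data.frame from [read_pubtator()].
#' @param sentences Sentence data.frame for the same records
#'   (heading-stripped).
#' @return A mention data.frame with raw (unnormalized) canonical fields.
#' @export
external_to_mentions <- function(annotations, sentences) {
  if (nrow(annotations) == 0) return(.empty_mentions())
  out <- list()
  dropped <- 0L
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    sent <- sentences[sentences$pmid == a$pmid &
                        sentences$char_start <= a$start &
                        sentences$char_end >= a$end, , drop = FALSE]
    if (nrow(sent) == 0) { dropped <- dropped + 1L; next }
    s <- sent[1, ]
    out[[length(out) + 1L]] <- .mention_row(
      s$pmid, s$index, a$start - s$char_start, a$end - s$char_start,
      a$text, tolower(a$type), a$identifier %||% NA_character_,
      a$text, "external")
  }
  if (dropped > 0)
    warning(dropped, " annotation(s) outside sentence bounds rejected",
            call. = FALSE)
  if (length(out) == 0) return(.empty_mentions())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Reconcile mention channels with the dictionary retention gate
#'
#' Combines dictionary, rule and external mentions for the same corpus:
#' \itemize{
#'   \item external mentions are retained only if their surface (or
#'     identifier) normalizes in the lexicon — entities that do not match
#'     the dictionaries are not retained; their type is resolved to
#'     whichever lexicon category the surface normalizes in;
#'   \item rule-based RNA mentions bypass the gate (the rules exist to
#'     catch RNA names absent from the dictionary);
#'   \item identical spans of the same type found by several channels are
#'     deduplicated with precedence dictionary > rule > external;
#'   \item overlapping retained mentions of *different* types are both
#'     kept, flagged via `overlap_flag`; same-type overlaps keep the
#'     higher-precedence, then longer, mention.
#' }
#'
#' @param dictionary_mentions,rule_mentions,external_mentions Mention
#'   data.frames (any may be empty).
#' @param lexicon A `gerolit_lexicon` (the retention gate).
#' @return The reconciled mention data.frame, ordered by sentence and span.
#' @export
reconcile_mentions <- function(dictionary_mentions, rule_mentions = NULL,
                               external_mentions = NULL, lexicon) {
  rule_mentions <- rule_mentions %||% .empty_mentions()
  external_mentions <- external_mentions %||% .empty_mentions()

  # retention gate on the external channel
  if (nrow(external_mentions) > 0) {
    kept <- list()
    for (i in seq_len(nrow(external_mentions))) {
      m <- external_mentions[i, ]
      pref <- .EXTERNAL_TYPE_MAP[[tolower(m$entity_type)]] %||% .ENTITY_TYPES
      nm <- NULL
      for (tp in pref) {
        nm <- normalize_entity(m$surface, tp, lexicon)
        if (!is.null(nm)) break
      }
      if (is.null(nm) && !is.na(m$canonical_id))
        for (tp in pref) {
          nm <- normalize_entity(m$canonical_id, tp, lexicon)
          if (!is.null(nm)) break
        }
      if (is.null(nm)) next  # gate: not in any dictionary
      m$entity_type <- nm$entity_type
      m$canonical_id <- nm$canonical_id
      m$canonical_name <- nm$canonical_name
      kept[[length(kept) + 1L]] <- m
    }
    external_mentions <- if (length(kept)) do.call(rbind, kept)
      else .empty_mentions()
  }

  all_m <- rbind(dictionary_mentions, rule_mentions, external_mentions)
  if (nrow(all_m) == 0) return(.empty_mentions())

  prec <- c(dictionary = 1L, rule = 2L, external = 3L)
  all_m <- all_m[order(all_m$pmid, all_m$sentence_index, all_m$start,
                       all_m$entity_type, prec[all_m$method],
                       -(all_m$end - all_m$start)), , drop = FALSE]
  # exact-duplicate spans of the same type: keep highest precedence
  key <- paste(all_m$pmid, all_m$sentence_index, all_m$start, all_m$end,
               all_m$entity_type)
  all_m <- all_m[!duplicated(key), , drop = FALSE]

  # same-type overlap resolution (precedence then length, via sort order)
  keep <- rep(TRUE, nrow(all_m))
  sk <- paste(all_m$pmid, all_m$sentence_index, all_m$entity_type)
  for (grp in split(seq_len(nrow(all_m)), sk)) {
    g <- grp[order(prec[all_m$method[grp]],
                   -(all_m$end[grp] - all_m$start[grp]), all_m$start[grp])]
    taken <- list()
    for (i in g) {
      overl <- any(vapply(taken, function(t)
        all_m$start[i] < t[2] && all_m$end[i] > t[1], logical(1)))
      if (overl) keep[i] <- FALSE
      else taken[[length(taken) + 1L]] <- c(all_m$start[i], all_m$end[i])
    }
  }
  all_m <- all_m[keep, , drop = FALSE]

  # flag cross-type overlaps
  all_m$overlap_flag <- FALSE
  ck <- paste(all_m$pmid, all_m$sentence_index)
  for (grp in split(seq_len(nrow(all_m)), ck)) {
    if (length(grp) < 2) next
    for (a in grp) for (b in grp) {
      if (a < b && all_m$entity_type[a] != all_m$entity_type[b] &&
          all_m$start[a] < all_m$end[b] && all_m$end[a] > all_m$start[b]) {
        all_m$overlap_flag[c(a, b)] <- TRUE
      }
    }
  }
  all_m <- all_m[order(all_m$pmid, all_m$sentence_index, all_m$start,
                       all_m$entity_type), , drop = FALSE]
  rownames(all_m) <- NULL
  all_m
}

#' Annotate a whole sentence table
#'
#' Convenience wrapper: dictionary + rule channels per sentence, optional
#' external mentions, reconciled with [reconcile_mentions()].
#'
#' @param sentences Sentence data.frame (heading-stripped).
#' @param lexicon A `gerolit_lexicon`.
#' @param external_mentions Optional mention data.frame from
#'   [external_to_mentions()].
#' @return The reconciled mention data.frame.
#' @export
annotate_sentences <- function(sentences, lexicon, external_mentions = NULL) {
  dict <- list(); rule <- list()
  for (i in seq_len(nrow(sentences))) {
    s <- sentences[i, ]
    dict[[i]] <- match_dictionary(s, lexicon)
    rule[[i]] <- match_rna_rules(s)
  }
  reconcile_mentions(
    if (length(dict)) do.call(rbind, dict) else .empty_mentions(),
    if (length(rule)) do.call(rbind, rule) else .empty_mentions(),
    external_mentions, lexicon)
}
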