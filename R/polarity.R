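## Relation polarity and aging/longevity biomarker identification.
##
## Positive and association relations between a molecular entity and a
## disease are aging-promoting evidence; negative (preventive or
## ameliorative) relations are longevity-promoting evidence.

#' The polarity lexicon
#'
#' Three pairwise-disjoint sets of verb lemmas. The `seed` members are the
#' canonical example verbs of each class (lead/cause, associated/related,
#' prevent/ameliorate); the remainder are conservative extensions, tagged
#' so users can audit or restrict the configuration.
#'
#' @param seeds_only If TRUE, return only the seed verbs.
#' @return `list(positive=, association=, negative=)` of character
#'   vectors, each carrying a `"seed"` attribute marking seed members.
#' @export
polarity_lexicon <- function(seeds_only = FALSE) {
  mk <- function(seed, ext) {
    v <- c(seed, if (!seeds_only) ext)
    attr(v, "seed") <- v %in% seed
    v
  }
  lex <- list(
    positive = mk(c("lead", "cause"),
                  c("induce", "promote", "increase", "contribute")),
    association = mk(c("associate", "relate"),
                     c("correlate", "link")),
    negative = mk(c("prevent", "ameliorate"),
                  c("inhibit", "reduce", "suppress", "protect"))
  )
  .validate_polarity_lexicon(lex)
  lex
}

.validate_polarity_lexicon <- function(lex) {
  .stop_if(!all(c("positive", "association", "negative") %in% names(lex)),
           "polarity lexicon needs positive/association/negative sets")
  v <- c(lex$positive, lex$association, lex$negative)
  .stop_if(anyDuplicated(v) > 0,
           "polarity classes must be pairwise disjoint: ",
           paste(unique(v[duplicated(v)]), collapse = ", "))
  invisible(lex)
}

## crude inflection stripper so passive participles ("caused", "linked")
## and 3rd-person forms resolve to their lemma before lookup
.verb_lemma_guess <- function(word, known) {
  w <- tolower(word)
  if (w %in% known) return(w)
  cands <- c(sub("ed$", "", w), sub("ed$", "e", w), sub("d$", "", w),
             sub("s$", "", w), sub("es$", "", w), sub("ies$", "y", w),
             sub("ing$", "", w), sub("ing$", "e", w))
  hit <- cands[cands %in% known]
  if (length(hit)) hit[1] else w
}

#' Classify the polarity of a relation triple
#'
#' The head-verb lemma of the relation phrase is looked up in the three
#' polarity classes; `"unknown"` when absent from all. Passive-derived
#' surface forms are lemmatized before lookup ("caused" -> cause).
#'
#' @param triple One-row triple data.frame (uses `head_lemma`, falling
#'   back to the first word of `relation`).
#' @param lexicon A polarity lexicon, see [polarity_lexicon()].
#' @return One of `"positive"`, `"association"`, `"negative"`,
#'   `"unknown"`.
#' @export
classify_polarity <- function(triple, lexicon = polarity_lexicon()) {
  .validate_polarity_lexicon(lexicon)
  known <- tolower(c(lexicon$positive, lexicon$association,
                     lexicon$negative))
  head_word <- triple$head_lemma
  if (is.null(head_word) || is.na(head_word) || !nzchar(head_word))
    head_word <- strsplit(triple$relation, " ", fixed = TRUE)[[1]][1]
  lemma <- .verb_lemma_guess(head_word, known)
  if (lemma %in% tolower(lexicon$positive)) return("positive")
  if (lemma %in% tolower(lexicon$association)) return("association")
  if (lemma %in% tolower(lexicon$negative)) return("negative")
  "unknown"
}

#' Classify polarity for a whole triple table
#'
#' @param triples Triple data.frame.
#' @inheritParams classify_polarity
#' @return The data.frame with its `polarity` column filled.
#' @export
classify_triples <- function(triples, lexicon = polarity_lexicon()) {
  if (nrow(triples) == 0) return(triples)
  triples$polarity <- vapply(seq_len(nrow(triples)), function(i)
    classify_polarity(triples[i, ], lexicon), character(1))
  triples
}

#' Identify aging and longevity biomarkers
#'
#' A non-disease entity is called an *aging* biomarker when it has at
#' least one positive or association relation with a disease entity, and
#' a *longevity* biomarker when it has at least one negative relation
#' with a disease entity; an entity may receive both calls. Triple
#' orientation is ignored by default (entity--disease in either direction
#' counts); set `strict_direction = TRUE` to require the entity on the
#' source side. Unknown-polarity triples and entity--entity triples
#' contribute nothing.
#'
#' @param triples Triple data.frame (polarity filled; otherwise it is
#'   computed with `lexicon`).
#' @param lexicon Polarity lexicon used if polarities are missing.
#' @param strict_direction Require entity -> disease orientation.
#' @return Data.frame with one row per (entity, class):
#'   `canonical_id`, `canonical_name`, `entity_type`, `biomarker_class`,
#'   `n_support`, plus list columns `disease_partners` and `support`
#'   (row indices into `triples`).
#' @export
identify_biomarkers <- function(triples, lexicon = polarity_lexicon(),
                                strict_direction = FALSE) {
  empty <- data.frame(canonical_id = character(),
                      canonical_name = character(),
                      entity_type = character(),
                      biomarker_class = character(),
                      n_support = integer(), stringsAsFactors = FALSE)
  empty$disease_partners <- list(); empty$support <- list()
  if (nrow(triples) == 0) return(empty)
  if (all(is.na(triples$polarity))) triples <- classify_triples(triples, lexicon)

  side <- function(i, which) triples[[paste0(which, "_", "type")]][i]
  rows <- list()
  for (i in seq_len(nrow(triples))) {
    pol <- triples$polarity[i]
    if (is.na(pol) || pol == "unknown") next
    cls <- if (pol %in% c("positive", "association")) "aging" else "longevity"
    # entity -> disease orientation
    if (triples$source_type[i] != "disease" &&
        triples$target_type[i] == "disease") {
      rows[[length(rows) + 1L]] <- list(
        id = triples$source_id[i], name = triples$source_name[i],
        type = triples$source_type[i], cls = cls,
        partner = triples$target_id[i], row = i)
    }
    # disease -> entity orientation (unless strict)
    if (!strict_direction && triples$source_type[i] == "disease" &&
        triples$target_type[i] != "disease") {
      rows[[length(rows) + 1L]] <- list(
        id = triples$target_id[i], name = triples$target_name[i],
        type = triples$target_type[i], cls = cls,
        partner = triples$source_id[i], row = i)
    }
  }
  if (length(rows) == 0) return(empty)
  key <- vapply(rows, function(r) paste(r$id, r$type, r$cls), character(1))
  out <- lapply(split(rows, key), function(grp) {
    df <- data.frame(canonical_id = grp[[1]]$id,
                     canonical_name = grp[[1]]$name,
                     entity_type = grp[[1]]$type,
                     biomarker_class = grp[[1]]$cls,
                     n_support = length(grp), stringsAsFactors = FALSE)
    df$disease_partners <- list(sort(unique(vapply(grp, `[[`, character(1),
                                                   "partner"))))
    df$support <- list(vapply(grp, `[[`, integer(1), "row"))
    df
  })
  res <- do.call(rbind, out)
  res <- res[order(res$biomarker_class, res$canonical_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
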