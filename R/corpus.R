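## Literature ingestion, selection filters and sentence segmentation.

# The 14 title/abstract search terms of the retrieval expression, in order.
.QUERY_TERMS <- c(
  "aging", "ageing", "longevity", "centenarian", "the elderly", "the aged",
  "old people", "older people", "old age", "gerontology", "geroscience",
  "lifespan", "healthspan", "life expectancy"
)

#' PubMed retrieval expression for the aging/longevity corpus
#'
#' Returns the full PubMed query used to delimit the human aging and
#' longevity literature: fourteen title/abstract terms OR-joined, restricted
#' to journal articles, human studies (MeSH) and English language. The
#' string is constant; it is reproduced so that a corpus can be re-retrieved
#' (with any Entrez client) or audited.
#'
#' @return A single character string.
#' @examples
#' q <- build_query()
#' grepl("centenarian", q)
#' @export
build_query <- function() {
  ta <- paste(sprintf("“%s” [Title/Abstract]", .QUERY_TERMS),
              collapse = " OR ")
  paste0(
    "(", ta,
    " AND “Journal Article” [ptyp]",
    " AND “humans” [MeSH Terms]",
    " AND “English” [lang])"
  )
}

.RECORD_COLS <- c(
  "pmid", "title", "abstract", "journal_title", "journal_abbrev",
  "impact_factor", "impact_factor_5yr", "pub_date", "language", "place",
  "source"
)

.empty_corpus <- function() {
  df <- data.frame(
    pmid = character(), title = character(), abstract = character(),
    journal_title = character(), journal_abbrev = character(),
    impact_factor = numeric(), impact_factor_5yr = numeric(),
    pub_date = character(), language = character(), place = character(),
    source = character(), stringsAsFactors = FALSE
  )
  df$authors <- list()
  df$pub_types <- list()
  df
}

.record_row <- function(x) {
  df <- data.frame(
    pmid = .opt_chr(x$pmid),
    title = .opt_chr(x$title) %||% NA_character_,
    abstract = .opt_chr(x$abstract),
    journal_title = .opt_chr(x$journal_title),
    journal_abbrev = .opt_chr(x$journal_abbrev),
    impact_factor = .opt_num(x$impact_factor),
    impact_factor_5yr = .opt_num(x$impact_factor_5yr),
    pub_date = .opt_chr(x$pub_date),
    language = .opt_chr(x$language),
    place = .opt_chr(x$place),
    source = .opt_chr(x$source),
    stringsAsFactors = FALSE
  )
  df$abstract[is.na(df$abstract)] <- ""
  df$authors <- list(as.character(x$authors %||% character()))
  df$pub_types <- list(as.character(x$pub_types %||% character()))
  df
}

.validate_corpus <- function(corpus) {
  bad <- is.na(corpus$pmid) | !nzchar(corpus$pmid)
  .stop_if(any(bad), "literature record without a PMID (record ",
           paste(which(bad), collapse = ", "), ")")
  dup <- corpus$pmid[duplicated(corpus$pmid)]
  .stop_if(length(dup) > 0, "duplicate PMID in corpus: ",
           paste(unique(dup), collapse = ", "))
  corpus
}

#' Read literature records
#'
#' Reads article records from one of two common PubMed export dialects:
#' \describe{
#'   \item{`medline-json`}{a JSON array of objects with fields `pmid`,
#'     `title`, `abstract`, `journal_title`, `journal_abbrev`,
#'     `impact_factor`, `impact_factor_5yr`, `pub_date`, `authors`,
#'     `pub_types`, `language`, `place`, `source`; all but `pmid` optional.}
#'   \item{`tagged-field`}{the MEDLINE tagged format (`PMID- `, `TI  - `,
#'     `AB  - `, `JT  - `, `TA  - `, `DP  - `, `AU  - `, `PT  - `,
#'     `LA  - `, `PL  - `, `SO  - `), records separated by blank lines,
#'     continuation lines indented six spaces.}
#' }
#' Missing optional fields are kept absent (`NA`/empty), never fabricated;
#' a missing abstract becomes the empty string so downstream filters can
#' test it. PMIDs must be unique.
#'
#' @param path Path to the export file.
#' @param format `"medline-json"` or `"tagged-field"`.
#' @return A data.frame with one row per article (list columns `authors`,
#'   `pub_types`).
#' @export
read_literature <- function(path, format = c("medline-json", "tagged-field")) {
  format <- match.arg(format)
  .stop_if(!file.exists(path), "file not found: ", path)
  recs <- switch(format,
    "medline-json" = .read_medline_json(path),
    "tagged-field" = .read_tagged_field(path)
  )
  if (length(recs) == 0) return(.empty_corpus())
  corpus <- do.call(rbind, lapply(recs, .record_row))
  rownames(corpus) <- NULL
  .validate_corpus(corpus)
}

.read_medline_json <- function(path) {
  recs <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed JSON in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  .stop_if(!is.list(recs), "expected a JSON array of records in ", path)
  recs
}

.read_tagged_field <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  cur <- NULL
  tag <- NULL
  flush <- function(cur) if (!is.null(cur) && length(cur)) cur else NULL
  push <- function() {
    if (!is.null(cur) && length(cur)) recs[[length(recs) + 1L]] <<- cur
    cur <<- NULL; tag <<- NULL
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) { push(); next }
    if (grepl("^[A-Z0-9]{1,4} *- ", ln)) {
      tag <- trimws(sub("^([A-Z0-9]{1,4}) *- .*$", "\\1", ln))
      val <- sub("^[A-Z0-9]{1,4} *- ", "", ln)
      if (is.null(cur)) cur <- list()
      cur[[tag]] <- c(cur[[tag]], val)
    } else if (grepl("^ {6}", ln) && !is.null(tag)) {
      n <- length(cur[[tag]])
      cur[[tag]][n] <- paste(cur[[tag]][n], trimws(ln))
    } else {
      stop("malformed tagged-field line ", i, " in ", path, ": ", ln,
           call. = FALSE)
    }
  }
  push()
  lapply(recs, function(r) list(
    pmid = r$PMID,
    title = if (is.null(r$TI)) NULL else paste(r$TI, collapse = " "),
    abstract = if (is.null(r$AB)) NULL else paste(r$AB, collapse = " "),
    journal_title = r$JT, journal_abbrev = r$TA, pub_date = r$DP,
    authors = r$AU, pub_types = r$PT, language = r$LA, place = r$PL,
    source = r$SO
  ))
}

#' Select the working corpus
#'
#' Keeps exactly the records that (a) have a nonempty abstract and (b)
#' carry at least one species annotation equal to taxon `"9606"`
#' (*Homo sapiens*). Input order is preserved; the operation is idempotent.
#'
#' @param corpus Data.frame from [read_literature()].
#' @param species Data.frame with columns `pmid`, `taxon_id` (e.g. from
#'   [read_pubtator()]).
#' @return The filtered corpus data.frame.
#' @export
filter_corpus <- function(corpus, species) {
  if (nrow(corpus) == 0) return(corpus)
  has_abs <- !is.na(corpus$abstract) & nzchar(trimws(corpus$abstract))
  human <- unique(species$pmid[species$taxon_id == "9606"])
  keep <- has_abs & corpus$pmid %in% human
  out <- corpus[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## abbreviations whose trailing period never ends a sentence
.ABBREVS <- c("vs", "e.g", "i.e", "etc", "et al", "al", "cf", "ca", "approx",
              "fig", "figs", "dr", "no", "st", "resp")

.empty_sentences <- function() {
  data.frame(pmid = character(), index = integer(), text = character(),
             char_start = integer(), char_end = integer(),
             stringsAsFactors = FALSE)
}

#' Split an abstract into sentences
#'
#' Rule-based, abbreviation-aware segmentation: a boundary is a run of
#' `.`, `!` or `?` followed by whitespace, unless the token ending at the
#' period is a known abbreviation (`vs.`, `e.g.`, `et al.`, ...) or a single
#' capital initial. Offsets are 0-based half-open into the abstract and
#' each sentence's `text` equals the corresponding abstract slice.
#'
#' @param record A single-row corpus data.frame (or a list with `pmid` and
#'   `abstract`).
#' @return Data.frame with columns `pmid`, `index`, `text`, `char_start`,
#'   `char_end`.
#' @export
segment_sentences <- function(record) {
  pmid <- as.character(record$pmid)[1]
  abstract <- as.character(record$abstract)[1]
  if (is.na(abstract) || !nzchar(trimws(abstract))) return(.empty_sentences())

  chars <- strsplit(abstract, "", fixed = TRUE)[[1]]
  n <- length(chars)
  bounds <- integer(0)  # index of last char of each sentence
  i <- 1L
  while (i <= n) {
    if (chars[i] %in% c(".", "!", "?")) {
      j <- i
      while (j < n && chars[j + 1L] %in% c(".", "!", "?")) j <- j + 1L
      if (j == n || grepl("\\s", chars[j + 1L])) {
        # token preceding the period run (letters and internal periods)
        k <- i - 1L
        while (k >= 1 && grepl("[A-Za-z.]", chars[k])) k <- k - 1L
        tok <- if (i - 1L >= k + 1L) tolower(substr(abstract, k + 1L, i - 1L)) else ""
        # a single letter only counts as an initial when word-initial
        # ("J. Smith"), not at the tail of an identifier ("hsa-miR-34a.")
        is_initial <- grepl("^[a-z]$", tok) &&
          (k < 1L || grepl("\\s", chars[k]))
        is_abbrev <- chars[i] == "." && j == i &&
          (tok %in% .ABBREVS || is_initial)
        if (!is_abbrev || j == n) bounds <- c(bounds, j)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(bounds) == 0 || bounds[length(bounds)] < n) bounds <- c(bounds, n)

  start <- 1L
  rows <- list()
  idx <- 0L
  for (b in bounds) {
    seg <- substr(abstract, start, b)
    # trim leading/trailing whitespace but keep offsets aligned
    lead <- nchar(seg) - nchar(sub("^\\s+", "", seg))
    trail <- nchar(seg) - nchar(sub("\\s+$", "", seg))
    s0 <- start + lead
    e0 <- b - trail
    if (e0 >= s0) {
      rows[[length(rows) + 1L]] <- data.frame(
        pmid = pmid, index = idx, text = substr(abstract, s0, e0),
        char_start = s0 - 1L, char_end = e0, stringsAsFactors = FALSE
      )
      idx <- idx + 1L
    }
    start <- b + 1L
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Strip an all-caps section heading from a sentence
#'
#' Abstracts often carry structured-section labels (`"CONCLUSION: ..."`,
#' `"METHODS: ..."`) that derail dependency parsing. If a sentence begins
#' with a run of two or more uppercase letters/spaces immediately followed
#' by a colon, that prefix, the colon and following whitespace are removed
#' and `char_start` advanced accordingly, so `text` still equals the
#' abstract slice. Mixed-case prefixes (`"Aging: a process"`) are left
#' alone. Idempotent.
#'
#' @param sentences Sentence data.frame from [segment_sentences()].
#' @return The data.frame with headings removed and offsets adjusted.
#' @export
strip_heading <- function(sentences) {
  if (nrow(sentences) == 0) return(sentences)
  m <- regexpr("^[A-Z][A-Z ]{1,}:\\s*", sentences$text)
  hit <- m == 1L & attr(m, "match.length") >= 3L
  # require >= 2 chars of caps before the colon
  for (i in which(hit)) {
    len <- attr(m, "match.length")[i]
    prefix <- substr(sentences$text[i], 1, len)
    caps <- sub(":\\s*$", "", prefix)
    if (nchar(gsub(" ", "", caps)) < 2) next
    sentences$text[i] <- substr(sentences$text[i], len + 1L,
                                nchar(sentences$text[i]))
    sentences$char_start[i] <- sentences$char_start[i] + len
  }
  sentences
}
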