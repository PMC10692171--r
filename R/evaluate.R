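## Set-overlap evaluation against reference gene lists and
## article-count entity ranking.

#' Compare an extracted gene set with a reference list
#'
#' The overlap percentage is computed against the *reference* set
#' (`100 * |ours ∩ reference| / |reference|`), matching the convention
#' "X% of the genes in the reference database overlapped with ours",
#' rounded half-up to one decimal. Symbols are compared case-insensitively
#' after trimming.
#'
#' @param ours,reference Character vectors of normalized gene symbols
#'   (duplicates ignored).
#' @param top_k Optional: also report the overlap among the first
#'   `top_k` elements of `ours` (taken in the given ranking order).
#' @return `list(ours_size, reference_size, overlap_size,
#'   percent_of_reference, top_k_overlap)`.
#' @export
compare_gene_sets <- function(ours, reference, top_k = NULL) {
  norm <- function(x) unique(toupper(trimws(x)))
  o <- norm(ours); r <- norm(reference)
  .stop_if(length(r) == 0,
           "empty reference set: overlap percentage undefined")
  ov <- length(intersect(o, r))
  out <- list(ours_size = length(o), reference_size = length(r),
              overlap_size = ov,
              percent_of_reference = round_half_up(100 * ov / length(r), 1),
              top_k_overlap = NULL)
  if (!is.null(top_k)) {
    topo <- norm(ours)[seq_len(min(top_k, length(norm(ours))))]
    out$top_k_overlap <- length(intersect(topo, r))
  }
  out
}

#' Synthetic gene sets with prescribed sizes and overlap
#'
#' Utility for arithmetic checks: builds two symbol sets of given sizes
#' sharing exactly `overlap` members.
#'
#' @param ours_size,reference_size,overlap Nonnegative counts with
#'   `overlap <= min(ours_size, reference_size)`.
#' @return `list(ours=, reference=)` character vectors.
#' @export
make_overlap_sets <- function(ours_size, reference_size, overlap) {
  .stop_if(overlap > min(ours_size, reference_size),
           "overlap exceeds a set size")
  shared <- sprintf("SHARED%05d", seq_len(overlap))
  list(
    ours = c(shared, sprintf("OURS%05d", seq_len(ours_size - overlap))),
    reference = c(shared, sprintf("REF%05d",
                                  seq_len(reference_size - overlap)))
  )
}

#' Rank entities by distinct-article count
#'
#' Entities (optionally restricted to one type and a year range) ranked
#' by the number of distinct PMIDs mentioning them, ties broken by symbol
#' order; the top `k` are returned.
#'
#' @param entity_records Data.frame with columns `canonical_id`, `pmid`
#'   and optionally `entity_type`, `year`.
#' @param k Number of entities to return (`k >= 1`).
#' @param year_range Optional `c(from, to)` filter on `year`.
#' @param type Optional entity type filter.
#' @return Data.frame `canonical_id`, `n_articles`, ranked.
#' @export
top_k_entities <- function(entity_records, k, year_range = NULL,
                           type = NULL) {
  .stop_if(k < 1, "k must be >= 1")
  df <- entity_records
  if (!is.null(type) && "entity_type" %in% names(df))
    df <- df[df$entity_type == type, , drop = FALSE]
  if (!is.null(year_range) && "year" %in% names(df)) {
    y <- as.integer(df$year)
    df <- df[!is.na(y) & y >= year_range[1] & y <= year_range[2], ,
             drop = FALSE]
  }
  if (nrow(df) == 0)
    return(data.frame(canonical_id = character(), n_articles = integer(),
                      stringsAsFactors = FALSE))
  counts <- vapply(split(df$pmid, df$canonical_id),
                   function(p) length(unique(p)), integer(1))
  out <- data.frame(canonical_id = names(counts),
                    n_articles = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_articles, out$canonical_id), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, k)
}
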