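## Knowledge-graph aggregation, graph-database CSV export, structured
## JSON export and direct/indirect path queries.

#' Aggregate mentions and triples into a weighted knowledge graph
#'
#' One node per canonical entity (isolated entities permitted), with
#' `frequency` = number of distinct PMIDs mentioning it; one directed
#' edge per (source, relation, target), with `weight` = number of
#' supporting (pmid, sentence) occurrences, so edge weights sum to the
#' number of retained triples. Node ids are `"<type>:<canonical_id>"`.
#' Relation phrases aggregate case-insensitively. Edge `type` is the
#' polarity class (modal over supporting triples, ties alphabetical).
#'
#' @param mentions Reconciled mention data.frame.
#' @param triples Classified triple data.frame.
#' @return A `gerolit_graph`: `list(nodes=, edges=)`.
#' @export
build_graph <- function(mentions, triples) {
  node_id <- function(type, id) paste0(type, ":", id)
  mk <- paste(mentions$entity_type, mentions$canonical_id)
  nodes <- do.call(rbind, lapply(split(seq_len(nrow(mentions)), mk),
                                 function(ix) {
    m <- mentions[ix, , drop = FALSE]
    data.frame(ID = node_id(m$entity_type[1], m$canonical_id[1]),
               name = m$canonical_name[1], type = m$entity_type[1],
               frequency = length(unique(m$pmid)),
               label = m$canonical_name[1], stringsAsFactors = FALSE)
  }))
  if (is.null(nodes)) nodes <- data.frame(ID = character(),
                                          name = character(),
                                          type = character(),
                                          frequency = integer(),
                                          label = character(),
                                          stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$ID), , drop = FALSE]
  rownames(nodes) <- NULL

  edges <- data.frame(start_ID = character(), end_ID = character(),
                      relation = character(), weight = integer(),
                      method = character(), type = character(),
                      stringsAsFactors = FALSE)
  if (nrow(triples) > 0) {
    s_id <- node_id(triples$source_type, triples$source_id)
    t_id <- node_id(triples$target_type, triples$target_id)
    missing <- unique(c(s_id[!s_id %in% nodes$ID], t_id[!t_id %in% nodes$ID]))
    .stop_if(length(missing) > 0,
             "triple references entity absent from mentions: ",
             paste(missing, collapse = ", "))
    ek <- paste(s_id, t_id, tolower(triples$relation), sep = "\r")
    edges <- do.call(rbind, lapply(split(seq_len(nrow(triples)), ek),
                                   function(ix) {
      tr <- triples[ix, , drop = FALSE]
      pol <- tr$polarity[!is.na(tr$polarity)]
      pol <- if (length(pol)) names(sort(table(pol), decreasing = TRUE))[1]
        else "unknown"
      data.frame(start_ID = s_id[ix[1]], end_ID = t_id[ix[1]],
                 relation = tolower(tr$relation[1]),
                 weight = length(ix),
                 method = paste(sort(unique(tr$method)), collapse = ";"),
                 type = pol, stringsAsFactors = FALSE)
    }))
    edges <- edges[order(edges$start_ID, edges$end_ID, edges$relation), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges), class = "gerolit_graph")
}

#' @export
print.gerolit_graph <- function(x, ...) {
  cat("<gerolit_graph> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (total weight ", sum(x$edges$weight), ")\n", sep = "")
  invisible(x)
}

#' Write the graph as graph-database bulk-import CSVs
#'
#' Emits `Entities.csv` (header `ID,name,type,frequency,label`) and
#' `Roles.csv` (header `start_ID,end_ID,relation,weight,method,type`),
#' UTF-8 with RFC 4180 quoting, suitable for Neo4j bulk import.
#'
#' @param graph A `gerolit_graph`.
#' @param directory Output directory (created if needed).
#' @return Paths of the two files, invisibly.
#' @export
write_neo4j_csv <- function(graph, directory) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  .stop_if(!dir.exists(directory), "cannot create directory: ", directory)
  ents <- file.path(directory, "Entities.csv")
  roles <- file.path(directory, "Roles.csv")
  write_rfc4180(graph$nodes, ents)
  write_rfc4180(graph$edges, roles)
  invisible(c(ents, roles))
}

#' Read a graph back from bulk-import CSVs
#'
#' Inverse of [write_neo4j_csv()]; round-trips the node and edge tables.
#'
#' @param directory Directory holding `Entities.csv` and `Roles.csv`.
#' @return A `gerolit_graph`.
#' @export
read_neo4j_csv <- function(directory) {
  ents <- file.path(directory, "Entities.csv")
  roles <- file.path(directory, "Roles.csv")
  .stop_if(!file.exists(ents) || !file.exists(roles),
           "Entities.csv / Roles.csv not found in ", directory)
  nodes <- utils::read.csv(ents, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  edges <- utils::read.csv(roles, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  nodes$frequency <- as.integer(nodes$frequency)
  edges$weight <- as.integer(edges$weight)
  structure(list(nodes = nodes, edges = edges), class = "gerolit_graph")
}

#' Query direct and indirect paths between two entities
#'
#' Simple paths between two nodes in the undirected view of the graph
#' with hop count in `[min_hops, max_hops]`. Length-1 paths are direct
#' relations (a triple from a single sentence); longer paths are
#' indirect, predicted relations spanning several sentences.
#'
#' @param graph A `gerolit_graph`.
#' @param entity_a,entity_b Node ids (`"<type>:<canonical_id>"`).
#' @param min_hops,max_hops Path length bounds, `1 <= min <= max`.
#' @return List of character vectors of node ids (each path includes
#'   both endpoints), ordered deterministically.
#' @export
query_paths <- function(graph, entity_a, entity_b, min_hops = 1,
                        max_hops = 2) {
  .stop_if(min_hops < 1 || max_hops < min_hops,
           "need 1 <= min_hops <= max_hops")
  .stop_if(!entity_a %in% graph$nodes$ID, "unknown entity: ", entity_a)
  .stop_if(!entity_b %in% graph$nodes$ID, "unknown entity: ", entity_b)
  if (nrow(graph$edges) == 0) return(list())
  g <- igraph::graph_from_data_frame(
    unique(graph$edges[, c("start_ID", "end_ID")]), directed = FALSE,
    vertices = graph$nodes$ID)
  paths <- igraph::all_simple_paths(g, from = entity_a, to = entity_b,
                                    cutoff = max_hops)
  out <- lapply(paths, function(p) igraph::as_ids(p))
  out <- out[vapply(out, length, integer(1)) - 1L >= min_hops]
  out[order(vapply(out, length, integer(1)),
            vapply(out, paste, character(1), collapse = "\r"))]
}

.TABLE2_FIELDS <- list(
  literature = c("PMID", "TI", "AB", "IF", "IF5", "AU", "FAU", "AD", "PT",
                 "DP", "PL", "JT", "TA", "SO"),
  entity = c("entity", "type", "official full name", "PMID", "sentence",
             "number of articles", "JT", "TA", "IF", "IF5", "years",
             "alias names", "description", "url", "mutation position",
             "mutation alleles", "MeSH ID", "relation", "external links",
             "aging biomarker", "longevity biomarker"),
  relation = c("source entity", "relationship", "target entity", "method",
               "sentence", "source", "target", "source type",
               "target type", "PMID", "DP", "date", "TI", "TA", "IF",
               "IF5"),
  biomarker = c("source entity", "relationship", "target entity",
                "sentence", "source", "target", "source type",
                "target type", "PMID", "DP", "date", "TI", "TA", "IF",
                "IF5")
)

#' Field schemas of the JSON exports
#'
#' @return Named list of character vectors (`literature`, `entity`,
#'   `relation`, `biomarker`).
#' @export
json_schemas <- function() .TABLE2_FIELDS

.year_of <- function(dp) {
  y <- regmatches(dp, regexpr("[0-9]{4}", dp))
  if (length(y)) y else NA_character_
}

.rec_lookup <- function(corpus, pmid) {
  i <- match(pmid, corpus$pmid)
  if (is.na(i)) NULL else corpus[i, , drop = FALSE]
}

.triple_record <- function(tr, rec, with_method = TRUE) {
  out <- list(
    "source entity" = tr$source_name,
    "relationship" = tr$relation,
    "target entity" = tr$target_name)
  if (with_method) out$method <- tr$method
  c(out, list(
    sentence = tr$sentence_text,
    source = tr$source_id,
    target = tr$target_id,
    "source type" = tr$source_type,
    "target type" = tr$target_type,
    PMID = tr$pmid,
    DP = if (!is.null(rec)) rec$pub_date else NA_character_,
    date = if (!is.null(rec)) .year_of(rec$pub_date) else NA_character_,
    TI = if (!is.null(rec)) rec$title else NA_character_,
    TA = if (!is.null(rec)) rec$journal_abbrev else NA_character_,
    IF = if (!is.null(rec)) rec$impact_factor else NA_real_,
    IF5 = if (!is.null(rec)) rec$impact_factor_5yr else NA_real_))
}

#' Write the five structured JSON exports
#'
#' Emits `Literature_Info.json`, `Entity_Info.json`,
#' `Relation_Info.json`, `Aging_Biomarkers.json` and
#' `Longevity_Biomarkers.json`, each an array of objects carrying exactly
#' the documented field names (see [json_schemas()]). Dangling
#' cross-references (a triple citing a PMID absent from the corpus, or a
#' biomarker support row out of range) are integrity errors.
#'
#' @param corpus Corpus data.frame (filtered).
#' @param mentions Reconciled mention data.frame.
#' @param triples Classified triple data.frame.
#' @param calls Biomarker call data.frame from [identify_biomarkers()].
#' @param lexicon Optional `gerolit_lexicon` for alias/external-link
#'   enrichment of `Entity_Info.json`.
#' @param directory Output directory.
#' @return Paths of the five files, invisibly.
#' @export
write_hald_json <- function(corpus, mentions, triples, calls, directory,
                            lexicon = NULL) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  bad <- unique(triples$pmid[!triples$pmid %in% corpus$pmid])
  .stop_if(length(bad) > 0, "triple references PMID absent from corpus: ",
           paste(bad, collapse = ", "))
  if (nrow(calls) > 0) {
    sup <- unlist(calls$support)
    .stop_if(any(sup < 1 | sup > nrow(triples)),
             "biomarker call references a triple out of range")
  }

  lit <- lapply(seq_len(nrow(corpus)), function(i) {
    r <- corpus[i, , drop = FALSE]
    list(PMID = r$pmid, TI = r$title, AB = r$abstract,
         IF = r$impact_factor, IF5 = r$impact_factor_5yr,
         AU = as.list(r$authors[[1]]), FAU = as.list(r$authors[[1]]),
         AD = list(), PT = as.list(r$pub_types[[1]]), DP = r$pub_date,
         PL = r$place, JT = r$journal_title, TA = r$journal_abbrev,
         SO = r$source)
  })

  aging_ids <- calls$canonical_id[calls$biomarker_class == "aging"]
  long_ids <- calls$canonical_id[calls$biomarker_class == "longevity"]
  mk <- paste(mentions$entity_type, mentions$canonical_id)
  ents <- lapply(split(seq_len(nrow(mentions)), mk), function(ix) {
    m <- mentions[ix, , drop = FALSE]
    cid <- m$canonical_id[1]; tp <- m$entity_type[1]
    pmids <- unique(m$pmid)
    recs <- corpus[match(pmids, corpus$pmid), , drop = FALSE]
    lx <- if (!is.null(lexicon)) {
      hit <- which(lexicon$entries$canonical_id == cid &
                     lexicon$entries$entity_type == tp)
      if (length(hit)) lexicon$entries[hit[1], , drop = FALSE] else NULL
    }
    rel <- unique(c(triples$relation[triples$source_id == cid |
                                       triples$target_id == cid]))
    list(
      entity = cid, type = tp,
      "official full name" = m$canonical_name[1],
      PMID = as.list(pmids),
      sentence = as.list(unique(paste0(m$pmid, ":", m$sentence_index))),
      "number of articles" = length(pmids),
      JT = as.list(recs$journal_title), TA = as.list(recs$journal_abbrev),
      IF = as.list(recs$impact_factor), IF5 = as.list(recs$impact_factor_5yr),
      years = as.list(vapply(recs$pub_date, .year_of, character(1),
                             USE.NAMES = FALSE)),
      "alias names" = if (!is.null(lx)) as.list(lx$surface_forms[[1]]) else list(),
      description = NA_character_, url = NA_character_,
      "mutation position" = if (!is.null(lx)) lx$mutation_position else NA_character_,
      "mutation alleles" = if (!is.null(lx)) lx$mutation_alleles else NA_character_,
      "MeSH ID" = if (!is.null(lx)) (lx$external_refs[[1]]$mesh_id %||% NA_character_) else NA_character_,
      relation = as.list(rel),
      "external links" = if (!is.null(lx)) lx$external_refs[[1]] else list(),
      "aging biomarker" = cid %in% aging_ids,
      "longevity biomarker" = cid %in% long_ids)
  })
  names(ents) <- NULL

  rels <- lapply(seq_len(nrow(triples)), function(i) {
    tr <- triples[i, , drop = FALSE]
    .triple_record(tr, .rec_lookup(corpus, tr$pmid), with_method = TRUE)
  })

  bio_rows <- function(cls) {
    ix <- sort(unique(unlist(calls$support[calls$biomarker_class == cls])))
    lapply(ix, function(i) {
      tr <- triples[i, , drop = FALSE]
      .triple_record(tr, .rec_lookup(corpus, tr$pmid), with_method = FALSE)
    })
  }

  paths <- file.path(directory, c(
    "Literature_Info.json", "Entity_Info.json", "Relation_Info.json",
    "Aging_Biomarkers.json", "Longevity_Biomarkers.json"))
  wj <- function(x, p) jsonlite::write_json(x, p, auto_unbox = TRUE,
                                            null = "null", na = "null",
                                            digits = NA)
  wj(lit, paths[1]); wj(ents, paths[2]); wj(rels, paths[3])
  wj(bio_rows("aging"), paths[4]); wj(bio_rows("longevity"), paths[5])
  invisible(paths)
}
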