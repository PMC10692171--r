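## Normalization dictionaries for the 10 entity types.
##
## Canonical identifiers follow the field's authorities: HGNC approved
## symbols for gene/RNA, MeSH unique IDs for the seven MeSH-derived
## categories, dbSNP rsIDs for mutations.

.ENTITY_TYPES <- c("gene", "rna", "carbohydrate", "peptide", "lipid",
                   "protein", "pharmaceutical_preparations", "toxin",
                   "mutation", "disease")

.MESH_CATEGORIES <- c("carbohydrate", "peptide", "lipid", "protein",
                      "pharmaceutical_preparations", "toxin", "disease")

#' The ten entity types recognized by the pipeline
#'
#' @return Character vector of type names.
#' @export
entity_types <- function() .ENTITY_TYPES

.new_lexicon <- function(entries) {
  entries$canonical_id <- as.character(entries$canonical_id)
  entries$canonical_name <- as.character(entries$canonical_name)
  obj <- list(entries = entries, index = .build_index(entries))
  class(obj) <- "gerolit_lexicon"
  obj
}

.empty_entries <- function() {
  df <- data.frame(canonical_id = character(), canonical_name = character(),
                   entity_type = character(),
                   mutation_position = character(),
                   mutation_alleles = character(),
                   stringsAsFactors = FALSE)
  df$surface_forms <- list()
  df$external_refs <- list()
  df
}

## index: case-folded surface form -> integer vector of entry rows
.build_index <- function(entries) {
  idx <- new.env(parent = emptyenv())
  if (nrow(entries) == 0) return(idx)
  for (i in seq_len(nrow(entries))) {
    for (s in unique(tolower(entries$surface_forms[[i]]))) {
      idx[[s]] <- c(idx[[s]], i)
    }
  }
  idx
}

#' @export
print.gerolit_lexicon <- function(x, ...) {
  tab <- table(x$entries$entity_type)
  cat("<gerolit_lexicon> ", nrow(x$entries), " entries, ",
      length(ls(x$index)), " surface forms\n", sep = "")
  for (tp in names(tab)) cat("  ", tp, ": ", tab[[tp]], "\n", sep = "")
  invisible(x)
}

.split_multi <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character())
  trimws(strsplit(x, "\\|")[[1]])
}

#' Build the gene/RNA lexicon from an HGNC-style table
#'
#' One entry per approved symbol; the approved symbol and name plus all
#' previous/alias symbols and names become surface forms; the NCBI gene id
#' is stored under `external_refs$ncbi_gene_id`. Multi-valued columns use
#' `|` as separator.
#'
#' @param hgnc_table Data.frame with columns `approved_symbol`,
#'   `approved_name`, `previous_symbols`, `alias_symbols`,
#'   `previous_names`, `alias_names`, `ncbi_gene_id` (missing auxiliary
#'   columns are tolerated; `approved_symbol` is required). An optional
#'   `locus_type` column routes RNA genes (`locus_type` containing "RNA")
#'   to entity type `rna`; default is `gene`.
#' @return A `gerolit_lexicon`.
#' @export
build_gene_rna_lexicon <- function(hgnc_table) {
  .stop_if(!"approved_symbol" %in% names(hgnc_table),
           "HGNC table lacks required column 'approved_symbol'")
  for (col in c("approved_name", "previous_symbols", "alias_symbols",
                "previous_names", "alias_names", "ncbi_gene_id",
                "locus_type")) {
    if (!col %in% names(hgnc_table))
      hgnc_table[[col]] <- rep(NA_character_, nrow(hgnc_table))
  }
  if (nrow(hgnc_table) == 0) return(.new_lexicon(.empty_entries()))
  rows <- lapply(seq_len(nrow(hgnc_table)), function(i) {
    r <- hgnc_table[i, ]
    sym <- as.character(r$approved_symbol)
    name <- .opt_chr(r$approved_name)
    forms <- unique(c(sym,
                      if (!is.na(name)) name,
                      .split_multi(.opt_chr(r$previous_symbols)),
                      .split_multi(.opt_chr(r$alias_symbols)),
                      .split_multi(.opt_chr(r$previous_names)),
                      .split_multi(.opt_chr(r$alias_names))))
    type <- if (grepl("RNA", .opt_chr(r$locus_type) %||% "", ignore.case = FALSE))
      "rna" else "gene"
    df <- data.frame(canonical_id = sym,
                     canonical_name = if (is.na(name)) sym else name,
                     entity_type = type,
                     mutation_position = NA_character_,
                     mutation_alleles = NA_character_,
                     stringsAsFactors = FALSE)
    df$surface_forms <- list(forms)
    df$external_refs <- list(list(ncbi_gene_id = .opt_chr(r$ncbi_gene_id)))
    df
  })
  .new_lexicon(do.call(rbind, rows))
}

#' Build a MeSH-category lexicon
#'
#' One entry per MeSH descriptor; every concept term becomes a surface
#' form; the MeSH unique ID is the canonical identifier and is also stored
#' under `external_refs$mesh_id`.
#'
#' @param mesh_records A list of records (or a data.frame) with fields
#'   `mesh_id`, `name`, `terms` (character vector of synonymous terms).
#' @param category One of carbohydrate, peptide, lipid, protein,
#'   pharmaceutical_preparations, toxin, disease. Genes come from HGNC,
#'   not MeSH; any other value is an error.
#' @return A `gerolit_lexicon`.
#' @export
build_mesh_lexicon <- function(mesh_records, category) {
  .stop_if(!is.character(category) || length(category) != 1 ||
             !category %in% .MESH_CATEGORIES,
           "unknown MeSH category: ", paste(category, collapse = ", "),
           " (expected one of ", paste(.MESH_CATEGORIES, collapse = ", "), ")")
  if (is.data.frame(mesh_records)) {
    mesh_records <- lapply(seq_len(nrow(mesh_records)), function(i) {
      r <- mesh_records[i, ]
      trs <- if (is.list(r$terms)) r$terms[[1]] else .split_multi(.opt_chr(r$terms))
      list(mesh_id = r$mesh_id, name = r$name, terms = trs)
    })
  }
  if (length(mesh_records) == 0) return(.new_lexicon(.empty_entries()))
  rows <- lapply(mesh_records, function(r) {
    name <- .opt_chr(r$name)
    forms <- unique(c(name, as.character(r$terms %||% character())))
    df <- data.frame(canonical_id = as.character(r$mesh_id),
                     canonical_name = name,
                     entity_type = category,
                     mutation_position = NA_character_,
                     mutation_alleles = NA_character_,
                     stringsAsFactors = FALSE)
    df$surface_forms <- list(forms)
    df$external_refs <- list(list(mesh_id = as.character(r$mesh_id)))
    df
  })
  .new_lexicon(do.call(rbind, rows))
}

#' Build the mutation lexicon from a dbSNP-style table
#'
#' One entry per rsID with `mutation_position` and `mutation_alleles`
#' populated; duplicate rsID rows are merged (surface forms unioned, first
#' nonmissing position/alleles kept). Rows whose `rsid` does not match
#' `rs<digits>` are skipped with a warning reporting the count.
#'
#' @param dbsnp_table Data.frame with columns `rsid`, `position`,
#'   `alleles` and optionally `labels` (`|`-separated extra surface forms).
#' @return A `gerolit_lexicon`.
#' @export
build_mutation_lexicon <- function(dbsnp_table) {
  for (col in c("rsid", "position", "alleles"))
    .stop_if(!col %in% names(dbsnp_table),
             "dbSNP table lacks required column '", col, "'")
  if (!"labels" %in% names(dbsnp_table))
    dbsnp_table$labels <- rep(NA_character_, nrow(dbsnp_table))
  if (nrow(dbsnp_table) == 0) return(.new_lexicon(.empty_entries()))
  ok <- grepl("^rs[0-9]+$", dbsnp_table$rsid)
  if (any(!ok)) {
    warning(sum(!ok), " dbSNP row(s) with malformed rsID skipped",
            call. = FALSE)
    dbsnp_table <- dbsnp_table[ok, , drop = FALSE]
  }
  if (nrow(dbsnp_table) == 0) return(.new_lexicon(.empty_entries()))
  rows <- lapply(split(seq_len(nrow(dbsnp_table)), dbsnp_table$rsid),
                 function(ix) {
    r <- dbsnp_table[ix, , drop = FALSE]
    rsid <- r$rsid[1]
    forms <- unique(c(rsid, unlist(lapply(r$labels, .split_multi))))
    df <- data.frame(canonical_id = rsid, canonical_name = rsid,
                     entity_type = "mutation",
                     mutation_position = .opt_chr(r$position[!is.na(r$position)]),
                     mutation_alleles = .opt_chr(r$alleles[!is.na(r$alleles)]),
                     stringsAsFactors = FALSE)
    df$surface_forms <- list(forms)
    df$external_refs <- list(list(dbsnp_id = rsid))
    df
  })
  ent <- do.call(rbind, rows)
  ent <- ent[order(ent$canonical_id), , drop = FALSE]
  rownames(ent) <- NULL
  .new_lexicon(ent)
}

#' Merge lexicons of different entity types into one
#'
#' @param ... `gerolit_lexicon` objects.
#' @return A combined `gerolit_lexicon`.
#' @export
combine_lexicons <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "gerolit_lexicon")) parts <- parts[[1]]
  ent <- do.call(rbind, lapply(parts, function(p) p$entries))
  rownames(ent) <- NULL
  .new_lexicon(ent)
}

#' Normalize a surface form to its canonical identifier
#'
#' Case-insensitive exact lookup of `surface` among the surface forms of
#' the given entity type. Ambiguous surfaces (one string indexing several
#' entries) resolve to the entry whose canonical id equals the surface
#' (case-insensitively), else to the first entry in sorted canonical-id
#' order; all candidates are attached as attribute `"candidates"`.
#' No match is signalled by returning `NULL`, not by an error.
#'
#' @param surface Character string as it appears in text.
#' @param entity_type One of the 10 entity types, or `NULL` to search all.
#' @param lexicon A `gerolit_lexicon`.
#' @return `list(canonical_id=, canonical_name=, entity_type=)` or `NULL`.
#' @export
normalize_entity <- function(surface, entity_type = NULL, lexicon) {
  rows <- lexicon$index[[tolower(surface)]]
  if (is.null(rows)) {
    # canonical identifiers (e.g. MeSH unique IDs) normalize to themselves
    # even when they are not prose surface forms
    rows <- which(tolower(lexicon$entries$canonical_id) == tolower(surface))
    if (length(rows) == 0) return(NULL)
  }
  ent <- lexicon$entries[rows, , drop = FALSE]
  if (!is.null(entity_type)) ent <- ent[ent$entity_type == entity_type, ,
                                        drop = FALSE]
  if (nrow(ent) == 0) return(NULL)
  ent <- ent[order(ent$canonical_id), , drop = FALSE]
  pick <- which(tolower(ent$canonical_id) == tolower(surface))
  i <- if (length(pick)) pick[1] else 1L
  out <- list(canonical_id = ent$canonical_id[i],
              canonical_name = ent$canonical_name[i],
              entity_type = ent$entity_type[i])
  if (nrow(ent) > 1) attr(out, "candidates") <- ent$canonical_id
  out
}

#' Serialize / deserialize a lexicon as JSON
#'
#' @param lexicon A `gerolit_lexicon`.
#' @param path Output (or input) file path.
#' @return `write_lexicon` returns `path` invisibly; `read_lexicon`
#'   returns a `gerolit_lexicon`.
#' @export
write_lexicon <- function(lexicon, path) {
  ent <- lexicon$entries
  recs <- lapply(seq_len(nrow(ent)), function(i) list(
    canonical_id = ent$canonical_id[i],
    canonical_name = ent$canonical_name[i],
    entity_type = ent$entity_type[i],
    surface_forms = ent$surface_forms[[i]],
    external_refs = ent$external_refs[[i]],
    mutation_position = ent$mutation_position[i],
    mutation_alleles = ent$mutation_alleles[i]
  ))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, null = "null",
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(recs) == 0) return(.new_lexicon(.empty_entries()))
  rows <- lapply(recs, function(r) {
    df <- data.frame(canonical_id = r$canonical_id,
                     canonical_name = r$canonical_name,
                     entity_type = r$entity_type,
                     mutation_position = .opt_chr(r$mutation_position),
                     mutation_alleles = .opt_chr(r$mutation_alleles),
                     stringsAsFactors = FALSE)
    df$surface_forms <- list(as.character(unlist(r$surface_forms)))
    df$external_refs <- list(r$external_refs)
    df
  })
  .new_lexicon(do.call(rbind, rows))
}
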