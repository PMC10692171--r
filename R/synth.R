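## Deterministic synthetic corpora: templated abstracts with known
## entities, controlled voice/negation/polarity, emitted together with
## their dependency parses and a gold standard for every pipeline stage.
##
## Templates emit their own CoNLL-U-style parses, so tests are hermetic
## (no parser model); the gold standard is derived from template
## knowledge, never by running the extraction code.

#' Synthetic-corpus configuration
#'
#' Defaults describe a plain literature-mining regime: three relational
#' sentences per abstract with 2-3 entities each, 30% passive voice, 10%
#' negated relations, a positive/association/negative verb mix of
#' 40/30/30, half of the relation targets disease entities, and a tenth
#' of the subjects are rule-recognizable RNA names absent from the
#' dictionaries. Passive templates are binary (subject + agent), so
#' three-entity sentences are always active.
#'
#' @param n_abstracts Number of abstracts.
#' @param sentences_per_abstract Relational sentences per abstract.
#' @param entities_per_sentence Integer range `c(min, max)` (2 or 3).
#' @param fraction_passive Probability a relation is expressed passively.
#' @param fraction_negated Probability a relation is negated (negated
#'   relations yield no gold triple).
#' @param polarity_mix Named probabilities over positive/association/
#'   negative; must sum to 1.
#' @param disease_fraction Probability a relation target is a disease.
#' @param rna_rule_fraction Probability the subject is a rule-based RNA
#'   name (miRNA/lincRNA) absent from the dictionaries.
#' @param distractor_prob Probability an abstract opens with an
#'   entity-free distractor sentence.
#' @param heading_prob Probability a sentence carries an all-caps section
#'   heading (stripped by the pipeline before parsing).
#' @param seed Integer RNG seed; the same seed reproduces the corpus
#'   exactly.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_abstracts = 100,
                         sentences_per_abstract = 3,
                         entities_per_sentence = c(2L, 3L),
                         fraction_passive = 0.3,
                         fraction_negated = 0.1,
                         polarity_mix = c(positive = 0.4,
                                          association = 0.3,
                                          negative = 0.3),
                         disease_fraction = 0.5,
                         rna_rule_fraction = 0.1,
                         distractor_prob = 0.5,
                         heading_prob = 0.3,
                         seed = 1L) {
  cfg <- list(n_abstracts = as.integer(n_abstracts),
              sentences_per_abstract = as.integer(sentences_per_abstract),
              entities_per_sentence = as.integer(entities_per_sentence),
              fraction_passive = fraction_passive,
              fraction_negated = fraction_negated,
              polarity_mix = polarity_mix,
              disease_fraction = disease_fraction,
              rna_rule_fraction = rna_rule_fraction,
              distractor_prob = distractor_prob,
              heading_prob = heading_prob,
              seed = as.integer(seed))
  probs <- c(cfg$fraction_passive, cfg$fraction_negated,
             cfg$disease_fraction, cfg$rna_rule_fraction,
             cfg$distractor_prob, cfg$heading_prob)
  .stop_if(any(probs < 0 | probs > 1), "probabilities must lie in [0, 1]")
  .stop_if(cfg$n_abstracts < 1, "n_abstracts must be >= 1")
  .stop_if(cfg$sentences_per_abstract < 1,
           "sentences_per_abstract must be >= 1")
  .stop_if(length(cfg$entities_per_sentence) != 2 ||
             cfg$entities_per_sentence[1] < 2 ||
             cfg$entities_per_sentence[2] > 3 ||
             cfg$entities_per_sentence[1] > cfg$entities_per_sentence[2],
           "entities_per_sentence must be a range within [2, 3]")
  .stop_if(!setequal(names(cfg$polarity_mix),
                     c("positive", "association", "negative")) ||
             abs(sum(cfg$polarity_mix) - 1) > 1e-8 ||
             any(cfg$polarity_mix < 0),
           "polarity_mix must be nonnegative over positive/association/",
           "negative and sum to 1")
  class(cfg) <- "synth_config"
  cfg
}

#' Source tables emulating HGNC, MeSH and dbSNP exports
#'
#' Small, fixed snapshots in the documented schemas: an HGNC-like gene/RNA
#' table (~50 approved symbols with previous/alias forms, including
#' deliberately ambiguous aliases such as "AP1" on two entries and
#' cross-type collisions such as "insulin" as both a gene name and a
#' pharmaceutical term), MeSH-like descriptor records for all seven
#' categories, and a dbSNP-like variant table. Real downloads in the same
#' schemas drop in unchanged.
#'
#' @return `list(hgnc = data.frame, mesh = named list of record lists,
#'   dbsnp = data.frame)`.
#' @export
fixture_lexicons <- function() {
  g <- function(sym, name, prev = NA, alias = NA, aliasn = NA, ncbi = NA,
                locus = "gene with protein product") {
    data.frame(approved_symbol = sym, approved_name = name,
               previous_symbols = prev, alias_symbols = alias,
               previous_names = NA_character_, alias_names = aliasn,
               ncbi_gene_id = as.character(ncbi), locus_type = locus,
               stringsAsFactors = FALSE)
  }
  hgnc <- rbind(
    g("TP53", "tumor protein p53", alias = "p53|LFS1", ncbi = 7157),
    g("SIRT1", "sirtuin 1", alias = "SIR2L1", ncbi = 23411),
    g("FOXO3", "forkhead box O3", prev = "FOXO3A", alias = "FKHRL1",
      ncbi = 2309),
    g("IGF1", "insulin like growth factor 1", alias = "IGFI",
      aliasn = "insulin-like growth factor 1|somatomedin C", ncbi = 3479),
    g("APOE", "apolipoprotein E", alias = "AD2", ncbi = 348),
    g("IL6", "interleukin 6", alias = "IFNB2", ncbi = 3569),
    g("TNF", "tumor necrosis factor", prev = "TNFA", alias = "cachectin",
      ncbi = 7124),
    g("CRP", "C-reactive protein", ncbi = 1401),
    g("INS", "insulin", ncbi = 3630),
    g("ALB", "albumin", ncbi = 213),
    g("MAPT", "microtubule associated protein tau", alias = "tau",
      ncbi = 4137),
    g("CD4", "CD4 molecule", ncbi = 920),
    g("CD8A", "CD8 subunit alpha", prev = "CD8", ncbi = 925),
    g("CDKN2A", "cyclin dependent kinase inhibitor 2A",
      alias = "p16|p16INK4a", ncbi = 1029),
    g("CDKN1A", "cyclin dependent kinase inhibitor 1A", alias = "p21",
      ncbi = 1026),
    g("TERT", "telomerase reverse transcriptase", alias = "hTERT",
      ncbi = 7015),
    g("KL", "klotho", alias = "KLOTHO", ncbi = 9365),
    g("MTOR", "mechanistic target of rapamycin kinase", prev = "FRAP1",
      ncbi = 2475),
    g("SOD2", "superoxide dismutase 2", alias = "MnSOD", ncbi = 6648),
    g("CAT", "catalase", ncbi = 847),
    g("GH1", "growth hormone 1", ncbi = 2688),
    g("GHR", "growth hormone receptor", ncbi = 2690),
    g("SIRT6", "sirtuin 6", ncbi = 51548),
    g("AKT1", "AKT serine/threonine kinase 1", alias = "PKB", ncbi = 207),
    g("JUN", "Jun proto-oncogene", alias = "AP1|c-Jun", ncbi = 3725),
    g("FOS", "Fos proto-oncogene", alias = "AP1|c-Fos", ncbi = 2353),
    g("NFE2L2", "NFE2 like bZIP transcription factor 2", alias = "NRF2",
      ncbi = 4780),
    g("TGFB1", "transforming growth factor beta 1", ncbi = 7040),
    g("VEGFA", "vascular endothelial growth factor A", prev = "VEGF",
      ncbi = 7422),
    g("BDNF", "brain derived neurotrophic factor", ncbi = 627),
    g("APP", "amyloid beta precursor protein", ncbi = 351),
    g("PSEN1", "presenilin 1", prev = "AD3", ncbi = 5663),
    g("LMNA", "lamin A/C", ncbi = 4000),
    g("WRN", "WRN RecQ like helicase", ncbi = 7486),
    g("ATM", "ATM serine/threonine kinase", ncbi = 472),
    g("PTEN", "phosphatase and tensin homolog", ncbi = 5728),
    g("EGFR", "epidermal growth factor receptor", prev = "ERBB",
      ncbi = 1956),
    g("ESR1", "estrogen receptor 1", ncbi = 2099),
    g("KLF4", "KLF transcription factor 4", ncbi = 9314),
    g("NAMPT", "nicotinamide phosphoribosyltransferase", alias = "visfatin",
      ncbi = 10135),
    g("PPARG", "peroxisome proliferator activated receptor gamma",
      ncbi = 5468),
    g("HIF1A", "hypoxia inducible factor 1 subunit alpha", ncbi = 3091),
    g("NFKB1", "nuclear factor kappa B subunit 1", ncbi = 4790),
    g("STAT3", "signal transducer and activator of transcription 3",
      ncbi = 6774),
    g("IGF1R", "insulin like growth factor 1 receptor", ncbi = 3480),
    g("MIR21", "microRNA 21", alias = "miRNA21", ncbi = 406991,
      locus = "RNA, micro"),
    g("MIR146A", "microRNA 146a", ncbi = 406938, locus = "RNA, micro"),
    g("TERC", "telomerase RNA component", ncbi = 7012,
      locus = "RNA, long non-coding"),
    g("NEAT1", "nuclear paraspeckle assembly transcript 1", ncbi = 283131,
      locus = "RNA, long non-coding"),
    g("XIST", "X inactive specific transcript", ncbi = 7503,
      locus = "RNA, long non-coding")
  )

  m <- function(id, name, terms = character()) {
    list(mesh_id = id, name = name, terms = terms)
  }
  mesh <- list(
    carbohydrate = list(
      m("D005947", "glucose", c("dextrose", "D-glucose")),
      m("D005632", "fructose"), m("D013395", "sucrose"),
      m("D006003", "glycogen"), m("D014199", "trehalose"),
      m("D007785", "lactose"), m("D008320", "maltose"),
      m("D007444", "inulin")),
    peptide = list(
      m("D005978", "glutathione", "GSH"),
      m("D054439", "ghrelin"), m("D000809", "angiotensin"),
      m("D010121", "oxytocin"), m("D014667", "vasopressin"),
      m("D004932", "endorphins"), m("D005971", "glucagon")),
    lipid = list(
      m("D002784", "cholesterol"), m("D002518", "ceramide", "ceramides"),
      m("D013109", "sphingomyelin"), m("D014280", "triglyceride",
                                       "triglycerides"),
      m("D010714", "phosphatidylcholine"), m("D002308", "cardiolipin")),
    protein = list(
      m("D005293", "ferritin", "ferritins"), m("D003094", "collagen"),
      m("D004549", "elastin"), m("D009211", "myoglobin"),
      m("D005340", "fibrinogen"), m("D014168", "transferrin"),
      m("D006454", "hemoglobin", "haemoglobin")),
    pharmaceutical_preparations = list(
      m("D008687", "metformin"), m("D020123", "rapamycin", "sirolimus"),
      m("D000077185", "resveratrol"), m("D001241", "aspirin",
                                        "acetylsalicylic acid"),
      m("D019821", "simvastatin"), m("D000077215", "quercetin"),
      m("D000069439", "dasatinib"), m("D013095", "spermidine"),
      m("D007328", "insulin")),
    toxin = list(
      m("D000348", "aflatoxin", "aflatoxins"),
      m("D009793", "ochratoxin", "ochratoxins"),
      m("D004731", "endotoxin", "endotoxins"),
      m("D012402", "rotenone"), m("D010269", "paraquat"),
      m("D000171", "acrolein")),
    disease = list(
      m("D055948", "sarcopenia"), m("D010024", "osteoporosis"),
      m("D003704", "dementia"), m("D050197", "atherosclerosis"),
      m("D003920", "diabetes", "diabetes mellitus"),
      m("D009369", "cancer", "neoplasms"),
      m("D020521", "stroke"), m("D006973", "hypertension"),
      m("D009765", "obesity"),
      m("D000073496", "frailty"), m("D002386", "cataract"),
      m("D001168", "arthritis"),
      m("D000544", "Alzheimer disease", "Alzheimer's disease"),
      m("D010300", "parkinsonism"), m("D007676", "nephropathy"))
  )

  dbsnp <- data.frame(
    rsid = c("rs429358", "rs7412", "rs2802292", "rs1042522", "rs1800795",
             "rs1800629", "rs10757278", "rs2811712", "rs1556516",
             "rs7859727"),
    position = c("19:44908684", "19:44908822", "6:108587315",
                 "17:7676154", "7:22727026", "6:31575254", "9:22124478",
                 "9:21998086", "9:22100176", "9:22102165"),
    alleles = c("T/C", "C/T", "G/T", "C/G", "G/C", "G/A", "A/G", "C/T",
                "C/G", "C/T"),
    labels = NA_character_,
    stringsAsFactors = FALSE
  )

  list(hgnc = hgnc, mesh = mesh, dbsnp = dbsnp)
}

#' Combined fixture lexicon over all 10 entity types
#'
#' @return A `gerolit_lexicon` built from [fixture_lexicons()].
#' @export
build_fixture_lexicon <- function() {
  src <- fixture_lexicons()
  parts <- c(list(build_gene_rna_lexicon(src$hgnc)),
             lapply(names(src$mesh), function(cat)
               build_mesh_lexicon(src$mesh[[cat]], cat)),
             list(build_mutation_lexicon(src$dbsnp)))
  combine_lexicons(parts)
}

## verb inventory: lemma, 3rd-person form, past participle, trailing
## preposition (NA = plain transitive), polarity class, usable voices
.VERB_TABLE <- data.frame(
  lemma = c("lead", "cause", "induce", "promote", "increase", "contribute",
            "associate", "relate", "correlate", "link",
            "prevent", "ameliorate", "inhibit", "reduce", "suppress",
            "protect"),
  third = c("leads", "causes", "induces", "promotes", "increases",
            "contributes", "associates", "relates", "correlates", "links",
            "prevents", "ameliorates", "inhibits", "reduces", "suppresses",
            "protects"),
  pastpart = c("led", "caused", "induced", "promoted", "increased",
               "contributed", "associated", "related", "correlated",
               "linked", "prevented", "ameliorated", "inhibited",
               "reduced", "suppressed", "protected"),
  prep = c("to", NA, NA, NA, NA, "to", "with", "to", "with", "to",
           NA, NA, NA, NA, NA, "against"),
  polarity = c(rep("positive", 6), rep("association", 4),
               rep("negative", 6)),
  active_ok = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                FALSE, TRUE, TRUE, FALSE,
                TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
  passive_ok = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE,
                 TRUE, TRUE, TRUE, TRUE,
                 TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
  stringsAsFactors = FALSE
)

.RULE_RNA_POOL <- c("hsa-miR-21", "hsa-miR-34a", "microRNA-146b",
                    "linc00662", "linc01234", "hsa-miR-126")

.DISTRACTORS <- c(
  "This prospective cohort was followed for twelve years.",
  "Recruitment and consent procedures are described elsewhere.",
  "An independent committee reviewed all outcome adjudications.",
  "Baseline characteristics were balanced between both arms.",
  "Analyses were prespecified in the trial registry."
)

.HEADINGS <- c("BACKGROUND:", "METHODS:", "RESULTS:", "CONCLUSION:")

## surfaces usable in templates: canonical surface maps to exactly one
## entry across the whole lexicon, is a single token and dictionary pools
## stay disjoint from the rule-RNA pool
.template_pool <- function(lexicon) {
  ent <- lexicon$entries
  ok <- vapply(seq_len(nrow(ent)), function(i) {
    s <- ent$canonical_id[i]
    if (ent$entity_type[i] %in% .MESH_CATEGORIES)
      s <- ent$canonical_name[i]
    !grepl(" ", s) &&
      length(lexicon$index[[tolower(s)]]) == 1 &&
      !tolower(s) %in% tolower(.RULE_RNA_POOL)
  }, logical(1))
  pool <- ent[ok, c("canonical_id", "canonical_name", "entity_type")]
  pool$surface <- ifelse(pool$entity_type %in% .MESH_CATEGORIES,
                         pool$canonical_name, pool$canonical_id)
  rownames(pool) <- NULL
  pool
}

.tok <- function(id, form, lemma, upos, xpos, head, deprel) {
  data.frame(id = id, form = form, lemma = lemma, upos = upos, xpos = xpos,
             head = head, deprel = deprel, stringsAsFactors = FALSE)
}

## build tokens for one relational sentence; returns list(tokens, text,
## entity_offsets = data.frame(slot, start, end))
.build_sentence <- function(verb, passive, negated, ents) {
  nent <- nrow(ents)
  prep <- verb$prep
  toks <- list()
  ent_tok <- integer(nent)  # token id of each entity

  add <- function(form, lemma, upos, xpos, head, deprel) {
    id <- length(toks) + 1L
    toks[[id]] <<- .tok(id, form, lemma, upos, xpos, head, deprel)
    id
  }
  if (!passive) {
    # E1 [does not] V(3rd|base) [prep] E2 [and E3] .
    # verb token id depends on negation
    vid <- if (negated) 4L else 2L
    ent_tok[1] <- add(ents$surface[1], ents$surface[1], "NOUN", "NN",
                      vid, "nsubj")
    if (negated) {
      add("does", "do", "AUX", "VBZ", vid, "aux")
      add("not", "not", "PART", "RB", vid, "advmod")
      add(verb$lemma, verb$lemma, "VERB", "VB", 0L, "root")
    } else {
      add(verb$third, verb$lemma, "VERB", "VBZ", 0L, "root")
    }
    if (!is.na(prep)) {
      pid <- add(prep, prep, "ADP", "IN", vid, "prep")
      ent_tok[2] <- add(ents$surface[2], ents$surface[2], "NOUN", "NN",
                        pid, "pobj")
    } else {
      ent_tok[2] <- add(ents$surface[2], ents$surface[2], "NOUN", "NN",
                        vid, "dobj")
    }
    if (nent == 3) {
      add("and", "and", "CCONJ", "CC", ent_tok[2], "cc")
      ent_tok[3] <- add(ents$surface[3], ents$surface[3], "NOUN", "NN",
                        ent_tok[2], "conj")
    }
    add(".", ".", "PUNCT", ".", vid, "punct")
  } else {
    # E2 is [not] V(pp) (by|prep) E1 .
    vid <- if (negated) 4L else 3L
    ent_tok[2] <- add(ents$surface[2], ents$surface[2], "NOUN", "NN",
                      vid, "nsubjpass")
    add("is", "be", "AUX", "VBZ", vid, "auxpass")
    if (negated) add("not", "not", "PART", "RB", vid, "advmod")
    add(verb$pastpart, verb$lemma, "VERB", "VBN", 0L, "root")
    marker <- if (verb$polarity == "association" && !is.na(prep)) prep
      else "by"
    pid <- add(marker, marker, "ADP", "IN", vid, "prep")
    ent_tok[1] <- add(ents$surface[1], ents$surface[1], "NOUN", "NN",
                      pid, "pobj")
    add(".", ".", "PUNCT", ".", vid, "punct")
  }
  tokens <- do.call(rbind, toks)
  # render text: space-joined words, final period attached
  words <- tokens$form
  n <- nrow(tokens)
  text <- paste(words[-n], collapse = " ")
  starts <- cumsum(c(0L, nchar(words[-n]) + 1L))[seq_len(n - 1)]
  text <- paste0(text, ".")
  offs <- data.frame(slot = seq_len(nent),
                     start = starts[ent_tok],
                     end = starts[ent_tok] + nchar(words[ent_tok]))
  list(tokens = tokens, text = text, entity_offsets = offs)
}

## gold relation phrase from template knowledge
.gold_phrase <- function(verb, passive) {
  if (!passive) {
    if (is.na(verb$prep)) verb$lemma else paste(verb$lemma, verb$prep)
  } else {
    if (verb$polarity == "association" && !is.na(verb$prep))
      paste(verb$pastpart, verb$prep)
    else verb$pastpart
  }
}

## gold biomarker calls straight from the template definition: a
## non-disease entity with a positive/association (resp. negative)
## relation to a disease is an aging (resp. longevity) biomarker.
## Deliberately written apart from identify_biomarkers() so the gold
## standard stays an independent oracle for the end-to-end checks.
.gold_calls <- function(triples) {
  empty <- data.frame(canonical_id = character(),
                      canonical_name = character(),
                      entity_type = character(),
                      biomarker_class = character(),
                      stringsAsFactors = FALSE)
  empty$disease_partners <- list()
  if (nrow(triples) == 0) return(empty)
  acc <- list()
  for (i in seq_len(nrow(triples))) {
    ent_side <- if (triples$source_type[i] != "disease" &&
                      triples$target_type[i] == "disease") "source"
      else if (triples$target_type[i] != "disease" &&
                 triples$source_type[i] == "disease") "target"
      else next
    dis_side <- if (ent_side == "source") "target" else "source"
    cls <- switch(triples$polarity[i],
                  positive = "aging", association = "aging",
                  negative = "longevity", next)
    key <- paste(triples[[paste0(ent_side, "_id")]][i], cls)
    acc[[key]] <- list(
      id = triples[[paste0(ent_side, "_id")]][i],
      name = triples[[paste0(ent_side, "_name")]][i],
      type = triples[[paste0(ent_side, "_type")]][i],
      cls = cls,
      partners = sort(unique(c(acc[[key]]$partners,
                               triples[[paste0(dis_side, "_id")]][i]))))
  }
  if (length(acc) == 0) return(empty)
  out <- do.call(rbind, lapply(acc, function(r) {
    df <- data.frame(canonical_id = r$id, canonical_name = r$name,
                     entity_type = r$type, biomarker_class = r$cls,
                     stringsAsFactors = FALSE)
    df$disease_partners <- list(r$partners)
    df
  }))
  out <- out[order(out$biomarker_class, out$canonical_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a synthetic corpus with gold standard
#'
#' Instantiates templated abstracts from the fixture lexicons under a
#' [synth_config()]: each relational sentence has a known subject entity
#' (dictionary entry or rule-recognizable RNA name), verb of a chosen
#' polarity class, voice, optional negation and one or two object
#' entities (diseases with probability `disease_fraction`); abstracts
#' may open with an entity-free distractor and sentences may carry
#' all-caps section headings. Parses are emitted from the templates
#' (deterministic, no parser model). The gold standard (mentions,
#' triples, biomarker calls) is derived from template knowledge only.
#' The same seed reproduces the corpus exactly.
#'
#' @param config A `synth_config`.
#' @param lexicon Optional `gerolit_lexicon`; defaults to
#'   [build_fixture_lexicon()].
#' @return `list(config, corpus, species, parses, gold, observed)` where
#'   `gold = list(mentions, triples, calls)` and `observed` reports the
#'   realized passive/negated fractions.
#' @export
generate_corpus <- function(config = synth_config(), lexicon = NULL) {
  .stop_if(!inherits(config, "synth_config"),
           "config must come from synth_config()")
  if (is.null(lexicon)) lexicon <- build_fixture_lexicon()
  pool <- .template_pool(lexicon)
  subj_pool <- pool[pool$entity_type != "disease", , drop = FALSE]
  dis_pool <- pool[pool$entity_type == "disease", , drop = FALSE]
  obj_pool <- subj_pool

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  journals <- data.frame(
    jt = c("Journal of Synthetic Gerontology", "Annals of Model Aging",
           "Archives of Template Biology"),
    ta = c("J Synth Gerontol", "Ann Model Aging", "Arch Template Biol"),
    stringsAsFactors = FALSE)

  recs <- list(); species <- list(); parses <- list()
  g_mentions <- list(); g_triples <- list()
  n_pass <- 0L; n_neg <- 0L; n_rel <- 0L

  for (a in seq_len(config$n_abstracts)) {
    pmid <- sprintf("9%07d", a)
    sent_texts <- character(0)
    sidx <- 0L
    if (stats::runif(1) < config$distractor_prob) {
      sent_texts <- sample(.DISTRACTORS, 1)
      sidx <- 1L
    }
    for (s in seq_len(config$sentences_per_abstract)) {
      passive <- stats::runif(1) < config$fraction_passive
      negated <- stats::runif(1) < config$fraction_negated
      pol <- sample(names(config$polarity_mix), 1,
                    prob = config$polarity_mix)
      vt <- .VERB_TABLE[.VERB_TABLE$polarity == pol &
                          (if (passive) .VERB_TABLE$passive_ok
                           else .VERB_TABLE$active_ok), , drop = FALSE]
      verb <- vt[sample(nrow(vt), 1), ]
      rng <- config$entities_per_sentence
      nent <- if (passive) 2L else if (rng[1] == rng[2]) rng[1] else
        sample(rng[1]:rng[2], 1)

      use_rule_rna <- stats::runif(1) < config$rna_rule_fraction
      e1 <- if (use_rule_rna) {
        surf <- sample(.RULE_RNA_POOL, 1)
        data.frame(canonical_id = surf, canonical_name = surf,
                   entity_type = "rna", surface = surf,
                   stringsAsFactors = FALSE)
      } else subj_pool[sample(nrow(subj_pool), 1), ]
      objs <- list()
      for (k in seq_len(nent - 1L)) {
        repeat {
          o <- if (stats::runif(1) < config$disease_fraction)
            dis_pool[sample(nrow(dis_pool), 1), ]
          else obj_pool[sample(nrow(obj_pool), 1), ]
          ids <- c(e1$canonical_id,
                   vapply(objs, function(x) x$canonical_id, character(1)))
          if (!o$canonical_id %in% ids) break
        }
        objs[[k]] <- o
      }
      ents <- do.call(rbind, c(list(e1), objs))
      built <- .build_sentence(verb, passive, negated, ents)

      n_rel <- n_rel + 1L
      if (passive) n_pass <- n_pass + 1L
      if (negated) n_neg <- n_neg + 1L

      heading <- stats::runif(1) < config$heading_prob
      stored_text <- if (heading)
        paste(sample(.HEADINGS, 1), built$text) else built$text
      sent_texts <- c(sent_texts, stored_text)

      key <- paste0(pmid, ":", sidx)
      parses[[key]] <- .new_parse(key, built$text, built$tokens)

      method <- c(if (use_rule_rna) "rule" else "dictionary",
                  rep("dictionary", nent - 1L))
      g_mentions[[length(g_mentions) + 1L]] <- data.frame(
        pmid = pmid, sentence_index = sidx,
        start = built$entity_offsets$start,
        end = built$entity_offsets$end,
        surface = ents$surface, entity_type = ents$entity_type,
        canonical_id = ents$canonical_id,
        canonical_name = ents$canonical_name,
        method = method, overlap_flag = FALSE, stringsAsFactors = FALSE)

      if (!negated) {
        phrase <- .gold_phrase(verb, passive)
        for (k in seq_len(nent - 1L)) {
          src <- if (passive) 1L else 1L  # subject is always the agent
          tgt <- k + 1L
          g_triples[[length(g_triples) + 1L]] <- data.frame(
            pmid = pmid, sentence_index = sidx,
            source_id = ents$canonical_id[src],
            source_name = ents$canonical_name[src],
            source_type = ents$entity_type[src],
            target_id = ents$canonical_id[tgt],
            target_name = ents$canonical_name[tgt],
            target_type = ents$entity_type[tgt],
            relation = phrase, head_lemma = verb$lemma,
            voice = if (passive) "passive" else "active",
            method = "shortest_path", polarity = verb$polarity,
            sentence_text = built$text, stringsAsFactors = FALSE)
        }
      }
      sidx <- sidx + 1L
    }

    jr <- journals[sample(nrow(journals), 1), ]
    year <- sample(2000:2023, 1)
    abs_text <- paste(sent_texts, collapse = " ")
    rec <- data.frame(
      pmid = pmid, title = paste("Synthetic abstract", a),
      abstract = abs_text, journal_title = jr$jt, journal_abbrev = jr$ta,
      impact_factor = round(stats::runif(1, 0.5, 30), 1),
      impact_factor_5yr = round(stats::runif(1, 0.5, 30), 1),
      pub_date = paste(year, sample(month.abb, 1)),
      language = "eng", place = "Nowhere", source = "Synthetic corpus",
      stringsAsFactors = FALSE)
    rec$authors <- list(c("Doe J", "Roe R"))
    rec$pub_types <- list("Journal Article")
    recs[[a]] <- rec
    species[[length(species) + 1L]] <- data.frame(
      pmid = pmid, taxon_id = "9606", stringsAsFactors = FALSE)
    if (stats::runif(1) < 0.2)
      species[[length(species) + 1L]] <- data.frame(
        pmid = pmid, taxon_id = "10090", stringsAsFactors = FALSE)
  }

  corpus <- do.call(rbind, recs); rownames(corpus) <- NULL
  gold_m <- do.call(rbind, g_mentions); rownames(gold_m) <- NULL
  gold_t <- if (length(g_triples)) do.call(rbind, g_triples)
    else .empty_triples()
  rownames(gold_t) <- NULL
  gold_calls <- .gold_calls(gold_t)

  list(config = config, corpus = corpus,
       species = do.call(rbind, species), parses = parses,
       gold = list(mentions = gold_m, triples = gold_t,
                   calls = gold_calls),
       observed = list(passive_fraction = n_pass / n_rel,
                       negated_fraction = n_neg / n_rel,
                       n_relational_sentences = n_rel))
}
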