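# gerolit

Literature mining of human aging and longevity research into a typed,
weighted knowledge graph, with aging/longevity biomarker calls.

Most of what is known about the molecular basis of human aging is
scattered across millions of PubMed abstracts. `gerolit` re-implements, as
a reusable and fully testable R pipeline, the workflow that turns such
abstracts into structured knowledge:

1. **Corpus selection** — literature records (MEDLINE JSON or tagged-field
   exports) are filtered to articles with an abstract and at least one
   species annotation of taxon `9606` (*Homo sapiens*), then segmented
   into sentences with an abbreviation-aware splitter; all-caps section
   headings (`CONCLUSION:`, ...) are stripped before parsing.
2. **Named entity recognition** — dictionary matching over normalization
   lexicons built from HGNC-style (gene/RNA), MeSH-style (carbohydrate,
   peptide, lipid, protein, pharmaceutical preparations, toxin, disease)
   and dbSNP-style (mutation) source tables; rule-based recognition of
   miRNA/lncRNA names (`MIR…`, `MIRN…`, `microRNA-…`, `hsa-miR-…`,
   `linc…`); ingestion of external annotator exports in PubTator format.
   External mentions are retained only if they normalize in the
   dictionaries (the retention gate); every retained mention carries its
   canonical identifier (approved symbol, MeSH unique ID, or rsID).
3. **Relation extraction** — for every pair of entities co-occurring in a
   sentence, the *main verb* is the verb-tagged token on the shortest
   path between the two mention heads in the dependency tree (ties by
   summed endpoint distance, then token index). Verb voice decides
   direction: finite tags (VB, VBD, VBG, VBP, VBZ) are active, so the
   pre-verbal mention is the source; a VBN participle with a *be*
   auxiliary (or modifying a nominal) is passive, and the post-verbal
   agent becomes the source. Relation phrases grow over particles,
   complements and prepositions ("be potential targets for" rather than
   "be"). Relations whose main verb governs an adverbial negator (*no,
   not, never, hardly, barely, scarcely, rarely, few, little, seldom,
   neither, nor*) are discarded.
4. **Biomarker identification** — relation polarity is looked up by
   head-verb lemma in three disjoint classes (positive: *lead, cause, …*;
   association: *associate, relate, …*; negative: *prevent, ameliorate,
   …*). A non-disease entity with a positive or association relation to a
   disease is called an **aging biomarker**; one with a negative
   (preventive/ameliorative) relation a **longevity biomarker**; an
   entity can be both.
5. **Knowledge graph** — one node per canonical entity (frequency =
   distinct articles), one edge per (source, relation, target) with
   weight = number of supporting sentence occurrences. Exports:
   graph-database bulk-import CSVs (`Entities.csv`, `Roles.csv`) and five
   structured JSON files (`Literature_Info`, `Entity_Info`,
   `Relation_Info`, `Aging_Biomarkers`, `Longevity_Biomarkers`).
   `query_paths()` answers direct (1-hop) and indirect (multi-hop,
   predicted) relationship queries.

A deterministic synthetic-corpus generator (`generate_corpus()`) emits
templated abstracts together with their dependency parses and a gold
standard for every stage, so the whole pipeline is testable end to end
without network access or parser models. `compare_gene_sets()` evaluates
extracted gene sets against reference databases by overlap percentage of
the reference set.

## Worked example

Three bundled articles, their PubTator annotations and pre-parsed
sentences:

```r
library(gerolit)
lit    <- system.file("extdata/example_literature.json", package = "gerolit")
ann    <- system.file("extdata/example_annotations.tsv", package = "gerolit")
par    <- system.file("extdata/example_parses.conllu",  package = "gerolit")

corpus <- read_literature(lit, "medline-json")
pt     <- read_pubtator(ann)
parses <- read_conllu(par)
res <- run_pipeline(corpus, pt$species, parses, build_fixture_lexicon(),
                    external_annotations = pt$annotations)
res
#> <gerolit_result>
#>   articles:            2
#>   sentences:           3
#>   entity mentions:     6 (6 entities)
#>   relation triples:    2
#>   aging biomarkers:    1
#>   longevity biomarkers: 1
res$triples[, c("source_id", "relation", "target_id", "voice", "polarity")]
#>    source_id        relation target_id   voice    polarity
#> 1      SIRT1         prevent   D055948  active    negative
#> 2 D000073496 associated with       IL6 passive association
```

The mouse-only record is filtered out; `SIRT1 prevents sarcopenia`
yields a negative entity–disease relation, so SIRT1 is called a
longevity biomarker; `IL6 is associated with frailty` is passive (the
agent-side mention becomes the source) and yields an aging-biomarker
call for IL6; `Metformin does not prevent dementia` is negated and
yields no triple. `write_neo4j_csv(res$graph, dir)` and
`write_hald_json(...)` emit the graph and JSON exports;
`inst/cli/gerolit` wraps the same functions for shell use
(`gerolit query`, `synth`, `run`, `lexicon`, `overlap`).

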