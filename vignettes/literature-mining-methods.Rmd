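---
title: "Methods: from abstracts to an aging/longevity knowledge graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from abstracts to an aging/longevity knowledge graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gerolit)
```

## The extraction model

`gerolit` treats knowledge extraction from biomedical abstracts as a
cascade of deliberately simple, auditable decisions rather than as a
learned model. Each stage has a closed-form rule, which is what makes the
whole pipeline testable against brute-force oracles and a synthetic gold
standard.

**Corpus definition.** The retrieval expression (`build_query()`) is a
fixed disjunction of fourteen title/abstract terms (aging, ageing,
longevity, centenarian, the elderly, the aged, old people, older people,
old age, gerontology, geroscience, lifespan, healthspan, life
expectancy), restricted to English-language journal articles indexed
with the human MeSH term. Retrieval itself is out of scope — records
enter as files — but the working corpus is defined the same way
downstream: an article participates iff it has a nonempty abstract and
at least one species annotation equal to taxon `9606`. Species
annotations are consumed from external annotator exports rather than
inferred from text, since species tagging is a solved upstream problem
and re-deriving it here would only add noise.

**Sentences.** Segmentation is rule-based: a boundary is a run of
`.!?` followed by whitespace, vetoed when the token ending at the period
is a known abbreviation (`vs.`, `e.g.`, `et al.`, ...) or a single
word-initial letter ("J. Smith"). The veto deliberately does *not* fire
for identifiers that merely end in a letter (`hsa-miR-34a.`), which a
naive initial rule would swallow. Offsets are 0-based half-open into the
abstract and every sentence equals its abstract slice, so provenance is
exact. Heading stripping removes only a leading run of two or more
capitals/spaces before a colon: the paper-section labels this targets
are all-caps, and a looser rule would mutilate titles like
"Aging: a review".

**Entity recognition.** Dictionary matching is case-insensitive,
word-boundary-anchored and leftmost-longest per entity type. A boundary
character is anything other than a letter, digit or hyphen; treating the
hyphen as word-internal prevents "insulin-like" from yielding an
"insulin" mention. Between channels, the *retention gate* applies:
external annotator mentions survive only if their surface or identifier
normalizes in the active lexicons, with the type resolved to whichever
category the surface normalizes in; dictionary mentions pass by
construction; rule-based RNA mentions bypass the gate because the naming
rules exist precisely to catch RNA symbols the dictionaries lag behind.
Duplicate spans deduplicate with precedence dictionary > rule >
external; overlapping mentions of different types are both kept but
flagged. Ambiguous surfaces (one alias, several entries — "AP1") resolve
to the entry whose canonical id equals the surface, else the first in
sorted canonical-id order, with all candidates attached for audit.

**Relation extraction.** For each co-occurring pair, the main verb is
the verb-POS token on the shortest dependency path between the two
mention head tokens (head = the last token of the span, since
biomedical noun phrases are typically head-final). If several verbs lie
on shortest paths, the smallest summed endpoint distance wins, then the
smallest token index; on trees the summed distance is constant along
the path, so the index tie-break is what usually decides. No verb on
the path means no relation — conjoined objects ("... E2 and E3") thus
correctly yield no E2–E3 triple. Voice follows the Penn tags: VB, VBD,
VBG, VBP, VBZ are always active (normalized to the lemma); VBN is
passive only with a *be*-lemma auxiliary/copula dependent or when
attached to a nominal by a clausal/adjectival-modifier relation (`acl`,
`amod`, ...; the exact label set is a configuration decision recorded in
the code, since "complement of the subject or object" names no labels).
The perfect ("has increased") therefore stays active. Negation is
verb-scoped: an adverb-tagged token from the negator list depending on
the verb or its auxiliaries kills the candidate triple; a bag-of-words
rule would also kill unrelated clauses of the same sentence.

**Phrase expansion.** The emitted relation is the normalized verb plus
its particles, copular/adjectival complements (with their local
modifiers and trailing prepositions) and verb-attached prepositions, in
surface order — "be potential targets for", "lead to" — with the
passive agent marker "by" excluded. The expander understands
Stanford-style prepositional attachment (`prep`/`pobj`), which is also
the convention the synthetic parses use.

**Polarity and biomarkers.** The three polarity classes are
configuration, seeded with the canonical example verbs (positive:
*lead, cause*; association: *associate, relate*; negative: *prevent,
ameliorate*) and extended with conservative synonyms (*induce, promote,
increase, contribute; correlate, link; inhibit, reduce, suppress,
protect*), each member tagged seed vs extension in
`polarity_lexicon()`. Lookup is by head-verb lemma with a small
inflection stripper so passive participles resolve ("caused" → cause).
Biomarker calling ignores triple orientation by default — the criterion
is the relationship class between entity and disease, not which side of
the verb the entity landed on; a strict-direction mode is available.
Any disease-type entity qualifies as a partner; whether the disease
itself must be aging-related is not decidable from the rule set, and
restricting it would be a curation decision, not an extraction one.

**Aggregation.** Node ids are `"<type>:<canonical_id>"` (the id scheme
is this package's choice; stable and human-readable). Edges are
directed per triple; path queries use the undirected view, matching how
such graphs are browsed. Edge weight is the count of supporting
(article, sentence) occurrences, so edge weights always sum to the
number of retained triples; node frequency is the distinct-article
count. The edge `type` column carries the polarity class (the modal
class over supporting triples, ties alphabetical) — the alternative
reading, entity-pair type, is recoverable from the node ids and would
duplicate information.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| negation word list | 12 adverbs (`negation_words()`) | negators that veto a relation when verb-governed |
| be-conjugation list | be, is, are, was, were, been, being, am | lemma/form check for passive auxiliaries, robust to tagger variation |
| polarity lexicon | 6 seeds + 10 extensions | class membership by verb lemma; disjointness enforced |
| `strict_direction` | `FALSE` | require entity→disease orientation for biomarker calls |
| ambiguity resolution | canonical-match, then sorted id | deterministic normalization of shared aliases |

All are plain R objects; swapping in a custom list changes behaviour
without touching code.

## What the synthetic corpus emulates — and what it does not

`generate_corpus()` instantiates templated sentences from the fixture
lexicons with controlled voice (default 30% passive), negation (10%),
polarity mix (40/30/30 positive/association/negative), disease targets
(50%), rule-recognizable RNA subjects (10%), entity-free distractor
openings and all-caps headings. Defaults were chosen once as a plausible
regime for abstract sentences about molecular aging: passives and
negations are common but minority constructions, and roughly half of the
extracted relations in this literature involve a disease partner.
Templates emit their own parses in the conventions above, so tests are
hermetic; the gold standard (mentions, triples, biomarker calls) is
derived from template knowledge, never by running the pipeline, and
passive templates are binary (subject + agent), so three-entity
sentences are always active.

What passing against this corpus shows: every rule of the cascade —
segmentation, boundary-anchored matching, the retention gate, shortest
path verb selection, voice, negation, phrase expansion, polarity,
calling, aggregation — composes correctly and deterministically.

What it does not show: robustness to real parser errors, coordination
ambiguity, anaphora, hedging ("may contribute to"), nested clauses, or
dictionary gaps — real abstracts contain all of these, and real-world
precision/recall will be strictly worse than the synthetic 1.0. The
generator's vocabulary is also disjoint between distractor text and
lexicon surfaces by construction, so synthetic precision is well-defined
but optimistic.

## Numerical and degenerate-input choices

* Overlap percentages are computed against the *reference* set and
  rounded half-up to one decimal (base `round()` rounds half to even,
  which would disagree with printed tables); an empty reference is an
  error, not a 0 or NaN.
* Ranking ties (same article count) break lexicographically; verb ties
  break by token index; both are documented so results reproduce.
* Empty inputs flow through: empty corpora give empty sentence tables,
  sentences without two entities give no pairs, triple-free graphs are
  node-only, biomarker-free exports are valid empty JSON arrays.
* Parses are validated as single-rooted acyclic trees on read; a
  mention whose head token cannot be aligned skips its pair with a
  warning rather than failing the run.
* The problem sizes exercised by the test-suite and acceptance run —
  up to ~330 abstracts / ~1,000 relational sentences, lexicons of ~120
  entries — were chosen as the smallest sizes at which every rule and
  the binomial checks on voice/negation rates are well-resolved.

## Known limitations

* No coreference or cross-sentence extraction: indirect relationships
  are a graph query (`query_paths()`), not an extraction feature.
* No confidence scores on triples; method tags (`dictionary`, `rule`,
  `external`, `shortest_path`) are the only provenance of that kind.
* The lexicon snapshots bundled for testing are small; production use
  requires real HGNC/MeSH/dbSNP exports in the documented schemas.
* Live parsing is pluggable in principle (any backend producing the
  same token/tag/arc contract yields identical analyses — tested by
  round-tripping CoNLL-U), but no parser is bundled.
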