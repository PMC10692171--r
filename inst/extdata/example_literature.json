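[
  {
    "pmid": "30000001",
    "title": "Sirtuins and inflammatory markers in late-life health",
    "abstract": "CONCLUSION: SIRT1 prevents sarcopenia. IL6 is associated with frailty.",
    "journal_title": "Journal of Synthetic Gerontology",
    "journal_abbrev": "J Synth Gerontol",
    "impact_factor": 6.1,
    "impact_factor_5yr": 5.8,
    "pub_date": "2021 Jun",
    "authors": ["Doe J", "Roe R"],
    "pub_types": ["Journal Article"],
    "language": "eng",
    "place": "Nowhere",
    "source": "J Synth Gerontol. 2021 Jun."
  },
  {
    "pmid": "30000002",
    "title": "Metformin and cognition",
    "abstract": "Metformin does not prevent dementia.",
    "journal_title": "Annals of Model Aging",
    "journal_abbrev": "Ann Model Aging",
    "impact_factor": 3.4,
    "pub_date": "2020",
    "authors": ["Poe E"],
    "pub_types": ["Journal Article"],
    "language": "eng"
  },
  {
    "pmid": "30000003",
    "title": "A murine study without abstract",
    "pub_date": "2019",
    "language": "eng"
  }
]
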