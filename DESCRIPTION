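Package: ClinTermEnrich
Title: Clinical-Finding Term Retrieval, Nomenclature Synonym Mapping and
    Recognition in Chinese Physician Notes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for enriching a referenced Chinese clinical nomenclature
    (Chinese SNOMED III / Chinese ICD-10 descriptions) with daily-used
    synonyms mined from clinical free text, and for recognising clinical
    finding terms in physician notes. Implements candidate term extraction
    from chief complaints and impression diagnoses, literal similarity by
    Jaro-Winkler and a suffix-adjusted variant, diagnosis co-occurrence
    similarity by TF-IDF weighted cosine over ICD-10 three-character
    categories, hybrid similarity concept-mapping queues with rank
    diagnostics, a rule- and terminology-based recogniser (reverse maximum
    matching with context exceptions, aggregation expansion and negation
    detection, BIEO output), a CRF featurisation pipeline with chi-square
    associative-strength features and greedy forward feature selection,
    span-level evaluation metrics, the CRF-minus-rule new-term discovery
    loop, and a seeded synthetic corpus generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
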