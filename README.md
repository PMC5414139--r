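# ClinTermEnrich

Clinical free text rarely uses the exact wording of a nomenclature: Chinese
physician notes are full of synonyms, abbreviations and modifier-laden
variants of clinical-finding terms, so a referenced nomenclature (Chinese
SNOMED III, Chinese ICD-10) alone recognises only a fraction of what is
actually written. ClinTermEnrich implements a complete pipeline for
terminology enrichment and term recognition in this setting, for medical
informatics teams who need to (1) mine candidate finding terms from brief
clinical records, (2) map them to referenced nomenclature concepts so the
synonyms can be reviewed and adopted, and (3) recognise the enriched
dictionary's terms — with negation flags — in narrative notes.

## What it computes

**Candidate extraction.** Chief complaints follow a "finding + duration"
pattern (e.g. 咽痛、吞咽梗阻3 + 月); records are split into clauses at
full- and half-width punctuation and the duration phrase is stripped
reverse-iteratively with time-period and number keyword groups. Impression
diagnoses are split into short phrases at any punctuation except brackets
and hyphen. Candidates must occur strictly more than a frequency threshold
(10 for chief complaints, 20 for impression diagnoses).

**Hybrid similarity for concept mapping.** For a term pair, literal
similarity is

    JWD(s1,s2) = JD + preLen · preScale · (1 − JD)

with JD the Jaro similarity, together with a suffix-adjusted variant (AJWD)
where the bonus length is the common *suffix* — in Chinese finding terms the
suffix is usually the sensation and carries the clinical meaning; LS is the
larger of the two. Diagnosis-related similarity is the cosine of
TF-IDF-weighted vectors over ICD-10 three-character discharge-diagnosis
categories, with w_ij = tf_ij · |D|/df_j. The hybrid score combines them
with weight β as an arithmetic sum β·LS + (1−β)·DS or quadratic sum
√(β·LS² + (1−β)·DS²). Every term gets a descending-HS queue of concept
candidates for expert review; rank diagnostics (mean gold rank, top-k
coverage, detection rate per HS bin) and a β/combiner sweep are provided.

**Recognition.** The rule- and terminology-based recogniser segments text
into clauses (caesura sign exempt), runs reverse maximum matching against
the dictionary within a 16-character window, drops matches invalidated by
exception-with-context phrases (多尿 inside 多尿期), expands aggregated
surfaces (颈肩部麻木 → 颈部麻木 + 肩部麻木) through a reviewed affix index,
detects clause-bounded negation from six cues (不伴, 无, 否认, 未, 消失,
不明显), and emits BIEO tags. A CRF featurisation pipeline produces
CoNLL-style training files and templates for an external linear-chain
engine, including chi-square associative-strength features (gate at the
df = 1, α = 0.05 critical value 3.841) and greedy forward feature
selection; spans marked by the CRF but missed by the rules feed a
new-term discovery queue.

A seeded synthetic-corpus generator plants synonym groups on shared latent
diagnosis distributions and emits every on-disk format, so the whole
pipeline is testable without clinical data.

## Worked example

```r
library(ClinTermEnrich)
lex  <- defaultKeywordLexicon()
dict <- termDictionary(data.frame(
  surface = c("发热", "咳嗽", "高血压"),
  frequency = c(120, 80, 40), source = "CCC", status = "VALID"))
r <- recognize("患者发热3天,无咳嗽,最高血压150", dict, lex)
r$spans
#>   start end surface negated origin
#> 1     2   4    发热   FALSE   RTBA
#> 2     8  10    咳嗽    TRUE   RTBA
r$tagged
#> TaggedSequence of length 18
#>   患 者 发 热 3 天 , 无 咳 嗽 , 最 高 血 压 1 5 0
#>   O O B E O O O O B E O O O O O O O O
```

发热 (fever) is recognised and not negated; 咳嗽 (cough) is negated by the
preceding cue 无; 高血压 (hypertension) is *not* recognised because its
match lies inside the exception context 最高血压 (the highest blood
pressure). Similarity and metric arithmetic:

```r
literalSimilarity("头部疼痛", "腹部疼痛")   # 0.8833 (suffix bonus on 部疼痛)
prf(list(tp = 10165, fp = 743, fn = 1053))
#> precision    recall    fscore
#>     0.932     0.906     0.919
stripDuration("吞咽梗阻3 + 月", lex)        # "吞咽梗阻"
```

A command-line front end wrapping these functions ships in
`inst/scripts/ctcf.R` (subcommands `extract-ccc`, `extract-cid`, `map`,
`recognize`, `evaluate`, `discover`, `simulate`).

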