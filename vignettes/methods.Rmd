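---
title: "Terminology enrichment and clinical term recognition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Terminology enrichment and clinical term recognition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ClinTermEnrich)
```

## The problem

Chinese clinical notes describe findings (symptoms, signs, disorders, test
results, clinical states) in daily language that diverges from referenced
nomenclatures: word order varies, modifiers are mingled into terms,
abbreviations and aggregated surfaces are common, and Chinese has no word
spaces to anchor segmentation. The package covers the full loop used to
close that gap: mine candidate terms from brief records, map them onto
referenced-nomenclature concepts by a hybrid of literal and
diagnosis-co-occurrence similarity, recognise the enriched dictionary in
narrative text, and harvest new candidates from the disagreement between a
statistical recogniser and the rule-based one.

All text is handled at the Unicode code-point level; "character" always
means code point. This matters for the mixed full-width/half-width
punctuation of clinical Chinese and is enforced by routing every string
operation through explicit code-point helpers rather than locale-dependent
functions.

## Candidate extraction

Chief complaints have the fixed shape "finding + duration". Records are
split into clauses at an explicitly enumerated punctuation inventory —
half-width `, . : ; " ' ? ! ( ) [ ] / \ -` and full-width
`，。：；""''、？！（）【】《》`. The published material names only examples
of this inventory, so the tables here are a conservative superset and are
configurable. Each clause then has its trailing duration phrase removed by
reverse iteration: as long as the clause ends with a time-period entry
(年, 月, 周, 天, 小时, ...) or a number entry, the match is removed. The
number group deliberately includes ASCII and full-width digits, Chinese
numerals, `+`, `.` and whitespace so that a suffix like `3 + 月` strips
completely. Stripping is idempotent by construction (a residue that ends in
no entry is a fixed point), which the test suite checks property-style.

Impression diagnoses are short phrases rather than sentences; they are
split at any punctuation except brackets and hyphen (so `高血压(原发性)`
survives intact). Both extractors emit a candidate only when its tally
strictly exceeds the threshold — "more than N" is read as a strict
inequality — with defaults of 10 (chief complaints) and 20 (impression
diagnoses). Duration-only clauses reduce to the empty residue and are
dropped silently. Whether residues should be further split at interior
whitespace is genuinely open; the package trims ends only, since interior
spaces inside a candidate are rare and reviewable downstream.

## Similarity metrics

**Literal.** The Jaro similarity is the canonical basis: matches within a
window of `floor(max(|s1|,|s2|)/2) - 1`, transpositions equal to half the
out-of-order matched pairs. The Winkler variant adds
`preLen · preScale · (1 − JD)`. Because Chinese finding terms typically put
the body part first and the sensation last, a shared *suffix* is the
stronger clinical signal, so a suffix-adjusted variant replaces the prefix
length with the common-suffix length; literal similarity is the maximum of
the two. `preScale = 0.1` and a cap of 4 on the affix length follow the
classical Winkler convention; the cap also guarantees scores never exceed
1 for long shared suffixes, a case the published description leaves open.

**Diagnosis-related.** Every term carries a sparse profile of ICD-10
three-character discharge-diagnosis categories (three characters, not four,
to avoid sparsity). Weights are TF-IDF: `w_ij = tf_ij × |D|/df_j` where
`df_j` counts the terms whose profile contains category `j` and `|D|` is
the number of distinct categories observed — the printed definition of the
IDF numerator. For the term-frequency denominator the printed formula sums
over terms within a category, which conflicts with "term frequency"
semantics; the package normalises within the term's own profile by default
(so tf sums to 1 per term) and exposes `tfDenominator = "printed"` for the
literal reading. The IDF ratio is used unlogged by default, again for
fidelity, with `logIdf = TRUE` available. Terms whose surface contains a
negation cue are excluded from the scheme (empty vector); exclusion is
term-level rather than mention-level, the simpler of the two readings.
Similarity is the cosine; zero-norm or empty vectors give 0, the
conservative value where the cosine is undefined.

**Hybrid.** `AS = β·LS + (1−β)·DS` and `QS = sqrt(β·LS² + (1−β)·DS²)`,
with β defaulting to 0.6 (the initial empirical setting). The β/combiner
sweep (`sweepBeta()`) exists precisely because the best operating point is
an empirical question; both are exposed and nothing is hard-wired to the
sweep's outcome.

## Concept mapping queues

Each term is scored against every referenced-concept surface and given a
queue in descending hybrid score, ties broken lexicographically for
determinism. Review thresholds are strict (`hs > 0.3` for the screening
export), queue exports truncate at a configurable depth (default 20, the
depth a reviewer realistically scans), and ranks are 1-based. A gold
concept missing from a queue is scored at queue length + 1 rather than
dropped, so the mean rank degrades instead of silently improving.

## Rule- and terminology-based recognition

Clauses are re-segmented for recognition with the caesura sign exempt
(enumerations like 咽痛、咳嗽 stay in one clause and both items match).
Reverse maximum matching scans right to left, trying the longest
dictionary surface ending at each position within a 16-code-point window —
16 being the longest valid term length, which also caps the dictionary's
`maxLength`. Offsets are 0-based half-open throughout.

Four refinements sit on top:

* **Exception contexts.** A match is removed iff its interval lies inside
  an occurrence of an exception-with-context phrase (多尿 in 多尿期,
  高血压 in 最高血压). This is the practical resolution of overlapping
  ambiguity strings in clinical text.
* **Modifier pass.** Modifiers mingled inside terms (持续, 明显, ...)
  defeat exact matching, so when the raw pass misses, a second pass deletes
  modifier occurrences, re-matches, and maps hits back to original offsets
  spanning the modifier. The published material states the requirement but
  not a mechanism; this deletion-and-remap design keeps the dictionary
  clean of combinatorial modifier variants.
* **Aggregation.** Term pairs sharing a prefix (or suffix) register their
  residuals as potential suffixes (or prefixes) of each other at index
  build time. At recognition time an affix adjacent to a match either
  emits the constituent term's span (if the affix has been accepted by
  review) or merely increments its observation tally (feeding review).
  Constituent spans are reported in the span list only — they are
  non-contiguous in the text, so they carry the constituent surface while
  their interval covers the aggregated region, and they never enter the
  BIEO tags.
* **Negation.** Six cues, position-tagged: 不伴, 无, 否认, 未 precede
  their target; 消失, 不明显 follow it. Scope is clause-bounded, and
  another recognised span between cue and target blocks the attachment —
  in 无咳嗽发热 only 咳嗽 is negated.

Output is BIEO per character; a single-character term is tagged as a lone
B, since the scheme has no singleton tag and sub-2-character terms are
edge cases in practice. The grammar enforced on every output (I/E only
after B/I, I always continued) is validated by a dedicated checker that
tests run over all recogniser output.

## CRF featurisation

Parameter estimation is deliberately delegated to an external linear-chain
CRF engine through emitted artefacts: CoNLL-style tab-separated files
(blank line between records, gold tag last) and a template in the common
`U<id>:%x[row,col]` dialect covering every feature column at offsets
`-cws..cws`. The bespoke content is the featurisation: per code point, the
character, the n-grams ending at it (unigram through quadgram), a
stop-character flag, the covering word and its POS from a pluggable
tokenizer adapter, neighbouring words, and a binary associative-strength
flag on word boundaries. Word-level attributes are projected onto each
character of the word — the simplest defensible alignment. Missing values
carry the sentinel `_NULL_` so the table stays rectangular.

The association feature gates adjacent word pairs by the chi-square
statistic on the 2×2 adjacency table (pair observed / left-word-only /
right-word-only / neither), uncorrected, with the df = 1, α = 0.05
critical value 3.841 — uncorrected precisely because 3.841 is the
uncorrected critical value. The exact marginal construction for "two
adjacent words" is unstated in the source material; the bigram-vs-margins
table used here is the standard collocation reading. Greedy forward
selection mirrors the published procedure: evaluate each candidate feature
alone on the baseline, sort by gain, then add sequentially keeping only
strict improvements, logging every evaluated configuration.

Tag decoding turns maximal `B(I)*E` runs (and lone `B`s) into spans;
malformed runs are repaired by the longest valid prefix (an unclosed run
closes at its last tagged character) and logged rather than discarded, so
engine noise degrades gracefully.

## Evaluation and discovery

Span evaluation uses exact (start, end) matching — the convention of the
exact-F benchmarks this line of work compares against — so a partial
overlap is both a false positive and a false negative. All 0/0 ratios are
defined as 0. Comparisons against published 3-decimal values use half-up
rounding. Inter-annotator agreement uses Cohen's kappa for the
validation/mapping decisions and pairwise F for span annotation (kappa is
undefined without negative cases). Discovery collects CRF spans with no
exact rule-based counterpart, tallies surfaces, and returns those at or
above a frequency floor, high-frequency first, with example contexts —
exact matching again, so boundary disagreements surface as candidates for
review rather than being silently absorbed.

## The synthetic corpus

No clinical corpus ships with the package, so a seeded generator stands in
for it as a first-class, tested module. It builds concepts from a fixed
body-part × sensation inventory of real CJK code points (so Unicode paths
are genuinely exercised), derives synonyms by truncation, modifier
insertion and modifier prefixing, and plants each concept's synonyms on a
shared 3-category latent diagnosis distribution perturbed by `dsNoise`.
Chief complaints append sampled durations; impression diagnoses join
concept surfaces with punctuation; narrative records compose clauses with
negation cues, modifier variants, optional aggregated surfaces and
exception contexts, with gold spans and negation flags recorded at
generation time.

Defaults: 24 concepts × 3 synonyms, 40 diagnosis categories, 300 records
per stream, modifier and negation rates 0.15, exception rate 0.05,
aggregation rate 0 (aggregations are review-gated in the pipeline, so they
are opt-in in the generator too), duration rate 0.9, `dsNoise = 0.1`.
These are desk-scale sizes chosen so the full suite runs in well under the
package's test budget while leaving each phenomenon frequent enough to be
asserted on; they are the package's fixed study conditions, not tuning
knobs. Acceptance-style checks run the mapping recovery on the generated
corpus (planted concept ranked first for at least 80% of synonyms), the
recogniser at F = 1.0 on text whose gold spans are exactly plantable, and
a coarse-binned monotone detection-rate curve.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: natural clinical syntax, misspellings,
cross-clause findings (大便干结,表面带血 as one finding split over two
clauses is explicitly out of scope for the recogniser), genuine ICD coding
noise, and the long-tailed synonym morphology of real notes. Results on
the synthetic corpus bound algorithmic correctness, not clinical
performance.

## Numerical and degenerate-input choices

* Cosine values are clamped to [0, 1] against floating-point overshoot so
  downstream range contracts hold exactly.
* Two empty strings have Jaro similarity 1; one empty, 0.
* Queue and discovery ties break lexicographically (C-locale radix order)
  for reproducibility.
* Duplicate dictionary surfaces merge by summing frequencies and keeping
  the most-valid status (VALID > CANDIDATE > REJECTED): a term confirmed
  anywhere stays confirmed.
* Empty extraction streams, empty concept sets and empty dictionaries all
  return empty containers rather than errors; malformed TSV rows fail fast
  with the line number.

## Limitations

The recogniser's recall is bounded by dictionary coverage by design — that
is what the discovery loop exists to fix iteratively. The modifier second
pass can only bridge modifiers that appear verbatim in the lexicon. The
aggregation expansion fires only on directly adjacent affixes and is
review-gated, so novel aggregations are tallied but not recognised until
accepted. CRF training itself is out of scope: the package emits and
consumes the engine's file contracts, and the in-package end-to-end test
uses a memorising mock in place of a trained model.
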