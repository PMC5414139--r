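# Candidate term extraction from chief complaints (CCC) and impression
# diagnoses (CID). Chief complaints follow the "finding + duration" pattern;
# duration phrases are stripped reverse-iteratively with the timePeriod and
# number keyword groups. Thresholds are strict: a candidate must occur more
# than minFreq times.

#' Split text into clauses at punctuation
#'
#' Splits on every code point of the configured full- and half-width
#' punctuation inventory. When `keepCaesura` is TRUE the ideographic caesura
#' sign 、 does not split (the recogniser's convention). Empty clauses are
#' dropped; the concatenation of clauses plus removed delimiters equals the
#' input.
#'
#' @param text A string.
#' @param keepCaesura Logical; exempt 、 from splitting.
#' @param punctuation Punctuation inventory.
#' @param offsets Logical; also return 0-based clause start offsets.
#' @return Character vector of clauses, or (with `offsets`) a data.frame with
#'   columns clause, start.
#' @export
#' @examples
#' splitClauses("咽痛、吞咽梗阻3 + 月")
splitClauses <- function(text, keepCaesura = FALSE,
                         punctuation = defaultPunctuation(),
                         offsets = FALSE) {
  if (keepCaesura) punctuation <- setdiff(punctuation, CAESURA)
  ch <- cpChars(text)
  isDelim <- ch %in% punctuation
  if (length(ch) == 0L) {
    if (offsets) return(data.frame(clause = character(0), start = integer(0)))
    return(character(0))
  }
  # collect maximal runs of non-delimiter code points
  starts <- integer(0); clauses <- character(0)
  i <- 1L
  while (i <= length(ch)) {
    if (isDelim[i]) { i <- i + 1L; next }
    j <- i
    while (j < length(ch) && !isDelim[j + 1L]) j <- j + 1L
    clauses <- c(clauses, paste(ch[i:j], collapse = ""))
    starts <- c(starts, i - 1L)
    i <- j + 1L
  }
  if (offsets) data.frame(clause = clauses, start = starts,
                          stringsAsFactors = FALSE)
  else clauses
}

#' Strip a trailing duration phrase from a clause
#'
#' Repeatedly removes, from the right end, any match of a timePeriod or
#' number entry (the number group includes digits, Chinese numerals, '+', '.'
#' and whitespace) until no entry matches. A clause consisting only of a
#' duration phrase reduces to the empty string.
#'
#' @param clause Non-empty string.
#' @param lexicon A [KeywordLexicon-class].
#' @return The residue (possibly unchanged or empty).
#' @export
#' @examples
#' stripDuration("吞咽梗阻3 + 月", defaultKeywordLexicon())
stripDuration <- function(clause, lexicon) {
  stopifnot(nzchar(clause))
  entries <- c(lexicon@timePeriod, lexicon@number)
  entries <- entries[order(-vapply(entries, cpN, integer(1)))]
  x <- clause
  repeat {
    n <- cpN(x)
    if (n == 0L) break
    hit <- FALSE
    for (e in entries) {
      ne <- cpN(e)
      if (ne <= n && cpSub(x, n - ne + 1L, n) == e) {
        x <- cpSub(x, 1L, n - ne)
        hit <- TRUE
        break
      }
    }
    if (!hit) break
  }
  x
}

tallyToCandidates <- function(counts, minFreq, source) {
  counts <- counts[order(-counts, names(counts), method = "radix")]
  new("CandidateTally", counts = counts, minFreq = as.integer(minFreq),
      source = source)
}

#' Extract candidate terms from chief complaints
#'
#' Each record is split into clauses (caesura splits), each clause has its
#' duration phrase stripped, and the non-empty residues are tallied.
#' Candidates are residues occurring strictly more than `minFreq` times.
#'
#' @param records Character vector of chief-complaint records.
#' @param lexicon A [KeywordLexicon-class].
#' @param minFreq Strict occurrence threshold (default 10).
#' @param punctuation Punctuation inventory for clause splitting.
#' @return A [CandidateTally-class]; use [candidates()] for the emitted rows.
#' @export
extractCccCandidates <- function(records, lexicon = defaultKeywordLexicon(),
                                 minFreq = 10L,
                                 punctuation = defaultPunctuation()) {
  residues <- character(0)
  for (rec in records) {
    rec <- trimws(rec)
    if (!nzchar(rec)) next
    for (cl in splitClauses(rec, keepCaesura = FALSE, punctuation)) {
      r <- trimws(stripDuration(cl, lexicon))
      if (nzchar(r)) residues <- c(residues, r)
    }
  }
  counts <- if (length(residues)) {
    tab <- table(residues)
    stats::setNames(as.integer(tab), names(tab))
  } else stats::setNames(integer(0), character(0))
  tallyToCandidates(counts, minFreq, "CCC")
}

#' Extract candidate terms from impression diagnoses
#'
#' Each record is split into short phrases on every punctuation code point
#' except brackets ( ) （ ） [ ] 【 】 and the hyphen; phrases occurring
#' strictly more than `minFreq` times are candidates.
#'
#' @param records Character vector of impression-diagnosis records.
#' @param minFreq Strict occurrence threshold (default 20).
#' @param punctuation Punctuation inventory.
#' @return A [CandidateTally-class].
#' @export
extractCidCandidates <- function(records, minFreq = 20L,
                                 punctuation = defaultPunctuation()) {
  splitters <- setdiff(punctuation,
                       c("(", ")", "（", "）", "[", "]", "【", "】", "-"))
  phrases <- character(0)
  for (rec in records) {
    rec <- trimws(rec)
    if (!nzchar(rec)) next
    phrases <- c(phrases,
                 trimws(splitClauses(rec, punctuation = splitters)))
  }
  phrases <- phrases[nzchar(phrases)]
  counts <- if (length(phrases)) {
    tab <- table(phrases)
    stats::setNames(as.integer(tab), names(tab))
  } else stats::setNames(integer(0), character(0))
  tallyToCandidates(counts, minFreq, "CID")
}
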