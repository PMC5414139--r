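# Rule- and terminology-based recognition.
#
# Pipeline per input text: clause segmentation (all punctuation except the
# caesura sign) -> reverse maximum matching against the term dictionary
# (window = longest term length, default 16 code points) -> removal of
# matches invalidated by an exception-with-context phrase -> aggregation
# expansion (a matched term's accepted potential prefixes/suffixes fire on
# the neighbouring characters, recovering the constituent terms of an
# aggregated surface) -> clause-bounded negation detection -> BIEO tagging.
#
# Spans use 0-based half-open code-point offsets into the source text.

emptySpans <- function() {
  data.frame(start = integer(0), end = integer(0), surface = character(0),
             negated = logical(0), origin = character(0),
             stringsAsFactors = FALSE)
}

makeSpans <- function(start, end, surface, negated = FALSE, origin = "RTBA") {
  data.frame(start = as.integer(start), end = as.integer(end),
             surface = surface, negated = negated, origin = origin,
             stringsAsFactors = FALSE)
}

#' Reverse maximum matching over one clause
#'
#' Scans the clause right to left. At each position the longest dictionary
#' surface ending there (up to `maxLen` code points) is tried; a hit emits a
#' span and the scan jumps left past it, otherwise the scan moves one code
#' point left. Spans are non-overlapping and reported left to right.
#'
#' @param clause A string (one clause, no internal clause punctuation).
#' @param dict A [TermDictionary-class].
#' @param maxLen Matching window in code points (default 16, the longest
#'   observed valid term length).
#' @return data.frame of spans (start, end, surface, negated, origin).
#' @export
rmmMatch <- function(clause, dict, maxLen = 16L) {
  ch <- cpChars(clause)
  n <- length(ch)
  spans <- emptySpans()
  e <- n
  while (e >= 1L) {
    hit <- FALSE
    for (L in seq(min(maxLen, e), 1L)) {
      cand <- paste(ch[(e - L + 1L):e], collapse = "")
      if (dictContains(dict, cand)) {
        spans <- rbind(makeSpans(e - L, e, cand), spans)
        e <- e - L
        hit <- TRUE
        break
      }
    }
    if (!hit) e <- e - 1L
  }
  rownames(spans) <- NULL
  spans
}

# Second matching pass that ignores in-term modifiers: delete modifier
# occurrences from the clause, re-run RMM on the residue, and map hits back
# to original offsets (a mapped span stretches across any deleted modifier).
rmmModifierPass <- function(clause, dict, lexicon, maxLen, existing) {
  ch <- cpChars(clause)
  n <- length(ch)
  if (n == 0L) return(emptySpans())
  deleted <- logical(n)
  for (mod in lexicon@modifier[order(-vapply(lexicon@modifier, cpN, integer(1)))]) {
    for (s in cpFindAll(clause, mod)) {
      idx <- (s + 1L):(s + cpN(mod))
      if (!any(deleted[idx])) deleted[idx] <- TRUE
    }
  }
  if (!any(deleted)) return(emptySpans())
  keepIdx <- which(!deleted)              # reduced position -> original (1-based)
  reduced <- paste(ch[keepIdx], collapse = "")
  hits <- rmmMatch(reduced, dict, maxLen)
  if (nrow(hits) == 0L) return(emptySpans())
  out <- emptySpans()
  for (i in seq_len(nrow(hits))) {
    origStart <- keepIdx[hits$start[i] + 1L] - 1L
    origEnd <- keepIdx[hits$end[i]]
    surf <- paste(ch[(origStart + 1L):origEnd], collapse = "")
    # only add if the modifier actually sits inside the span and the region
    # is free of already-recognised spans
    if (!any(deleted[(origStart + 1L):origEnd])) next
    overlaps <- nrow(existing) > 0L &&
      any(existing$start < origEnd & existing$end > origStart)
    if (!overlaps) out <- rbind(out, makeSpans(origStart, origEnd, surf))
  }
  out
}

#' Remove matches invalidated by an exception context
#'
#' A span is dropped iff some exception-with-context phrase occurs in the
#' clause and the span's interval lies within that occurrence (e.g. 多尿
#' inside 多尿期, or 高血压 inside 最高血压).
#'
#' @param spans data.frame of spans over `clause`.
#' @param clause The clause text.
#' @param lexicon A [KeywordLexicon-class].
#' @return Filtered spans data.frame.
#' @export
filterExceptions <- function(spans, clause, lexicon) {
  if (nrow(spans) == 0L) return(spans)
  drop <- logical(nrow(spans))
  for (exc in lexicon@exceptionWithContext) {
    ne <- cpN(exc)
    for (s in cpFindAll(clause, exc)) {
      within <- spans$start >= s & spans$end <= s + ne
      drop <- drop | within
    }
  }
  out <- spans[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the aggregation affix index from a dictionary
#'
#' For every pair of dictionary terms sharing a common prefix (resp. suffix),
#' each term's residual is registered as a potential suffix (resp. prefix)
#' of the other, together with the constituent term it encodes. Frequencies
#' start at zero; no affix is accepted until flagged.
#'
#' @param dict A [TermDictionary-class].
#' @param accepted Optional data.frame (term, affix, side) of affixes already
#'   reviewed and accepted.
#' @return An [AggregationIndex-class].
#' @export
buildAggregationIndex <- function(dict, accepted = NULL) {
  surfaces <- dict@entries$surface
  rows <- list()
  nS <- length(surfaces)
  if (nS >= 2L) {
    for (i in seq_len(nS - 1L)) {
      for (j in (i + 1L):nS) {
        a <- surfaces[i]; b <- surfaces[j]
        na <- cpN(a); nb <- cpN(b)
        # shared prefix: residuals become mutual potential suffixes
        p <- commonPrefixLen(a, b)
        if (p >= 1L && p < na && p < nb) {
          ra <- cpSub(a, p + 1L, na); rb <- cpSub(b, p + 1L, nb)
          rows[[length(rows) + 1L]] <-
            data.frame(term = c(a, b), affix = c(rb, ra), side = "suffix",
                       constituent = c(b, a), stringsAsFactors = FALSE)
        }
        # shared suffix: residuals become mutual potential prefixes
        s <- commonSuffixLen(a, b)
        if (s >= 1L && s < na && s < nb) {
          ra <- cpSub(a, 1L, na - s); rb <- cpSub(b, 1L, nb - s)
          rows[[length(rows) + 1L]] <-
            data.frame(term = c(a, b), affix = c(rb, ra), side = "prefix",
                       constituent = c(b, a), stringsAsFactors = FALSE)
        }
      }
    }
  }
  af <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(term = character(0), affix = character(0),
               side = character(0), constituent = character(0),
               stringsAsFactors = FALSE)
  af$frequency <- rep(0L, nrow(af))
  af$accepted <- rep(FALSE, nrow(af))
  if (!is.null(accepted) && nrow(af)) {
    key <- paste(af$term, af$affix, af$side)
    accKey <- paste(accepted$term, accepted$affix, accepted$side)
    af$accepted <- key %in% accKey
  }
  rownames(af) <- NULL
  new("AggregationIndex", affixes = af)
}

#' Expand aggregated surfaces around matched spans
#'
#' For each matched span, the term's potential affixes are tested against the
#' immediately adjacent characters of the clause. An accepted affix that
#' matches emits an additional span for the constituent term (covering affix
#' plus matched region, origin "RTBA_AGG"); an unaccepted match only
#' increments the affix's observation tally, feeding later review.
#'
#' @param spans data.frame of spans over `clause`.
#' @param clause The clause text.
#' @param index An [AggregationIndex-class].
#' @return list(spans = augmented spans, index = index with updated tallies).
#' @export
expandAggregations <- function(spans, clause, index) {
  af <- index@affixes
  if (nrow(spans) == 0L || nrow(af) == 0L)
    return(list(spans = spans, index = index))
  ch <- cpChars(clause)
  n <- length(ch)
  extra <- emptySpans()
  for (i in seq_len(nrow(spans))) {
    rows <- which(af$term == spans$surface[i])
    for (r in rows) {
      alen <- cpN(af$affix[r])
      if (af$side[r] == "prefix") {
        s0 <- spans$start[i] - alen
        if (s0 < 0L) next
        adjacent <- paste(ch[(s0 + 1L):spans$start[i]], collapse = "")
      } else {
        e1 <- spans$end[i] + alen
        if (e1 > n) next
        adjacent <- paste(ch[(spans$end[i] + 1L):e1], collapse = "")
      }
      if (adjacent != af$affix[r]) next
      af$frequency[r] <- af$frequency[r] + 1L
      if (af$accepted[r]) {
        if (af$side[r] == "prefix")
          extra <- rbind(extra, makeSpans(spans$start[i] - alen, spans$end[i],
                                          af$constituent[r],
                                          origin = "RTBA_AGG"))
        else
          extra <- rbind(extra, makeSpans(spans$start[i], spans$end[i] + alen,
                                          af$constituent[r],
                                          origin = "RTBA_AGG"))
      }
    }
  }
  out <- rbind(spans, extra)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  index@affixes <- af
  list(spans = out, index = index)
}

#' Is a recognised span negated in its clause?
#'
#' TRUE iff a PRECEDING cue occurs in the clause before the span start, or a
#' FOLLOWING cue occurs after the span end, with no other recognised span
#' lying between the cue and the span (negation scope is clause-bounded).
#'
#' @param start,end Span offsets (0-based half-open) within the clause.
#' @param clause The clause text.
#' @param lexicon A [KeywordLexicon-class].
#' @param otherSpans data.frame of the other recognised spans in the clause.
#' @return Logical.
#' @export
detectNegation <- function(start, end, clause, lexicon,
                           otherSpans = emptySpans()) {
  nc <- lexicon@negationCue
  blocked <- function(gapStart, gapEnd) {
    if (gapStart >= gapEnd || nrow(otherSpans) == 0L) return(FALSE)
    any(otherSpans$start < gapEnd & otherSpans$end > gapStart &
          !(otherSpans$start == start & otherSpans$end == end))
  }
  for (i in seq_len(nrow(nc))) {
    cue <- nc$cue[i]
    clen <- cpN(cue)
    for (s in cpFindAll(clause, cue)) {
      if (nc$position[i] == "PRECEDING" && s + clen <= start) {
        if (!blocked(s + clen, start)) return(TRUE)
      }
      if (nc$position[i] == "FOLLOWING" && s >= end) {
        if (!blocked(end, s)) return(TRUE)
      }
    }
  }
  FALSE
}

#' Convert spans to a BIEO tag sequence
#'
#' Characters of each span are tagged B, I..., E (a single-character span is
#' tagged B alone); everything else is O.
#'
#' @param text The source text.
#' @param spans data.frame of non-overlapping spans (aggregation-derived
#'   spans, origin "RTBA_AGG", are skipped).
#' @return A [TaggedSequence-class].
#' @export
spansToBieo <- function(text, spans) {
  ch <- cpChars(text)
  tags <- rep("O", length(ch))
  primary <- spans[spans$origin != "RTBA_AGG", , drop = FALSE]
  for (i in seq_len(nrow(primary))) {
    s <- primary$start[i]; e <- primary$end[i]
    len <- e - s
    if (len == 1L) tags[s + 1L] <- "B"
    else {
      tags[s + 1L] <- "B"
      tags[e] <- "E"
      if (len > 2L) tags[(s + 2L):(e - 1L)] <- "I"
    }
  }
  new("TaggedSequence", characters = ch, tags = tags)
}

#' Check a tag vector against the BIEO grammar
#'
#' I and E may only follow B or I; an I must be continued (by I or E); a
#' single-character span is a lone B.
#'
#' @param tags Character vector of B/I/E/O tags.
#' @return Logical.
#' @export
isValidBieo <- function(tags) {
  if (length(tags) == 0L) return(TRUE)
  if (!all(tags %in% c("B", "I", "E", "O"))) return(FALSE)
  prev <- "O"
  for (t in tags) {
    if (t %in% c("I", "E") && !prev %in% c("B", "I")) return(FALSE)
    if (prev == "I" && !t %in% c("I", "E")) return(FALSE)
    prev <- t
  }
  prev != "I"
}

#' Recognise clinical-finding terms in free text
#'
#' Runs the full rule- and terminology-based pipeline: clause segmentation
#' (caesura kept), reverse maximum matching (with an optional second pass
#' ignoring in-term modifiers), exception filtering, aggregation expansion,
#' negation detection and BIEO tagging. Span offsets refer to the full input
#' text.
#'
#' @param text Input string (one record).
#' @param dict A [TermDictionary-class].
#' @param lexicon A [KeywordLexicon-class].
#' @param index Optional [AggregationIndex-class]; when supplied, accepted
#'   affixes emit constituent-term spans (origin "RTBA_AGG") and all matches
#'   update the tallies.
#' @param maxLen RMM window (default the dictionary's maxLength).
#' @param modifierPass Run the modifier-deletion second pass (default TRUE).
#' @return list(spans = data.frame(start, end, surface, negated, origin),
#'   tagged = [TaggedSequence-class], index = updated index or NULL).
#' @export
recognize <- function(text, dict, lexicon = defaultKeywordLexicon(),
                      index = NULL, maxLen = dict@maxLength,
                      modifierPass = TRUE) {
  clauses <- splitClauses(text, keepCaesura = TRUE, offsets = TRUE)
  allSpans <- emptySpans()
  for (k in seq_len(nrow(clauses))) {
    cl <- clauses$clause[k]
    off <- clauses$start[k]
    spans <- rmmMatch(cl, dict, maxLen)
    if (modifierPass) {
      spans <- rbind(spans, rmmModifierPass(cl, dict, lexicon, maxLen, spans))
      spans <- spans[order(spans$start), , drop = FALSE]
    }
    spans <- filterExceptions(spans, cl, lexicon)
    if (!is.null(index)) {
      ex <- expandAggregations(spans, cl, index)
      spans <- ex$spans
      index <- ex$index
    }
    if (nrow(spans)) {
      primary <- spans[spans$origin != "RTBA_AGG", , drop = FALSE]
      spans$negated <- vapply(seq_len(nrow(spans)), function(i)
        detectNegation(spans$start[i], spans$end[i], cl, lexicon, primary),
        logical(1))
      spans$start <- spans$start + off
      spans$end <- spans$end + off
      allSpans <- rbind(allSpans, spans)
    }
  }
  allSpans <- allSpans[order(allSpans$start, allSpans$end), , drop = FALSE]
  rownames(allSpans) <- NULL
  list(spans = allSpans, tagged = spansToBieo(text, allSpans), index = index)
}

#' Write spans for one or more records to TSV
#'
#' Columns `recordId<TAB>start<TAB>end<TAB>surface<TAB>negated<TAB>origin`.
#'
#' @param spans data.frame with a recordId column plus span columns.
#' @param path Output file.
#' @export
exportSpans <- function(spans, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(spans$recordId, spans$start, spans$end, spans$surface,
                   as.integer(spans$negated), spans$origin, sep = "\t"), con)
  invisible(path)
}

#' Write BIEO output in CoNLL style
#'
#' Two columns `character<TAB>tag`, blank line between records.
#'
#' @param tagged List of [TaggedSequence-class] objects.
#' @param path Output file.
#' @export
exportBieo <- function(tagged, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (k in seq_along(tagged)) {
    ts <- tagged[[k]]
    writeLines(paste(ts@characters, ts@tags, sep = "\t"), con)
    if (k < length(tagged)) writeLines("", con)
  }
  invisible(path)
}
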