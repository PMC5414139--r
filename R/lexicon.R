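# Term dictionary, keyword lexicon and referenced-concept I/O.
#
# File contracts (UTF-8 TSV, '#'-prefixed comment lines ignored):
#   term dictionary:     surface <TAB> frequency <TAB> source <TAB> status
#   keyword lexicon:     group <TAB> entry [<TAB> positionTag]
#   referenced concepts: surface <TAB> nomenclature <TAB> conceptCode

readTsvLines <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Construct a TermDictionary from an entries data.frame
#'
#' Duplicate surfaces are merged by summing frequencies; the retained status
#' is the "most valid" one (VALID > CANDIDATE > REJECTED), so a term
#' confirmed anywhere stays confirmed.
#'
#' @param entries data.frame with columns surface, frequency, source, status.
#' @param maxLength maximum surface length in code points for VALID entries.
#' @return A [TermDictionary-class] object.
#' @export
termDictionary <- function(entries, maxLength = 16L) {
  entries$surface <- enc2utf8(as.character(entries$surface))
  entries$frequency <- as.integer(entries$frequency)
  entries$source <- as.character(entries$source)
  entries$status <- as.character(entries$status)
  if (anyDuplicated(entries$surface)) {
    sp <- split(entries, entries$surface)
    entries <- do.call(rbind, lapply(sp, function(g) {
      data.frame(surface = g$surface[1L],
                 frequency = sum(g$frequency),
                 source = g$source[1L],
                 status = TERM_STATUSES[min(match(g$status, TERM_STATUSES))],
                 stringsAsFactors = FALSE)
    }))
  }
  rownames(entries) <- NULL
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  for (s in entries$surface) assign(s, TRUE, envir = idx)
  new("TermDictionary", entries = entries, index = idx,
      maxLength = as.integer(maxLength))
}

#' Is a surface present in the dictionary?
#' @param dict A TermDictionary.
#' @param surface Character vector of surfaces.
#' @return Logical vector.
#' @export
dictContains <- function(dict, surface) {
  vapply(enc2utf8(surface), function(s) exists(s, envir = dict@index,
                                               inherits = FALSE), logical(1),
         USE.NAMES = FALSE)
}

#' Load a term dictionary from TSV
#'
#' @param path TSV file (surface, frequency, source, status).
#' @param statusFilter Optional status; only matching rows are kept.
#' @param maxLength Maximum VALID surface length in code points.
#' @return A [TermDictionary-class].
#' @export
loadTermDictionary <- function(path, statusFilter = NULL, maxLength = 16L) {
  tl <- readTsvLines(path)
  rows <- strsplit(tl$lines, "\t", fixed = TRUE)
  bad <- which(lengths(rows) != 4L)
  if (length(bad))
    stop("line ", tl$lineno[bad[1L]], ": expected 4 columns, got ",
         length(rows[[bad[1L]]]))
  e <- data.frame(surface = vapply(rows, `[`, "", 1L),
                  frequency = vapply(rows, `[`, "", 2L),
                  source = vapply(rows, `[`, "", 3L),
                  status = vapply(rows, `[`, "", 4L),
                  stringsAsFactors = FALSE)
  freq <- suppressWarnings(as.integer(e$frequency))
  if (anyNA(freq) && nrow(e))
    stop("line ", tl$lineno[which(is.na(freq))[1L]],
         ": frequency is not an integer")
  e$frequency <- freq
  if (!is.null(statusFilter)) {
    statusFilter <- match.arg(statusFilter, TERM_STATUSES)
    e <- e[e$status == statusFilter, , drop = FALSE]
  }
  termDictionary(e, maxLength = maxLength)
}

#' Save a term dictionary to TSV
#' @param dict A TermDictionary.
#' @param path Output file.
#' @export
saveTermDictionary <- function(dict, path) {
  e <- dict@entries
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(e$surface, e$frequency, e$source, e$status, sep = "\t"),
             con, useBytes = FALSE)
  invisible(path)
}

#' Validate a term surface
#'
#' A valid clinical-finding term contains no punctuation code point (the
#' exclusion criterion applied during manual candidate validation) and is at
#' most `maxLength` code points long.
#'
#' @param surface Non-empty string.
#' @param maxLength Length cap in code points (default 16).
#' @param punctuation Punctuation inventory, see [defaultPunctuation()].
#' @return Named logical vector c(punctuationFree=, withinMaxLength=).
#' @export
#' @examples
#' validateTerm("咽痛")
#' validateTerm("大便干结,表面带血")
validateTerm <- function(surface, maxLength = 16L,
                         punctuation = defaultPunctuation()) {
  if (length(surface) != 1L || is.na(surface) || !nzchar(surface))
    stop("surface must be a non-empty string")
  c(punctuationFree = !containsPunctuation(surface, punctuation),
    withinMaxLength = cpN(surface) <= maxLength)
}

# Built-in keyword defaults. Every group ships the examples used throughout
# recognition; negation cues carry a PRECEDING/FOLLOWING position tag.
defaultKeywordGroups <- function() {
  list(
    timePeriod = c("小时", "分钟", "星期", "年", "月", "周", "天", "日", "夜",
                   "秒"),
    number = c(as.character(0:9), cpChars("０１２３４５６７８９"),
               "半", "一", "二", "两", "三", "四", "五", "六", "七", "八",
               "九", "十", "百", "零", "余", "数", "+", ".", " ", "　"),
    modifier = c("持续", "逐渐", "明显", "稍显", "反复", "轻度", "轻微",
                 "略有"),
    exceptionWithContext = c("抗乙肝药物", "多尿期", "最高血压"),
    negationCue = data.frame(
      cue = c("不伴", "无", "否认", "未", "消失", "不明显"),
      position = c("PRECEDING", "PRECEDING", "PRECEDING", "PRECEDING",
                   "FOLLOWING", "FOLLOWING"),
      stringsAsFactors = FALSE),
    stopChar = c("的", "了", "之", "其", "此", "而")
  )
}

#' The built-in keyword lexicon
#'
#' Time-period and number entries for duration stripping, in-term modifiers,
#' exception-with-context phrases, the six negation cues
#' (不伴, 无, 否认, 未, 消失, 不明显) and stop characters.
#'
#' @return A [KeywordLexicon-class].
#' @export
defaultKeywordLexicon <- function() {
  d <- defaultKeywordGroups()
  new("KeywordLexicon", timePeriod = d$timePeriod, number = d$number,
      modifier = d$modifier, exceptionWithContext = d$exceptionWithContext,
      negationCue = d$negationCue, stopChar = d$stopChar)
}

#' Load a keyword lexicon from TSV
#'
#' Columns `group<TAB>entry[<TAB>positionTag]`. Groups missing from the file
#' fall back to the built-in defaults; an unknown group name is an error.
#'
#' @param path TSV file.
#' @return A [KeywordLexicon-class].
#' @export
loadKeywordLexicon <- function(path) {
  tl <- readTsvLines(path)
  rows <- strsplit(tl$lines, "\t", fixed = TRUE)
  short <- which(lengths(rows) < 2L)
  if (length(short))
    stop("line ", tl$lineno[short[1L]], ": expected at least 2 columns")
  groups <- vapply(rows, `[`, "", 1L)
  unknown <- setdiff(unique(groups), KEYWORD_GROUPS)
  if (length(unknown))
    stop("unknown keyword group: ", paste(unknown, collapse = ", "))
  d <- defaultKeywordGroups()
  for (g in setdiff(KEYWORD_GROUPS, "negationCue")) {
    hit <- groups == g
    if (any(hit)) d[[g]] <- vapply(rows[hit], `[`, "", 2L)
  }
  hit <- groups == "negationCue"
  if (any(hit)) {
    cues <- vapply(rows[hit], `[`, "", 2L)
    pos <- vapply(rows[hit], function(r)
      if (length(r) >= 3L) r[3L] else "PRECEDING", "")
    d$negationCue <- data.frame(cue = cues, position = pos,
                                stringsAsFactors = FALSE)
  }
  new("KeywordLexicon", timePeriod = d$timePeriod, number = d$number,
      modifier = d$modifier, exceptionWithContext = d$exceptionWithContext,
      negationCue = d$negationCue, stopChar = d$stopChar)
}

#' Load referenced concepts from TSV
#'
#' Columns `surface<TAB>nomenclature<TAB>conceptCode`; (surface, nomenclature)
#' must be unique and conceptCode non-empty.
#'
#' @param path TSV file.
#' @return data.frame with columns surface, nomenclature, conceptCode.
#' @export
loadConcepts <- function(path) {
  tl <- readTsvLines(path)
  rows <- strsplit(tl$lines, "\t", fixed = TRUE)
  bad <- which(lengths(rows) != 3L)
  if (length(bad))
    stop("line ", tl$lineno[bad[1L]], ": expected 3 columns")
  cc <- data.frame(surface = vapply(rows, `[`, "", 1L),
                   nomenclature = vapply(rows, `[`, "", 2L),
                   conceptCode = vapply(rows, `[`, "", 3L),
                   stringsAsFactors = FALSE)
  if (!all(cc$nomenclature %in% NOMENCLATURES))
    stop("nomenclature must be one of ", paste(NOMENCLATURES, collapse = ", "))
  if (any(!nzchar(cc$conceptCode))) stop("conceptCode must be non-empty")
  if (anyDuplicated(paste(cc$surface, cc$nomenclature)))
    stop("(surface, nomenclature) pairs must be unique")
  cc
}
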