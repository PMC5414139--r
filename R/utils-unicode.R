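# Code-point level string helpers. "Character" throughout the package means
# Unicode code point; all splitting/indexing goes through utf8ToInt so that
# behaviour is locale-independent.

#' Split a string into code points
#'
#' @param x A length-one character string.
#' @return Character vector with one element per Unicode code point.
#' @keywords internal
cpChars <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  intToUtf8(utf8ToInt(enc2utf8(x)), multiple = TRUE)
}

#' @keywords internal
cpN <- function(x) {
  if (is.na(x) || !nzchar(x)) return(0L)
  length(utf8ToInt(enc2utf8(x)))
}

#' Code-point substring, 1-based inclusive indices
#' @keywords internal
cpSub <- function(x, start, end) {
  cps <- utf8ToInt(enc2utf8(x))
  if (start > end || start > length(cps)) return("")
  intToUtf8(cps[start:min(end, length(cps))])
}

#' Default punctuation inventory
#'
#' Explicit enumeration of the half-width and full-width punctuation code
#' points used for clause splitting and term validation. The inventory can be
#' extended by the caller; membership is tested per code point.
#'
#' @param which One of "all", "halfwidth", "fullwidth".
#' @return Character vector of single code points.
#' @export
#' @examples
#' "，" %in% defaultPunctuation() # full-width comma
defaultPunctuation <- function(which = c("all", "halfwidth", "fullwidth")) {
  which <- match.arg(which)
  half <- c(",", ".", ":", ";", "\"", "'", "?", "!", "(", ")", "[", "]",
            "/", "\\", "-")
  full <- cpChars("，。：；“”‘’、？！（）【】《》")
  switch(which, halfwidth = half, fullwidth = full, all = c(half, full))
}

# Caesura sign (ideographic comma), exempt from clause splitting inside the
# recogniser.
CAESURA <- "、"

#' Does a surface contain any punctuation code point?
#' @keywords internal
containsPunctuation <- function(surface, punctuation = defaultPunctuation()) {
  any(cpChars(surface) %in% punctuation)
}

#' Longest common prefix / suffix length in code points
#' @keywords internal
commonPrefixLen <- function(a, b) {
  ca <- utf8ToInt(enc2utf8(a)); cb <- utf8ToInt(enc2utf8(b))
  n <- min(length(ca), length(cb))
  if (n == 0L) return(0L)
  neq <- which(ca[seq_len(n)] != cb[seq_len(n)])
  if (length(neq) == 0L) n else neq[1L] - 1L
}

#' @keywords internal
commonSuffixLen <- function(a, b) {
  ca <- rev(utf8ToInt(enc2utf8(a))); cb <- rev(utf8ToInt(enc2utf8(b)))
  n <- min(length(ca), length(cb))
  if (n == 0L) return(0L)
  neq <- which(ca[seq_len(n)] != cb[seq_len(n)])
  if (length(neq) == 0L) n else neq[1L] - 1L
}

#' All occurrences of a needle in a haystack, code-point offsets
#'
#' @return Integer vector of 0-based start offsets (possibly overlapping).
#' @keywords internal
cpFindAll <- function(haystack, needle) {
  h <- cpChars(haystack); nd <- cpChars(needle)
  nh <- length(h); nn <- length(nd)
  if (nn == 0L || nn > nh) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(nh - nn + 1L)) {
    if (all(h[i:(i + nn - 1L)] == nd)) hits <- c(hits, i - 1L)
  }
  hits
}

`%||%` <- function(a, b) if (is.null(a)) b else a
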