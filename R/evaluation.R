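# Span-level evaluation (exact-match precision/recall/F-score), Cohen's
# kappa for categorical agreement, pairwise-F annotation agreement, and the
# CRF-minus-rule new-term discovery loop.

checkNoOverlap <- function(spans, label) {
  if (nrow(spans) < 2L) return(invisible())
  o <- order(spans$start, spans$end)
  s <- spans[o, , drop = FALSE]
  if (any(s$start[-1L] < s$end[-nrow(s)]))
    stop("overlapping spans within ", label, " input")
  invisible()
}

#' Exact-span confusion counts
#'
#' A predicted span is a true positive iff some gold span has exactly the
#' same (start, end); a partially overlapping prediction counts as both a
#' false positive and a false negative. Spans within one side must be
#' non-overlapping.
#'
#' @param gold,predicted data.frames with columns start, end (and optionally
#'   recordId; counts are then accumulated per record).
#' @return list(tp, fp, fn).
#' @export
spanConfusion <- function(gold, predicted) {
  if (!"recordId" %in% names(gold)) gold$recordId <- 1L
  if (!"recordId" %in% names(predicted)) predicted$recordId <- 1L
  tp <- 0L
  for (rid in union(unique(gold$recordId), unique(predicted$recordId))) {
    g <- gold[gold$recordId == rid, , drop = FALSE]
    p <- predicted[predicted$recordId == rid, , drop = FALSE]
    checkNoOverlap(g, "gold")
    checkNoOverlap(p, "predicted")
    gk <- paste(g$start, g$end)
    pk <- paste(p$start, p$end)
    tp <- tp + length(intersect(gk, pk))
  }
  list(tp = tp, fp = nrow(predicted) - tp, fn = nrow(gold) - tp)
}

#' Precision, recall and F-score from confusion counts
#'
#' P = TP/(TP+FP), R = TP/(TP+FN), F = 2PR/(P+R); any 0/0 ratio is 0.
#'
#' @param counts list or vector with tp, fp, fn.
#' @return Named numeric c(precision=, recall=, fscore=).
#' @export
#' @examples
#' prf(list(tp = 10165, fp = 743, fn = 1053)) # 0.932 / 0.906 / 0.919
prf <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]; fn <- counts[["fn"]]
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, fscore = f)
}

#' Cohen's kappa for two categorical label lists
#'
#' kappa = (p_o - p_e) / (1 - p_e) with observed and chance agreement from
#' the contingency table. If chance agreement is 1 the statistic is defined
#' as 1 when observed agreement is also 1, else 0.
#'
#' @param labels1,labels2 Equal-length vectors.
#' @return The kappa statistic.
#' @export
cohenKappa <- function(labels1, labels2) {
  if (length(labels1) != length(labels2))
    stop("label lists must have equal length")
  stopifnot(length(labels1) >= 1L)
  n <- length(labels1)
  po <- mean(labels1 == labels2)
  cats <- union(unique(labels1), unique(labels2))
  p1 <- vapply(cats, function(k) mean(labels1 == k), numeric(1))
  p2 <- vapply(cats, function(k) mean(labels2 == k), numeric(1))
  pe <- sum(p1 * p2)
  if (abs(1 - pe) < .Machine$double.eps^0.5)
    return(if (abs(1 - po) < .Machine$double.eps^0.5) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Pairwise-F agreement between two annotators' spans
#'
#' F-score of one annotation against the other; the F component is symmetric
#' in the two arguments (swapping them exchanges precision and recall).
#'
#' @param annot1,annot2 Span data.frames over the same text/corpus.
#' @return Named numeric c(precision=, recall=, fscore=).
#' @export
annotationAgreementF <- function(annot1, annot2) {
  prf(spanConfusion(annot1, annot2))
}

#' Discover new term candidates from CRF-minus-rule differences
#'
#' Collects the surfaces of CRF spans with no exact-match rule-based span in
#' the same record, tallies them, and emits surfaces with tally >= `minFreq`
#' sorted by tally descending (ties by surface), with up to 5 example
#' contexts each.
#'
#' @param crfSpans,rtbaSpans data.frames (recordId, start, end, surface).
#' @param minFreq Minimum tally (default 2).
#' @param texts Optional named/indexed character vector of record texts for
#'   context snippets.
#' @param contextWindow Code points of context either side (default 8).
#' @return data.frame (surface, frequency, exampleContexts).
#' @export
discoverNewTerms <- function(crfSpans, rtbaSpans, minFreq = 2L, texts = NULL,
                             contextWindow = 8L) {
  if (!"recordId" %in% names(crfSpans)) crfSpans$recordId <- 1L
  if (!"recordId" %in% names(rtbaSpans)) rtbaSpans$recordId <- 1L
  rtbaKey <- paste(rtbaSpans$recordId, rtbaSpans$start, rtbaSpans$end)
  crfKey <- paste(crfSpans$recordId, crfSpans$start, crfSpans$end)
  novel <- crfSpans[!crfKey %in% rtbaKey, , drop = FALSE]
  if (nrow(novel) == 0L)
    return(data.frame(surface = character(0), frequency = integer(0),
                      exampleContexts = character(0), stringsAsFactors = FALSE))
  tab <- table(novel$surface)
  keep <- tab[tab >= minFreq]
  if (length(keep) == 0L)
    return(data.frame(surface = character(0), frequency = integer(0),
                      exampleContexts = character(0), stringsAsFactors = FALSE))
  ord <- order(-as.integer(keep), names(keep), method = "radix")
  surfaces <- names(keep)[ord]
  contexts <- vapply(surfaces, function(sf) {
    rows <- utils::head(which(novel$surface == sf), 5L)
    if (is.null(texts)) return("")
    snips <- vapply(rows, function(r) {
      txt <- texts[[novel$recordId[r]]]
      lo <- max(1L, novel$start[r] - contextWindow + 1L)
      hi <- min(cpN(txt), novel$end[r] + contextWindow)
      cpSub(txt, lo, hi)
    }, "")
    paste(snips, collapse = " | ")
  }, "", USE.NAMES = FALSE)
  data.frame(surface = surfaces, frequency = as.integer(keep)[ord],
             exampleContexts = contexts, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Bundled recognition benchmark confusion counts
#'
#' Published span-level TP/FP/FN counts for a family of character-feature CRF
#' models, word-feature selection rounds, and the rule- and terminology-based
#' recogniser, all evaluated on one 11,218-span test corpus. Used to exercise
#' the metric arithmetic.
#'
#' @return data.frame (group, model, round, tp, fp, fn).
#' @export
loadRecognitionBenchmarks <- function() {
  path <- system.file("extdata", "recognition_eval_counts.tsv",
                      package = "ClinTermEnrich", mustWork = TRUE)
  tl <- readTsvLines(path)
  rows <- strsplit(tl$lines, "\t", fixed = TRUE)
  stopifnot(all(lengths(rows) == 6L))
  data.frame(group = vapply(rows, `[`, "", 1L),
             model = vapply(rows, `[`, "", 2L),
             round = vapply(rows, `[`, "", 3L),
             tp = as.integer(vapply(rows, `[`, "", 4L)),
             fp = as.integer(vapply(rows, `[`, "", 5L)),
             fn = as.integer(vapply(rows, `[`, "", 6L)),
             stringsAsFactors = FALSE)
}

#' Round half up
#'
#' Rounding convention used when comparing computed metrics against published
#' 3-decimal values (base R rounds half to even).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
roundHalfUp <- function(x, digits = 3L) {
  floor(x * 10^digits + 0.5) / 10^digits
}
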