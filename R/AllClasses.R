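#' @import methods
NULL

TERM_SOURCES  <- c("CCC", "CID", "DISCOVERY")
TERM_STATUSES <- c("VALID", "CANDIDATE", "REJECTED") # "most valid" first
KEYWORD_GROUPS <- c("timePeriod", "number", "modifier", "exceptionWithContext",
                    "negationCue", "stopChar")
NEGATION_POSITIONS <- c("PRECEDING", "FOLLOWING")
NOMENCLATURES <- c("SNOMED3_ZH", "ICD10_ZH")

#' TermDictionary: a dictionary of clinical-finding terms
#'
#' Holds term entries (surface, frequency, source, status) with unique
#' surfaces, plus a surface-keyed hash index used by the reverse
#' maximum-matching recogniser.
#'
#' @slot entries data.frame with columns surface, frequency, source, status.
#' @slot index environment hashing surface -> TRUE for O(1) membership.
#' @slot maxLength integer, the configured maximum term length in code points.
#' @export
setClass("TermDictionary",
  representation(entries = "data.frame", index = "environment",
                 maxLength = "integer"),
  prototype(entries = data.frame(surface = character(0),
                                 frequency = integer(0),
                                 source = character(0),
                                 status = character(0),
                                 stringsAsFactors = FALSE),
            maxLength = 16L))

setValidity("TermDictionary", function(object) {
  e <- object@entries
  msgs <- character(0)
  need <- c("surface", "frequency", "source", "status")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(e$surface)) msgs <- c(msgs, "surfaces must be unique")
  if (any(!nzchar(e$surface))) msgs <- c(msgs, "surfaces must be non-empty")
  if (any(e$frequency < 0)) msgs <- c(msgs, "frequencies must be non-negative")
  if (!all(e$source %in% TERM_SOURCES))
    msgs <- c(msgs, "source must be one of CCC, CID, DISCOVERY")
  if (!all(e$status %in% TERM_STATUSES))
    msgs <- c(msgs, "status must be one of VALID, CANDIDATE, REJECTED")
  valid <- e$surface[e$status == "VALID"]
  if (length(valid)) {
    bad <- valid[vapply(valid, containsPunctuation, logical(1)) |
                   vapply(valid, cpN, integer(1)) > object@maxLength]
    if (length(bad))
      msgs <- c(msgs, paste0("VALID entries must be punctuation-free and at most ",
                             object@maxLength, " code points: ",
                             paste(utils::head(bad, 3), collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' KeywordLexicon: keyword groups for term retrieval and recognition
#'
#' The word groups driving extraction and recognition: time-period and number
#' entries for duration stripping, in-term modifiers, exception-with-context
#' phrases, negation cues (with a PRECEDING/FOLLOWING position tag) and stop
#' characters.
#'
#' @export
setClass("KeywordLexicon",
  representation(timePeriod = "character", number = "character",
                 modifier = "character", exceptionWithContext = "character",
                 negationCue = "data.frame", stopChar = "character"))

setValidity("KeywordLexicon", function(object) {
  msgs <- character(0)
  for (nm in c("timePeriod", "number", "modifier", "exceptionWithContext",
               "stopChar")) {
    v <- slot(object, nm)
    if (length(v) == 0L) msgs <- c(msgs, paste(nm, "must be non-empty"))
    if (any(!nzchar(v))) msgs <- c(msgs, paste(nm, "contains an empty entry"))
  }
  nc <- object@negationCue
  if (!all(c("cue", "position") %in% names(nc)))
    return("negationCue needs columns cue, position")
  if (nrow(nc) == 0L) msgs <- c(msgs, "negationCue must be non-empty")
  if (any(!nzchar(nc$cue))) msgs <- c(msgs, "negationCue contains an empty cue")
  if (!all(nc$position %in% NEGATION_POSITIONS))
    msgs <- c(msgs, "negation position must be PRECEDING or FOLLOWING")
  if (any(vapply(object@stopChar, cpN, integer(1)) != 1L))
    msgs <- c(msgs, "stopChar entries must be single code points")
  if (length(msgs)) msgs else TRUE
})

#' CandidateTally: tallied candidate terms from record streams
#'
#' @slot counts named integer vector, surface -> occurrence count.
#' @slot minFreq strict emission threshold (candidates need count > minFreq).
#' @slot source origin record type of the tally ("CCC" or "CID").
#' @export
setClass("CandidateTally",
  representation(counts = "integer", minFreq = "integer", source = "character"))

setValidity("CandidateTally", function(object) {
  if (length(object@counts) && any(object@counts < 1L))
    return("all tallied counts must be >= 1")
  if (length(object@counts) && is.null(names(object@counts)))
    return("counts must be named by surface")
  TRUE
})

#' MappingQueue: ranked referenced-concept candidates for one term
#'
#' @slot termSurface the query term.
#' @slot candidates data.frame with columns surface, nomenclature,
#'   conceptCode, ls, ds, hs, sorted by hs descending (ties by surface).
#' @export
setClass("MappingQueue",
  representation(termSurface = "character", candidates = "data.frame"))

setValidity("MappingQueue", function(object) {
  cd <- object@candidates
  need <- c("surface", "nomenclature", "conceptCode", "ls", "ds", "hs")
  if (!all(need %in% names(cd)))
    return(paste("candidates must have columns", paste(need, collapse = ", ")))
  if (nrow(cd) > 1L && any(diff(cd$hs) > 1e-12))
    return("hs must be non-increasing down the queue")
  if (anyDuplicated(paste(cd$surface, cd$nomenclature)))
    return("duplicate (surface, nomenclature) candidates")
  TRUE
})

#' AggregationIndex: potential prefixes/suffixes for aggregated terms
#'
#' For pairs of dictionary terms sharing a prefix (or suffix), the residual of
#' one term is a potential suffix (or prefix) of the other; hits observed in
#' text are tallied and only accepted affixes fire at recognition time.
#'
#' @slot affixes data.frame with columns term, affix, side ("prefix" or
#'   "suffix"), constituent (the full constituent term the affix encodes),
#'   frequency, accepted.
#' @export
setClass("AggregationIndex", representation(affixes = "data.frame"))

setValidity("AggregationIndex", function(object) {
  a <- object@affixes
  need <- c("term", "affix", "side", "constituent", "frequency", "accepted")
  if (!all(need %in% names(a)))
    return(paste("affixes must have columns", paste(need, collapse = ", ")))
  if (nrow(a) && any(!nzchar(a$affix))) return("affix must never be empty")
  if (nrow(a) && !all(a$side %in% c("prefix", "suffix")))
    return("side must be prefix or suffix")
  TRUE
})

#' TaggedSequence: characters with BIEO tags
#'
#' @slot characters character vector of single code points.
#' @slot tags character vector of B/I/E/O, same length.
#' @export
setClass("TaggedSequence",
  representation(characters = "character", tags = "character"))

setValidity("TaggedSequence", function(object) {
  if (length(object@characters) != length(object@tags))
    return("characters and tags must have equal length")
  if (!all(object@tags %in% c("B", "I", "E", "O")))
    return("tags must be B, I, E or O")
  if (!isValidBieo(object@tags)) return("tag sequence violates BIEO grammar")
  TRUE
})

#' GoldCorpus: a generated synthetic corpus with planted truth
#'
#' @slot dictionary the planted TermDictionary.
#' @slot concepts data.frame of referenced concepts (surface, nomenclature,
#'   conceptCode).
#' @slot conceptMap data.frame term -> planted true concept surface/code.
#' @slot ccc,cid,hpi character vectors of generated records.
#' @slot goldSpans data.frame (recordId, start, end, surface, negated) over hpi.
#' @slot diagCooccur data.frame (termSurface, icd3Category, count) covering
#'   both terms and concept surfaces.
#' @slot cccTally named integer vector, planted CCC surface tally.
#' @slot config the GeneratorConfig list used.
#' @export
setClass("GoldCorpus",
  representation(dictionary = "TermDictionary", concepts = "data.frame",
                 conceptMap = "data.frame", ccc = "character",
                 cid = "character", hpi = "character",
                 goldSpans = "data.frame", diagCooccur = "data.frame",
                 cccTally = "integer", config = "list"))

# ---- show methods -----------------------------------------------------------

setMethod("show", "TermDictionary", function(object) {
  e <- object@entries
  cat("TermDictionary with", nrow(e), "entries\n")
  if (nrow(e)) {
    tab <- table(e$status)
    cat("  status:", paste(names(tab), as.integer(tab), collapse = ", "), "\n")
    cat("  max surface length:", object@maxLength, "code points\n")
  }
})

setMethod("show", "KeywordLexicon", function(object) {
  cat("KeywordLexicon\n")
  cat("  timePeriod:", length(object@timePeriod),
      " number:", length(object@number),
      " modifier:", length(object@modifier), "\n")
  cat("  exceptionWithContext:", length(object@exceptionWithContext),
      " negationCue:", nrow(object@negationCue),
      " stopChar:", length(object@stopChar), "\n")
})

setMethod("show", "CandidateTally", function(object) {
  cat("CandidateTally (", object@source, "): ", length(object@counts),
      " distinct surfaces, minFreq > ", object@minFreq, "\n", sep = "")
  emitted <- sum(object@counts > object@minFreq)
  cat("  candidates above threshold:", emitted, "\n")
})

setMethod("show", "MappingQueue", function(object) {
  cat("MappingQueue for term:", object@termSurface, "\n")
  cat("  candidates:", nrow(object@candidates), "\n")
  if (nrow(object@candidates))
    print(utils::head(object@candidates, 5), row.names = FALSE)
})

setMethod("show", "AggregationIndex", function(object) {
  cat("AggregationIndex:", nrow(object@affixes), "potential affixes,",
      sum(object@affixes$accepted), "accepted\n")
})

setMethod("show", "TaggedSequence", function(object) {
  cat("TaggedSequence of length", length(object@characters), "\n")
  n <- min(length(object@characters), 20L)
  if (n) {
    cat(" ", paste(object@characters[seq_len(n)], collapse = " "), "\n")
    cat(" ", paste(object@tags[seq_len(n)], collapse = " "), "\n")
  }
})

setMethod("show", "GoldCorpus", function(object) {
  cat("GoldCorpus (seed ", object@config$seed, ")\n", sep = "")
  cat("  dictionary:", nrow(object@dictionary@entries), "terms;",
      nrow(object@concepts), "concepts\n")
  cat("  records: CCC", length(object@ccc), "/ CID", length(object@cid),
      "/ HPI", length(object@hpi), "\n")
  cat("  gold spans:", nrow(object@goldSpans), "\n")
})

# ---- accessors --------------------------------------------------------------

#' Accessors for package containers
#'
#' @param x The object.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dictEntries", function(x, ...) standardGeneric("dictEntries"))
#' @rdname accessors
#' @export
setMethod("dictEntries", "TermDictionary", function(x, ...) x@entries)

#' @rdname accessors
#' @export
setGeneric("dictSurfaces", function(x, ...) standardGeneric("dictSurfaces"))
#' @rdname accessors
#' @export
setMethod("dictSurfaces", "TermDictionary", function(x, ...) x@entries$surface)

#' @param group One of timePeriod, number, modifier, exceptionWithContext,
#'   stopChar.
#' @rdname accessors
#' @export
setGeneric("keywordGroup", function(x, group, ...) standardGeneric("keywordGroup"))
#' @rdname accessors
#' @export
setMethod("keywordGroup", "KeywordLexicon", function(x, group, ...) {
  group <- match.arg(group, c("timePeriod", "number", "modifier",
                              "exceptionWithContext", "stopChar"))
  slot(x, group)
})

#' @rdname accessors
#' @export
setGeneric("negationCues", function(x, ...) standardGeneric("negationCues"))
#' @rdname accessors
#' @export
setMethod("negationCues", "KeywordLexicon", function(x, ...) x@negationCue)

#' @param minFreq Optional override of the tally's emission threshold.
#' @rdname accessors
#' @export
setGeneric("candidates", function(x, ...) standardGeneric("candidates"))

#' @rdname accessors
#' @export
setMethod("candidates", "CandidateTally", function(x, minFreq = NULL, ...) {
  thr <- as.integer(minFreq %||% x@minFreq)
  keep <- x@counts[x@counts > thr]
  ord <- order(-keep, names(keep), method = "radix")
  keep <- keep[ord]
  data.frame(surface = names(keep), frequency = as.integer(keep),
             source = rep(x@source, length(keep)),
             status = rep("CANDIDATE", length(keep)),
             stringsAsFactors = FALSE, row.names = NULL)
})

#' @rdname accessors
#' @export
setMethod("candidates", "MappingQueue", function(x, ...) x@candidates)

#' @rdname accessors
#' @export
setGeneric("tagSeq", function(x, ...) standardGeneric("tagSeq"))
#' @rdname accessors
#' @export
setMethod("tagSeq", "TaggedSequence", function(x, ...) x@tags)
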