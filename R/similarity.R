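# Similarity metrics for concept mapping.
#
# Literal similarity (LS) is the higher of the Jaro-Winkler score (prefix
# bonus) and its suffix-adjusted variant (suffix bonus): Chinese finding terms
# typically put the body part first and the sensation last, so a shared
# suffix is the stronger signal of a shared clinical meaning.
#
# Diagnosis-related similarity (DS) is the cosine between TF-IDF-weighted
# sparse vectors of ICD-10 three-character discharge-diagnosis categories
# co-occurring with each term.
#
# The hybrid score (HS) combines the two with weight beta, either as an
# arithmetic sum AS = beta*LS + (1-beta)*DS or a quadratic sum
# QS = sqrt(beta*LS^2 + (1-beta)*DS^2).

#' Similarity parameters
#'
#' @param preScale Winkler bonus scaling factor (default 0.1).
#' @param preLenCap Cap on the common prefix/suffix length entering the bonus
#'   (default 4); preScale * preLenCap must not exceed 1 so scores stay in
#'   \[0, 1\].
#' @param beta Weight of literal similarity in the hybrid score (default 0.6).
#' @param combiner "AS" (arithmetic) or "QS" (quadratic).
#' @param tfDenominator "per_term" (term-frequency normalised within each
#'   term's diagnosis profile, the default) or "printed" (normalised by the
#'   corpus-wide category total).
#' @param logIdf Use log(|D|/df) instead of the plain ratio (default FALSE).
#' @return A validated list of class "SimilarityParams".
#' @export
simParams <- function(preScale = 0.1, preLenCap = 4L, beta = 0.6,
                      combiner = c("AS", "QS"),
                      tfDenominator = c("per_term", "printed"),
                      logIdf = FALSE) {
  combiner <- match.arg(combiner)
  tfDenominator <- match.arg(tfDenominator)
  stopifnot(beta >= 0, beta <= 1, preScale >= 0, preLenCap >= 0,
            preScale * preLenCap <= 1)
  structure(list(preScale = preScale, preLenCap = as.integer(preLenCap),
                 beta = beta, combiner = combiner,
                 tfDenominator = tfDenominator, logIdf = logIdf),
            class = "SimilarityParams")
}

#' Jaro similarity
#'
#' Standard Jaro similarity over code points: matches are equal code points
#' within a window of floor(max(|s1|,|s2|)/2) - 1; transpositions are half
#' the number of out-of-order matched pairs. Two empty strings score 1;
#' exactly one empty or zero matches scores 0.
#'
#' @param s1,s2 Strings.
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' jaroSim("MARTHA", "MARHTA") # 0.9444
jaroSim <- function(s1, s2) {
  a <- cpChars(s1); b <- cpChars(s2)
  la <- length(a); lb <- length(b)
  if (la == 0L && lb == 0L) return(1)
  if (la == 0L || lb == 0L) return(0)
  window <- max(floor(max(la, lb) / 2) - 1, 0)
  bUsed <- logical(lb)
  aMatch <- integer(0)  # positions in b of a's matches, in a-order
  for (i in seq_len(la)) {
    lo <- max(1L, i - window); hi <- min(lb, i + window)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!bUsed[j] && a[i] == b[j]) {
        bUsed[j] <- TRUE
        aMatch <- c(aMatch, j)
        break
      }
    }
  }
  m <- length(aMatch)
  if (m == 0L) return(0)
  # transpositions: matched characters compared in s1-order vs s2-order
  transp <- sum(b[aMatch] != b[sort(aMatch)]) / 2
  (m / la + m / lb + (m - transp) / m) / 3
}

#' Jaro-Winkler similarity (prefix bonus)
#'
#' JWD = JD + preLen * preScale * (1 - JD), where preLen is the common-prefix
#' length capped at `preLenCap`.
#'
#' @param s1,s2 Strings.
#' @param params A [simParams()] object.
#' @return A number in \[0, 1\].
#' @export
jaroWinkler <- function(s1, s2, params = simParams()) {
  jd <- jaroSim(s1, s2)
  preLen <- min(commonPrefixLen(s1, s2), params$preLenCap)
  jd + preLen * params$preScale * (1 - jd)
}

#' Suffix-adjusted Jaro-Winkler similarity
#'
#' Identical to [jaroWinkler()] but the bonus rewards the common suffix
#' instead of the prefix, reflecting that shared sensation suffixes carry the
#' clinical meaning in Chinese finding terms.
#'
#' @inheritParams jaroWinkler
#' @return A number in \[0, 1\].
#' @export
adjustedJaroWinkler <- function(s1, s2, params = simParams()) {
  jd <- jaroSim(s1, s2)
  sufLen <- min(commonSuffixLen(s1, s2), params$preLenCap)
  jd + sufLen * params$preScale * (1 - jd)
}

#' Literal similarity
#'
#' The higher of the prefix-bonus and suffix-bonus Jaro-Winkler scores.
#'
#' @inheritParams jaroWinkler
#' @return A number in \[0, 1\].
#' @export
literalSimilarity <- function(s1, s2, params = simParams()) {
  max(jaroWinkler(s1, s2, params), adjustedJaroWinkler(s1, s2, params))
}

#' Corpus-level diagnosis statistics
#'
#' From a list of per-term diagnosis profiles, computes the document
#' frequency df_j of each ICD-10 three-character category (the number of
#' terms whose profile contains it), the per-category corpus totals, and
#' |D|, the number of distinct diagnosis categories observed.
#'
#' @param profiles Named list (term surface -> named numeric vector of
#'   category counts), or a data.frame with columns termSurface,
#'   icd3Category, count.
#' @return List with elements totalDiagnoses, docFreq, catTotals, class
#'   "CorpusDiagnosisStats".
#' @export
buildCorpusStats <- function(profiles) {
  if (is.data.frame(profiles)) profiles <- profilesFromCooccur(profiles)
  allCats <- unlist(lapply(profiles, names), use.names = FALSE)
  df <- table(unlist(lapply(profiles, function(p) unique(names(p)))))
  tot <- tapply(unlist(profiles, use.names = FALSE), allCats, sum)
  structure(list(totalDiagnoses = length(df),
                 docFreq = stats::setNames(as.integer(df), names(df)),
                 catTotals = stats::setNames(as.numeric(tot), names(tot))),
            class = "CorpusDiagnosisStats")
}

#' Convert a co-occurrence table to per-term profiles
#'
#' @param cooccur data.frame with columns termSurface, icd3Category, count.
#'   Category codes are truncated to their first three characters and
#'   uppercased on load.
#' @return Named list of named count vectors.
#' @export
profilesFromCooccur <- function(cooccur) {
  stopifnot(all(c("termSurface", "icd3Category", "count") %in% names(cooccur)))
  cat3 <- toupper(substr(cooccur$icd3Category, 1L, 3L))
  sp <- split(data.frame(cat = cat3, n = cooccur$count), cooccur$termSurface)
  lapply(sp, function(g) {
    v <- tapply(g$n, g$cat, sum)
    stats::setNames(as.numeric(v), names(v))
  })
}

#' Load a term-diagnosis co-occurrence TSV
#'
#' Columns `termSurface<TAB>icd3Category<TAB>count`; ICD codes are truncated
#' to three characters and uppercased.
#'
#' @param path TSV file.
#' @return data.frame with columns termSurface, icd3Category, count.
#' @export
loadCooccurrence <- function(path) {
  tl <- readTsvLines(path)
  rows <- strsplit(tl$lines, "\t", fixed = TRUE)
  bad <- which(lengths(rows) != 3L)
  if (length(bad)) stop("line ", tl$lineno[bad[1L]], ": expected 3 columns")
  data.frame(termSurface = vapply(rows, `[`, "", 1L),
             icd3Category = toupper(substr(vapply(rows, `[`, "", 2L), 1L, 3L)),
             count = as.numeric(vapply(rows, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' TF-IDF weight vector of one term's diagnosis profile
#'
#' w_j = tf_j * idf_j with tf_j the category's share of the term's diagnosis
#' occurrences (or, with `tfDenominator = "printed"`, the count over the
#' corpus-wide category total) and idf_j = |D| / df_j (optionally logged).
#' Terms whose surface contains a negation cue get an empty vector: negated
#' expressions are excluded from the TF-IDF scheme.
#'
#' @param profile Named numeric vector of category counts for one term.
#' @param stats A [buildCorpusStats()] result.
#' @param params A [simParams()] object.
#' @param surface Optional term surface, checked against `negation` cues.
#' @param negation Character vector of negation cues (default from the
#'   built-in lexicon).
#' @return Named numeric vector of non-negative weights (possibly empty).
#' @export
buildWeightVector <- function(profile, stats, params = simParams(),
                              surface = NULL,
                              negation = defaultKeywordGroups()$negationCue$cue) {
  if (!is.null(surface) &&
      any(vapply(negation, function(cue) length(cpFindAll(surface, cue)) > 0L,
                 logical(1))))
    return(stats::setNames(numeric(0), character(0)))
  if (length(profile) == 0L) return(stats::setNames(numeric(0), character(0)))
  cats <- names(profile)
  missing <- setdiff(cats, names(stats$docFreq))
  if (length(missing))
    stop("category missing from corpus stats: ",
         paste(missing, collapse = ", "))
  tf <- if (params$tfDenominator == "per_term") {
    profile / sum(profile)
  } else {
    profile / stats$catTotals[cats]
  }
  idf <- stats$totalDiagnoses / stats$docFreq[cats]
  if (params$logIdf) idf <- log(idf)
  w <- as.numeric(tf) * as.numeric(idf)
  stats::setNames(w, cats)
}

#' Cosine similarity of two sparse weight vectors
#'
#' @param v1,v2 Named numeric vectors (category -> weight). A zero-norm or
#'   empty vector yields 0.
#' @return A number in \[0, 1\].
#' @export
diagnosisSimilarity <- function(v1, v2) {
  if (length(v1) == 0L || length(v2) == 0L) return(0)
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) return(0)
  shared <- intersect(names(v1), names(v2))
  if (length(shared) == 0L) return(0)
  # clamp floating-point overshoot so downstream [0,1] contracts hold
  min(1, max(0, sum(v1[shared] * v2[shared]) / (n1 * n2)))
}

#' Hybrid similarity
#'
#' Combines literal and diagnosis-related similarity with weight `beta`:
#' arithmetic sum beta*ls + (1-beta)*ds, or quadratic sum
#' sqrt(beta*ls^2 + (1-beta)*ds^2).
#'
#' @param ls,ds Numbers in \[0, 1\].
#' @param params A [simParams()] object (fields beta, combiner).
#' @return A number in \[0, 1\].
#' @export
hybridSimilarity <- function(ls, ds, params = simParams()) {
  stopifnot(ls >= 0, ls <= 1, ds >= 0, ds <= 1)
  b <- params$beta
  if (params$combiner == "AS") b * ls + (1 - b) * ds
  else sqrt(b * ls^2 + (1 - b) * ds^2)
}
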