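# Concept mapping: every term is scored against every referenced-concept
# surface with the hybrid similarity and given a candidate queue in
# descending HS order for expert review, plus the rank diagnostics used to
# compare combiners and beta weights.

#' Build a ranked concept-candidate queue for one term
#'
#' Computes literal, diagnosis-related and hybrid similarity between the term
#' and every referenced concept, and returns the candidates sorted by hybrid
#' score descending (ties broken by concept surface).
#'
#' @param term Term surface (string).
#' @param concepts data.frame with columns surface, nomenclature, conceptCode.
#' @param profiles Named list of diagnosis profiles (surface -> named count
#'   vector) covering terms and concepts; surfaces without a profile get a
#'   zero diagnosis similarity.
#' @param stats A [buildCorpusStats()] result.
#' @param params A [simParams()] object.
#' @return A [MappingQueue-class].
#' @export
buildQueue <- function(term, concepts, profiles = list(), stats = NULL,
                       params = simParams()) {
  if (nrow(concepts) == 0L)
    return(new("MappingQueue", termSurface = term,
               candidates = data.frame(surface = character(0),
                                       nomenclature = character(0),
                                       conceptCode = character(0),
                                       ls = numeric(0), ds = numeric(0),
                                       hs = numeric(0),
                                       stringsAsFactors = FALSE)))
  vTerm <- if (!is.null(stats) && !is.null(profiles[[term]]))
    buildWeightVector(profiles[[term]], stats, params, surface = term)
  else stats::setNames(numeric(0), character(0))
  conceptVecs <- lapply(concepts$surface, function(s) {
    if (!is.null(stats) && !is.null(profiles[[s]]))
      buildWeightVector(profiles[[s]], stats, params, surface = s)
    else stats::setNames(numeric(0), character(0))
  })
  ls <- vapply(concepts$surface, literalSimilarity, numeric(1),
               s1 = term, params = params, USE.NAMES = FALSE)
  ds <- vapply(conceptVecs, diagnosisSimilarity, numeric(1), v1 = vTerm,
               USE.NAMES = FALSE)
  hs <- vapply(seq_along(ls), function(i)
    hybridSimilarity(ls[i], ds[i], params), numeric(1))
  cd <- data.frame(surface = concepts$surface,
                   nomenclature = concepts$nomenclature,
                   conceptCode = concepts$conceptCode,
                   ls = ls, ds = ds, hs = hs, stringsAsFactors = FALSE)
  cd <- cd[order(-cd$hs, cd$surface, method = "radix"), , drop = FALSE]
  rownames(cd) <- NULL
  new("MappingQueue", termSurface = term, candidates = cd)
}

#' Build queues for many terms
#'
#' @param terms Character vector of term surfaces.
#' @inheritParams buildQueue
#' @return Named list of [MappingQueue-class] objects.
#' @export
buildQueues <- function(terms, concepts, profiles = list(), stats = NULL,
                        params = simParams()) {
  stats::setNames(lapply(terms, buildQueue, concepts = concepts,
                         profiles = profiles, stats = stats, params = params),
                  terms)
}

#' Screen term-candidate pairs for review
#'
#' Returns every (term, candidate) pair whose hybrid score strictly exceeds
#' the review threshold, ordered by score descending, for export to human
#' review.
#'
#' @param queues List of [MappingQueue-class] objects.
#' @param reviewThreshold Strict HS threshold (default 0.3).
#' @return data.frame term, surface, nomenclature, conceptCode, ls, ds, hs.
#' @export
screenPairs <- function(queues, reviewThreshold = 0.3) {
  rows <- lapply(queues, function(q) {
    cd <- q@candidates
    cd <- cd[cd$hs > reviewThreshold, , drop = FALSE]
    if (nrow(cd)) cbind(term = q@termSurface, cd, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(term = character(0), surface = character(0),
                      nomenclature = character(0), conceptCode = character(0),
                      ls = numeric(0), ds = numeric(0), hs = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(-out$hs, out$term, out$surface, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a review list to TSV
#'
#' Columns `term<TAB>candidateSurface<TAB>nomenclature<TAB>conceptCode<TAB>
#' ls<TAB>ds<TAB>hs`, queues truncated at `top` candidates.
#'
#' @param queues List of [MappingQueue-class] objects.
#' @param path Output file.
#' @param top Queue truncation depth (default 20).
#' @export
exportQueues <- function(queues, path, top = 20L) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (q in queues) {
    cd <- utils::head(q@candidates, top)
    if (nrow(cd) == 0L) next
    writeLines(paste(q@termSurface, cd$surface, cd$nomenclature,
                     cd$conceptCode, format(cd$ls, digits = 6),
                     format(cd$ds, digits = 6), format(cd$hs, digits = 6),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Rank diagnostics against a gold mapping
#'
#' For each gold (term, true concept surface) pair, finds the 1-based
#' position of the true concept in the term's queue. A gold concept absent
#' from a queue counts at rank (queue length + 1). Reports the mean rank,
#' top-k coverage, and the fraction of candidate pairs in each HS bin that
#' are gold ("detection rate").
#'
#' @param queues Named list of [MappingQueue-class] objects (names = terms).
#' @param goldPairs Named character vector, term -> true concept surface.
#' @param ks Top-k levels for coverage (default 1, 5, 10, 20).
#' @param binWidth HS bin width for the detection-rate curve (default 0.01).
#' @return List with averageRank, topKCoverage, detectionRateByBin (data.frame
#'   bin, n, nGold, rate), ranks.
#' @export
rankMetrics <- function(queues, goldPairs, ks = c(1L, 5L, 10L, 20L),
                        binWidth = 0.01) {
  terms <- names(goldPairs)
  missing <- setdiff(terms, names(queues))
  if (length(missing))
    stop("no queue for gold term(s): ", paste(missing, collapse = ", "))
  ranks <- vapply(terms, function(tm) {
    cd <- queues[[tm]]@candidates
    pos <- match(goldPairs[[tm]], cd$surface)
    if (is.na(pos)) {
      message("gold concept absent from queue of ", tm,
              "; counted at rank ", nrow(cd) + 1L)
      nrow(cd) + 1L
    } else pos
  }, numeric(1))
  coverage <- vapply(ks, function(k) mean(ranks <= k), numeric(1))
  # detection rate per HS bin over all candidate pairs
  allHs <- numeric(0); allGold <- logical(0)
  for (tm in names(queues)) {
    cd <- queues[[tm]]@candidates
    if (nrow(cd) == 0L) next
    allHs <- c(allHs, cd$hs)
    gold <- if (tm %in% terms) cd$surface == goldPairs[[tm]]
            else rep(FALSE, nrow(cd))
    allGold <- c(allGold, gold)
  }
  bins <- pmin(floor(allHs / binWidth), floor(1 / binWidth) - 1)
  binDf <- if (length(allHs)) {
    agg <- tapply(allGold, bins, function(g) c(n = length(g), nGold = sum(g)))
    m <- do.call(rbind, agg)
    data.frame(bin = as.numeric(names(agg)) * binWidth,
               n = m[, "n"], nGold = m[, "nGold"],
               rate = m[, "nGold"] / m[, "n"], row.names = NULL)
  } else data.frame(bin = numeric(0), n = integer(0), nGold = integer(0),
                    rate = numeric(0))
  list(averageRank = mean(ranks),
       topKCoverage = stats::setNames(coverage, ks),
       detectionRateByBin = binDf,
       ranks = ranks)
}

#' Sweep the hybrid weight and combiner
#'
#' Rebuilds the queues at each (beta, combiner) grid point and reports the
#' mean gold rank, identifying the best cell.
#'
#' @param terms Character vector of term surfaces.
#' @param concepts,profiles,stats As in [buildQueue()].
#' @param goldPairs Named character vector, term -> true concept surface.
#' @param betaGrid Numeric vector in \[0, 1\].
#' @param combiners Subset of c("AS", "QS").
#' @param params Base [simParams()] whose beta/combiner are overridden.
#' @return data.frame (beta, combiner, averageRank) with attribute "best".
#' @export
sweepBeta <- function(terms, concepts, profiles, stats, goldPairs,
                      betaGrid = seq(0, 1, by = 0.1),
                      combiners = c("AS", "QS"), params = simParams()) {
  stopifnot(all(betaGrid >= 0 & betaGrid <= 1))
  grid <- expand.grid(beta = betaGrid, combiner = combiners,
                      stringsAsFactors = FALSE)
  grid$averageRank <- vapply(seq_len(nrow(grid)), function(i) {
    p <- params
    p$beta <- grid$beta[i]
    p$combiner <- grid$combiner[i]
    qs <- buildQueues(terms, concepts, profiles, stats, p)
    rankMetrics(qs, goldPairs)$averageRank
  }, numeric(1))
  best <- grid[which.min(grid$averageRank), , drop = FALSE]
  attr(grid, "best") <- best
  grid
}
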