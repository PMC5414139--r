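# Seeded synthetic corpus generator. Emulates, at desk scale, the corpus
# structure the pipeline consumes: a dictionary of finding terms built from a
# fixed body-part x sensation inventory, synonym groups planted on shared
# latent diagnosis distributions, chief complaints with duration suffixes,
# punctuation-joined impression diagnoses, and narrative clauses with
# modifiers, negation cues, aggregated surfaces and exception contexts, with
# gold spans. It makes no attempt at clinically realistic language; only the
# statistical and structural properties the algorithms rely on.

BODY_PARTS <- c("头", "颈", "肩", "腰", "背", "胸", "腹", "膝", "肘", "腕",
                "踝", "臀", "髋", "咽", "眼", "耳", "鼻", "腿")
SENSATIONS <- c("疼痛", "麻木", "肿胀", "无力", "瘙痒", "酸胀", "僵硬",
                "灼热", "抽搐", "发麻")

#' Generator configuration
#'
#' Defaults give a small but non-trivial corpus: 24 concepts with 3 synonyms
#' each over 40 diagnosis categories, 300 records per stream, moderate
#' modifier/negation rates, aggregations off (they are routed through
#' review), and low diagnosis-sampling noise.
#'
#' @param seed Integer RNG seed; identical seed + config reproduce the
#'   corpus exactly.
#' @param nConcepts,synonymsPerConcept,nDiagnosisCategories,nRecords Counts
#'   (nRecords applies to each of the CCC, CID and HPI streams).
#' @param modifierRate,negationRate,aggregationRate,durationRate,exceptionRate
#'   Per-clause probabilities.
#' @param dsNoise Dispersion of each term's diagnosis sampling around its
#'   concept's latent category distribution (0 = identical distributions).
#' @return List of class "GeneratorConfig".
#' @export
generatorConfig <- function(seed = 1L, nConcepts = 24L,
                            synonymsPerConcept = 3L,
                            nDiagnosisCategories = 40L, nRecords = 300L,
                            modifierRate = 0.15, negationRate = 0.15,
                            aggregationRate = 0, durationRate = 0.9,
                            exceptionRate = 0.05, dsNoise = 0.1) {
  probs <- c(modifierRate, negationRate, aggregationRate, durationRate,
             exceptionRate)
  stopifnot(all(probs >= 0 & probs <= 1), dsNoise >= 0,
            nConcepts >= 1, synonymsPerConcept >= 1,
            nDiagnosisCategories >= 3, nRecords >= 1,
            nConcepts <= length(BODY_PARTS) * length(SENSATIONS))
  structure(list(seed = as.integer(seed), nConcepts = as.integer(nConcepts),
                 synonymsPerConcept = as.integer(synonymsPerConcept),
                 nDiagnosisCategories = as.integer(nDiagnosisCategories),
                 nRecords = as.integer(nRecords),
                 modifierRate = modifierRate, negationRate = negationRate,
                 aggregationRate = aggregationRate,
                 durationRate = durationRate, exceptionRate = exceptionRate,
                 dsNoise = dsNoise),
            class = "GeneratorConfig")
}

sampleDuration <- function(lexicon) {
  num <- sample(c(as.character(1:9), "半"), 1L)
  unit <- sample(c("天", "月", "周", "年", "小时"), 1L)
  plus <- if (stats::runif(1) < 0.3) " + " else ""
  paste0(num, plus, unit)
}

synonymSurface <- function(body, sensation, variant, modifiers) {
  canonical <- paste0(body, "部", sensation)
  switch(((variant - 1L) %% 4L) + 1L,
         canonical,
         paste0(body, sensation),                                  # truncation
         paste0(body, "部", sample(modifiers, 1L), sensation),     # modifier in
         paste0(sample(modifiers, 1L), body, "部", sensation))     # modifier pre
}

#' Generate a synthetic gold corpus
#'
#' See [generatorConfig()] for the knobs. Synonyms of one concept share the
#' concept's latent diagnosis distribution (up to `dsNoise`); chief
#' complaints append duration phrases; impression diagnoses join concept
#' surfaces with punctuation; narrative records carry gold spans with
#' negation flags.
#'
#' @param config A [generatorConfig()].
#' @return A [GoldCorpus-class].
#' @export
generateCorpus <- function(config = generatorConfig()) {
  set.seed(config$seed)
  lexicon <- defaultKeywordLexicon()
  modifiers <- lexicon@modifier

  grid <- expand.grid(body = BODY_PARTS, sens = SENSATIONS,
                      stringsAsFactors = FALSE)
  grid <- grid[sample(nrow(grid), config$nConcepts), , drop = FALSE]

  catPool <- unique(paste0(sample(LETTERS, config$nDiagnosisCategories,
                                  replace = TRUE),
                           sprintf("%02d", sample(0:99,
                                                  config$nDiagnosisCategories,
                                                  replace = TRUE))))
  while (length(catPool) < config$nDiagnosisCategories)
    catPool <- unique(c(catPool, paste0(sample(LETTERS, 1L),
                                        sprintf("%02d", sample(0:99, 1L)))))

  concepts <- data.frame(
    surface = paste0(grid$body, "部", grid$sens),
    nomenclature = rep(c("SNOMED3_ZH", "ICD10_ZH"),
                       length.out = config$nConcepts),
    conceptCode = sprintf("C%04d", seq_len(config$nConcepts)),
    stringsAsFactors = FALSE)

  # latent diagnosis distribution per concept: 3 categories, fixed shape
  latent <- lapply(seq_len(config$nConcepts), function(i) {
    cats <- sample(catPool, 3L)
    stats::setNames(c(0.6, 0.3, 0.1), cats)
  })

  sampleProfile <- function(lat, noise) {
    p <- lat / sum(lat)
    if (noise > 0) {
      p <- p * (1 - noise) + noise * stats::runif(length(p))
      p <- p / sum(p)
    }
    counts <- as.integer(stats::rmultinom(1L, size = 60L, prob = p))
    keep <- counts > 0L
    stats::setNames(counts[keep], names(lat)[keep])
  }

  # synonym terms per concept
  termRows <- list(); mapRows <- list(); cooccur <- list()
  for (i in seq_len(config$nConcepts)) {
    for (v in seq_len(config$synonymsPerConcept)) {
      surf <- synonymSurface(grid$body[i], grid$sens[i], v, modifiers)
      termRows[[length(termRows) + 1L]] <- surf
      mapRows[[length(mapRows) + 1L]] <-
        data.frame(term = surf, conceptSurface = concepts$surface[i],
                   conceptCode = concepts$conceptCode[i],
                   stringsAsFactors = FALSE)
      prof <- sampleProfile(latent[[i]], config$dsNoise)
      cooccur[[length(cooccur) + 1L]] <-
        data.frame(termSurface = surf, icd3Category = names(prof),
                   count = as.numeric(prof), stringsAsFactors = FALSE)
    }
    prof <- sampleProfile(latent[[i]], config$dsNoise)
    cooccur[[length(cooccur) + 1L]] <-
      data.frame(termSurface = concepts$surface[i],
                 icd3Category = names(prof), count = as.numeric(prof),
                 stringsAsFactors = FALSE)
  }
  termSurfaces <- unique(unlist(termRows))
  conceptMap <- do.call(rbind, mapRows)
  conceptMap <- conceptMap[!duplicated(conceptMap$term), , drop = FALSE]

  extraTerms <- character(0)
  if (config$exceptionRate > 0) extraTerms <- c("高血压", "多尿")

  dict <- termDictionary(data.frame(
    surface = c(termSurfaces, extraTerms),
    frequency = 1L, source = "CCC", status = "VALID",
    stringsAsFactors = FALSE))

  # ---- CCC stream: term (+ duration), skewed term sampling ----
  termProb <- 1 / seq_along(termSurfaces)
  termProb <- termProb / sum(termProb)
  ccc <- character(config$nRecords)
  cccTally <- stats::setNames(integer(length(termSurfaces)), termSurfaces)
  for (r in seq_len(config$nRecords)) {
    k <- sample(1:2, 1L, prob = c(0.7, 0.3))
    tms <- sample(termSurfaces, k, prob = termProb)
    cccTally[tms] <- cccTally[tms] + 1L
    parts <- vapply(tms, function(tm) {
      if (stats::runif(1) < config$durationRate)
        paste0(tm, sampleDuration(lexicon))
      else tm
    }, "")
    ccc[r] <- paste(parts, collapse = "、")
  }

  # ---- CID stream: punctuation-joined concept surfaces ----
  cid <- vapply(seq_len(config$nRecords), function(r) {
    k <- sample(2:3, 1L)
    paste(sample(concepts$surface, k), collapse = "，")
  }, "")

  # ---- HPI stream with gold spans ----
  hpi <- character(config$nRecords)
  goldRows <- list()
  sensByTerm <- stats::setNames(rep(grid$sens, each = config$synonymsPerConcept),
                                unlist(termRows))
  for (r in seq_len(config$nRecords)) {
    nClause <- sample(2:4, 1L)
    text <- ""
    offset <- 0L
    addChunk <- function(s) {
      text <<- paste0(text, s)
      offset <<- offset + cpN(s)
    }
    if (stats::runif(1) < 0.5) addChunk("患者")
    for (cidx in seq_len(nClause)) {
      u <- stats::runif(1)
      if (config$exceptionRate > 0 && u < config$exceptionRate) {
        # exception context: contains a dictionary surface but no gold span
        addChunk(sample(c(paste0("最高血压1", sample(3:8, 1L), "0"),
                          "进入多尿期"), 1L))
      } else if (u < config$exceptionRate + config$aggregationRate &&
                 config$aggregationRate > 0) {
        # aggregated surface: two same-sensation terms, shared part elided
        sens <- sample(grid$sens, 1L)
        bodies <- sample(BODY_PARTS, 2L)
        agg <- paste0(bodies[1L], bodies[2L], "部", sens)
        goldRows[[length(goldRows) + 1L]] <-
          data.frame(recordId = r, start = offset,
                     end = offset + cpN(agg), surface = agg,
                     negated = FALSE, stringsAsFactors = FALSE)
        addChunk(agg)
      } else {
        tm <- sample(termSurfaces, 1L, prob = termProb)
        negated <- stats::runif(1) < config$negationRate
        surf <- tm
        if (stats::runif(1) < config$modifierRate &&
            length(cpFindAll(tm, "部")) > 0L &&
            !any(vapply(modifiers, function(m)
              length(cpFindAll(tm, m)) > 0L, logical(1)))) {
          # plant a modifier variant right after the first 部
          pos <- cpFindAll(tm, "部")[1L] + 1L
          surf <- paste0(cpSub(tm, 1L, pos), sample(modifiers, 1L),
                         cpSub(tm, pos + 1L, cpN(tm)))
        }
        if (negated) {
          side <- sample(c("pre", "post"), 1L)
          if (side == "pre") {
            cue <- sample(c("无", "否认", "不伴", "未"), 1L)
            addChunk(cue)
            goldRows[[length(goldRows) + 1L]] <-
              data.frame(recordId = r, start = offset,
                         end = offset + cpN(surf), surface = surf,
                         negated = TRUE, stringsAsFactors = FALSE)
            addChunk(surf)
          } else {
            goldRows[[length(goldRows) + 1L]] <-
              data.frame(recordId = r, start = offset,
                         end = offset + cpN(surf), surface = surf,
                         negated = TRUE, stringsAsFactors = FALSE)
            addChunk(surf)
            addChunk(sample(c("消失", "不明显"), 1L))
          }
        } else {
          goldRows[[length(goldRows) + 1L]] <-
            data.frame(recordId = r, start = offset,
                       end = offset + cpN(surf), surface = surf,
                       negated = FALSE, stringsAsFactors = FALSE)
          addChunk(surf)
          if (stats::runif(1) < config$durationRate * 0.5)
            addChunk(sampleDuration(lexicon))
        }
      }
      addChunk(if (cidx < nClause) "，" else "。")
    }
    hpi[r] <- text
  }
  goldSpans <- if (length(goldRows)) do.call(rbind, goldRows) else
    data.frame(recordId = integer(0), start = integer(0), end = integer(0),
               surface = character(0), negated = logical(0),
               stringsAsFactors = FALSE)

  new("GoldCorpus", dictionary = dict, concepts = concepts,
      conceptMap = conceptMap, ccc = ccc, cid = cid, hpi = hpi,
      goldSpans = goldSpans, diagCooccur = do.call(rbind, cooccur),
      cccTally = cccTally, config = unclass(config))
}

#' Write all corpus artefacts to a directory
#'
#' Emits the on-disk formats the other modules read: dictionary TSV, concept
#' TSV, co-occurrence TSV, one-record-per-line CCC/CID/HPI text files, gold
#' span TSV and gold BIEO CoNLL file.
#'
#' @param corpus A [GoldCorpus-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
writeCorpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(dictionary = file.path(dir, "dictionary.tsv"),
             concepts = file.path(dir, "concepts.tsv"),
             cooccur = file.path(dir, "cooccur.tsv"),
             ccc = file.path(dir, "ccc.txt"),
             cid = file.path(dir, "cid.txt"),
             hpi = file.path(dir, "hpi.txt"),
             goldSpans = file.path(dir, "gold_spans.tsv"),
             goldBieo = file.path(dir, "gold.conll"))
  saveTermDictionary(corpus@dictionary, paths[["dictionary"]])
  writeUtf8 <- function(lines, path) {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(lines, con)
  }
  cc <- corpus@concepts
  writeUtf8(paste(cc$surface, cc$nomenclature, cc$conceptCode, sep = "\t"),
            paths[["concepts"]])
  dc <- corpus@diagCooccur
  writeUtf8(paste(dc$termSurface, dc$icd3Category, dc$count, sep = "\t"),
            paths[["cooccur"]])
  writeUtf8(corpus@ccc, paths[["ccc"]])
  writeUtf8(corpus@cid, paths[["cid"]])
  writeUtf8(corpus@hpi, paths[["hpi"]])
  gs <- corpus@goldSpans
  writeUtf8(paste(gs$recordId, gs$start, gs$end, gs$surface,
                  as.integer(gs$negated), "GOLD", sep = "\t"),
            paths[["goldSpans"]])
  tagged <- lapply(seq_along(corpus@hpi), function(r) {
    spans <- gs[gs$recordId == r, , drop = FALSE]
    spans$origin <- "GOLD"
    spansToBieo(corpus@hpi[r], spans)
  })
  exportBieo(tagged, paths[["goldBieo"]])
  invisible(paths)
}
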