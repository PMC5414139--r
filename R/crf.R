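# CRF featurisation pipeline. Parameter estimation itself is delegated to an
# external linear-chain CRF engine: this module produces the engine's inputs
# (CoNLL-style tab-separated training files and a feature template), the
# chi-square associative-strength table, the greedy forward feature
# selection procedure, and the decoding of predicted tag sequences back to
# spans.

SENTINEL <- "_NULL_"
CHI_SQUARE_THRESHOLD <- 3.841

#' CRF feature configuration
#'
#' @param cws Context window size, 0-4: how many characters on each side of
#'   the target character the template exposes.
#' @param ngrams Subset of c("U","B","T","Q") (unigram/bigram/trigram/
#'   quadgram columns); "U" must be present whenever any n-gram is enabled.
#' @param stopChar,currentWord,contextWord,pos,assocStrength Feature toggles.
#' @return List of class "FeatureConfig".
#' @export
featureConfig <- function(cws = 2L, ngrams = c("U", "B", "T"),
                          stopChar = FALSE, currentWord = FALSE,
                          contextWord = FALSE, pos = FALSE,
                          assocStrength = FALSE) {
  stopifnot(cws >= 0L, cws <= 4L, all(ngrams %in% c("U", "B", "T", "Q")))
  if (length(ngrams) && !"U" %in% ngrams)
    stop("'U' must be enabled whenever any n-gram feature is on")
  structure(list(cws = as.integer(cws), ngrams = ngrams,
                 stopChar = stopChar, currentWord = currentWord,
                 contextWord = contextWord, pos = pos,
                 assocStrength = assocStrength),
            class = "FeatureConfig")
}

featureColumns <- function(config) {
  cols <- "char"
  for (g in c("U", "B", "T", "Q")) if (g %in% config$ngrams)
    cols <- c(cols, paste0("ngram", g))
  if (config$stopChar) cols <- c(cols, "stopFlag")
  if (config$currentWord) cols <- c(cols, "word")
  if (config$pos) cols <- c(cols, "pos")
  if (config$contextWord) cols <- c(cols, "prevWord", "nextWord")
  if (config$assocStrength) cols <- c(cols, "assocFlag")
  cols
}

#' Character-level tokenizer adapter
#'
#' The trivial TokenizerAdapter: every code point is its own word with POS
#' tag "x". Adapters are functions text -> data.frame(word, pos) whose words
#' concatenate back to the text.
#'
#' @return A tokenizer function.
#' @export
characterTokenizer <- function() {
  function(text) {
    ch <- cpChars(text)
    data.frame(word = ch, pos = rep("x", length(ch)),
               stringsAsFactors = FALSE)
  }
}

#' Dictionary maximal-matching tokenizer adapter
#'
#' Greedy forward maximal matching against a word list; unknown characters
#' become single-character words. Dictionary words get POS "n", the rest "x".
#'
#' @param words Character vector of known words.
#' @param maxLen Longest match attempted.
#' @return A tokenizer function.
#' @export
maxMatchTokenizer <- function(words, maxLen = 8L) {
  wset <- new.env(parent = emptyenv(), hash = TRUE)
  for (w in words) assign(enc2utf8(w), TRUE, envir = wset)
  function(text) {
    ch <- cpChars(text)
    n <- length(ch)
    out <- list()
    i <- 1L
    while (i <= n) {
      hit <- 1L; isWord <- FALSE
      for (L in seq(min(maxLen, n - i + 1L), 1L)) {
        cand <- paste(ch[i:(i + L - 1L)], collapse = "")
        if (exists(cand, envir = wset, inherits = FALSE)) {
          hit <- L; isWord <- TRUE; break
        }
      }
      out[[length(out) + 1L]] <-
        c(paste(ch[i:(i + hit - 1L)], collapse = ""),
          if (isWord) "n" else "x")
      i <- i + hit
    }
    data.frame(word = vapply(out, `[`, "", 1L),
               pos = vapply(out, `[`, "", 2L), stringsAsFactors = FALSE)
  }
}

#' Chi-square test of adjacency between two words
#'
#' X^2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)) over the 2x2 adjacency table
#' a = #(w1 then w2), b = #(w1 then not-w2), c = #(not-w1 then w2),
#' d = #(neither). No continuity correction: 3.841 is the uncorrected
#' df = 1, alpha = 0.05 critical value. Two adjacent words are considered
#' combined only if X^2 exceeds that threshold.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @param threshold Critical value (default 3.841).
#' @return list(statistic, combined).
#' @export
chiSquareAdjacent <- function(a, b, c, d, threshold = CHI_SQUARE_THRESHOLD) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n <- a + b + c + d
  stopifnot(n > 0)
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) {
    warning("zero marginal in adjacency table; statistic set to 0")
    return(list(statistic = 0, combined = FALSE))
  }
  stat <- n * (a * d - b * c)^2 / prod(marg)
  list(statistic = stat, combined = stat > threshold)
}

#' The chi-square critical value used by the association gate
#'
#' @param alpha Significance level (default 0.05).
#' @param df Degrees of freedom (default 1).
#' @return Upper critical value, e.g. 3.841 at the defaults (3 decimals).
#' @export
chiSquareCriticalValue <- function(alpha = 0.05, df = 1) {
  stats::qchisq(1 - alpha, df)
}

#' Build the word-adjacency association table of a tokenised corpus
#'
#' Tallies adjacent word pairs across records and gates each observed pair
#' with [chiSquareAdjacent()].
#'
#' @param tokenLists List of character vectors (one tokenised record each).
#' @param threshold Chi-square critical value.
#' @return data.frame (w1, w2, a, chisq, combined).
#' @export
buildAssocTable <- function(tokenLists, threshold = CHI_SQUARE_THRESHOLD) {
  pairs <- list()
  for (toks in tokenLists) {
    if (length(toks) >= 2L)
      pairs[[length(pairs) + 1L]] <-
        data.frame(w1 = toks[-length(toks)], w2 = toks[-1L],
                   stringsAsFactors = FALSE)
  }
  if (length(pairs) == 0L)
    return(data.frame(w1 = character(0), w2 = character(0), a = integer(0),
                      chisq = numeric(0), combined = logical(0),
                      stringsAsFactors = FALSE))
  allPairs <- do.call(rbind, pairs)
  N <- nrow(allPairs)
  key <- paste(allPairs$w1, allPairs$w2, sep = "\r")
  aTab <- table(key)
  w1Tab <- table(allPairs$w1)
  w2Tab <- table(allPairs$w2)
  uk <- names(aTab)
  parts <- strsplit(uk, "\r", fixed = TRUE)
  w1 <- vapply(parts, `[`, "", 1L)
  w2 <- vapply(parts, `[`, "", 2L)
  a <- as.integer(aTab)
  b <- as.integer(w1Tab[w1]) - a
  c_ <- as.integer(w2Tab[w2]) - a
  d <- N - a - b - c_
  res <- lapply(seq_along(a), function(i)
    suppressWarnings(chiSquareAdjacent(a[i], b[i], c_[i], d[i], threshold)))
  data.frame(w1 = w1, w2 = w2, a = a,
             chisq = vapply(res, `[[`, numeric(1), "statistic"),
             combined = vapply(res, `[[`, logical(1), "combined"),
             stringsAsFactors = FALSE)
}

#' Featurise one record for the CRF engine
#'
#' Emits one row per code point with columns in fixed order: the character;
#' the n-gram ending at the character for each enabled n; the stop-character
#' flag; the current word and its POS; the neighbouring words; the
#' association flag of the word pair straddling the boundary after the
#' character (1 when the pair is chi-square combined, 0 when not, sentinel
#' inside a word). Absent values carry the sentinel `_NULL_`.
#'
#' @param text Record text.
#' @param config A [featureConfig()].
#' @param adapter Tokenizer adapter (required when word features are on).
#' @param assocTable A [buildAssocTable()] result (for assocStrength).
#' @param stopChars Character vector of stop characters (for stopChar).
#' @param goldTags Optional BIEO tag vector, appended as the last column.
#' @return data.frame, one row per code point ("FeatureTable").
#' @export
featurize <- function(text, config = featureConfig(), adapter = NULL,
                      assocTable = NULL, stopChars = NULL, goldTags = NULL) {
  ch <- cpChars(text)
  n <- length(ch)
  tab <- data.frame(char = ch, stringsAsFactors = FALSE)
  sizes <- c(U = 1L, B = 2L, T = 3L, Q = 4L)
  for (g in c("U", "B", "T", "Q")) {
    if (!g %in% config$ngrams) next
    k <- sizes[[g]]
    tab[[paste0("ngram", g)]] <- vapply(seq_len(n), function(i) {
      if (i < k) SENTINEL
      else paste(ch[(i - k + 1L):i], collapse = "")
    }, "")
  }
  if (config$stopChar) {
    sc <- stopChars %||% defaultKeywordGroups()$stopChar
    tab$stopFlag <- as.character(as.integer(ch %in% sc))
  }
  needWords <- config$currentWord || config$contextWord || config$pos ||
    config$assocStrength
  if (needWords) {
    if (is.null(adapter)) stop("word features require a tokenizer adapter")
    toks <- adapter(text)
    if (paste(toks$word, collapse = "") != paste(ch, collapse = ""))
      stop("tokenizer output does not cover the text exactly")
    wlen <- vapply(toks$word, cpN, integer(1))
    wordOf <- rep(seq_len(nrow(toks)), wlen)  # char index -> token index
    if (config$currentWord) tab$word <- toks$word[wordOf]
    if (config$pos) tab$pos <- toks$pos[wordOf]
    if (config$contextWord) {
      prevIdx <- wordOf - 1L
      nextIdx <- wordOf + 1L
      tab$prevWord <- ifelse(prevIdx >= 1L, toks$word[pmax(prevIdx, 1L)],
                             SENTINEL)
      tab$nextWord <- ifelse(nextIdx <= nrow(toks),
                             toks$word[pmin(nextIdx, nrow(toks))], SENTINEL)
    }
    if (config$assocStrength) {
      combinedKey <- if (!is.null(assocTable) && nrow(assocTable))
        paste(assocTable$w1, assocTable$w2, sep = "\r")[assocTable$combined]
      else character(0)
      wordEnd <- cumsum(wlen)  # char index of each token's last char
      tab$assocFlag <- vapply(seq_len(n), function(i) {
        ti <- wordOf[i]
        if (i == wordEnd[ti] && ti < nrow(toks)) {
          pairKey <- paste(toks$word[ti], toks$word[ti + 1L], sep = "\r")
          as.character(as.integer(pairKey %in% combinedKey))
        } else SENTINEL
      }, "")
    }
  }
  if (!is.null(goldTags)) {
    if (length(goldTags) != n) stop("goldTags length must match text length")
    tab$tag <- goldTags
  }
  tab
}

#' Emit a CRF training/decoding file
#'
#' Tab-separated columns, blank line between records; the last column of a
#' training table is the gold tag. All tables must share one column schema.
#'
#' @param tables List of [featurize()] results.
#' @param path Output file.
#' @param requireTags Require a gold tag column (training emission).
#' @export
emitTrainingFile <- function(tables, path, requireTags = TRUE) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(tables) == 0L) {
    warning("no feature tables; emitting empty file")
    return(invisible(path))
  }
  schema <- names(tables[[1L]])
  for (k in seq_along(tables)) {
    tb <- tables[[k]]
    if (!identical(names(tb), schema))
      stop("ragged feature tables: record ", k, " has a different schema")
    if (requireTags && !"tag" %in% names(tb))
      stop("training emission requires gold tags")
    writeLines(do.call(paste, c(unname(as.list(tb)), sep = "\t")), con)
    if (k < length(tables)) writeLines("", con)
  }
  invisible(path)
}

#' Emit a feature template for the external CRF engine
#'
#' One unigram-feature rule `U<id>:%x[row,col]` per feature column and
#' offset -cws..cws, plus the engine's bigram transition rule `B`.
#'
#' @param config A [featureConfig()].
#' @param path Output file.
#' @export
emitTemplate <- function(config, path) {
  cols <- featureColumns(config)
  lines <- character(0)
  id <- 0L
  for (colIdx in seq_along(cols) - 1L) {
    for (off in seq(-config$cws, config$cws)) {
      lines <- c(lines, sprintf("U%02d:%%x[%d,%d]", id, off, colIdx))
      id <- id + 1L
    }
  }
  lines <- c(lines, "", "B")
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Greedy forward feature selection
#'
#' Round 1 evaluates each candidate toggle alone on the baseline and sorts
#' the candidates by F-score gain descending; the sorted candidates are then
#' added sequentially, each retained only if it strictly increases the
#' running F-score. Every evaluated configuration is logged.
#'
#' @param baseline A [featureConfig()].
#' @param candidates Character vector of toggle names (subset of "stopChar",
#'   "currentWord", "contextWord", "pos", "assocStrength").
#' @param trainEval Callback config -> F-score (deterministic for a fixed
#'   seed).
#' @return list(bestConfig, bestF, roundLog = data.frame(round, added,
#'   retained, fscore)).
#' @export
greedyFeatureSelection <- function(baseline, candidates, trainEval) {
  toggles <- c("stopChar", "currentWord", "contextWord", "pos",
               "assocStrength")
  stopifnot(all(candidates %in% toggles))
  withToggle <- function(cfg, nm) { cfg[[nm]] <- TRUE; cfg }
  baseF <- trainEval(baseline)
  log <- data.frame(round = 0L, added = "(baseline)", retained = TRUE,
                    fscore = baseF, stringsAsFactors = FALSE)
  gains <- vapply(candidates, function(nm) {
    f <- trainEval(withToggle(baseline, nm))
    log <<- rbind(log, data.frame(round = 1L, added = nm, retained = NA,
                                  fscore = f, stringsAsFactors = FALSE))
    f - baseF
  }, numeric(1))
  ordered <- candidates[order(-gains)]
  current <- baseline
  currentF <- baseF
  round <- 1L
  for (nm in ordered) {
    round <- round + 1L
    cand <- withToggle(current, nm)
    f <- trainEval(cand)
    keep <- f > currentF
    log <- rbind(log, data.frame(round = round, added = nm, retained = keep,
                                 fscore = f, stringsAsFactors = FALSE))
    if (keep) { current <- cand; currentF <- f }
  }
  list(bestConfig = current, bestF = currentF, roundLog = log)
}

#' Decode a predicted tag sequence to spans
#'
#' Maximal B(I)*E runs (and lone B) become spans. Malformed runs are repaired
#' by the longest-valid-prefix rule: an unclosed B(I)* run is closed at its
#' last tagged character and logged; an I or E with no open run is treated
#' as O and logged.
#'
#' @param characters Character vector of code points.
#' @param predictedTags Tag vector of equal length.
#' @return data.frame of spans (start, end, surface, negated, origin = "CRF").
#' @export
decodeTags <- function(characters, predictedTags) {
  if (length(characters) != length(predictedTags))
    stop("characters and predictedTags must have equal length")
  n <- length(characters)
  spans <- emptySpans()
  open <- NA_integer_
  closeRun <- function(s, e, repaired) {
    surf <- paste(characters[(s + 1L):e], collapse = "")
    if (repaired) message("repaired unclosed span at ", s, "-", e)
    makeSpans(s, e, surf, origin = "CRF")
  }
  i <- 1L
  while (i <= n) {
    t <- predictedTags[i]
    if (t == "B") {
      # a lone B is a valid single-character span; a longer unclosed run is
      # repaired at its last tagged character
      if (!is.na(open))
        spans <- rbind(spans, closeRun(open, i - 1L, (i - 1L - open) > 1L))
      open <- i - 1L
      if (i == n) { spans <- rbind(spans, closeRun(open, i, FALSE)); open <- NA_integer_ }
    } else if (t == "I") {
      if (is.na(open)) message("stray I at position ", i - 1L, " treated as O")
      else if (i == n) { spans <- rbind(spans, closeRun(open, i, TRUE)); open <- NA_integer_ }
    } else if (t == "E") {
      if (is.na(open)) message("stray E at position ", i - 1L, " treated as O")
      else { spans <- rbind(spans, closeRun(open, i, FALSE)); open <- NA_integer_ }
    } else { # O
      if (!is.na(open)) {
        spans <- rbind(spans, closeRun(open, i - 1L, (i - 1L - open) > 1L))
        open <- NA_integer_
      }
    }
    i <- i + 1L
  }
  rownames(spans) <- NULL
  spans
}
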